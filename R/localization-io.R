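#' Localization tables
#'
#' The raw currency of SMLM: one row per localized signal with the camera
#' `frame` (integer >= 0), the fitted 3D position `x`, `y`, `z` in nm and the
#' localization `accuracy` (the fit's standard deviation in the focal plane)
#' in nm. The table carries an axis-aligned region of interest (`roi`, a box
#' as in [as_box()]) and the camera pixel size in nm (default 160), which
#' drives per-frame merging.
#'
#' @param records Data frame with columns `frame`, `x`, `y`, `z`, `accuracy`.
#' @param roi Optional box; defaults to the record extent.
#' @param camera_pixel_nm Camera pixel size, nm.
#' @return An object of class `loc_table` (a data frame with attributes).
#' @export
localization_table <- function(records, roi = NULL, camera_pixel_nm = 160) {
  need <- c("frame", "x", "y", "z", "accuracy")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[need]
  n <- nrow(records)
  if (n > 0L) {
    if (!all(is.finite(as.matrix(records[c("x", "y", "z")]))))
      stop("coordinates must be finite")
    if (any(records$accuracy <= 0, na.rm = FALSE) ||
        any(!is.finite(records$accuracy)))
      stop("accuracy must be finite and > 0")
    if (any(records$frame < 0)) stop("frames must be >= 0")
  }
  if (is.null(roi)) {
    roi <- if (n == 0L) as_box(c(1, 1, 1)) else
      as_box(rbind(min = c(min(records$x), min(records$y), min(records$z)),
                   max = c(max(records$x), max(records$y),
                           max(records$z)) + 1e-9))
  } else roi <- as_box(roi)
  structure(records, roi = roi, camera_pixel_nm = camera_pixel_nm,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table: %d signals, frames %s, pixel %g nm\n",
              nrow(x),
              if (nrow(x)) paste(range(x$frame), collapse = "-") else "-",
              attr(x, "camera_pixel_nm")))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

loc_dialects <- list(
  minimal = c(frame = "^frame$", x = "^x$", y = "^y$", z = "^z$",
              accuracy = "^accuracy$"),
  thunderstorm = c(frame = "^frame$", x = "^x \\[nm\\]$", y = "^y \\[nm\\]$",
                   z = "^z \\[nm\\]$", accuracy = "^uncertainty.* \\[nm\\]$")
)

#' Read a localization table from CSV
#'
#' Two comma-separated dialects are supported, both with nm units and `.`
#' decimals: `"minimal"` (header `frame,x,y,z,accuracy`) and
#' `"thunderstorm"` (headers `"frame"`, `"x [nm]"`, `"y [nm]"`, `"z [nm]"`,
#' `"uncertainty [nm]"`, extra columns ignored). Rows with missing
#' coordinates are rejected and counted (attribute `n_rejected`, plus a
#' message); a non-numeric coordinate is a parse error reporting the file
#' line.
#'
#' @param path CSV file path.
#' @param dialect `"minimal"` or `"thunderstorm"`.
#' @param camera_pixel_nm Camera pixel size, nm.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("minimal", "thunderstorm"),
                               camera_pixel_nm = 160) {
  if (length(dialect) == 1L && !dialect %in% names(loc_dialects))
    stop(sprintf("unknown dialect '%s' (use %s)", dialect,
                 paste(names(loc_dialects), collapse = " or ")))
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  map <- loc_dialects[[dialect]]
  cols <- lapply(map, function(rx) {
    hit <- grep(rx, names(raw))
    if (length(hit) != 1L)
      stop(sprintf("dialect '%s': expected exactly one column matching %s",
                   dialect, rx))
    hit
  })
  df <- data.frame(lapply(cols, function(j) raw[[j]]),
                   stringsAsFactors = FALSE)
  num <- lapply(df, function(v) suppressWarnings(as.numeric(v)))
  for (nm in names(num)) {
    bad <- is.na(num[[nm]]) & !is.na(df[[nm]]) & trimws(df[[nm]]) != "" &
      toupper(trimws(df[[nm]])) != "NA"
    if (any(bad))
      stop(sprintf("non-numeric value in column '%s' at file line %d: '%s'",
                   nm, which(bad)[1L] + 1L, df[[nm]][which(bad)[1L]]))
  }
  df <- as.data.frame(num)
  miss <- !stats::complete.cases(df[c("x", "y", "z")])
  if (any(miss))
    message(sum(miss), " row(s) with missing coordinates rejected")
  tab <- localization_table(df[!miss, , drop = FALSE],
                            camera_pixel_nm = camera_pixel_nm)
  attr(tab, "n_rejected") <- sum(miss)
  tab
}

#' Write a localization table as CSV
#'
#' Canonical fields are written at 0.01 nm precision, making the
#' read/write round trip lossless at that precision.
#'
#' @param table A [localization_table()].
#' @param path File path.
#' @param dialect Output dialect, `"minimal"` or `"thunderstorm"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("minimal", "thunderstorm")) {
  dialect <- match.arg(dialect)
  df <- data.frame(frame = table$frame,
                   x = sprintf("%.2f", table$x),
                   y = sprintf("%.2f", table$y),
                   z = sprintf("%.2f", table$z),
                   accuracy = sprintf("%.2f", table$accuracy))
  if (dialect == "thunderstorm")
    names(df) <- c("frame", "x [nm]", "y [nm]", "z [nm]", "uncertainty [nm]")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge repeated per-frame detections of the same molecule
#'
#' Signals falling in the same camera pixel (`pixel_nm` square, grid anchored
#' at the ROI minimum corner) in consecutive frames are taken to come from
#' one molecule and merged: maximal runs with frame increments of exactly 1
#' collapse to a single record at the inverse-variance-weighted mean position
#' (z averaged with the same weights), with quadrature-combined accuracy
#' `sigma = (sum sigma_k^-2)^-1/2` and the first frame of the run.
#'
#' @param table A [localization_table()].
#' @param pixel_nm Merge pixel size, nm; defaults to the table's camera
#'   pixel.
#' @return A merged [localization_table()].
#' @export
merge_consecutive <- function(table, pixel_nm = NULL) {
  stopifnot(inherits(table, "loc_table"))
  if (is.null(pixel_nm)) pixel_nm <- attr(table, "camera_pixel_nm")
  stopifnot(pixel_nm > 0)
  if (nrow(table) == 0L) return(table)
  roi <- attr(table, "roi")
  cx <- floor((table$x - roi["min", "x"]) / pixel_nm)
  cy <- floor((table$y - roi["min", "y"]) / pixel_nm)
  ord <- order(cx, cy, table$frame)
  d <- as.data.frame(table)[ord, ]
  cx <- cx[ord]; cy <- cy[ord]
  new_run <- c(TRUE, diff(cx) != 0 | diff(cy) != 0 | diff(d$frame) != 1L)
  run <- cumsum(new_run)
  w <- 1 / d$accuracy^2
  sw <- tapply(w, run, sum)
  merged <- data.frame(
    frame = as.integer(tapply(d$frame, run, function(f) f[1L])),
    x = tapply(w * d$x, run, sum) / sw,
    y = tapply(w * d$y, run, sum) / sw,
    z = tapply(w * d$z, run, sum) / sw,
    accuracy = 1 / sqrt(sw))
  merged <- merged[order(merged$frame, merged$x, merged$y), ]
  rownames(merged) <- NULL
  localization_table(merged, roi = roi,
                     camera_pixel_nm = attr(table, "camera_pixel_nm"))
}

# 2D count histogram of (x, y) on a fixed grid; used by drift estimation
hist2d <- function(x, y, roi, bin_nm) {
  nx <- max(1L, ceiling((roi["max", "x"] - roi["min", "x"]) / bin_nm))
  ny <- max(1L, ceiling((roi["max", "y"] - roi["min", "y"]) / bin_nm))
  ix <- pmin(pmax(floor((x - roi["min", "x"]) / bin_nm), 0), nx - 1L)
  iy <- pmin(pmax(floor((y - roi["min", "y"]) / bin_nm), 0), ny - 1L)
  m <- matrix(0, nx, ny)
  tab <- table(iy * nx + ix) # column-major linear index
  m[as.integer(names(tab)) + 1L] <- as.integer(tab)
  m
}

# subpixel peak of a cross-correlation surface by 3-point parabola per axis
xcorr_shift <- function(a, b) {
  # linear cross-correlation of equally sized matrices via zero-padded FFT;
  # returns the shift (in bins) that maps b onto a
  nr <- nrow(a); nc <- ncol(a)
  pa <- matrix(0, 2L * nr, 2L * nc); pa[1:nr, 1:nc] <- a
  pb <- matrix(0, 2L * nr, 2L * nc); pb[1:nr, 1:nc] <- b
  cc <- Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  refine <- function(im, i, n) {
    g <- function(k) im[((k - 1) %% n) + 1L]
    p0 <- g(i); pm <- g(i - 1L); pp <- g(i + 1L)
    den <- pm - 2 * p0 + pp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (pm - pp) / den))
  }
  di <- refine(cc[, pk[2L]], pk[1L], 2L * nr)
  dj <- refine(cc[pk[1L], ], pk[2L], 2L * nc)
  sh <- c(pk[1L] - 1L + di, pk[2L] - 1L + dj)
  sh[1L] <- if (sh[1L] > nr) sh[1L] - 2 * nr else sh[1L]
  sh[2L] <- if (sh[2L] > nc) sh[2L] - 2 * nc else sh[2L]
  sh
}

stack_of <- function(frames, boundaries) {
  s <- findInterval(frames, boundaries)
  if (any(s == 0L))
    stop("record frames precede the first stack boundary")
  s
}

#' Estimate xy drift between z stacks
#'
#' The acquisition proceeds stack by stack; slow stage drift shifts later
#' stacks laterally. Two estimators are provided. `"autocorrelation"`
#' renders each stack as a 2D count histogram (`bin_nm` bins) and locates the
#' cross-correlation peak against the first stack with subpixel (parabolic)
#' refinement. `"fiducial"` tracks the centroid of a user-marked bright
#' cluster (within `fiducial_radius` of `fiducial`) per stack.
#'
#' @param table A [localization_table()].
#' @param stack_boundaries Increasing vector of each stack's first frame.
#' @param method `"autocorrelation"` or `"fiducial"`.
#' @param bin_nm Histogram bin for the autocorrelation method, nm.
#' @param fiducial Length-2 xy position (nm) of the marked cluster.
#' @param fiducial_radius Search radius around `fiducial`, nm.
#' @return A `drift_track`: data frame with `stack`, `start_frame`, `dx`,
#'   `dy` (nm, relative to the first stack, whose vector is zero), with the
#'   boundaries and method as attributes.
#' @export
estimate_drift <- function(table, stack_boundaries,
                           method = c("autocorrelation", "fiducial"),
                           bin_nm = 20, fiducial = NULL,
                           fiducial_radius = 250) {
  method <- match.arg(method)
  stopifnot(inherits(table, "loc_table"), length(stack_boundaries) >= 1L,
            !is.unsorted(stack_boundaries, strictly = TRUE))
  ns <- length(stack_boundaries)
  s <- stack_of(table$frame, stack_boundaries)
  empty <- setdiff(seq_len(ns), unique(s))
  track <- data.frame(stack = seq_len(ns), start_frame = stack_boundaries,
                      dx = 0, dy = 0)
  if (ns < 2L) {
    warning("fewer than 2 stacks; returning a zero drift track")
    return(structure(track, boundaries = stack_boundaries, method = method,
                     class = c("drift_track", "data.frame")))
  }
  if (length(empty) > 0L)
    stop("stack ", empty[1L], " contains no localizations")
  roi <- attr(table, "roi")
  if (method == "autocorrelation") {
    hists <- lapply(seq_len(ns), function(k)
      hist2d(table$x[s == k], table$y[s == k], roi, bin_nm))
    for (k in 2:ns) {
      sh <- xcorr_shift(hists[[k]], hists[[1L]])
      track$dx[k] <- sh[1L] * bin_nm
      track$dy[k] <- sh[2L] * bin_nm
    }
  } else {
    if (is.null(fiducial) || length(fiducial) != 2L)
      stop("method 'fiducial' needs a length-2 xy position in 'fiducial'")
    cent <- function(k, ref) {
      d2 <- (table$x[s == k] - ref[1L])^2 + (table$y[s == k] - ref[2L])^2
      keep <- d2 <= fiducial_radius^2
      if (!any(keep)) stop("no fiducial localizations in stack ", k)
      c(mean(table$x[s == k][keep]), mean(table$y[s == k][keep]))
    }
    c1 <- cent(1L, fiducial)
    for (k in 2:ns) {
      ck <- cent(k, c1)
      track$dx[k] <- ck[1L] - c1[1L]
      track$dy[k] <- ck[2L] - c1[2L]
    }
  }
  structure(track, boundaries = stack_boundaries, method = method,
            class = c("drift_track", "data.frame"))
}

#' Apply (subtract) a drift track
#'
#' Subtracts each record's stack drift vector from its xy position. Applying
#' a zero track is the identity; applying a track and then its negation
#' restores the original table.
#'
#' @param table A [localization_table()].
#' @param track A `drift_track` from [estimate_drift()] covering every stack
#'   present in the table.
#' @return The drift-corrected [localization_table()].
#' @export
apply_drift <- function(table, track) {
  stopifnot(inherits(table, "loc_table"), inherits(track, "drift_track"))
  s <- stack_of(table$frame, attr(track, "boundaries"))
  if (any(!s %in% track$stack))
    stop("drift track does not cover stack ", setdiff(s, track$stack)[1L])
  out <- as.data.frame(table)
  out$x <- out$x - track$dx[s]
  out$y <- out$y - track$dy[s]
  localization_table(out, roi = attr(table, "roi"),
                     camera_pixel_nm = attr(table, "camera_pixel_nm"))
}

#' Negate a drift track
#' @param track A `drift_track`.
#' @return The track with both displacement columns negated.
#' @export
negate_track <- function(track) {
  track$dx <- -track$dx
  track$dy <- -track$dy
  track
}

#' Extract a z slice of a localization table as a point pattern
#'
#' Keeps signals with z in the half-open slab
#' `[center_z - thickness/2, center_z + thickness/2)`, so that a tiling of
#' slabs partitions the table. The returned pattern's box is the table ROI in
#' xy and the slab in z.
#'
#' @param table A [localization_table()].
#' @param center_z Slab centre, nm.
#' @param thickness Slab thickness, nm (default 60).
#' @return A [point_pattern()].
#' @export
slice_z <- function(table, center_z, thickness = 60) {
  stopifnot(inherits(table, "loc_table"), thickness > 0)
  lo <- center_z - thickness / 2
  hi <- center_z + thickness / 2
  keep <- table$z >= lo & table$z < hi
  roi <- attr(table, "roi")
  box <- rbind(min = c(roi["min", "x"], roi["min", "y"], lo),
               max = c(roi["max", "x"], roi["max", "y"], hi))
  point_pattern(cbind(table$x, table$y, table$z)[keep, , drop = FALSE],
                box = box)
}

#' Convert a point pattern to a localization table
#'
#' Ground-truth patterns have no camera frames or fit uncertainties; frame is
#' set to 0 and `accuracy` to the model's focal-plane accuracy (or 1 if the
#' model accuracy is zero), which is what the rendering kernel needs.
#'
#' @param pattern A [point_pattern()].
#' @param accuracy Accuracy assigned to every signal, nm.
#' @return A [localization_table()].
#' @export
pattern_to_table <- function(pattern, accuracy = 20) {
  stopifnot(inherits(pattern, "point_pattern"))
  localization_table(
    data.frame(frame = 0L, x = pattern$coords[, 1L],
               y = pattern$coords[, 2L], z = pattern$coords[, 3L],
               accuracy = max(accuracy, 1e-6)),
    roi = pattern$box)
}
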