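#' Axis-aligned bounding box
#'
#' Boxes are 2 x 3 matrices (rows `min`, `max`; columns `x`, `y`, `z`) in nm.
#' `as_box()` accepts such a matrix, or a length-3 vector of box dimensions
#' which is anchored at the origin.
#'
#' @param box A 2 x 3 min/max matrix or a length-3 vector `c(x, y, z)` of
#'   dimensions in nm.
#' @return A validated 2 x 3 box matrix.
#' @examples
#' as_box(c(2000, 2000, 300))
#' @export
as_box <- function(box) {
  if (is.numeric(box) && is.null(dim(box)) && length(box) == 3L) {
    box <- rbind(min = c(0, 0, 0), max = as.numeric(box))
  }
  box <- as.matrix(box)
  if (!all(dim(box) == c(2L, 3L)))
    stop("a box must be a 2 x 3 min/max matrix or a length-3 dimension vector")
  dimnames(box) <- list(c("min", "max"), c("x", "y", "z"))
  if (!all(is.finite(box)) || any(box["max", ] <= box["min", ]))
    stop("box must be finite and nondegenerate (max > min on every axis)")
  box
}

box_sides <- function(box) box["max", ] - box["min", ]
box_volume <- function(box) prod(box_sides(box))

#' 3D point patterns
#'
#' A point pattern is a bag of 3D coordinates (nm) together with the
#' axis-aligned box in which it was generated or observed, and optionally a
#' per-point category label (`"sheet"` or `"free-dimer"` for simulated
#' patterns). Localization noise may displace points outside the box; such
#' points are kept — region selection is a separate, explicit step.
#'
#' @param coords Numeric n x 3 matrix of positions in nm (columns x, y, z).
#' @param box A box as accepted by [as_box()]; defaults to the coordinate
#'   range (or a unit box for an empty pattern).
#' @param labels Optional character vector of per-point categories.
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(coords, box = NULL, labels = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(coords) > 0L && !all(is.finite(coords)))
    stop("coordinates must be finite")
  if (is.null(box)) {
    box <- if (nrow(coords) == 0L) as_box(c(1, 1, 1)) else
      as_box(rbind(min = apply(coords, 2L, min),
                   max = apply(coords, 2L, max) + 1e-9))
  } else box <- as_box(box)
  if (!is.null(labels) && length(labels) != nrow(coords))
    stop("'labels' must have one entry per point")
  structure(list(coords = coords, box = box, labels = labels),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  s <- box_sides(x$box)
  cat(sprintf("3D point pattern: %d points in a %g x %g x %g nm box\n",
              n_points(x), s[1], s[2], s[3]))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Number of points in a pattern
#' @param pattern A [point_pattern()].
#' @return Integer count.
#' @export
n_points <- function(pattern) nrow(pattern$coords)

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  df <- as.data.frame(x$coords)
  if (!is.null(x$labels)) df$label <- x$labels
  df
}

subset_pattern <- function(pattern, keep) {
  point_pattern(pattern$coords[keep, , drop = FALSE], box = pattern$box,
                labels = if (is.null(pattern$labels)) NULL else
                  pattern$labels[keep])
}

#' Write / read a point pattern as CSV
#'
#' The on-disk form is the "minimal" localization dialect
#' (`frame,x,y,z,accuracy`, nm units, frame = 0, accuracy = NA for noise-free
#' ground truth) plus a `label` column when the pattern carries categories.
#' Leading lines starting with `#` are treated as comments on read.
#'
#' @param pattern A [point_pattern()].
#' @param path File path.
#' @param comments Optional character vector written as `# `-prefixed header
#'   lines (provenance).
#' @return `write_pattern_csv()` returns `path` invisibly;
#'   `read_pattern_csv()` returns a [point_pattern()].
#' @export
write_pattern_csv <- function(pattern, path, comments = NULL) {
  df <- data.frame(frame = 0L,
                   x = sprintf("%.4f", pattern$coords[, 1L]),
                   y = sprintf("%.4f", pattern$coords[, 2L]),
                   z = sprintf("%.4f", pattern$coords[, 3L]),
                   accuracy = NA_real_)
  if (!is.null(pattern$labels)) df$label <- pattern$labels
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste0("# box_min: ", paste(pattern$box["min", ], collapse = ",")),
             con)
  writeLines(paste0("# box_max: ", paste(pattern$box["max", ], collapse = ",")),
             con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"))
  box <- NULL
  gm <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) == 1L)
      as.numeric(strsplit(sub(paste0("^# ", key, ": "), "", ln), ",")[[1L]])
    else NULL
  }
  lo <- gm("box_min"); hi <- gm("box_max")
  if (!is.null(lo) && !is.null(hi)) box <- rbind(min = lo, max = hi)
  point_pattern(cbind(df$x, df$y, df$z), box = box, labels = df$label)
}
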