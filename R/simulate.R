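#' Simulate complete spatial randomness (CSR)
#'
#' Draws `n` points independently and uniformly in `box` — the homogeneous
#' Poisson (binomial) null used by the fold-increase statistic.
#'
#' @param n Number of points.
#' @param box Box as accepted by [as_box()].
#' @param seed Optional integer seed for reproducibility.
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(n, box, seed = NULL) {
  box <- as_box(box)
  stopifnot(n >= 0)
  with_seed(seed, {
    coords <- vapply(1:3, function(a)
      runif(n, box["min", a], box["max", a]), numeric(n))
    point_pattern(matrix(coords, ncol = 3L), box = box)
  })
}

# unit vectors at `theta` radians from +x in the xy-plane
xy_dir <- function(theta) cbind(cos(theta), sin(theta), 0)

#' Simulate a field of randomly placed, randomly oriented dimers
#'
#' Each dimer is a pair of labels exactly `dimer_label_distance` apart, with
#' its centre uniform in `box` and its orientation uniform in the xy-plane
#' (dimers lie on a membrane). No detection thinning or localization noise is
#' applied; see [thin_detection()] and [add_localization_noise()].
#'
#' @param n_dimers Number of dimers (the pattern has `2 * n_dimers` labels).
#' @inheritParams simulate_csr
#' @param params A [sheet_model_params()] object.
#' @return A [point_pattern()] with labels `"free-dimer"`.
#' @export
simulate_dimer_field <- function(n_dimers, box, params = sheet_model_params(),
                                 seed = NULL) {
  box <- as_box(box)
  stopifnot(n_dimers >= 0, inherits(params, "sheet_model_params"))
  with_seed(seed, {
    centres <- vapply(1:3, function(a)
      runif(n_dimers, box["min", a], box["max", a]), numeric(n_dimers))
    centres <- matrix(centres, ncol = 3L)
    u <- xy_dir(runif(n_dimers, 0, 2 * pi))
    h <- params$dimer_label_distance / 2
    coords <- rbind(centres + h * u, centres - h * u)
    # interleave so the two labels of dimer k are rows 2k-1, 2k
    idx <- as.vector(rbind(seq_len(n_dimers), n_dimers + seq_len(n_dimers)))
    point_pattern(coords[idx, , drop = FALSE], box = box,
                  labels = rep("free-dimer", 2L * n_dimers))
  })
}

#' Simulate one flat filamentous oligomer (FFO)
#'
#' A filament is a string of dimers: centres every `intra_filament_spacing` nm
#' along `axis_direction`, each dimer's label pair laid along a direction
#' tilted by `tilt` degrees from the filament axis within the sheet (xy)
#' plane, labels at centre +/- `dimer_label_distance / 2`. Deterministic.
#'
#' @param n_dimers Number of dimers in the filament (>= 1).
#' @param origin Length-3 position (nm) of the first dimer centre.
#' @param axis_direction Length-3 vector in the xy-plane giving the filament
#'   axis; normalized internally.
#' @param params A [sheet_model_params()] object.
#' @param tilt_sign `+1` or `-1`: side of the axis the dimer tilts towards
#'   (used for antiparallel packing).
#' @return A [point_pattern()] with labels `"sheet"`.
#' @export
simulate_ffo <- function(n_dimers, origin = c(0, 0, 0),
                         axis_direction = c(1, 0, 0),
                         params = sheet_model_params(), tilt_sign = 1) {
  stopifnot(n_dimers >= 1, length(origin) == 3L,
            inherits(params, "sheet_model_params"))
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) stop("'axis_direction' must be a nonzero vector")
  if (abs(axis_direction[3L]) > 1e-8 * nrm)
    stop("'axis_direction' must lie in the xy (sheet) plane")
  a <- axis_direction / nrm
  th <- tilt_sign * params$tilt * pi / 180
  u <- c(a[1L] * cos(th) - a[2L] * sin(th),
         a[1L] * sin(th) + a[2L] * cos(th), 0)
  k <- seq_len(n_dimers) - 1L
  centres <- matrix(origin, n_dimers, 3L, byrow = TRUE) +
    outer(k * params$intra_filament_spacing, a)
  h <- params$dimer_label_distance / 2
  off <- matrix(h * u, n_dimers, 3L, byrow = TRUE)
  coords <- rbind(centres + off, centres - off)
  idx <- as.vector(rbind(seq_len(n_dimers), n_dimers + seq_len(n_dimers)))
  point_pattern(coords[idx, , drop = FALSE],
                labels = rep("sheet", 2L * n_dimers))
}

# dimer centres + tilt directions of a rectangular sheet patch, centred at
# `centre`, filaments along +x. Returns list(centres, tilt_sign_per_dimer).
sheet_lattice <- function(n_sheet_dimers, centre, params) {
  sp <- params$intra_filament_spacing
  lat <- params$filament_lateral_spacing
  side <- sqrt(n_sheet_dimers * sp * lat)
  n_fil <- max(1L, as.integer(round(side / lat)))
  n_per <- as.integer(ceiling(n_sheet_dimers / n_fil))
  j <- rep(seq_len(n_fil) - 1L, each = n_per)[seq_len(n_sheet_dimers)]
  k <- rep(seq_len(n_per) - 1L, times = n_fil)[seq_len(n_sheet_dimers)]
  x <- (k - (n_per - 1) / 2) * sp
  y <- (j - (n_fil - 1) / 2) * lat
  centres <- cbind(centre[1L] + x, centre[2L] + y, centre[3L])
  sign <- if (params$alignment == "antiparallel") ifelse(j %% 2L == 0L, 1, -1)
          else rep(1, n_sheet_dimers)
  list(centres = centres, tilt_sign = sign,
       extent = c((n_per - 1) * sp, (n_fil - 1) * lat))
}

#' Simulate labels under the FFO-sheet hypothesis
#'
#' A fraction `sheet_fraction` of the labels is placed in one planar patch of
#' laterally packed parallel filaments (lateral spacing
#' `filament_lateral_spacing`, shared axis along x; the antiparallel option
#' flips the tilt side on alternate filaments). The patch lies parallel to the
#' xy-plane at box mid-z and is a near-square region sized by the number of
#' sheet dimers at the lattice's areal density. The remaining labels are free
#' dimers, uniform in the 3D box.
#'
#' @param n_labels_total Total number of labels (must be even; labels come in
#'   dimer pairs).
#' @inheritParams simulate_dimer_field
#' @return A [point_pattern()] with labels `"sheet"` / `"free-dimer"`.
#' @export
simulate_sheet <- function(n_labels_total, box, params = sheet_model_params(),
                           seed = NULL) {
  box <- as_box(box)
  stopifnot(inherits(params, "sheet_model_params"))
  if (n_labels_total %% 2L != 0L)
    stop("'n_labels_total' must be even (labels come in dimer pairs)")
  n_sheet <- 2L * round(params$sheet_fraction * n_labels_total / 2)
  n_free_dimers <- (n_labels_total - n_sheet) %/% 2L
  centre <- colMeans(box)
  sheet_pat <- NULL
  if (n_sheet > 0L) {
    lat <- sheet_lattice(n_sheet %/% 2L, centre, params)
    margin <- params$dimer_label_distance
    if (any(lat$extent + margin > box_sides(box)[1:2]))
      stop(sprintf(paste("sheet patch (%.0f x %.0f nm) does not fit the box;",
                         "use a bigger box"),
                   lat$extent[1L] + margin, lat$extent[2L] + margin))
    th <- lat$tilt_sign * params$tilt * pi / 180
    h <- params$dimer_label_distance / 2
    off <- cbind(h * cos(th), h * sin(th), 0)
    coords <- rbind(lat$centres + off, lat$centres - off)
    nd <- nrow(lat$centres)
    idx <- as.vector(rbind(seq_len(nd), nd + seq_len(nd)))
    sheet_pat <- coords[idx, , drop = FALSE]
  }
  with_seed(seed, {
    free <- simulate_dimer_field(n_free_dimers, box, params)
    coords <- rbind(sheet_pat, free$coords)
    point_pattern(coords, box = box,
                  labels = c(rep("sheet", n_sheet),
                             rep("free-dimer", 2L * n_free_dimers)))
  })
}

#' Thin a pattern by independent detection
#'
#' Keeps each label independently with probability `p`, emulating the
#' fraction of molecules whose label is photoconverted and localized.
#'
#' @param pattern A [point_pattern()].
#' @param p Detection probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A [point_pattern()] on the same box.
#' @export
thin_detection <- function(pattern, p, seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"), p >= 0, p <= 1)
  with_seed(seed, subset_pattern(pattern, runif(n_points(pattern)) < p))
}

#' Add Gaussian localization noise
#'
#' Displaces every label by an independent anisotropic Gaussian error:
#' sigma = `accuracy_xy` in x and y, `z_accuracy_factor * accuracy_xy` in z
#' (axial localization is less precise than lateral). Points pushed outside
#' the box are kept; region selection is a separate step.
#'
#' @inheritParams thin_detection
#' @param params A [sheet_model_params()] object.
#' @return A [point_pattern()] with the same number of points.
#' @export
add_localization_noise <- function(pattern, params = sheet_model_params(),
                                   seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- n_points(pattern)
  s <- params$accuracy_xy
  if (s == 0 || n == 0L) return(pattern)
  with_seed(seed, {
    noise <- cbind(rnorm(n, 0, s), rnorm(n, 0, s),
                   rnorm(n, 0, s * params$z_accuracy_factor))
    point_pattern(pattern$coords + noise, box = pattern$box,
                  labels = pattern$labels)
  })
}

#' Render points as a 2D Gaussian-splat image
#'
#' Accumulates a unit-mass Gaussian of width `sigma_px` pixels (truncated at
#' 4 sigma) at every xy position. The image is centred on the coordinate
#' origin: pixel (1,1) covers the corner at
#' `(-image_size/2 * pixel_size, ...)`.
#'
#' @param coords n x 2 (or n x 3; z ignored) matrix of positions, nm.
#' @param image_size Image side, pixels.
#' @param pixel_size Pixel side, nm.
#' @param sigma_px Splat sigma in pixels.
#' @return `image_size` x `image_size` matrix (first index = x) with
#'   attributes `pixel_size`.
#' @export
render_points_image <- function(coords, image_size, pixel_size,
                                sigma_px = 1) {
  img <- matrix(0, image_size, image_size)
  if (!is.null(coords) && nrow(coords) > 0L) {
    px <- coords[, 1L] / pixel_size + image_size / 2 + 0.5
    py <- coords[, 2L] / pixel_size + image_size / 2 + 0.5
    w <- ceiling(4 * sigma_px)
    for (i in seq_along(px)) {
      ix <- max(1L, floor(px[i] - w)):min(image_size, ceiling(px[i] + w))
      iy <- max(1L, floor(py[i] - w)):min(image_size, ceiling(py[i] + w))
      if (length(ix) == 0L || length(iy) == 0L) next
      gx <- dnorm(ix, px[i], sigma_px)
      gy <- dnorm(iy, py[i], sigma_px)
      img[ix, iy] <- img[ix, iy] + outer(gx, gy)
    }
  }
  structure(img, pixel_size = pixel_size)
}

# anisotropic Gaussian splats with principal axes (axis_dir, lateral_dir)
splat_anisotropic <- function(coords, image_size, pixel_size,
                              sigma_axis_px, sigma_lat_px, axis_angle) {
  img <- matrix(0, image_size, image_size)
  if (is.null(coords) || nrow(coords) == 0L)
    return(structure(img, pixel_size = pixel_size))
  th <- axis_angle * pi / 180
  a <- c(cos(th), sin(th)); l <- c(-sin(th), cos(th))
  px <- coords[, 1L] / pixel_size + image_size / 2 + 0.5
  py <- coords[, 2L] / pixel_size + image_size / 2 + 0.5
  w <- ceiling(4 * max(sigma_axis_px, sigma_lat_px))
  for (i in seq_along(px)) {
    ix <- max(1L, floor(px[i] - w)):min(image_size, ceiling(px[i] + w))
    iy <- max(1L, floor(py[i] - w)):min(image_size, ceiling(py[i] + w))
    if (length(ix) == 0L || length(iy) == 0L) next
    dx <- outer(ix - px[i], rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), iy - py[i])
    da <- dx * a[1L] + dy * a[2L]
    dl <- dx * l[1L] + dy * l[2L]
    img[ix, iy] <- img[ix, iy] +
      exp(-0.5 * ((da / sigma_axis_px)^2 + (dl / sigma_lat_px)^2))
  }
  structure(img, pixel_size = pixel_size)
}

#' Render a synthetic striation image of a sheet patch
#'
#' Draws a noise-free, fully labeled sheet lattice covering the whole field of
#' view and renders every label as a Gaussian splat. As in the electron
#' micrographs the generator emulates, the striations are laterally
#' continuous protein rows: each splat is therefore elongated along the
#' stripe (lateral) direction (sigma = `filament_lateral_spacing / 2` nm,
#' washing out sub-stripe lateral structure) while the axial sigma stays at
#' 1 px, preserving the axial repeat.
#' The striations run perpendicular to the filament axis with pitch
#' `intra_filament_spacing`, and the Fourier analysis of the result recovers
#' that pitch as the dominant period.
#'
#' @param params A [sheet_model_params()] object.
#' @param image_size Image side in pixels (default 512).
#' @param pixel_size Pixel size in nm; must satisfy the Nyquist condition
#'   `pixel_size <= intra_filament_spacing / 2` (default 0.5).
#' @param axis_angle Filament axis direction, degrees from +x (default 0).
#' @return Matrix image (first index = x) with attributes `pixel_size` and
#'   `axis_angle`.
#' @export
render_striation_image <- function(params = sheet_model_params(),
                                   image_size = 512, pixel_size = 0.5,
                                   axis_angle = 0) {
  stopifnot(inherits(params, "sheet_model_params"))
  if (pixel_size > params$intra_filament_spacing / 2)
    stop(sprintf(paste("pixel_size %g nm violates Nyquist for a %g nm pitch;",
                       "use <= %g nm"), pixel_size,
                 params$intra_filament_spacing,
                 params$intra_filament_spacing / 2))
  half <- image_size * pixel_size / 2
  reach <- half * sqrt(2) + params$dimer_label_distance
  sp <- params$intra_filament_spacing
  lat <- params$filament_lateral_spacing
  k <- seq(-ceiling(reach / sp), ceiling(reach / sp))
  j <- seq(-ceiling(reach / lat), ceiling(reach / lat))
  g <- expand.grid(k = k, j = j)
  th0 <- axis_angle * pi / 180
  a <- c(cos(th0), sin(th0))          # filament axis
  b <- c(-sin(th0), cos(th0))         # lateral direction
  centres <- outer(g$k * sp, a) + outer(g$j * lat, b)
  sgn <- if (params$alignment == "antiparallel")
    ifelse(g$j %% 2 == 0, 1, -1) else rep(1, nrow(g))
  th <- th0 + sgn * params$tilt * pi / 180
  h <- params$dimer_label_distance / 2
  off <- cbind(h * cos(th), h * sin(th))
  pts <- rbind(centres + off, centres - off)
  sig_lat <- params$filament_lateral_spacing / 2 / pixel_size
  pad <- 4 * max(1, sig_lat) * pixel_size
  keep <- abs(pts[, 1L]) <= half + pad & abs(pts[, 2L]) <= half + pad
  img <- splat_anisotropic(pts[keep, , drop = FALSE], image_size, pixel_size,
                           sigma_axis_px = 1, sigma_lat_px = sig_lat,
                           axis_angle = axis_angle)
  attr(img, "axis_angle") <- axis_angle
  img
}

#' Write / read a grayscale image as 32-bit float TIFF
#'
#' @param image Numeric matrix (first index = x).
#' @param path File path.
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   the matrix with a `pixel_size` attribute if given.
#' @param pixel_size Optional pixel size in nm, restored on read from the
#'   calling code (TIFF tags are not used).
#' @export
write_image_tiff <- function(image, path) {
  # tiff stores row-major top-down images; transpose so x stays first index
  tiff::writeTIFF(t(unclass(image)), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_size = NULL) {
  m <- t(tiff::readTIFF(path, as.is = FALSE))
  if (!is.null(pixel_size)) attr(m, "pixel_size") <- pixel_size
  m
}
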