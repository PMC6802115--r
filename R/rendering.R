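#' Mixed-Gaussian density rendering of a localization table
#'
#' Visualizes molecule positions as the sum of one anisotropic Gaussian per
#' signal: the signal's own localization accuracy is the sigma in x and y and
#' `z_factor` times it in z (axial localization is less precise). Each kernel
#' is evaluated at voxel centres, truncated at 4 sigma and renormalized so
#' its discrete mass is exactly 1; total rendered mass therefore equals the
#' number of signals.
#'
#' @param table A [localization_table()].
#' @param voxel_size Isotropic voxel edge, nm (default 10). A warning is
#'   issued if it exceeds the smallest accuracy (undersampled kernels).
#' @param z_factor Axial/lateral sigma ratio (default 2).
#' @return A `density_volume`: list with `values` (3D array, x-y-z),
#'   `voxel_size`, `origin` (nm position of the corner of voxel
#'   \[1, 1, 1\]).
#' @export
render_density <- function(table, voxel_size = 10, z_factor = 2) {
  stopifnot(inherits(table, "loc_table"), voxel_size > 0)
  roi <- attr(table, "roi")
  if (nrow(table) > 0L && voxel_size > min(table$accuracy))
    warning("voxel_size exceeds the smallest accuracy; kernels undersampled")
  pad <- if (nrow(table) > 0L) 4 * max(table$accuracy) * z_factor else 0
  origin <- floor((roi["min", ] - pad) / voxel_size) * voxel_size
  dims <- pmax(1L, ceiling((roi["max", ] + pad - origin) / voxel_size))
  vol <- array(0, dims)
  centres <- lapply(1:3, function(a)
    origin[a] + (seq_len(dims[a]) - 0.5) * voxel_size)
  for (i in seq_len(nrow(table))) {
    s <- c(table$accuracy[i], table$accuracy[i],
           z_factor * table$accuracy[i])
    pos <- c(table$x[i], table$y[i], table$z[i])
    idx <- g <- vector("list", 3L)
    for (a in 1:3) {
      within <- abs(centres[[a]] - pos[a]) <= 4 * s[a] + voxel_size / 2
      idx[[a]] <- which(within)
      g[[a]] <- dnorm(centres[[a]][within], pos[a], s[a])
    }
    if (any(lengths(idx) == 0L)) next
    k <- outer(outer(g[[1L]], g[[2L]]), g[[3L]])
    vol[idx[[1L]], idx[[2L]], idx[[3L]]] <-
      vol[idx[[1L]], idx[[2L]], idx[[3L]]] + k / sum(k)
  }
  structure(list(values = vol, voxel_size = voxel_size, origin = origin,
                 z_factor = z_factor),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Density volume: %d x %d x %d voxels of %g nm, mass %.3f\n",
              d[1L], d[2L], d[3L], x$voxel_size, sum(x$values)))
  invisible(x)
}

#' Sum a z slab of a density volume into a 2D image
#'
#' Adds the voxel layers whose centres fall in the half-open slab
#' `[center_z - thickness/2, center_z + thickness/2)`; complementary slabs
#' therefore partition the volume's total mass.
#'
#' @param volume A `density_volume` from [render_density()].
#' @param center_z Slab centre, nm.
#' @param thickness Slab thickness, nm (default 60).
#' @return 2D matrix (x by y) with attribute `voxel_size`; zero with a
#'   warning if the slab misses the grid.
#' @export
extract_slice <- function(volume, center_z, thickness = 60) {
  stopifnot(inherits(volume, "density_volume"), thickness > 0)
  d <- dim(volume$values)
  zc <- volume$origin[3L] + (seq_len(d[3L]) - 0.5) * volume$voxel_size
  keep <- zc >= center_z - thickness / 2 & zc < center_z + thickness / 2
  if (!any(keep)) {
    warning("slab does not intersect the rendered grid; returning zeros")
    return(structure(matrix(0, d[1L], d[2L]),
                     voxel_size = volume$voxel_size))
  }
  img <- apply(volume$values[, , keep, drop = FALSE], c(1L, 2L), sum)
  structure(img, voxel_size = volume$voxel_size)
}

#' Write a density volume as a multi-page 32-bit float TIFF
#'
#' One page per z layer, x across columns after the standard image
#' transpose.
#'
#' @param volume A `density_volume`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  pages <- lapply(seq_len(dim(volume$values)[3L]), function(k)
    t(volume$values[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
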