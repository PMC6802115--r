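#' Geometric model parameters for sheet-forming dimer lattices
#'
#' Bundles the constants of the generative model used throughout the package:
#' a banana-shaped F-BAR protein dimerizes, dimers string into flat
#' filamentous oligomers (FFOs), and FFOs pack laterally into two-dimensional
#' sheets on the membrane. The defaults describe the GAS7 F-BAR lattice as
#' derived from its crystal packing and the imaging conditions of the
#' accompanying PALM experiments.
#'
#' @param dimer_label_distance Distance between the two fluorescent labels of
#'   one dimer, nm. Each molecule carries one label, so a dimer contributes a
#'   label pair. Default 11.
#' @param intra_filament_spacing Centre-to-centre spacing of consecutive
#'   dimers along a filament, nm. This is also the striation pitch of a sheet.
#'   Default 5.
#' @param tilt Angle between a dimer's long axis and the filament axis,
#'   degrees, in (0, 90]. Default 40.
#' @param dimer_length End-to-end length of one dimer, nm. Default 22.
#' @param filament_lateral_spacing Centre-to-centre distance of laterally
#'   packed filaments in a sheet, nm. Default 14, i.e. filaments in side
#'   contact at the filament width.
#' @param sheet_fraction Fraction of labels that belong to the sheet patch
#'   (the remainder are free dimers), in \[0, 1\]. Default 0.4.
#' @param detection_prob Probability that a label yields an observed
#'   localization, in \[0, 1\]. Default 0.1.
#' @param accuracy_xy Localization accuracy (Gaussian sigma) in the focal
#'   plane, nm. Default 20.
#' @param z_accuracy_factor Ratio of axial (z) to lateral accuracy. Default 2.
#' @param alignment `"parallel"` or `"antiparallel"` packing of neighbouring
#'   filaments in a sheet. Default `"parallel"`.
#'
#' @return An object of class `sheet_model_params` (a validated list).
#' @examples
#' p <- sheet_model_params()
#' filament_width(p) # ~14 nm
#' @export
sheet_model_params <- function(dimer_label_distance = 11,
                               intra_filament_spacing = 5,
                               tilt = 40,
                               dimer_length = 22,
                               filament_lateral_spacing = 14,
                               sheet_fraction = 0.4,
                               detection_prob = 0.1,
                               accuracy_xy = 20,
                               z_accuracy_factor = 2,
                               alignment = c("parallel", "antiparallel")) {
  alignment <- match.arg(alignment)
  p <- list(
    dimer_label_distance = dimer_label_distance,
    intra_filament_spacing = intra_filament_spacing,
    tilt = tilt,
    dimer_length = dimer_length,
    filament_lateral_spacing = filament_lateral_spacing,
    sheet_fraction = sheet_fraction,
    detection_prob = detection_prob,
    accuracy_xy = accuracy_xy,
    z_accuracy_factor = z_accuracy_factor,
    alignment = alignment
  )
  lens <- c("dimer_label_distance", "intra_filament_spacing", "dimer_length",
            "filament_lateral_spacing")
  for (nm in lens) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive length in nm", nm))
  }
  for (nm in c("sheet_fraction", "detection_prob")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1]", nm))
  }
  if (!is.numeric(p$tilt) || length(p$tilt) != 1L ||
      p$tilt <= 0 || p$tilt > 90)
    stop("'tilt' must be in (0, 90] degrees")
  if (p$accuracy_xy < 0) stop("'accuracy_xy' must be >= 0")
  if (p$z_accuracy_factor <= 0) stop("'z_accuracy_factor' must be > 0")
  structure(p, class = "sheet_model_params")
}

#' @export
print.sheet_model_params <- function(x, ...) {
  cat("Sheet lattice model parameters\n")
  cat(sprintf("  dimer: label distance %g nm, length %g nm\n",
              x$dimer_label_distance, x$dimer_length))
  cat(sprintf("  filament: spacing %g nm, tilt %g deg (width %.1f nm)\n",
              x$intra_filament_spacing, x$tilt, filament_width(x)))
  cat(sprintf("  sheet: lateral spacing %g nm, %s, sheet fraction %g\n",
              x$filament_lateral_spacing, x$alignment, x$sheet_fraction))
  cat(sprintf("  imaging: detection %g, accuracy %g nm (z x%g)\n",
              x$detection_prob, x$accuracy_xy, x$z_accuracy_factor))
  invisible(x)
}

#' Perpendicular width of a filamentous oligomer
#'
#' A filament is a string of dimers tilted by `tilt` degrees from the filament
#' axis; its envelope width perpendicular to the axis is the projection of the
#' dimer length, `dimer_length * sin(tilt)`. At the defaults (22 nm, 40 deg)
#' this is about 14 nm, the width of the crystal-lattice filament.
#'
#' @param params A [sheet_model_params()] object.
#' @return Width in nm.
#' @examples
#' filament_width(sheet_model_params()) # 22 * sin(40 deg) = 14.14
#' @export
filament_width <- function(params) {
  stopifnot(inherits(params, "sheet_model_params"))
  params$dimer_length * sin(params$tilt * pi / 180)
}
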