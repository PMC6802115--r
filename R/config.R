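#' Run configuration
#'
#' A run configuration bundles the generative model constants, the analysis
#' settings (trials, slicing, Fourier band) and I/O choices, together with
#' one master seed, and round-trips losslessly through YAML. All defaults
#' equal the model's stated constants.
#'
#' @param model A [sheet_model_params()] object.
#' @param n_signals Signals per analysed/simulated pattern.
#' @param box Box dimensions, nm (length-3 or 2 x 3, see [as_box()]).
#' @param n_trials Monte-Carlo trials for nulls and model ensembles.
#' @param slice_thickness z-slab thickness for analysis, nm.
#' @param band Fourier period search band, nm.
#' @param pixel_nm Camera pixel (merge grid), nm.
#' @param dialect Localization CSV dialect.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model = sheet_model_params(), n_signals = 3000,
                       box = c(2000, 2000, 300), n_trials = 20,
                       slice_thickness = 60, band = c(3, 10),
                       pixel_nm = 160, dialect = "minimal", seed = 1L) {
  structure(list(
    model = model,
    analysis = list(n_signals = as.integer(n_signals), box = as_box(box),
                    n_trials = as.integer(n_trials),
                    slice_thickness = slice_thickness, band = band),
    io = list(pixel_nm = pixel_nm, dialect = dialect),
    seed = as.integer(seed)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()] object.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- do.call(sheet_model_params, y$model)
  run_config(model = model,
             n_signals = y$analysis$n_signals,
             box = matrix(unlist(y$analysis$box), 2L, 3L, byrow = TRUE),
             n_trials = y$analysis$n_trials,
             slice_thickness = y$analysis$slice_thickness,
             band = unlist(y$analysis$band),
             pixel_nm = y$io$pixel_nm,
             dialect = y$io$dialect,
             seed = y$seed)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- list(
    model = unclass(config$model),
    analysis = list(n_signals = config$analysis$n_signals,
                    box = list(as.numeric(config$analysis$box["min", ]),
                               as.numeric(config$analysis$box["max", ])),
                    n_trials = config$analysis$n_trials,
                    slice_thickness = config$analysis$slice_thickness,
                    band = as.numeric(config$analysis$band)),
    io = config$io,
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

config_provenance <- function(config, extra = character()) {
  m <- unclass(config$model)
  c(sprintf("ffosheets %s",
            as.character(utils::packageVersion("ffosheets"))),
    sprintf("seed: %d", config$seed),
    sprintf("model: %s", paste(sprintf("%s=%s", names(m),
                                       vapply(m, format, "")),
                               collapse = " ")),
    extra)
}
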