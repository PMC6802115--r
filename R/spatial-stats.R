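#' Distance shells of the neighbour statistic
#'
#' The statistic counts neighbours in eight 5-nm shells
#' \[5i, 5(i+1)) nm for i = 2..9, i.e. distances from 10 to 50 nm. Distances
#' below 10 nm are not reported: so few signal pairs fall there that the fold
#' increase has very large variance.
#'
#' @return Data frame with columns `bin_index`, `lo_nm`, `hi_nm`.
#' @export
shell_bins <- function() {
  i <- 2:9
  data.frame(bin_index = i, lo_nm = 5 * i, hi_nm = 5 * (i + 1))
}

new_neighbor_profile <- function(counts, n_signals) {
  out <- shell_bins()
  out$count <- as.numeric(counts)
  structure(out, n_signals = as.integer(n_signals),
            class = c("neighbor_profile", "data.frame"))
}

#' Per-shell neighbour counts of a 3D point pattern
#'
#' For every ordered pair of distinct signals, the 3D Euclidean distance
#' d increments shell i when 5i <= d < 5(i+1), i = 2..9. Counts are directed,
#' so each unordered pair contributes 0 or 2. Distances are always 3D, even
#' for near-planar data. Neighbour search uses a cell list with a 50 nm
#' cutoff; its correctness is pinned to a brute-force all-pairs oracle in the
#' test-suite.
#'
#' @param pattern A [point_pattern()].
#' @return A `neighbor_profile`: the [shell_bins()] frame plus a `count`
#'   column, with attribute `n_signals`.
#' @examples
#' p <- point_pattern(rbind(c(0, 0, 0), c(12, 0, 0)))
#' neighbor_counts(p) # both directed pairs fall in the [10,15) shell
#' @export
neighbor_counts <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- n_points(pattern)
  if (n == 0L) return(new_neighbor_profile(rep(0, 8L), 0L))
  counts <- shell_counts_cpp(pattern$coords, 5, 2L, 9L)
  new_neighbor_profile(counts, n)
}

#' Monte-Carlo CSR null ensemble for the neighbour statistic
#'
#' Simulates `n_trials` complete-spatial-randomness patterns of exactly
#' `n_signals` points in `box` and reduces each to a [neighbor_counts()]
#' profile. The per-shell mean and SD across trials define the null against
#' which observed counts are expressed as fold increases. No edge correction
#' is applied: the null lives in the identical box, so boundary depletion
#' cancels to first order in the fold ratio.
#'
#' @param n_signals Points per trial (must match the observed pattern).
#' @param box Box as accepted by [as_box()].
#' @param n_trials Number of trials (>= 2, default 20).
#' @param seed Optional integer seed.
#' @return A `null_ensemble`: list with `counts` (`n_trials` x 8 matrix),
#'   `mean`, `sd`, `n_signals`, `n_trials`, `box`, `bins`.
#' @export
random_null <- function(n_signals, box, n_trials = 20, seed = NULL) {
  box <- as_box(box)
  stopifnot(n_trials >= 2)
  counts <- with_seed(seed, t(vapply(seq_len(n_trials), function(t)
    neighbor_counts(simulate_csr(n_signals, box))$count, numeric(8L))))
  structure(list(counts = counts,
                 mean = colMeans(counts),
                 sd = apply(counts, 2L, sd),
                 n_signals = as.integer(n_signals),
                 n_trials = as.integer(n_trials),
                 box = box, bins = shell_bins()),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("CSR null ensemble: %d trials of %d signals\n",
              x$n_trials, x$n_signals))
  print(cbind(x$bins, mean = x$mean, sd = x$sd))
  invisible(x)
}

new_fold_curve <- function(fold, sd, n_signals, n_trials) {
  out <- shell_bins()
  out$fold <- fold
  out$sd <- sd
  structure(out, n_signals = as.integer(n_signals),
            n_trials = as.integer(n_trials),
            class = c("fold_curve", "data.frame"))
}

#' Fold increase of neighbour counts over the CSR null
#'
#' Per shell: observed count divided by the mean null count; the attached SD
#' is the null's across-trial SD expressed on the fold scale
#' (`sd(null) / mean(null)`), the +/- SD band of the trial simulations.
#' Shells whose null mean is zero are undefined (`NA`). The null must be
#' matched: same number of signals as the observation.
#'
#' @param observed A `neighbor_profile` from [neighbor_counts()].
#' @param null A `null_ensemble` from [random_null()].
#' @return A `fold_curve`: [shell_bins()] plus `fold` and `sd` columns.
#' @export
fold_increase <- function(observed, null) {
  stopifnot(inherits(observed, "neighbor_profile"),
            inherits(null, "null_ensemble"))
  if (attr(observed, "n_signals") != null$n_signals)
    stop(sprintf(paste("observed pattern has %d signals but the null was",
                       "built for %d; the null must be matched"),
                 attr(observed, "n_signals"), null$n_signals))
  ok <- null$mean > 0
  fold <- ifelse(ok, observed$count / null$mean, NA_real_)
  sdv <- ifelse(ok, null$sd / null$mean, NA_real_)
  new_fold_curve(fold, sdv, null$n_signals, null$n_trials)
}

# one synthetic observation matched in signal number: simulate the model at
# full labelling, thin by the detection probability, add localization noise,
# then subsample to exactly n_signals.
simulate_model_pattern <- function(model = c("random", "dimer", "sheet"),
                                   n_signals, box, params,
                                   params_override = NULL) {
  model <- match.arg(model)
  box <- as_box(box)
  if (model == "random") return(simulate_csr(n_signals, box))
  p <- params$detection_prob
  over <- 1.05
  for (attempt in 1:3) {
    m <- ceiling(n_signals / max(p, 1e-12) * over)
    m <- m + m %% 2L
    pat <- switch(model,
      dimer = simulate_dimer_field(m %/% 2L, box, params),
      sheet = simulate_sheet(m, box, params))
    pat <- thin_detection(pat, p)
    pat <- add_localization_noise(pat, params)
    if (n_points(pat) >= n_signals) {
      keep <- sample.int(n_points(pat), n_signals)
      return(subset_pattern(pat, keep))
    }
    over <- over * 1.5
  }
  stop("model could not yield the requested number of signals")
}

#' Reference ensembles of the candidate models
#'
#' For each of the three generative hypotheses (CSR `random`, free `dimer`
#' field, FFO `sheet`) simulates `n_trials` observation-matched patterns
#' (full labelling, detection thinning, localization noise, subsampled to
#' `n_signals`) and records their shell-count profiles. Used by
#' [classify_pattern()] and [model_curves()].
#'
#' @inheritParams random_null
#' @param params A [sheet_model_params()] object.
#' @param models Character vector of models to include.
#' @return Named list of `n_trials` x 8 count matrices.
#' @export
model_reference <- function(n_signals, box, params = sheet_model_params(),
                            n_trials = 20, seed = NULL,
                            models = c("random", "dimer", "sheet")) {
  box <- as_box(box)
  stopifnot(n_trials >= 2)
  with_seed(seed, {
    out <- lapply(models, function(m)
      t(vapply(seq_len(n_trials), function(t)
        neighbor_counts(simulate_model_pattern(m, n_signals, box,
                                               params))$count,
        numeric(8L))))
    names(out) <- models
    out
  })
}

#' Model fold-increase curves (dimer field vs FFO sheet)
#'
#' Runs `n_trials` observation-matched simulations of the free-dimer model
#' and of the FFO-sheet model, scores each by [neighbor_counts()], and folds
#' every trial against the mean of a shared CSR null of the same size. Each
#' model's curve is the across-trial mean fold with the across-trial SD — the
#' +/- SD dashed band of the trial simulations.
#'
#' @inheritParams model_reference
#' @return List with `null` (the shared [random_null()] ensemble) and
#'   `curves`, a named list of `fold_curve`s (`dimer`, `sheet`).
#' @export
model_curves <- function(n_signals, box, params = sheet_model_params(),
                         n_trials = 20, seed = NULL) {
  box <- as_box(box)
  with_seed(seed, {
    null <- random_null(n_signals, box, n_trials)
    ref <- model_reference(n_signals, box, params, n_trials,
                           models = c("dimer", "sheet"))
    curves <- lapply(ref, function(cm) {
      folds <- sweep(cm, 2L, null$mean, "/")
      new_fold_curve(colMeans(folds), apply(folds, 2L, sd),
                     n_signals, n_trials)
    })
    list(null = null, curves = curves)
  })
}

#' Classify an observed pattern against the three generative models
#'
#' Scores the observation's shell-count profile against the trial ensemble of
#' each candidate model (CSR, free dimers, FFO sheet) by the sum over shells
#' of squared z-scores, `sum(((obs - mean_m) / sd_m)^2)`, and returns the
#' nearest model. This operationalizes the visual comparison of observed and
#' simulated fold-increase curves.
#'
#' @param observed A [point_pattern()] with >= 500 points.
#' @param box Box the observation lives in.
#' @param params A [sheet_model_params()] object.
#' @param seed Optional integer seed (for the reference simulations).
#' @param n_trials Trials per model ensemble (default 100: the decision
#'   boundary needs stabler per-shell means and SDs than the plotted +/- SD
#'   bands do).
#' @param ref Optional precomputed [model_reference()] (must match
#'   `n_points(observed)`); computing it once and reusing it across many
#'   classifications is much cheaper.
#' @return `"random"`, `"dimer"` or `"sheet"`, with attribute `scores`.
#' @export
classify_pattern <- function(observed, box, params = sheet_model_params(),
                             seed = NULL, n_trials = 100, ref = NULL) {
  stopifnot(inherits(observed, "point_pattern"))
  n <- n_points(observed)
  if (n < 500L)
    stop("classification needs at least 500 signals")
  if (is.null(ref))
    ref <- model_reference(n, box, params, n_trials, seed)
  obs <- neighbor_counts(observed)$count
  scores <- vapply(ref, function(cm) {
    mu <- colMeans(cm)
    s <- pmax(apply(cm, 2L, sd), 1)
    sum(((obs - mu) / s)^2)
  }, numeric(1L))
  structure(names(which.min(scores)), scores = scores)
}

#' Export a profile or fold curve as tidy CSV
#'
#' @param x A `neighbor_profile` or `fold_curve`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Overlay plot of observed and model fold-increase curves
#'
#' Reproduces the standard presentation: fold increase vs distance with the
#' observed curve and the dimer/sheet model curves, dashed +/- SD bands, and
#' the fold = 1 CSR reference line.
#'
#' @param observed A `fold_curve` for the observation (or `NULL`).
#' @param models Named list of model `fold_curve`s (e.g. from
#'   [model_curves()]), or `NULL`.
#' @return A ggplot object.
#' @export
plot_fold_curves <- function(observed = NULL, models = NULL) {
  pieces <- list()
  if (!is.null(observed))
    pieces$observed <- transform(as.data.frame(observed), curve = "observed")
  for (nm in names(models))
    pieces[[nm]] <- transform(as.data.frame(models[[nm]]), curve = nm)
  df <- do.call(rbind, pieces)
  df$mid <- (df$lo_nm + df$hi_nm) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fold,
                                   colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fold + .data$sd),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fold - .data$sd),
                       linetype = "dashed") +
    ggplot2::labs(x = "distance (nm)", y = "fold increase over random",
                  colour = NULL) +
    ggplot2::theme_classic()
}
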