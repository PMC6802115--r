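test_that("shell counts match simple hand constructions", {
  two <- point_pattern(rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_equal(neighbor_counts(two)$count, c(2, 0, 0, 0, 0, 0, 0, 0))
  one <- point_pattern(rbind(c(0, 0, 0)))
  expect_equal(sum(neighbor_counts(one)$count), 0)
  empty <- neighbor_counts(point_pattern(matrix(numeric(0), 0, 3)))
  expect_equal(attr(empty, "n_signals"), 0L)
  expect_equal(sum(empty$count), 0)
  # exact 15 nm falls in the [15, 20) shell (half-open bins)
  edge <- point_pattern(rbind(c(0, 0, 0), c(15, 0, 0)))
  expect_equal(neighbor_counts(edge)$count[2L], 2)
})

test_that("a planar grid profile equals the exhaustive enumeration", {
  g <- as.matrix(expand.grid(x = (0:3) * 20, y = (0:3) * 20, z = 0))
  pat <- point_pattern(g)
  expect_equal(neighbor_counts(pat)$count, brute_force_counts(pat))
})

test_that("cell-list counting equals the brute-force oracle on random
          patterns", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:300, 1L)
    box <- c(runif(1, 60, 400), runif(1, 60, 400), runif(1, 20, 200))
    pat <- simulate_csr(n, box)
    expect_equal(neighbor_counts(pat)$count, brute_force_counts(pat))
  }
  # clustered patterns stress the cell list harder than CSR
  for (rep in 1:10) {
    pat <- add_localization_noise(
      simulate_sheet(300, c(400, 400, 100), sheet_model_params()),
      sheet_model_params())
    expect_equal(neighbor_counts(pat)$count, brute_force_counts(pat))
  }
})

test_that("profiles are even-count and rigid-motion invariant", {
  pat <- simulate_csr(400, c(300, 300, 100), seed = 55)
  prof <- neighbor_counts(pat)
  expect_true(all(prof$count %% 2 == 0))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- point_pattern(pat$coords %*% t(R) +
                           matrix(c(50, -20, 10), n_points(pat), 3L,
                                  byrow = TRUE))
  expect_equal(neighbor_counts(moved)$count, prof$count)
})

test_that("the CSR null ensemble is seeded, sized and calibrated", {
  box <- c(1000, 1000, 1000)
  null <- random_null(500, box, n_trials = 20, seed = 10)
  expect_equal(nrow(null$counts), 20L)
  null2 <- random_null(500, box, n_trials = 20, seed = 10)
  expect_identical(null$counts, null2$counts)
  expect_error(random_null(500, box, n_trials = 1), "n_trials")
})

test_that("mean null counts match the analytic shell-volume expectation", {
  # all box sides >> 50 nm so boundary depletion is negligible
  n <- 12000
  box <- c(8000, 8000, 8000)
  null <- random_null(n, box, n_trials = 40, seed = 17)
  b <- shell_bins()
  vshell <- 4 * pi / 3 * (b$hi_nm^3 - b$lo_nm^3)
  expected <- n * (n - 1) * vshell / prod(box)
  se <- null$sd / sqrt(null$n_trials)
  expect_true(all(abs(null$mean - expected) <= 3 * se))
})

test_that("fold increase is a ratio against the matched null", {
  box <- c(1500, 1500, 300)
  null <- random_null(1000, box, n_trials = 10, seed = 23)
  ident <- structure(transform(shell_bins(), count = null$mean),
                     n_signals = 1000L,
                     class = c("neighbor_profile", "data.frame"))
  fc <- fold_increase(ident, null)
  expect_equal(fc$fold, rep(1, 8L))
  # mismatched n is an error: the null must be matched
  obs <- neighbor_counts(simulate_csr(999, box, seed = 1))
  expect_error(fold_increase(obs, null), "matched")
  # fresh CSR observations stay within the 3 SD band in nearly all replicates
  ok <- vapply(1:10, function(s) {
    null20 <- random_null(1000, box, n_trials = 20, seed = 300 + s)
    fc2 <- fold_increase(neighbor_counts(simulate_csr(1000, box,
                                                      seed = 600 + s)),
                         null20)
    all(abs(fc2$fold - 1) <= 3 * fc2$sd)
  }, logical(1L))
  expect_gte(sum(ok), 8L)
})

test_that("an FFO-sheet observation is enriched over random below 25 nm", {
  p <- sheet_model_params()
  box <- c(2000, 2000, 300)
  obs <- ffosheets:::simulate_model_pattern("sheet", 3000, as_box(box), p)
  fc <- withr::with_seed(31,
    fold_increase(neighbor_counts(obs), random_null(3000, box, 20)))
  expect_true(all(fc$fold[1:3] > 1 + 3 * fc$sd[1:3]))
})

test_that("model curves order as sheet >= dimer below 25 nm, and a
          noise-free dimer field loads only the 11 nm shell", {
  p <- sheet_model_params()
  box <- c(2000, 2000, 300)
  mc <- model_curves(3000, box, p, n_trials = 10, seed = 35)
  expect_true(all(mc$curves$sheet$fold[1:3] >= mc$curves$dimer$fold[1:3]))
  expect_true(all(is.finite(mc$curves$dimer$sd)))
  # minimum trials boundary
  mc2 <- model_curves(800, box, p, n_trials = 2, seed = 36)
  expect_true(all(is.finite(mc2$curves$sheet$sd)))
  # ideal detection, no noise: every dimer pair lands at exactly 11 nm
  ideal <- sheet_model_params(detection_prob = 1, accuracy_xy = 0)
  sparse <- ffosheets:::simulate_model_pattern("dimer", 2000,
                                               as_box(c(4000, 4000, 1000)),
                                               ideal)
  fci <- withr::with_seed(37,
    fold_increase(neighbor_counts(sparse),
                  random_null(2000, c(4000, 4000, 1000), 10)))
  expect_gt(fci$fold[1L], 5)
  expect_true(all(fci$fold[2:8] < fci$fold[1L] / 5))
})

test_that("increasing the sheet fraction monotonically raises the fold
          below 20 nm", {
  box <- c(2000, 2000, 300)
  folds <- vapply(c(0, 0.4, 0.8), function(fr) {
    p <- sheet_model_params(sheet_fraction = fr)
    mc <- model_curves(2000, box, p, n_trials = 5, seed = 91)
    mean(mc$curves$sheet$fold[1:2])
  }, numeric(1L))
  expect_true(all(diff(folds) > 0))
})

test_that("antiparallel packing gives the same neighbour profile within the
          null band", {
  box <- c(2000, 2000, 300)
  n <- 2500
  par <- sheet_model_params(alignment = "parallel")
  anti <- sheet_model_params(alignment = "antiparallel")
  null <- random_null(n, box, 20, seed = 44)
  fp <- withr::with_seed(45, colMeans(t(vapply(1:5, function(i)
    fold_increase(neighbor_counts(
      ffosheets:::simulate_model_pattern("sheet", n, as_box(box), par)),
      null)$fold, numeric(8L)))))
  fa <- withr::with_seed(46, colMeans(t(vapply(1:5, function(i)
    fold_increase(neighbor_counts(
      ffosheets:::simulate_model_pattern("sheet", n, as_box(box), anti)),
      null)$fold, numeric(8L)))))
  band <- 3 * apply(t(vapply(1:5, function(i)
    fold_increase(neighbor_counts(
      ffosheets:::simulate_model_pattern("sheet", n, as_box(box), par)),
      null)$fold, numeric(8L))), 2L, sd)
  expect_true(all(abs(fp - fa) <= pmax(band, 0.5)))
})

test_that("classification recovers the generating model", {
  p <- sheet_model_params()
  box <- c(2000, 2000, 300)
  n <- 3000
  ref <- model_reference(n, box, p, n_trials = 40, seed = 51)
  set.seed(52)
  for (m in c("random", "dimer", "sheet")) {
    hits <- sum(vapply(1:3, function(i)
      classify_pattern(ffosheets:::simulate_model_pattern(m, n, as_box(box),
                                                          p),
                       box, p, ref = ref) == m, logical(1L)))
    expect_gte(hits, 2L)
  }
  expect_error(classify_pattern(simulate_csr(100, box, seed = 1), box, p),
               "500")
})
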