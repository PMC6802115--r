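test_that("parameter validation enforces the model invariants", {
  expect_s3_class(sheet_model_params(), "sheet_model_params")
  expect_error(sheet_model_params(dimer_label_distance = -1), "positive")
  expect_error(sheet_model_params(sheet_fraction = 1.2), "fraction")
  expect_error(sheet_model_params(tilt = 0), "tilt")
  expect_error(sheet_model_params(tilt = 95), "tilt")
})

test_that("filament width is the dimer length projected by the tilt", {
  expect_equal(filament_width(sheet_model_params()), 22 * sin(40 * pi / 180))
  expect_equal(round(filament_width(sheet_model_params()), 1), 14.1)
  expect_equal(filament_width(sheet_model_params(tilt = 90)), 22)
  expect_lt(filament_width(sheet_model_params(tilt = 1e-6)), 1e-3)
})

test_that("CSR simulation is uniform, seeded, and sized", {
  expect_equal(n_points(simulate_csr(0, c(100, 100, 100))), 0L)
  a <- simulate_csr(50, c(100, 100, 100), seed = 3)
  b <- simulate_csr(50, c(100, 100, 100), seed = 3)
  expect_identical(a$coords, b$coords)
  big <- simulate_csr(1e4, c(1000, 1000, 1000), seed = 4)
  se <- 1000 / sqrt(12) / sqrt(1e4)
  for (ax in 1:3)
    expect_lt(abs(mean(big$coords[, ax]) - 500), 3 * se)
})

test_that("every within-dimer label distance is exact before noise", {
  pair_dists <- function(pat) {
    n <- n_points(pat) %/% 2L
    sqrt(rowSums((pat$coords[2 * seq_len(n) - 1L, , drop = FALSE] -
                    pat$coords[2 * seq_len(n), , drop = FALSE])^2))
  }
  p <- sheet_model_params()
  expect_equal(pair_dists(simulate_dimer_field(200, c(2000, 2000, 300), p,
                                               seed = 8)),
               rep(11, 200))
  expect_equal(pair_dists(simulate_ffo(25, params = p)), rep(11, 25))
  sh <- simulate_sheet(400, c(2000, 2000, 300), p, seed = 9)
  expect_equal(pair_dists(sh), rep(11, 200))
  expect_equal(n_points(simulate_dimer_field(1, c(100, 100, 100), p,
                                             seed = 1)), 2L)
})

test_that("nearest neighbours of a sparse dimer field sit at the label
          distance", {
  pat <- simulate_dimer_field(1000, c(10000, 10000, 2000),
                              sheet_model_params(), seed = 12)
  d <- as.matrix(dist(pat$coords))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  expect_gt(mean(abs(nn - 11) < 1e-9), 0.95)
})

test_that("filament geometry: 5 nm centre spacing, ~14 nm envelope width", {
  p <- sheet_model_params()
  f <- simulate_ffo(30, origin = c(5, 7, 0), axis_direction = c(1, 0, 0),
                    params = p)
  centres <- (f$coords[2 * (1:30) - 1L, ] + f$coords[2 * (1:30), ]) / 2
  expect_equal(diff(centres[, 1L]), rep(5, 29))
  expect_equal(sd(centres[, 2L]), 0)
  # label envelope across the axis, plus the dimer ends at +/- L/2
  half_label_extent <- diff(range(f$coords[, 2L])) # 11 * sin(40 deg)
  expect_equal(half_label_extent, 11 * sin(40 * pi / 180))
  expect_equal(2 * half_label_extent, filament_width(p), tolerance = 1e-12)
  expect_error(simulate_ffo(5, axis_direction = c(0, 0, 0)), "nonzero")
  expect_error(simulate_ffo(5, axis_direction = c(0, 0, 1)), "xy")
})

test_that("sheet simulation places the stated fraction in one mid-plane
          patch and conserves labels", {
  p <- sheet_model_params()
  n <- 5000
  pat <- simulate_sheet(n, c(2000, 2000, 300), p, seed = 21)
  expect_equal(n_points(pat), n)
  n_sheet <- sum(pat$labels == "sheet")
  expect_lte(abs(n_sheet - 0.4 * n), 2) # 40% up to whole-dimer rounding
  expect_equal(n_sheet + sum(pat$labels == "free-dimer"), n)
  z_sheet <- pat$coords[pat$labels == "sheet", 3L]
  expect_equal(unique(z_sheet), 150)
  expect_error(simulate_sheet(5001, c(2000, 2000, 300), p), "even")
  expect_error(simulate_sheet(2e6, c(500, 500, 300), p), "box")
  pure <- simulate_sheet(400, c(2000, 2000, 300),
                         sheet_model_params(sheet_fraction = 0), seed = 3)
  expect_true(all(pure$labels == "free-dimer"))
})

test_that("detection thinning is Bernoulli per label", {
  pat <- simulate_csr(1e4, c(1000, 1000, 1000), seed = 31)
  expect_equal(n_points(thin_detection(pat, 0, seed = 1)), 0L)
  expect_identical(thin_detection(pat, 1, seed = 1)$coords, pat$coords)
  kept <- n_points(thin_detection(pat, 0.1, seed = 2))
  expect_lt(abs(kept - 1000), 3 * sqrt(1e4 * 0.1 * 0.9))
  # sequential thinning composes multiplicatively (count statistics)
  counts <- vapply(1:40, function(s) {
    a <- thin_detection(thin_detection(pat, 0.5, seed = s), 0.4,
                        seed = 1000 + s)
    n_points(a)
  }, numeric(1L))
  expect_lt(abs(mean(counts) - 1e4 * 0.2), 3 * sd(counts) / sqrt(40))
})

test_that("localization noise has the stated anisotropic spread", {
  p <- sheet_model_params()
  pat <- simulate_csr(1e4, c(1000, 1000, 1000), seed = 41)
  noisy <- add_localization_noise(pat, p, seed = 42)
  expect_equal(n_points(noisy), n_points(pat))
  disp <- noisy$coords - pat$coords
  expect_equal(sd(disp[, 1L]), 20, tolerance = 0.05)
  expect_equal(sd(disp[, 2L]), 20, tolerance = 0.05)
  expect_equal(sd(disp[, 3L]), 40, tolerance = 0.05)
  # zero accuracy is the identity
  p0 <- sheet_model_params(accuracy_xy = 0)
  expect_identical(add_localization_noise(pat, p0, seed = 1)$coords,
                   pat$coords)
})

test_that("generators are reproducible bitwise under a fixed seed", {
  p <- sheet_model_params()
  box <- c(1000, 1000, 200)
  for (gen in list(
    function(s) simulate_csr(100, box, seed = s),
    function(s) simulate_dimer_field(50, box, p, seed = s),
    function(s) simulate_sheet(200, box, p, seed = s),
    function(s) add_localization_noise(simulate_csr(100, box, seed = 1), p,
                                       seed = s))) {
    expect_identical(gen(7)$coords, gen(7)$coords)
  }
})

test_that("striation image shows the 5 nm axial repeat and obeys Nyquist", {
  p <- sheet_model_params()
  img <- render_striation_image(p, image_size = 256, pixel_size = 0.5)
  # autocorrelation along the filament axis: first nonzero-lag peak at 5 nm
  prof <- rowMeans(img)
  ac <- stats::acf(prof - mean(prof), lag.max = 30, plot = FALSE)$acf[, 1, 1]
  # strongest nonzero-lag autocorrelation at one pitch (lag 10 px = 5 nm)
  best_lag <- which.max(ac[-(1:3)]) + 2L
  expect_equal(best_lag * 0.5, 5, tolerance = 0.5)
  expect_error(render_striation_image(p, pixel_size = 3), "Nyquist")
  # empty input renders an all-zero image
  expect_equal(sum(render_points_image(matrix(numeric(0), 0, 2), 64, 1)), 0)
})

test_that("pattern CSV round-trips through the minimal dialect", {
  pat <- simulate_sheet(400, c(2000, 2000, 300), sheet_model_params(),
                        seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pattern_csv(pat, path, comments = "fixture")
  back <- read_pattern_csv(path)
  expect_equal(back$coords, pat$coords, tolerance = 1e-4)
  expect_equal(back$labels, pat$labels)
  expect_equal(back$box, pat$box, ignore_attr = TRUE)
})
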