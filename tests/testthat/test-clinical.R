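test_that("the spoiled gradient-echo signal vanishes at zero flip angle", {
  expect_identical(spgr_signal(1000, 1.4, 4.43e-3, 0), 0)
  expect_gt(spgr_signal(1000, 1.4, 4.43e-3, 15), 0)
})

test_that("variable flip angle fitting recovers K and T10 from clean signals", {
  acq <- vfa_acquisition()
  truth <- expand.grid(K = c(800, 1000, 1200), T10 = c(0.8, 1.4, 2.0))
  sig <- t(apply(truth, 1, function(p)
    spgr_signal(p["K"], p["T10"], acq$tr, acq$flip_angles)))
  maps <- vfa_fit(sig, acq)
  expect_true(all(maps$valid))
  expect_identical(maps$n_failed, 0L)
  expect_true(all(abs(maps$k - truth$K) / truth$K < 1e-3))
  expect_true(all(abs(maps$t10 - truth$T10) / truth$T10 < 1e-3))
  # S0 is the signal equation evaluated at the dynamic settings
  dce <- dce_acquisition()
  expect_equal(maps$s0, spgr_signal(maps$k, maps$t10, dce$tr, dce$flip_angle),
               tolerance = 1e-12)
})

test_that("with two angles the linearized solution is already exact", {
  acq <- vfa_acquisition(flip_angles = c(5, 25))
  sig <- matrix(spgr_signal(950, 1.2, acq$tr, acq$flip_angles), nrow = 1)
  maps <- vfa_fit(sig, acq)
  expect_equal(as.numeric(maps$k), 950, tolerance = 1e-8)
  expect_equal(as.numeric(maps$t10), 1.2, tolerance = 1e-8)
})

test_that("signal to concentration inverts the forward signal model exactly", {
  g <- time_grid()
  acq <- dce_acquisition()
  K <- 1000; T10 <- 1.4
  conc_true <- conc_values(tissue_curve(0.25, 0.5, 0.08, 42, grid = g))
  # forward: C -> T1(t) -> spoiled-GRE signal
  r1t <- 1 / T10 + acq$r1 * conc_true
  sig <- spgr_signal(K, 1 / r1t, acq$tr, acq$flip_angle)

  vfa <- vfa_acquisition()
  vfa_sig <- matrix(spgr_signal(K, T10, vfa$tr, vfa$flip_angles), nrow = 1)
  maps <- vfa_fit(vfa_sig, vfa)
  conc <- signal_to_concentration(matrix(sig, nrow = 1), maps, acq)
  expect_lt(max(abs(conc - conc_true)), 1e-6)
  expect_identical(sum(attr(conc, "n_invalid")), 0)

  # S(t) = S0 (A = 1) maps to zero concentration
  s0_sig <- matrix(rep(maps$s0, 5), nrow = 1)
  c0 <- signal_to_concentration(s0_sig, maps, acq)
  expect_equal(as.numeric(c0), rep(0, 5), tolerance = 1e-10)

  # doubling the calibration factor doubles every concentration
  c2 <- signal_to_concentration(matrix(sig, nrow = 1), maps, acq, cf = 2)
  expect_equal(as.numeric(c2), 2 * as.numeric(conc), tolerance = 1e-12)
})

test_that("non-invertible frames are flagged missing, not fabricated", {
  acq <- dce_acquisition()
  vfa <- vfa_acquisition()
  vfa_sig <- matrix(spgr_signal(1000, 1.4, vfa$tr, vfa$flip_angles), nrow = 1)
  maps <- vfa_fit(vfa_sig, vfa)
  # an absurdly large enhancement leaves the valid domain of the inversion
  sig <- matrix(c(maps$s0, maps$s0 * 50), nrow = 1)
  conc <- signal_to_concentration(sig, maps, acq)
  expect_true(is.na(conc[1, 2]))
  expect_identical(as.integer(attr(conc, "n_invalid")), 1L)
})

test_that("the calibration factor is the trapezoidal AUC ratio", {
  g <- time_grid()
  aif <- population_aif(g)
  expect_equal(calibration_factor(aif, aif), 1)
  expect_equal(calibration_factor(aif, 2 * conc_values(aif)), 0.5)
  toy_a <- data.frame(time = c(0, 1, 2), conc = c(0, 2, 0))
  toy_v <- data.frame(time = c(0, 1, 2), conc = c(0, 4, 4))
  # hand trapezoids: 2 and 6
  expect_equal(calibration_factor(toy_a, toy_v), 2 / 6)
  expect_error(calibration_factor(aif, rep(0, g$n_frames)), "positive")
})

test_that("the venous output function is selected by mask or by peak search", {
  series <- array(0, c(3, 3, 4))
  series[2, 2, ] <- c(0, 5, 3, 1)   # hottest pixel
  series[1, 1, ] <- c(0, 2, 1, 0)
  mask <- matrix(FALSE, 3, 3); mask[1, 1] <- TRUE
  expect_equal(select_vof(series, mask = mask), c(0, 2, 1, 0))

  auto <- select_vof(series)
  expect_equal(as.numeric(auto), c(0, 5, 3, 1))
  expect_identical(attr(auto, "pixel"), 5L)

  mask2 <- matrix(FALSE, 3, 3); mask2[1, 1] <- TRUE; mask2[2, 2] <- TRUE
  expect_equal(select_vof(series, mask = mask2), c(0, 3.5, 2, 0.5))
  expect_error(select_vof(series, mask = matrix(FALSE, 3, 3)), "empty")
})

test_that("brain masking thresholds and keeps the largest component", {
  uni <- matrix(5, 4, 4)
  expect_true(all(make_brain_mask(uni, 0.5)))
  expect_true(all(make_brain_mask(uni, 0)))

  img <- matrix(0, 8, 8)
  img[2:6, 2:4] <- 10   # large blob (15 px)
  img[7:8, 7:8] <- 10   # small blob (4 px)
  m <- make_brain_mask(img, 0.5)
  expect_true(all(m[2:6, 2:4]))
  expect_false(any(m[7:8, 7:8]))
})

test_that("pixel-wise least-squares maps recover the generating parameters", {
  g <- time_grid()
  set.seed(77)
  nx <- 3; ny <- 3
  truth <- tibble::tibble(kep = runif(nx * ny, 0.05, 0.3),
                          ve = runif(nx * ny, 0.1, 0.5),
                          vp = runif(nx * ny, 0.01, 0.08),
                          tau_bat = runif(nx * ny, 41, 49))
  cp_ref <- apply_dispersion(population_aif(g), aif_config())
  conc <- array(0, c(nx, ny, g$n_frames))
  for (i in seq_len(nx * ny))
    conc[(i - 1) %% nx + 1, (i - 1) %/% nx + 1, ] <-
      conc_values(tissue_curve(truth$kep[i], truth$ve[i], truth$vp[i],
                               truth$tau_bat[i], grid = g))
  maps <- pixelwise_map(conc, cp_ref, nlsq_config(), grid = g)
  expect_true(all(abs(as.vector(maps$value$kep) - truth$kep) / truth$kep < 0.01))
  expect_true(all(abs(as.vector(maps$value$tau_bat) - truth$tau_bat) < 0.5))
  expect_true(all(is.na(as.vector(maps$uncertainty$kep))))
  expect_identical(maps$provenance$predictor, "nlsq")

  # per-pixel independence: a mask restricts computation to its pixels
  sub <- matrix(FALSE, nx, ny); sub[1, 1] <- TRUE
  m1 <- pixelwise_map(conc, cp_ref, nlsq_config(), mask = sub, grid = g)
  expect_equal(m1$value$kep[1, 1], maps$value$kep[1, 1], tolerance = 1e-8)
  expect_true(is.na(m1$value$kep[2, 2]))
})

test_that("a constant phantom yields constant network maps and dropout 0 yields zero uncertainty", {
  fit <- toy_fit(0)
  g <- time_grid()
  ds <- toy_dataset()
  conc <- array(0, c(2, 2, g$n_frames))
  for (i in 1:2) for (j in 1:2) conc[i, j, ] <- ds$ct[1, ]
  maps <- pixelwise_map(conc, ds$cp_ref, fit, n_mc = 5, grid = g)
  expect_equal(max(maps$value$kep) - min(maps$value$kep), 0, tolerance = 1e-10)
  expect_true(all(maps$uncertainty$ktrans == 0))
  expect_identical(maps$provenance$predictor, "rnn")

  ccc_tbl <- roi_ccc(maps, maps, matrix(TRUE, 2, 2), params = "kep") |>
    try(silent = TRUE)
  # identical constant maps have no variance: ccc is undefined there
  expect_s3_class(ccc_tbl, "try-error")
})
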