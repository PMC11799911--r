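test_that("population AIF starts at zero, stays non-negative, and matches the closed form", {
  g <- time_grid()
  cb <- population_aif(g)
  v <- conc_values(cb)

  expect_identical(v[1], 0)
  expect_true(all(v >= 0))

  # single dominant first-pass peak followed by a slowly decaying tail
  pk <- which.max(cb$fine)
  expect_lt(g$fine_times[pk], 30)
  tail_vals <- conc_values(cb)[40:65]
  expect_true(all(tail_vals < 0.25 * max(v)))
  expect_true(all(diff(tail_vals) < 0))

  # peak height and time against an independent 0.01 s evaluation
  t_fine <- oracle_fine_times(g)
  ref <- oracle_aif(t_fine)
  expect_lt(abs(max(cb$fine) - max(ref)) / max(ref), 1e-3)
  expect_lt(abs(g$fine_times[pk] - t_fine[which.max(ref)]), 0.1)
})

test_that("dispersion reduces to the delta-kernel limit and conserves area", {
  g <- time_grid()
  cb <- population_aif(g)

  out0 <- apply_dispersion(cb, aif_config(sf = 1, tau_d = 0, hct = 0.45))
  expect_equal(out0$fine, cb$fine / 0.55, tolerance = 1e-12)

  # fully decayed pulse: unit-mass kernel conserves area up to SF/(1 - Hct)
  pulse <- conc_curve(exp(-(g$fine_times - 40)^2 / (2 * 3^2)), g)
  for (tau_d in c(0.5, 2, 4)) {
    disp <- apply_dispersion(pulse, aif_config(sf = 0.9, tau_d = tau_d))
    auc_in <- pracma::trapz(g$fine_times, pulse$fine)
    auc_out <- pracma::trapz(g$fine_times, disp$fine)
    expect_lt(abs(auc_out - 0.9 / 0.55 * auc_in) / (0.9 / 0.55 * auc_in), 0.01)
  }

  expect_error(aif_config(tau_d = -1))
})

test_that("dispersed AIF matches brute-force quadrature and peaks later and lower", {
  g <- time_grid()
  cb <- population_aif(g)
  t_fine <- oracle_fine_times(g)

  disp <- apply_dispersion(cb, aif_config(sf = 1, tau_d = 4))
  ref <- approx(t_fine, oracle_cp(t_fine, sf = 1, tau_d = 4),
                xout = g$times)$y
  expect_lt(max_rel_err(conc_values(disp), ref), 1e-3)

  undisp <- apply_dispersion(cb, aif_config(sf = 1, tau_d = 0))
  expect_lt(max(disp$fine), max(undisp$fine))
  expect_gt(which.max(disp$fine), which.max(undisp$fine))
})

test_that("monotone dispersion: the plasma peak is non-increasing in tau_d", {
  g <- time_grid()
  cb <- population_aif(g)
  peaks <- vapply(c(0, 0.1, 0.5, 1, 2, 4, 8), function(td)
    max(apply_dispersion(cb, aif_config(tau_d = td))$fine), numeric(1))
  expect_true(all(diff(peaks) <= 0))
})

test_that("BAT shift delays, zeroes the pre-arrival window, and degenerates correctly", {
  g <- time_grid()
  cp <- apply_dispersion(population_aif(g), aif_config())

  expect_identical(shift_bat(cp, 0)$fine, cp$fine)
  expect_true(all(shift_bat(cp, max(g$times) + 10)$fine == 0))

  sh <- shift_bat(cp, 45)
  v <- conc_values(sh)
  # 45/4.8 = 9.375: frames 0..9 (t <= 45 s) are zero, frame 10 (t = 48 s) is not
  expect_true(all(v[1:10] == 0))
  expect_gt(v[11], 0)
  # the shifted curve reproduces the original at t - 45
  expect_equal(approx(g$fine_times, sh$fine, xout = 50)$y,
               approx(g$fine_times, cp$fine, xout = 5)$y, tolerance = 1e-9)
})

test_that("Tofts forward model vanishes and reduces to the plasma term as expected", {
  g <- time_grid()
  cp <- apply_dispersion(population_aif(g), aif_config())

  ct0 <- tofts_forward(cp, list(kep = 0, ve = 0.3, vp = 0, tau_bat = 45))
  expect_true(all(ct0$fine == 0))

  ctp <- tofts_forward(cp, list(kep = 0.2, ve = 0, vp = 0.05, tau_bat = 45))
  expect_equal(ctp$fine, 0.05 * shift_bat(cp, 45)$fine, tolerance = 1e-12)
})

test_that("Tofts forward model agrees with fine-grid quadrature over random in-range draws", {
  g <- time_grid()
  cb <- population_aif(g)
  set.seed(101)
  for (i in 1:10) {
    kep <- runif(1, 0.00025, 0.33)
    ve <- runif(1, 0.04, 0.6)
    vp <- runif(1, 0.005, 0.1)
    tau_bat <- runif(1, 40, 50)
    sf <- runif(1, 0.7, 1.3)
    tau_d <- runif(1, 0.1, 4)
    ct <- tissue_curve(kep, ve, vp, tau_bat, sf, tau_d, grid = g, cb = cb)
    ref <- oracle_tofts(g, kep, ve, vp, tau_bat, sf, tau_d)
    expect_lt(max_rel_err(conc_values(ct), ref), 1e-3)
    expect_true(all(conc_values(ct) >= 0))
  }
})

test_that("scaling SF scales plasma and tissue curves linearly, and causality holds", {
  g <- time_grid()
  cb <- population_aif(g)
  p <- list(kep = 0.25, ve = 0.4, vp = 0.03, tau_bat = 42)

  cp1 <- apply_dispersion(cb, aif_config(sf = 1, tau_d = 2))
  cp3 <- apply_dispersion(cb, aif_config(sf = 3, tau_d = 2))
  expect_equal(cp3$fine, 3 * cp1$fine, tolerance = 1e-12)
  expect_equal(tofts_forward(cp3, p)$fine, 3 * tofts_forward(cp1, p)$fine,
               tolerance = 1e-12)

  ct <- tofts_forward(cp1, p)
  expect_true(all(ct$fine[g$fine_times <= p$tau_bat] == 0))
})

test_that("ktrans is the product of kep and ve", {
  expect_identical(ktrans_of(0, 0.3), 0)
  expect_equal(ktrans_of(0.33, 0.6), 0.198)
  expect_equal(ktrans_of(0.2, 0.5), 0.1)
  expect_error(ktrans_of(-1, 0.5))
})

test_that("curves round-trip through columnar text", {
  g <- time_grid()
  ct <- tissue_curve(0.2, 0.3, 0.02, 45, grid = g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(ct, path)
  back <- read_curve(path)
  expect_equal(conc_values(back), conc_values(ct), tolerance = 1e-9)
})
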