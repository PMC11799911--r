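test_that("parameter draws stay within their ranges and match uniform moments", {
  cfg <- sim_config(n_samples = 10000, seed = 5)
  p <- sample_parameters(cfg)
  expect_true(all(p$kep >= 0.00025 & p$kep <= 0.33))
  expect_true(all(p$ve >= 0.04 & p$ve <= 0.6))
  expect_true(all(p$vp >= 0.005 & p$vp <= 0.1))
  expect_true(all(p$tau_bat >= 40 & p$tau_bat <= 50))
  expect_true(all(p$sf >= 0.7 & p$sf <= 1.3))
  expect_true(all(p$tau_d >= 0.1 & p$tau_d <= 4))
  expect_equal(p$ktrans, p$kep * p$ve)

  big <- sample_parameters(sim_config(n_samples = 1e5, seed = 6))
  # uniform mean (0.04 + 0.6)/2 within Monte Carlo error
  expect_lt(abs(mean(big$ve) - 0.32), 0.005)

  const <- sample_parameters(sim_config(n_samples = 50, ve_range = c(0.3, 0.3)))
  expect_true(all(const$ve == 0.3))
})

test_that("the PSNR schedule is geometric with exact endpoints", {
  expect_equal(psnr_schedule(c(20, 30), 2), c(20, 30))
  s3 <- psnr_schedule(c(20, 30), 3)
  expect_equal(s3, c(20, sqrt(600), 30))
  expect_equal(psnr_schedule(c(25, 25), 4), rep(25, 4))
  expect_equal(psnr_schedule(c(20, 30), 1), 20)
  s10 <- psnr_schedule(c(20, 30), 10)
  expect_equal(diff(log(s10)), rep(log(30 / 20) / 9, 9), tolerance = 1e-12)
})

test_that("injected noise has the prescribed peak-referenced standard deviation", {
  g <- time_grid()
  ct <- conc_values(tissue_curve(0.2, 0.4, 0.05, 45, grid = g))
  ct <- ct * (2 / max(ct))  # peak exactly 2 mM
  # psnr 20, peak 2 -> SD 0.1
  set.seed(9)
  reps <- 1600  # 1600 x 65 frames > 1e5 draws
  resid <- replicate(reps, add_noise(ct, 20) - ct)
  expect_lt(abs(sd(resid) - 0.1) / 0.1, 0.02)

  set.seed(11)
  a <- add_noise(ct, 15)
  set.seed(11)
  b <- add_noise(ct, 15)
  expect_identical(a, b)

  expect_warning(z <- add_noise(rep(0, 65), 20), "zero")
  expect_identical(z, rep(0, 65))
  expect_error(add_noise(ct, 0))
})

test_that("datasets are a pure function of their configuration", {
  cfg <- sim_config(n_samples = 10, seed = 123)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$ct, d2$ct)
  expect_identical(d1$params, d2$params)

  d3 <- generate_dataset(sim_config(n_samples = 10, seed = 124))
  expect_false(identical(d1$ct, d3$ct))

  # ground truth is stored unnoised; noise only touches channel 2
  expect_false(identical(d1$ct, d1$ct_clean))
  expect_identical(
    d1$cp_ref,
    conc_values(apply_dispersion(population_aif(cfg$grid),
                                 aif_config(sf = 1, tau_d = 0))))
})

test_that("clean curves regenerate exactly from the stored metadata", {
  cfg <- sim_config(n_samples = 6, seed = 77)
  ds <- generate_dataset(cfg)
  cb <- population_aif(cfg$grid)
  for (i in seq_len(6)) {
    rec <- conc_values(tissue_curve(
      ds$params$kep[i], ds$params$ve[i], ds$params$vp[i],
      ds$params$tau_bat[i], ds$params$sf[i], ds$params$tau_d[i],
      grid = cfg$grid, cb = cb))
    expect_equal(rec, ds$ct_clean[i, ], tolerance = 1e-12)
  }
})

test_that("the matched group design disables delay, dispersion, and SF variation", {
  cfg <- sim_config(n_samples = 5, seed = 31, use_bat_delay = FALSE,
                    use_dispersion = FALSE, sf_fixed = TRUE)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$params$tau_bat == 0))
  expect_true(all(ds$params$tau_d == 0))
  expect_true(all(ds$params$sf == 1))
  # channel-2 clean curves equal the forward model of the reference channel
  cp <- apply_dispersion(population_aif(cfg$grid), aif_config(sf = 1, tau_d = 0))
  for (i in 1:5) {
    ref <- conc_values(tofts_forward(cp, as.list(ds$params[i, ])))
    expect_equal(ds$ct_clean[i, ], ref, tolerance = 1e-12)
  }
})

test_that("a single-value PSNR case applies that PSNR to every sample", {
  ds <- generate_dataset(sim_config(n_samples = 8, seed = 2, psnr = 10))
  expect_true(all(ds$params$psnr == 10))
})

test_that("input arrays stack the shared reference and per-sample curves", {
  ds <- generate_dataset(sim_config(n_samples = 4, seed = 8))
  x <- input_array(ds)
  expect_identical(dim(x), c(4L, 65L, 2L))
  expect_identical(x[2, , 1], ds$cp_ref)
  expect_identical(x[3, , 2], ds$ct[3, ])
})

test_that("datasets round-trip through the text archive", {
  ds <- generate_dataset(sim_config(n_samples = 5, seed = 13))
  base <- file.path(withr::local_tempdir(), "ds")
  write_dataset(ds, base)
  back <- read_dataset(base)
  expect_equal(back$ct, ds$ct, tolerance = 1e-9)
  expect_equal(back$params$kep, ds$params$kep, tolerance = 1e-9)
  expect_identical(back$config$seed, ds$config$seed)
})
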