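test_that("model construction matches the requested architecture", {
  lstm <- build_rnn(model_config(cell = "lstm", n_layers = 4,
                                 hidden_units = 32), seed = 1)
  gru <- build_rnn(model_config(cell = "gru", n_layers = 4,
                                hidden_units = 32), seed = 1)
  # LSTM has one more gate than GRU at identical shape
  expect_gt(n_params(lstm), n_params(gru))
  expect_error(dcernn:::cpp_rnn_init("elman", 2L, 8L, 2L, 4L, 1L), "unknown")

  x <- array(rnorm(3 * 65 * 2), c(3, 65, 2))
  pr <- mcd_predict(gru, x, n_mc = 1, mc = FALSE) |> suppressWarnings()
  expect_identical(dim(pr$mean), c(3L, 5L))
})

test_that("backpropagation matches finite-difference gradients for both cells", {
  set.seed(14)
  n <- 3; tt <- 6
  x <- array(rnorm(n * tt * 2), c(n, tt, 2))
  y <- matrix(runif(n * 4), n, 4)
  eps <- 1e-6
  for (cell in c("lstm", "gru")) {
    net <- dcernn:::cpp_rnn_init(cell, 3L, 4L, 2L, 4L, 11L)
    res <- dcernn:::cpp_rnn_loss_grad(net, x, y, 0.0, 5L)
    worst <- 0
    for (l in seq_along(net$layers)) {
      for (f in intersect(names(net$layers[[l]]), c("W", "U", "b", "gamma", "beta"))) {
        for (k in unique(c(1, length(net$layers[[l]][[f]]) %/% 2 + 1,
                           length(net$layers[[l]][[f]])))) {
          np <- net; np$layers[[l]][[f]][k] <- np$layers[[l]][[f]][k] + eps
          nm <- net; nm$layers[[l]][[f]][k] <- nm$layers[[l]][[f]][k] - eps
          fd <- (dcernn:::cpp_rnn_loss_grad(np, x, y, 0, 5L)$loss -
                 dcernn:::cpp_rnn_loss_grad(nm, x, y, 0, 5L)$loss) / (2 * eps)
          an <- res$grads$layers[[l]][[f]][k]
          worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd)))
        }
      }
    }
    for (f in c("Wout", "bout")) {
      k <- length(net[[f]])
      np <- net; np[[f]][k] <- np[[f]][k] + eps
      nm <- net; nm[[f]][k] <- nm[[f]][k] - eps
      fd <- (dcernn:::cpp_rnn_loss_grad(np, x, y, 0, 5L)$loss -
             dcernn:::cpp_rnn_loss_grad(nm, x, y, 0, 5L)$loss) / (2 * eps)
      worst <- max(worst, abs(fd - res$grads[[f]][k]) / max(1e-6, abs(fd)))
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("target scaling maps ranges to the unit interval and inverts exactly", {
  ranges <- dcernn:::default_ranges()
  p <- tibble::tibble(kep = 0.00025, ve = 0.32, vp = 0.0525, tau_bat = 50)
  s <- scale_targets(p, ranges)
  expect_equal(s[1, "kep"], c(kep = 0))
  expect_equal(s[1, "ve"], c(ve = 0.5))
  expect_equal(s[1, "vp"], c(vp = 0.5))
  expect_equal(s[1, "tau_bat"], c(tau_bat = 1))

  set.seed(3)
  q <- sample_parameters(sim_config(n_samples = 40, seed = 4))
  rt <- unscale_targets(scale_targets(q, ranges), ranges)
  expect_equal(rt$kep, q$kep, tolerance = 1e-12)
  expect_equal(rt$tau_bat, q$tau_bat, tolerance = 1e-12)
  expect_error(scale_targets(q, modifyList(ranges, list(ve = c(0.3, 0.3)))))
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  fit <- toy_fit(0)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_identical(nrow(fit$history), 3L)

  fit2 <- train_rnn(toy_dataset(),
                    model_config(cell = "gru", n_layers = 2, hidden_units = 16,
                                 dropout_rate = 0),
                    train_config(epochs = 3, batch_size = 64, seed = 7))
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$net$Wout, fit2$net$Wout)

  # the 0.9/0.1 split is honoured exactly: val loss exists every epoch
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("with dropout 0 every MC pass is identical and uncertainty is exactly zero", {
  fit <- toy_fit(0)
  test <- generate_dataset(sim_config(n_samples = 20, seed = 91))
  pr <- mcd_predict(fit, test, n_mc = 10, mc = TRUE, seed = 3)
  expect_true(all(as.matrix(pr$sd) == 0))

  pr2 <- mcd_predict(fit, test, n_mc = 10, mc = TRUE, seed = 99)
  expect_identical(pr$mean, pr2$mean)
})

test_that("with dropout on, MC passes vary but are seed-reproducible", {
  fit <- toy_fit(0.25)
  test <- generate_dataset(sim_config(n_samples = 15, seed = 92))
  pr1 <- mcd_predict(fit, test, n_mc = 8, seed = 5)
  pr2 <- mcd_predict(fit, test, n_mc = 8, seed = 5)
  pr3 <- mcd_predict(fit, test, n_mc = 8, seed = 6)
  expect_identical(pr1$mean, pr2$mean)
  expect_identical(pr1$sd, pr2$sd)
  expect_false(identical(pr1$mean, pr3$mean))
  expect_true(all(as.matrix(pr1$sd) >= 0))
  expect_gt(mean(as.matrix(pr1$sd)), 0)
})

test_that("deterministic predictions are invariant to batch order", {
  fit <- toy_fit(0)
  test <- generate_dataset(sim_config(n_samples = 30, seed = 93))
  x <- input_array(test)
  pr <- suppressWarnings(mcd_predict(fit, x, n_mc = 1, mc = FALSE))
  perm <- rev(seq_len(30))
  prp <- suppressWarnings(mcd_predict(fit, x[perm, , , drop = FALSE],
                                      n_mc = 1, mc = FALSE))
  expect_equal(as.matrix(prp$mean), as.matrix(pr$mean)[perm, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a frame-count mismatch is rejected with a resampling hint", {
  fit <- toy_fit(0)
  bad <- array(0, c(2, 30, 2))
  expect_error(mcd_predict(fit, bad, n_mc = 1), "resample")
})

test_that("models round-trip through the JSON archive", {
  fit <- toy_fit(0)
  path <- withr::local_tempfile(fileext = ".json")
  write_rnn(fit, path)
  back <- read_rnn(path)
  expect_identical(back$model_config, fit$model_config)
  test <- generate_dataset(sim_config(n_samples = 5, seed = 94))
  a <- suppressWarnings(mcd_predict(fit, test, n_mc = 1, mc = FALSE))
  b <- suppressWarnings(mcd_predict(back, test, n_mc = 1, mc = FALSE))
  expect_equal(b$mean, a$mean, tolerance = 1e-12)
})

test_that("tidy and glance summarise fits and predictions", {
  fit <- toy_fit(0)
  td <- generics::tidy(fit)
  expect_setequal(unique(td$metric), c("loss", "val_loss"))
  gl <- generics::glance(fit)
  expect_identical(gl$cell, "gru")
  expect_identical(gl$epochs, 3L)

  test <- generate_dataset(sim_config(n_samples = 5, seed = 95))
  pr <- suppressWarnings(mcd_predict(fit, test, n_mc = 2))
  long <- generics::tidy(pr)
  expect_identical(nrow(long), 25L)  # 5 samples x 5 parameters
  expect_true(all(c("estimate", "sd") %in% names(long)))
})
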