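# Independent brute-force oracles: every convolution is recomputed as a
# trapezoid-weighted discrete convolution on a 0.01 s grid (FFT-accelerated
# but mathematically the plain quadrature sum), entirely separate from the
# package's exponential-integrator path.

ORACLE_DT <- 0.01

oracle_fine_times <- function(grid) seq(0, max(grid$times), by = ORACLE_DT)

# Parker closed form with the same zero-baseline convention as the package.
oracle_aif <- function(t) {
  raw <- dcernn:::parker_aif_eval(t)
  pmax(raw - dcernn:::parker_aif_eval(0), 0)
}

# y[i] = int_0^{t_i} x(tau) k(t_i - tau) dtau via trapezoid weights.
oracle_conv <- function(x, k, h = ORACLE_DT) {
  n <- length(x)
  full <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  y <- h * (full - 0.5 * x[1] * k - 0.5 * x * k[1])
  y[1] <- 0
  y
}

# Cp on the oracle grid: dispersion + SF/Hct scaling.
oracle_cp <- function(t, sf = 1, tau_d = 0, hct = 0.45) {
  cb <- oracle_aif(t)
  if (tau_d > 0) {
    kern <- exp(-t / tau_d) / tau_d
    cb <- oracle_conv(cb, kern)
  }
  sf / (1 - hct) * cb
}

# Full extended Tofts curve on the oracle grid, sampled at the frame times.
oracle_tofts <- function(grid, kep, ve, vp, tau_bat = 0, sf = 1, tau_d = 0) {
  t <- oracle_fine_times(grid)
  cp <- oracle_cp(t, sf = sf, tau_d = tau_d)
  cps <- if (tau_bat > 0)
    approx(t + tau_bat, cp, xout = t, yleft = 0, rule = 2)$y else cp
  if (tau_bat > 0) cps[t <= tau_bat] <- 0
  kmin <- kep / 60
  ees <- if (kep > 0) kmin * ve * oracle_conv(cps, exp(-kmin * t)) else 0 * t
  ct <- ees + vp * cps
  approx(t, ct, xout = grid$times)$y
}

max_rel_err <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# Small datasets / models shared across tests (built once per run).
toy_env <- new.env()

toy_dataset <- function() {
  if (is.null(toy_env$ds))
    toy_env$ds <- generate_dataset(sim_config(n_samples = 400, seed = 42))
  toy_env$ds
}

toy_fit <- function(dropout = 0) {
  key <- paste0("fit", dropout)
  if (is.null(toy_env[[key]]))
    toy_env[[key]] <- train_rnn(
      toy_dataset(),
      model_config(cell = "gru", n_layers = 2, hidden_units = 16,
                   dropout_rate = dropout),
      train_config(epochs = 3, batch_size = 64, seed = 7))
  toy_env[[key]]
}
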