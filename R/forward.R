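#' AIF transformation settings
#'
#' Scaling factor, exponential dispersion constant, hematocrit, and bolus
#' arrival time used to turn the whole-blood AIF `Cb(t)` into the plasma
#' input `Cp(t)` seen by a tissue voxel:
#' `Cp(t) = SF/(1 - Hct) * (Cb (*) exp(-t/tau_d)/tau_d)(t)`, delayed by
#' `tau_bat`.
#'
#' @param sf Dimensionless scaling factor (> 0) absorbing injected-dose and
#'   hematocrit variation.
#' @param tau_d Dispersion time constant in seconds (>= 0; 0 means no
#'   dispersion).
#' @param hct Hematocrit fraction in (0, 1); 0.45 by default.
#' @param tau_bat Bolus arrival time in seconds (>= 0).
#' @return A list of class `aif_config`.
#' @export
aif_config <- function(sf = 1, tau_d = 0, hct = 0.45, tau_bat = 0) {
  stopifnot(sf > 0, tau_d >= 0, hct > 0, hct < 1, tau_bat >= 0)
  structure(list(sf = sf, tau_d = tau_d, hct = hct, tau_bat = tau_bat),
            class = "aif_config")
}

# Unit-mass exponential dispersion kernel applied to x sampled at step h:
# y = x (*) exp(-t/tau)/tau. Exact for piecewise-linear x (exponential
# integrator), so accurate even when tau is comparable to h.
exp_kernel_filter <- function(x, h, tau) {
  if (tau <= 0) return(x)
  a <- h / tau
  E <- exp(-a)
  c1 <- -expm1(-a)                       # 1 - E
  # (1 - E(1+a))/a, series-protected against cancellation for tiny a
  q <- if (a < 1e-4) a / 2 - a^2 / 3 else (1 - E * (1 + a)) / a
  c2 <- c1 - q
  n <- length(x)
  z <- c(0, c1 * x[-n] + c2 * diff(x))
  .recursive_filter(z, E)
}

#' Apply dispersion, scaling, and hematocrit correction to the AIF
#'
#' Converts a whole-blood AIF `Cb(t)` into the plasma concentration
#' `Cp(t) = SF/(1 - Hct) * (Cb (*) exp(-t/tau_d)/tau_d)(t)`. The convolution
#' kernel has unit mass, so a fully decayed bolus conserves area up to the
#' `SF/(1 - Hct)` factor. With `tau_d = 0` the kernel is the identity.
#' Computed on the fine grid.
#'
#' @param cb A [conc_curve()] holding `Cb(t)`.
#' @param cfg An [aif_config()] (the `tau_bat` field is not applied here; see
#'   [shift_bat()]).
#' @return A [conc_curve()] holding `Cp(t)`.
#' @export
apply_dispersion <- function(cb, cfg) {
  stopifnot(inherits(cb, "conc_curve"), inherits(cfg, "aif_config"))
  g <- cb$grid
  y <- exp_kernel_filter(cb$fine, g$fine_dt, cfg$tau_d)
  conc_curve(cfg$sf / (1 - cfg$hct) * y, g)
}

#' Delay a curve by the bolus arrival time
#'
#' Returns `Cp(t - tau_bat)` with value 0 for `t <= tau_bat`, using linear
#' interpolation on the fine grid so non-integer frame shifts are exact for
#' the piecewise-linear representation.
#'
#' @param cp A [conc_curve()].
#' @param tau_bat Delay in seconds (>= 0).
#' @return A [conc_curve()].
#' @export
shift_bat <- function(cp, tau_bat) {
  stopifnot(inherits(cp, "conc_curve"), tau_bat >= 0)
  if (tau_bat == 0) return(cp)
  g <- cp$grid
  y <- approx(g$fine_times + tau_bat, cp$fine, xout = g$fine_times,
              yleft = 0, rule = 2)$y
  y[g$fine_times <= tau_bat] <- 0
  conc_curve(y, g)
}

#' Extended Tofts forward model
#'
#' Maps pharmacokinetic parameters and a plasma input to the tissue
#' concentration
#' `Ct(t) = kep*ve * int_0^t Cp(u - tau_bat) exp(-kep (t - u)) du
#'          + vp * Cp(t - tau_bat)`.
#' `kep` is carried in 1/min while the grid is in seconds; the single unit
#' conversion `kep/60` per second happens here. The convolution term is
#' evaluated as `ve` times the unit-mass exponential kernel with time
#' constant `60/kep` s, using the same exact piecewise-linear integrator as
#' [apply_dispersion()], on the fine grid.
#'
#' @param cp A [conc_curve()] holding the undelayed plasma input `Cp(t)`
#'   (already SF/Hct scaled); the `tau_bat` delay is applied internally.
#' @param params A list or one-row data frame with `kep` (1/min), `ve`, `vp`
#'   (fractions), and `tau_bat` (s).
#' @return A [conc_curve()] holding `Ct(t)`.
#' @examples
#' g <- time_grid()
#' cp <- apply_dispersion(population_aif(g), aif_config())
#' ct <- tofts_forward(cp, list(kep = 0.2, ve = 0.3, vp = 0.02, tau_bat = 45))
#' @export
tofts_forward <- function(cp, params) {
  stopifnot(inherits(cp, "conc_curve"))
  kep <- params$kep; ve <- params$ve; vp <- params$vp
  tau_bat <- params$tau_bat %||% 0
  stopifnot(kep >= 0, ve >= 0, ve <= 1, vp >= 0, vp <= 1)
  g <- cp$grid
  cps <- shift_bat(cp, tau_bat)
  ees <- if (kep > 0) ve * exp_kernel_filter(cps$fine, g$fine_dt, 60 / kep)
         else rep(0, g$n_fine)
  conc_curve(ees + vp * cps$fine, g)
}

#' Volume transfer constant
#'
#' `Ktrans = kep * ve` (1/min). Vectorised.
#'
#' @param kep Exchange rate constant, 1/min (>= 0).
#' @param ve Extravascular extracellular volume fraction in \[0, 1\].
#' @export
ktrans_of <- function(kep, ve) {
  stopifnot(all(kep >= 0), all(ve >= 0), all(ve <= 1))
  kep * ve
}

#' Pharmacokinetic parameter set
#'
#' Convenience constructor returning a one-row tibble with the derived
#' `ktrans = kep * ve` column, the unit of exchange between the simulator,
#' the fitters, and the metrics.
#'
#' @inheritParams ktrans_of
#' @param vp Plasma volume fraction in \[0, 1\].
#' @param tau_bat Bolus arrival time, s (>= 0).
#' @export
pk_params <- function(kep, ve, vp, tau_bat = 0) {
  stopifnot(kep >= 0, ve >= 0, ve <= 1, vp >= 0, vp <= 1, tau_bat >= 0)
  tibble::tibble(kep = kep, ve = ve, vp = vp, tau_bat = tau_bat,
                 ktrans = ktrans_of(kep, ve))
}

#' Full simulator chain for one tissue curve
#'
#' Convenience wrapper running [population_aif()] -> [apply_dispersion()] ->
#' [tofts_forward()] (the BAT delay is applied inside the Tofts step).
#'
#' @inheritParams pk_params
#' @param sf,tau_d,hct AIF settings, see [aif_config()].
#' @param grid A [time_grid()].
#' @param cb Optional precomputed whole-blood AIF [conc_curve()] (saves
#'   re-evaluating the closed form in tight loops).
#' @return A [conc_curve()] holding `Ct(t)`.
#' @export
tissue_curve <- function(kep, ve, vp, tau_bat = 0, sf = 1, tau_d = 0,
                         hct = 0.45, grid = time_grid(), cb = NULL) {
  if (is.null(cb)) cb <- population_aif(grid)
  cp <- apply_dispersion(cb, aif_config(sf = sf, tau_d = tau_d, hct = hct))
  tofts_forward(cp, list(kep = kep, ve = ve, vp = vp, tau_bat = tau_bat))
}
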