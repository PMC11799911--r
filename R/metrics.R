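#' Lin's concordance correlation coefficient
#'
#' Agreement of two variables with the identity line:
#' `ccc = 2*cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, using the
#' population (divide-by-N) variance convention of Lin's original
#' definition. Attenuates Pearson's r by scale and location shift, so
#' `|ccc| <= |r|`.
#'
#' @param x,y Numeric vectors of equal length >= 2; neither may be constant.
#' @return A value in \[-1, 1\].
#' @examples
#' ccc(c(0, 1, 2), c(1, 2, 3)) # 4/7
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0) abort("ccc is undefined for constant input")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Normalized root mean square error
#'
#' `100 * RMSE(pred, gt) / (max(gt) - min(gt))`, in percent. The denominator
#' is the ground-truth range over the evaluated collection, so the measure is
#' not symmetric in its arguments.
#'
#' @param pred Predicted values.
#' @param gt Ground-truth values (must span a nonzero range).
#' @return NRMSE in percent.
#' @export
nrmse <- function(pred, gt) {
  stopifnot(length(pred) == length(gt))
  rng <- max(gt) - min(gt)
  if (rng <= 0) abort("ground-truth range is zero")
  100 * sqrt(mean((pred - gt)^2)) / rng
}

#' Fisher z-transformation
#'
#' `z = atanh(r) = log((1 + r) / (1 - r)) / 2`, used to normalise correlation
#' coefficients before significance testing.
#'
#' @param r Correlation value(s) with `|r| < 1`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) abort("|r| must be < 1 for the Fisher z-transform")
  atanh(r)
}

#' Normalized predictive uncertainty
#'
#' The Monte Carlo dropout SD normalized by the ground-truth range of the
#' parameter over the evaluated collection, in percent:
#' `100 * SD / (max(gt) - min(gt))`. Vectorised over `sd`.
#'
#' @param sd Predictive SD(s), in parameter units (>= 0).
#' @param gt Ground-truth values of the parameter (must span a nonzero
#'   range), or a precomputed `c(min, max)` range.
#' @export
normalized_uncertainty <- function(sd, gt) {
  stopifnot(all(sd >= 0))
  rng <- max(gt) - min(gt)
  if (rng <= 0) abort("ground-truth range is zero")
  100 * sd / rng
}

#' Evaluate a prediction run against ground truth
#'
#' Per-parameter CCC, NRMSE, and (when predictive SDs are available) mean
#' normalized uncertainty for `kep`, `ve`, `vp`, `ktrans`, and `tau_bat`.
#' `ktrans` is derived per sample as `kep * ve` before any metric is
#' computed, and its normalizing range is the range of the derived values
#' over the test set. For predictors without uncertainties (NLSQ) `sigma_uc`
#' is `NA`, not zero.
#'
#' @param pred Tibble of predictions with columns `kep`, `ve`, `vp`,
#'   `tau_bat` (and optionally `ktrans`), or an `mcd_prediction`.
#' @param truth Tibble of ground truth with the same parameter columns
#'   (e.g. `dataset$params`).
#' @param params Parameters to evaluate (those present in both tables).
#' @return A tibble with columns `parameter`, `ccc`, `nrmse`, `sigma_uc`,
#'   `n_test`.
#' @export
evaluate_run <- function(pred, truth,
                         params = c("kep", "ve", "vp", "ktrans", "tau_bat")) {
  sds <- NULL
  if (inherits(pred, "mcd_prediction")) {
    sds <- pred$sd
    pred <- pred$mean
  }
  if (!"ktrans" %in% names(pred) && all(c("kep", "ve") %in% names(pred)))
    pred$ktrans <- pred$kep * pred$ve
  truth <- tibble::as_tibble(truth)
  if (!"ktrans" %in% names(truth))
    truth$ktrans <- truth$kep * truth$ve
  if (nrow(pred) != nrow(truth)) abort("pred and truth have different lengths")
  params <- intersect(params, intersect(names(pred), names(truth)))
  purrr::map(params, function(p) {
    gt <- truth[[p]]
    est <- pred[[p]]
    keep <- is.finite(est) & is.finite(gt)
    su <- if (!is.null(sds) && p %in% names(sds))
      mean(normalized_uncertainty(sds[[p]][keep], gt[keep])) else NA_real_
    tibble::tibble(parameter = p,
                   ccc = ccc(est[keep], gt[keep]),
                   nrmse = nrmse(est[keep], gt[keep]),
                   sigma_uc = su,
                   n_test = sum(keep))
  }) |> purrr::list_rbind()
}
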