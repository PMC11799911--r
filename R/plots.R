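#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   facet_wrap labs theme_minimal geom_raster scale_fill_viridis_c coord_fixed
NULL

#' @export
ggplot2::autoplot

#' Plot a concentration curve
#' @param object A [conc_curve()].
#' @param ... Unused.
#' @export
autoplot.conc_curve <- function(object, ...) {
  ggplot(as_tibble.conc_curve(object), aes(x = .data$time, y = .data$conc)) +
    geom_line(colour = "#2166ac") +
    labs(x = "time (s)", y = "concentration (mM)") +
    theme_minimal()
}

#' Plot training and validation loss against epoch
#' @param object An `rnn_fit`.
#' @param ... Unused.
#' @export
autoplot.rnn_fit <- function(object, ...) {
  ggplot(tidy.rnn_fit(object),
         aes(x = .data$epoch, y = .data$value, colour = .data$metric)) +
    geom_line() +
    labs(x = "epoch", y = "MSE loss (scaled targets)", colour = NULL) +
    theme_minimal()
}

#' Predicted-versus-truth concordance scatter
#'
#' One panel per parameter with the identity line, the visual counterpart
#' of the CCC/NRMSE metrics.
#'
#' @param pred An `mcd_prediction` or tibble of predictions.
#' @param truth Tibble of ground-truth parameters.
#' @param params Parameters to display.
#' @export
plot_concordance <- function(pred, truth,
                             params = c("kep", "ve", "vp", "ktrans",
                                        "tau_bat")) {
  if (inherits(pred, "mcd_prediction")) pred <- pred$mean
  truth <- tibble::as_tibble(truth)
  if (!"ktrans" %in% names(truth)) truth$ktrans <- truth$kep * truth$ve
  params <- intersect(params, intersect(names(pred), names(truth)))
  d <- purrr::map(params, function(p) {
    tibble::tibble(parameter = p, truth = truth[[p]], predicted = pred[[p]])
  }) |> purrr::list_rbind()
  ggplot(d, aes(x = .data$truth, y = .data$predicted)) +
    geom_point(alpha = 0.3, size = 0.6) +
    geom_abline(linetype = "dashed", colour = "grey40") +
    facet_wrap(~parameter, scales = "free") +
    labs(x = "ground truth", y = "predicted") +
    theme_minimal()
}

#' Display parameter or uncertainty maps
#'
#' @param object A `parameter_maps`.
#' @param what `"value"` or `"uncertainty"`.
#' @param params Parameters to display.
#' @param ... Unused.
#' @export
autoplot.parameter_maps <- function(object, what = c("value", "uncertainty"),
                                    params = c("kep", "ve", "vp", "ktrans",
                                               "tau_bat"), ...) {
  what <- match.arg(what)
  d <- purrr::map(params, function(p) {
    m <- object[[what]][[p]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    tibble::tibble(parameter = p,
                   x = as.vector(row(m)), y = as.vector(col(m)),
                   value = as.vector(m))
  }) |> purrr::list_rbind()
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90") +
    facet_wrap(~parameter) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = what) +
    theme_minimal()
}
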