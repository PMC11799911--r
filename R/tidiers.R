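#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a recurrent model
#'
#' One row per epoch and loss type (`loss`, `val_loss`).
#'
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @export
tidy.rnn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, cols = c("loss", "val_loss"),
                      names_to = "metric", values_to = "value")
}

#' One-row model summary
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @export
glance.rnn_fit <- function(x, ...) {
  cfg <- x$model_config
  tibble::tibble(cell = cfg$cell, n_layers = cfg$n_layers,
                 hidden_units = cfg$hidden_units,
                 dropout_rate = cfg$dropout_rate,
                 n_params = n_params(x),
                 epochs = nrow(x$history),
                 final_loss = if (nrow(x$history)) tail(x$history$loss, 1) else NA_real_,
                 final_val_loss = if (nrow(x$history)) tail(x$history$val_loss, 1) else NA_real_)
}

#' Tidy a single-curve least-squares fit
#'
#' One row per estimated parameter (plus derived `ktrans`).
#'
#' @param x A `tofts_fit`.
#' @param ... Unused.
#' @export
tidy.tofts_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' One-row fit summary
#' @param x A `tofts_fit`.
#' @param ... Unused.
#' @export
glance.tofts_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, converged = x$converged,
                 n_iter = x$n_iter)
}

#' Tidy a Monte Carlo dropout prediction
#'
#' Long format: one row per sample and parameter with the ensemble mean and
#' SD.
#'
#' @param x An `mcd_prediction`.
#' @param ... Unused.
#' @export
tidy.mcd_prediction <- function(x, ...) {
  m <- dplyr::mutate(x$mean, sample = dplyr::row_number())
  s <- dplyr::mutate(x$sd, sample = dplyr::row_number())
  ml <- tidyr::pivot_longer(m, -"sample", names_to = "parameter",
                            values_to = "estimate")
  sl <- tidyr::pivot_longer(s, -"sample", names_to = "parameter",
                            values_to = "sd")
  dplyr::left_join(ml, sl, by = c("sample", "parameter"))
}

#' @export
glance.mcd_prediction <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$mean), n_mc = x$n_mc,
                 dropout_rate = x$dropout_rate, mc = x$mc)
}
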