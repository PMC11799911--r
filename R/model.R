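#' Recurrent model configuration
#'
#' Architecture of the sequence regressor: a stack of `n_layers` LSTM or GRU
#' layers (all but the last returning full sequences, the last its final
#' state), batch normalization after each recurrent layer except the last, a
#' dropout stage after each recurrent block whose activity persists at
#' inference when Monte Carlo mode is on, and a final dense map to the four
#' pharmacokinetic outputs.
#'
#' @param cell `"lstm"` or `"gru"`.
#' @param n_layers Number of recurrent layers (default 4).
#' @param hidden_units Hidden state size per layer (default 256; 64-512
#'   studied).
#' @param dropout_rate Dropout fraction in \[0, 1) (0, 0.25, 0.5 studied).
#' @param n_outputs Number of regression outputs (4: kep, ve, vp, tau_bat).
#' @param input_channels Input channels (2: reference Cp and tissue Ct).
#' @param seq_len Expected number of frames (65).
#' @return A list of class `model_config`.
#' @export
model_config <- function(cell = c("gru", "lstm"), n_layers = 4,
                         hidden_units = 256, dropout_rate = 0.25,
                         n_outputs = 4, input_channels = 2, seq_len = 65) {
  cell <- match.arg(cell)
  dropout_rate <- as.numeric(dropout_rate)
  stopifnot(n_layers >= 1, hidden_units >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(cell = cell, n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, n_outputs = as.integer(n_outputs),
                 input_channels = as.integer(input_channels),
                 seq_len = as.integer(seq_len)),
            class = "model_config")
}

#' Training configuration
#'
#' Adam with initial learning rate 1e-3 and inverse-time decay
#' `lr = lr0 / (1 + 0.1 * epoch)`, mean-squared-error loss on range-scaled
#' targets, batch size 128, 50 epochs, and a 0.9/0.1 train/validation split.
#'
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_decay Inverse-time decay constant per epoch.
#' @param val_fraction Validation fraction in (0, 1).
#' @param seed Seed controlling weight init, the split, shuffling, and
#'   dropout masks (expanded into per-stage streams).
#' @export
train_config <- function(batch_size = 128, epochs = 50, initial_lr = 1e-3,
                         lr_decay = 0.1, val_fraction = 0.1, seed = 1L) {
  initial_lr <- as.numeric(initial_lr)
  lr_decay <- as.numeric(lr_decay)
  val_fraction <- as.numeric(val_fraction)
  stopifnot(batch_size >= 1, epochs >= 1, initial_lr > 0, lr_decay >= 0,
            val_fraction > 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_decay = lr_decay, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialise an untrained model
#'
#' Glorot-uniform weights (forget-gate bias 1 for LSTM), unit batch-norm
#' scale. The handle carries the architecture and the target-scaling ranges.
#'
#' @param cfg A [model_config()].
#' @param ranges Named list of `c(low, high)` sampling ranges for `kep`,
#'   `ve`, `vp`, `tau_bat`, used to scale targets to the unit interval.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `rnn_fit` (untrained: empty history).
#' @export
build_rnn <- function(cfg, ranges = default_ranges(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  net <- cpp_rnn_init(cfg$cell, cfg$n_layers, cfg$hidden_units,
                      cfg$input_channels, cfg$n_outputs, as.integer(seed))
  structure(list(net = net, model_config = cfg, ranges = ranges,
                 history = tibble::tibble(epoch = integer(), loss = numeric(),
                                          val_loss = numeric()),
                 trained = FALSE),
            class = "rnn_fit")
}

default_ranges <- function() {
  list(kep = c(0.00025, 0.33), ve = c(0.04, 0.6), vp = c(0.005, 0.1),
       tau_bat = c(40, 50))
}

#' Number of trainable parameters
#' @param fit An `rnn_fit`.
#' @export
n_params <- function(fit) cpp_rnn_n_params(fit$net)

#' Scale parameters to the unit interval by their sampling ranges
#'
#' Affine map `(x - low) / (high - low)` per parameter, so the MSE loss
#' weighs tau_bat (~45 s) and vp (~0.01) comparably. [unscale_targets()] is
#' the exact inverse.
#'
#' @param params Tibble/data frame with `kep`, `ve`, `vp`, `tau_bat`.
#' @param ranges Named list of `c(low, high)` per parameter.
#' @return Numeric matrix (n x 4) in column order kep, ve, vp, tau_bat.
#' @export
scale_targets <- function(params, ranges) {
  nm <- c("kep", "ve", "vp", "tau_bat")
  out <- vapply(nm, function(p) {
    r <- ranges[[p]]
    if (r[2] <= r[1]) abort(sprintf("zero-width scaling range for %s", p))
    (params[[p]] - r[1]) / (r[2] - r[1])
  }, numeric(nrow(params)))
  matrix(out, nrow = nrow(params), dimnames = list(NULL, nm))
}

#' @rdname scale_targets
#' @param scaled Matrix as produced by [scale_targets()] (or network output).
#' @export
unscale_targets <- function(scaled, ranges) {
  nm <- c("kep", "ve", "vp", "tau_bat")
  out <- vapply(seq_along(nm), function(j) {
    r <- ranges[[nm[j]]]
    scaled[, j] * (r[2] - r[1]) + r[1]
  }, numeric(nrow(scaled)))
  colnames(out) <- nm
  tibble::as_tibble(out)
}

#' Train a recurrent model on a synthetic dataset
#'
#' Splits the dataset 0.9/0.1 into training/validation (random split under
#' the training seed, ratio honoured exactly), scales targets to the unit
#' interval by the dataset's sampling ranges, and minimises the MSE with
#' Adam under the configured learning-rate schedule. Dropout is active
#' during training; validation loss is computed in inference mode.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An `rnn_fit` with a per-epoch `history` tibble (`epoch`, `loss`,
#'   `val_loss`).
#' @export
train_rnn <- function(dataset, cfg = model_config(), tcfg = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(dataset, "sim_dataset"))
  n <- nrow(dataset$ct)
  if (n < 2) abort("dataset too small to split")
  scfg <- dataset$config
  ranges <- list(kep = scfg$kep, ve = scfg$ve, vp = scfg$vp,
                 tau_bat = scfg$tau_bat)
  x <- input_array(dataset)
  y <- scale_targets(dataset$params, ranges)

  n_val <- max(1L, floor(n * tcfg$val_fraction))
  perm <- withr::with_seed(derive_seed(tcfg$seed, "split"), sample.int(n))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]

  net <- cpp_rnn_init(cfg$cell, cfg$n_layers, cfg$hidden_units,
                      cfg$input_channels, cfg$n_outputs,
                      derive_seed(tcfg$seed, "init"))
  res <- cpp_rnn_train(net,
                       x[tr_idx, , , drop = FALSE], y[tr_idx, , drop = FALSE],
                       x[val_idx, , , drop = FALSE], y[val_idx, , drop = FALSE],
                       cfg$dropout_rate, tcfg$batch_size, tcfg$epochs,
                       tcfg$initial_lr, tcfg$lr_decay,
                       derive_seed(tcfg$seed, "train"), verbose)
  structure(
    list(net = res$net, model_config = cfg, train_config = tcfg,
         ranges = ranges,
         history = tibble::tibble(epoch = seq_len(tcfg$epochs),
                                  loss = res$train_loss,
                                  val_loss = res$val_loss),
         trained = TRUE),
    class = "rnn_fit"
  )
}

#' @export
print.rnn_fit <- function(x, ...) {
  cfg <- x$model_config
  cat(sprintf(
    "<rnn_fit> %s, %d layers x %d units, dropout %.2g, %s (%.0f parameters)\n",
    toupper(cfg$cell), cfg$n_layers, cfg$hidden_units, cfg$dropout_rate,
    if (x$trained) sprintf("trained %d epochs", nrow(x$history)) else "untrained",
    n_params(x)))
  invisible(x)
}

#' Monte Carlo dropout prediction
#'
#' Runs `n_mc` stochastic forward passes with dropout active (batch-norm
#' layers use their stored statistics). Outputs are mapped back to parameter
#' units, `ktrans = kep * ve` is derived per pass, and the per-sample mean
#' over passes is the prediction while the SD is its uncertainty. With
#' dropout 0 (or `mc = FALSE`) every pass is identical and all SDs are
#' exactly 0.
#'
#' @param fit A trained `rnn_fit`.
#' @param newdata A `sim_dataset`, an (n, frames, 2) input array, or a
#'   matrix of tissue curves combined with `cp_ref`.
#' @param n_mc Number of Monte Carlo passes (default 100).
#' @param mc Keep dropout active at inference (default: whenever the model
#'   was configured with a nonzero dropout rate).
#' @param seed Seed for the dropout masks.
#' @param cp_ref Reference input channel when `newdata` is a plain matrix.
#' @return An object of class `mcd_prediction`: list with tibbles `mean` and
#'   `sd` (columns `kep`, `ve`, `vp`, `tau_bat`, `ktrans`) plus `n_mc`.
#' @export
mcd_predict <- function(fit, newdata, n_mc = 100,
                        mc = fit$model_config$dropout_rate > 0, seed = 1L,
                        cp_ref = NULL) {
  stopifnot(inherits(fit, "rnn_fit"), n_mc >= 1)
  x <- if (is.array(newdata) && length(dim(newdata)) == 3) newdata
       else input_array(newdata, cp_ref = cp_ref)
  if (dim(x)[2] != fit$model_config$seq_len)
    abort(sprintf(
      "input has %d frames but the model expects %d; resample the series to the model grid",
      dim(x)[2], fit$model_config$seq_len))
  if (n_mc == 1) warn("n_mc = 1: uncertainty reported as 0")
  active <- isTRUE(mc) && fit$model_config$dropout_rate > 0
  n_pass <- if (active) as.integer(n_mc) else 1L  # deterministic: one pass
  cube <- cpp_rnn_predict(fit$net, x, fit$model_config$dropout_rate,
                          n_pass, active, as.integer(seed))
  # unscale each pass, derive ktrans per pass, then reduce over passes
  n <- dim(cube)[1]
  passes <- lapply(seq_len(n_pass), function(k) {
    p <- unscale_targets(cube[, , k, drop = TRUE], fit$ranges)
    cbind(p$kep, p$ve, p$vp, p$tau_bat, p$kep * p$ve)
  })
  mean_mat <- Reduce(`+`, passes) / n_pass
  sd_mat <- if (n_pass > 1) {
    v <- Reduce(`+`, lapply(passes, function(p) (p - mean_mat)^2))
    sqrt(v / (n_pass - 1))
  } else matrix(0, n, 5)
  nm <- c("kep", "ve", "vp", "tau_bat", "ktrans")
  colnames(mean_mat) <- nm
  colnames(sd_mat) <- nm
  structure(list(mean = tibble::as_tibble(mean_mat),
                 sd = tibble::as_tibble(sd_mat),
                 n_mc = as.integer(n_mc), mc = isTRUE(mc),
                 dropout_rate = fit$model_config$dropout_rate),
            class = "mcd_prediction")
}

#' @export
predict.rnn_fit <- function(object, newdata, ...) {
  mcd_predict(object, newdata, ...)
}

#' @export
print.mcd_prediction <- function(x, ...) {
  cat(sprintf("<mcd_prediction> %d samples, %d MC passes (dropout %.2g%s)\n",
              nrow(x$mean), x$n_mc, x$dropout_rate,
              if (x$mc) ", active at inference" else ""))
  invisible(x)
}

#' Serialize a model to a JSON archive
#'
#' Weights, running statistics, configuration, and scaling ranges in one
#' plain-text JSON file.
#'
#' @param fit An `rnn_fit`.
#' @param path Output path.
#' @export
write_rnn <- function(fit, path) {
  pack_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  pack <- function(x) {
    if (is.matrix(x)) pack_mat(x)
    else if (is.list(x)) lapply(x, pack)
    else x
  }
  payload <- list(
    manifest = list(format = "dcernn-rnn", version = 1L,
                    cell = fit$model_config$cell, trained = fit$trained),
    model_config = unclass(fit$model_config),
    train_config = if (!is.null(fit$train_config)) unclass(fit$train_config),
    ranges = fit$ranges,
    history = as.list(fit$history),
    net = pack(fit$net)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rnn
#' @export
read_rnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  unpack <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data))
      matrix(x$data, nrow = x$dim[1], ncol = x$dim[2])
    else if (is.list(x)) lapply(x, unpack)
    else x
  }
  cfg <- do.call(model_config, p$model_config[c(
    "cell", "n_layers", "hidden_units", "dropout_rate", "n_outputs",
    "input_channels", "seq_len")])
  tcfg <- if (!is.null(p$train_config))
    do.call(train_config, p$train_config[c(
      "batch_size", "epochs", "initial_lr", "lr_decay", "val_fraction",
      "seed")])
  structure(list(net = unpack(p$net), model_config = cfg, train_config = tcfg,
                 ranges = p$ranges,
                 history = tibble::as_tibble(p$history),
                 trained = isTRUE(p$manifest$trained)),
            class = "rnn_fit")
}
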