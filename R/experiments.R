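#' Experiment specification
#'
#' Describes one of the simulation study designs at configurable scale:
#' `"sample_size"` and `"hidden_units"` sweeps, the `"dropout_psnr"` grid,
#' the `"bat_mismatch"` and `"dispersion_mismatch"` group designs, and the
#' RNN-versus-NLSQ `"method_comparison"`. Defaults mirror the full study
#' (5 repeats, 1000 test samples); pass smaller configurations to run at
#' reduced scale.
#'
#' @param design Design identifier.
#' @param sim Base [sim_config()]; its `n_samples` is the training set size.
#' @param model Base [model_config()].
#' @param train Base [train_config()].
#' @param nlsq An [nlsq_config()] (used by `method_comparison`).
#' @param n_repeats Independent training repetitions (default 5).
#' @param n_test Test samples per evaluation (default 1000).
#' @param n_mc Monte Carlo passes at prediction time.
#' @param grid_values Design-specific grid: sample sizes, hidden-unit
#'   counts, or dropout rates; `NULL` uses the studied values.
#' @param test_psnr PSNR cases for `dropout_psnr` (list of single values or
#'   ranges).
#' @param seed Global seed, expanded deterministically per stage and repeat.
#' @export
experiment_spec <- function(design = c("method_comparison", "bat_mismatch",
                                       "dispersion_mismatch", "dropout_psnr",
                                       "sample_size", "hidden_units"),
                            sim = sim_config(n_samples = 1e5),
                            model = model_config(),
                            train = train_config(),
                            nlsq = nlsq_config(),
                            n_repeats = 5, n_test = 1000, n_mc = 100,
                            grid_values = NULL, test_psnr = NULL,
                            seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_repeats >= 1, n_test >= 2)
  structure(list(design = design, sim = sim, model = model, train = train,
                 nlsq = nlsq, n_repeats = as.integer(n_repeats),
                 n_test = as.integer(n_test), n_mc = as.integer(n_mc),
                 grid_values = grid_values, test_psnr = test_psnr,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

set_sim <- function(sim, ...) {
  upd <- list(...)
  args <- list(
    n_samples = sim$n_samples, seed = sim$seed, kep_range = sim$kep,
    ve_range = sim$ve, vp_range = sim$vp, tau_bat_range = sim$tau_bat,
    sf_range = sim$sf, tau_d_range = sim$tau_d, psnr = sim$psnr,
    use_bat_delay = sim$use_bat_delay, use_dispersion = sim$use_dispersion,
    sf_fixed = sim$sf_fixed, shuffle_psnr = sim$shuffle_psnr, grid = sim$grid)
  do.call(sim_config, modifyList(args, upd))
}

set_cfg <- function(cfg, constructor, ...) {
  do.call(constructor, modifyList(unclass(cfg), list(...)))
}

train_once <- function(spec, sim_cfg, mcfg, seed) {
  ds <- generate_dataset(set_sim(sim_cfg, seed = derive_seed(seed, "data")))
  tcfg <- set_cfg(spec$train, train_config, seed = derive_seed(seed, "fit"))
  train_rnn(ds, mcfg, tcfg)
}

eval_rnn <- function(spec, fit, test_ds, seed,
                     params = c("kep", "ve", "vp", "ktrans", "tau_bat")) {
  pr <- mcd_predict(fit, test_ds, n_mc = spec$n_mc,
                    seed = derive_seed(seed, "mc"))
  evaluate_run(pr, test_ds$params, params = params)
}

#' Run a simulation experiment design
#'
#' Executes generate / train / predict (or fit) / evaluate for every cell of
#' the design and every repeat, fully seeded, and returns the per-repeat
#' evaluation table. Failures in individual cells are recorded (`error`
#' column) and the run continues.
#'
#' @param spec An [experiment_spec()].
#' @param verbose Print progress.
#' @return A tibble of per-repeat per-parameter metrics with design
#'   metadata columns; summarise with [summarise_experiment()].
#' @export
run_experiment <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  runner <- switch(spec$design,
    bat_mismatch = function(r, s) mismatch_repeat(spec, r, s, "bat"),
    dispersion_mismatch = function(r, s) mismatch_repeat(spec, r, s, "disp"),
    method_comparison = function(r, s) method_repeat(spec, r, s),
    dropout_psnr = function(r, s) dropout_psnr_repeat(spec, r, s),
    sample_size = function(r, s) sweep_repeat(spec, r, s, "n_train"),
    hidden_units = function(r, s) sweep_repeat(spec, r, s, "hidden_units"))
  out <- purrr::map(seq_len(spec$n_repeats), function(r) {
    if (verbose) message("repeat ", r, "/", spec$n_repeats)
    seed_r <- derive_seed(spec$seed, paste0("repeat", r))
    res <- tryCatch(runner(r, seed_r), error = function(e) {
      tibble::tibble(parameter = NA_character_, ccc = NA_real_,
                     nrmse = NA_real_, sigma_uc = NA_real_, n_test = NA_integer_,
                     error = conditionMessage(e))
    })
    dplyr::mutate(res, design = spec$design, repeat_id = r)
  }) |> purrr::list_rbind()
  if (!"error" %in% names(out)) out$error <- NA_character_
  out
}

mismatch_repeat <- function(spec, r, seed, which) {
  flag <- if (which == "bat") "use_bat_delay" else "use_dispersion"
  params <- if (which == "bat") c("kep", "ve", "vp", "ktrans")
            else c("kep", "ve", "vp", "ktrans", "tau_bat")
  # isolate the studied factor (SF variation off; the delay stays on in the
  # dispersion design so its tau_bat metric remains defined)
  base <- if (which == "bat")
    set_sim(spec$sim, use_bat_delay = FALSE, use_dispersion = FALSE,
            sf_fixed = TRUE)
  else
    set_sim(spec$sim, use_bat_delay = TRUE, use_dispersion = FALSE,
            sf_fixed = TRUE)
  sim_off <- base
  sim_on <- do.call(set_sim, c(list(base), setNames(list(TRUE), flag)))

  # paired seeds: the matched and mismatched sets share parameter and noise
  # draws and differ only in the toggled factor
  fit_off <- train_once(spec, sim_off, spec$model, derive_seed(seed, "m"))
  fit_on <- train_once(spec, sim_on, spec$model, derive_seed(seed, "m"))
  test_off <- generate_dataset(set_sim(sim_off, n_samples = spec$n_test,
                                       seed = derive_seed(seed, "t")))
  test_on <- generate_dataset(set_sim(sim_on, n_samples = spec$n_test,
                                      seed = derive_seed(seed, "t")))
  dplyr::bind_rows(
    dplyr::mutate(eval_rnn(spec, fit_off, test_off, seed, params), group = 1L),
    dplyr::mutate(eval_rnn(spec, fit_off, test_on, seed, params), group = 2L),
    dplyr::mutate(eval_rnn(spec, fit_on, test_on, seed, params), group = 3L))
}

method_repeat <- function(spec, r, seed) {
  fit <- train_once(spec, spec$sim, spec$model, derive_seed(seed, "model"))
  test <- generate_dataset(set_sim(spec$sim, n_samples = spec$n_test,
                                   seed = derive_seed(seed, "test")))
  rnn_rows <- dplyr::mutate(eval_rnn(spec, fit, test, seed), method = "rnn")
  nl <- fit_batch(test, spec$nlsq)
  nlsq_rows <- dplyr::mutate(evaluate_run(nl, test$params), method = "nlsq")
  dplyr::bind_rows(rnn_rows, nlsq_rows)
}

dropout_psnr_repeat <- function(spec, r, seed) {
  drs <- spec$grid_values %||% c(0, 0.25, 0.5)
  cases <- spec$test_psnr %||% list(10, 15, c(20, 30))
  purrr::map(drs, function(dr) {
    mcfg <- set_cfg(spec$model, model_config, dropout_rate = dr)
    fit <- train_once(spec, spec$sim, mcfg,
                      derive_seed(seed, paste0("dr", dr)))
    purrr::map(cases, function(ps) {
      test <- generate_dataset(set_sim(
        spec$sim, n_samples = spec$n_test, psnr = ps,
        seed = derive_seed(seed, paste0("test", paste(ps, collapse = "-")))))
      dplyr::mutate(eval_rnn(spec, fit, test, seed),
                    dropout_rate = dr,
                    psnr_case = paste(ps, collapse = "-"))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

sweep_repeat <- function(spec, r, seed, what) {
  vals <- spec$grid_values %||%
    if (what == "n_train") c(5e4, 1e5, 2e5) else c(64, 128, 256, 512)
  test <- generate_dataset(set_sim(spec$sim, n_samples = spec$n_test,
                                   seed = derive_seed(seed, "test")))
  purrr::map(vals, function(v) {
    sim_v <- if (what == "n_train") set_sim(spec$sim, n_samples = v)
             else spec$sim
    mcfg <- if (what == "hidden_units")
      set_cfg(spec$model, model_config, hidden_units = v) else spec$model
    fit <- train_once(spec, sim_v, mcfg, derive_seed(seed, paste0(what, v)))
    dplyr::mutate(eval_rnn(spec, fit, test, seed), !!what := v)
  }) |> purrr::list_rbind()
}

#' Mean and SD of experiment metrics across repeats
#'
#' Aggregates the per-repeat table of [run_experiment()] to mean +/- SD per
#' design cell and parameter, mirroring the study's bar-chart groupings.
#'
#' @param results Output of [run_experiment()].
#' @return A tibble with `*_mean` and `*_sd` columns for each metric.
#' @export
summarise_experiment <- function(results) {
  meta <- intersect(c("design", "group", "method", "dropout_rate",
                      "psnr_case", "n_train", "hidden_units", "parameter"),
                    names(results))
  results |>
    dplyr::filter(!is.na(.data$parameter)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta))) |>
    dplyr::summarise(dplyr::across(
      dplyr::any_of(c("ccc", "nrmse", "sigma_uc")),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))),
      n_repeats = dplyr::n(), .groups = "drop")
}
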