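#' Variable flip angle acquisition settings
#'
#' Spoiled gradient-echo multi-flip-angle protocol for pre-contrast T1
#' mapping: flip angles 5-30 degrees in 5-degree steps, TR 4.43 ms.
#'
#' @param flip_angles Flip angles in degrees (>= 2 distinct values).
#' @param tr Repetition time in seconds.
#' @export
vfa_acquisition <- function(flip_angles = c(5, 10, 15, 20, 25, 30),
                            tr = 4.43e-3) {
  stopifnot(length(unique(flip_angles)) >= 2, tr > 0)
  structure(list(flip_angles = flip_angles, tr = tr),
            class = "vfa_acquisition")
}

#' Dynamic acquisition settings
#'
#' DCE-MRI spoiled gradient-echo settings: TR 3.8 ms, flip angle 25 degrees,
#' and contrast-agent relaxivity r1 = 3.9 /mM/s (Gd-DTPA at 1.5 T).
#'
#' @param tr Repetition time in seconds.
#' @param flip_angle Flip angle in degrees.
#' @param r1 Longitudinal relaxivity in 1/(mM s).
#' @export
dce_acquisition <- function(tr = 3.8e-3, flip_angle = 25, r1 = 3.9) {
  stopifnot(tr > 0, flip_angle > 0, r1 > 0)
  structure(list(tr = tr, flip_angle = flip_angle, r1 = r1),
            class = "dce_acquisition")
}

#' Spoiled gradient-echo signal equation
#'
#' `S = K (1 - E) sin(alpha) / (1 - E cos(alpha))` with
#' `E = exp(-TR / T1)`. Vectorised over any argument.
#'
#' @param K Proportionality constant (proton density, coil sensitivity,
#'   T2* weighting).
#' @param t1 Longitudinal relaxation time, s.
#' @param tr Repetition time, s.
#' @param alpha_deg Flip angle in degrees.
#' @export
spgr_signal <- function(K, t1, tr, alpha_deg) {
  a <- alpha_deg * pi / 180
  E <- exp(-tr / t1)
  K * (1 - E) * sin(a) / (1 - E * cos(a))
}

as_pixel_matrix <- function(x) {
  d <- dim(x)
  if (length(d) == 3) {
    structure(matrix(x, d[1] * d[2], d[3]), img_dim = d[1:2])
  } else if (length(d) == 2) {
    structure(x, img_dim = NULL)
  } else abort("expected a (x, y, k) array or an (n_pixels, k) matrix")
}

reshape_map <- function(v, img_dim) {
  if (is.null(img_dim)) v else matrix(v, img_dim[1], img_dim[2])
}

#' Variable flip angle T1 mapping
#'
#' Per pixel, a linearized fit (`S/sin(a)` against `S/tan(a)`, whose slope is
#' `E = exp(-TR/T10)`) seeds a nonlinear least-squares fit of the spoiled
#' gradient-echo equation for `K` and `T10`. The baseline signal `S0` is then
#' evaluated from the same equation at the dynamic acquisition settings.
#' Pixels with non-physical solutions (`T10 <= 0`, `E` outside (0, 1)) or
#' non-convergent fits are masked out and counted.
#'
#' @param signals Per-pixel per-angle intensities: an (x, y, n_angles) array
#'   or (n_pixels, n_angles) matrix.
#' @param acq A [vfa_acquisition()].
#' @param dce A [dce_acquisition()] defining the settings at which `S0` is
#'   computed.
#' @param mask Optional logical mask (same spatial shape); pixels outside
#'   are skipped.
#' @return A list of class `vfa_maps`: `k`, `t10` (s), `s0`, logical
#'   `valid`, and `n_failed`.
#' @export
vfa_fit <- function(signals, acq = vfa_acquisition(), dce = dce_acquisition(),
                    mask = NULL) {
  stopifnot(inherits(acq, "vfa_acquisition"))
  sm <- as_pixel_matrix(signals)
  img_dim <- attr(sm, "img_dim")
  angles <- acq$flip_angles
  stopifnot(ncol(sm) == length(angles))
  a <- angles * pi / 180
  npix <- nrow(sm)
  sel <- if (is.null(mask)) rep(TRUE, npix) else as.logical(mask)
  stopifnot(length(sel) == npix)

  kv <- rep(NA_real_, npix)
  t10v <- rep(NA_real_, npix)
  valid <- rep(FALSE, npix)
  two_angles <- length(angles) == 2
  for (i in which(sel)) {
    s <- sm[i, ]
    if (!all(is.finite(s)) || all(s == 0)) next
    ylin <- s / sin(a)
    xlin <- s / tan(a)
    E <- stats::cov(xlin, ylin) / stats::var(xlin)
    icpt <- mean(ylin) - E * mean(xlin)
    if (!is.finite(E) || E <= 0 || E >= 1 || icpt <= 0) next
    K0 <- icpt / (1 - E)
    T0 <- -acq$tr / log(E)
    if (two_angles) {
      # two unknowns, two equations: the linearized solution is exact
      kv[i] <- K0; t10v[i] <- T0; valid[i] <- TRUE
      next
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(K0, T0),
        lower = c(1e-12, 1e-4), upper = c(Inf, 60),
        fn = function(p) spgr_signal(p[1], p[2], acq$tr, angles) - s,
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12)
      ),
      error = identity)
    if (inherits(fit, "error") || !fit$info %in% 1:4 || fit$par[2] <= 0) next
    kv[i] <- fit$par[1]
    t10v[i] <- fit$par[2]
    valid[i] <- TRUE
  }
  s0 <- ifelse(valid, spgr_signal(kv, t10v, dce$tr, dce$flip_angle), NA_real_)
  structure(list(k = reshape_map(kv, img_dim),
                 t10 = reshape_map(t10v, img_dim),
                 s0 = reshape_map(s0, img_dim),
                 valid = reshape_map(valid, img_dim),
                 n_failed = sum(sel) - sum(valid),
                 vfa = acq, dce = dce),
            class = "vfa_maps")
}

#' Convert a dynamic signal series to concentration
#'
#' Per pixel and frame: the enhancement ratio `A(t) = S(t)/S0` is inverted
#' through the spoiled gradient-echo equation to the longitudinal relaxation
#' rate `1/T1(t)`, converted to concentration
#' `C(t) = (1/r1) (1/T1(t) - 1/T10)`, and multiplied by the calibration
#' factor `CF`. Frames where the inversion leaves the valid domain of the
#' logarithm are set to `NA` and counted per pixel.
#'
#' @param series Signal series: (x, y, n_frames) array or (n_pixels,
#'   n_frames) matrix.
#' @param maps A `vfa_maps` from [vfa_fit()].
#' @param acq A [dce_acquisition()].
#' @param cf Calibration factor (> 0), see [calibration_factor()].
#' @return Concentration array of the same shape (mM), with an
#'   `n_invalid` attribute counting flagged frames per pixel.
#' @export
signal_to_concentration <- function(series, maps, acq = dce_acquisition(),
                                    cf = 1) {
  stopifnot(inherits(maps, "vfa_maps"), inherits(acq, "dce_acquisition"),
            cf > 0)
  sm <- as_pixel_matrix(series)
  img_dim <- attr(sm, "img_dim")
  t10 <- as.vector(maps$t10)
  s0 <- as.vector(maps$s0)
  stopifnot(length(t10) == nrow(sm))
  ca <- cos(acq$flip_angle * pi / 180)
  E0 <- exp(-acq$tr / t10)
  A <- sm / s0
  B <- A * (E0 - 1) / (E0 * ca - 1)       # = A (1 - E0) / (1 - E0 cos a)
  num <- 1 - B
  den <- 1 - B * ca
  Et <- num / den
  bad <- !is.finite(Et) | Et <= 0 | num <= 0 | den <= 0
  Et[bad] <- NA
  r1t <- -log(Et) / acq$tr
  conc <- cf * (r1t - 1 / t10) / acq$r1
  n_invalid <- rowSums(bad & is.finite(sm))
  out <- if (is.null(img_dim)) conc
         else array(conc, c(img_dim, ncol(sm)))
  attr(out, "n_invalid") <- reshape_map(n_invalid, img_dim)
  out
}

#' Calibration factor from AIF and VOF areas
#'
#' `CF = AUC(AIF) / AUC(VOF)` with trapezoidal areas on each curve's own
#' time grid. Used to rescale measured concentrations so the venous output
#' function (free of partial-volume effects) matches the population AIF.
#'
#' @param aif The arterial input curve: a [conc_curve()] or a two-column
#'   data frame (`time`, `conc`).
#' @param vof The venous output curve, same forms, or a bare numeric vector
#'   sharing the AIF's grid.
#' @export
calibration_factor <- function(aif, vof) {
  curve_xy <- function(x, fallback_t = NULL) {
    if (inherits(x, "conc_curve")) list(t = x$grid$times, v = conc_values(x))
    else if (is.data.frame(x)) list(t = x[[1]], v = x[[2]])
    else list(t = fallback_t, v = as.numeric(x))
  }
  av <- curve_xy(aif)
  vv <- curve_xy(vof, fallback_t = av$t)
  if (is.null(vv$t)) abort("vof needs a time axis (conc_curve or data frame)")
  auc_a <- pracma::trapz(av$t, av$v)
  auc_v <- pracma::trapz(vv$t, vv$v)
  if (auc_v <= 0) abort("VOF area under the curve must be positive")
  auc_a / auc_v
}

#' Extract the venous output function from a concentration series
#'
#' With a mask, the mean curve over the masked pixels; without one, the
#' curve of the pixel with the maximum peak concentration inside the brain
#' mask (the superior sagittal sinus carries the hottest, partial-volume
#' free venous signal).
#'
#' @param conc Concentration series: (x, y, n_frames) array or (n_pixels,
#'   n_frames) matrix.
#' @param mask Optional logical vessel mask.
#' @param brain_mask Optional logical search region for auto-selection.
#' @return Numeric frame curve with attribute `pixel` (selected index) when
#'   auto-selected.
#' @export
select_vof <- function(conc, mask = NULL, brain_mask = NULL) {
  cm <- as_pixel_matrix(conc)
  if (!is.null(mask)) {
    sel <- which(as.logical(mask))
    if (length(sel) == 0) abort("empty VOF mask")
    return(colMeans(cm[sel, , drop = FALSE], na.rm = TRUE))
  }
  search <- if (is.null(brain_mask)) seq_len(nrow(cm))
            else which(as.logical(brain_mask))
  if (length(search) == 0) abort("empty brain mask")
  peaks <- apply(cm[search, , drop = FALSE], 1, max, na.rm = TRUE)
  best <- search[which.max(peaks)]
  structure(cm[best, ], pixel = best)
}

# Largest 4-connected component of a logical matrix.
largest_component <- function(mask) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
    tab <- tabulate(lab[lab > 0])
    return(lab == which.max(tab))
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1) p - 1L, if (i < nr) p + 1L,
                  if (j > 1) p - nr, if (j < ncol(mask)) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab == which.max(tabulate(lab[lab > 0]))
}

#' Threshold-based brain mask
#'
#' Binary mask of pixels whose baseline signal exceeds
#' `threshold_fraction * max(S0)`; only the largest connected component is
#' retained. A user-supplied mask can always be passed downstream instead.
#'
#' @param s0_map Baseline signal image (matrix).
#' @param threshold_fraction Fraction of the image maximum in \[0, 1).
#' @return Logical matrix.
#' @export
make_brain_mask <- function(s0_map, threshold_fraction = 0.5) {
  stopifnot(is.matrix(s0_map), threshold_fraction >= 0, threshold_fraction < 1)
  s0 <- s0_map
  s0[!is.finite(s0)] <- -Inf
  mask <- s0 > threshold_fraction * max(s0)
  if (!any(mask)) abort("threshold leaves an empty mask")
  largest_component(mask)
}

#' Pixel-wise pharmacokinetic parameter and uncertainty maps
#'
#' For every masked pixel, assembles the two-channel input (the reference
#' plasma curve with no delay, dispersion, or scaling as channel 1, the
#' pixel's concentration curve as channel 2) and applies either a trained
#' recurrent model via [mcd_predict()] or the constrained least-squares fit
#' via [fit_batch()]. Clinical uncertainties are reported as raw SDs in
#' parameter units. Frames flagged `NA` by the concentration conversion are
#' set to zero for the network input and excluded from least-squares
#' residuals; a per-pixel quality counter is kept.
#'
#' @param conc Concentration series: (x, y, n_frames) array or matrix.
#' @param cp_ref Reference plasma curve: frame values, or a [conc_curve()]
#'   (its fine-grid representation is then used directly by the NLSQ path).
#' @param predictor A trained `rnn_fit` or an [nlsq_config()].
#' @param mask Logical mask of pixels to process (default: all).
#' @param grid [time_grid()] of the series (needed for the NLSQ path).
#' @param n_mc Monte Carlo passes for the RNN path.
#' @param seed Seed for the dropout masks.
#' @return A list of class `parameter_maps`: `value` and `uncertainty`
#'   (named lists of maps for kep, ve, vp, tau_bat, ktrans), `n_invalid`,
#'   and `provenance`.
#' @export
pixelwise_map <- function(conc, cp_ref, predictor, mask = NULL,
                          grid = time_grid(n_frames = dim_last(conc)),
                          n_mc = 100, seed = 1L) {
  cm <- as_pixel_matrix(conc)
  img_dim <- attr(cm, "img_dim")
  npix <- nrow(cm)
  sel <- if (is.null(mask)) rep(TRUE, npix) else as.logical(mask)
  idx <- which(sel)
  if (length(idx) == 0) abort("empty mask")
  sub <- cm[idx, , drop = FALSE]
  n_invalid <- rowSums(!is.finite(sub))

  nm <- c("kep", "ve", "vp", "tau_bat", "ktrans")
  cp_frames <- if (inherits(cp_ref, "conc_curve")) conc_values(cp_ref)
               else cp_ref
  if (inherits(predictor, "rnn_fit")) {
    xin <- sub
    xin[!is.finite(xin)] <- 0
    pr <- mcd_predict(predictor, xin, n_mc = n_mc, seed = seed,
                      cp_ref = cp_frames)
    vals <- pr$mean
    uncs <- pr$sd
    prov <- list(predictor = "rnn", cell = predictor$model_config$cell,
                 dropout_rate = predictor$model_config$dropout_rate,
                 n_mc = pr$n_mc)
  } else if (inherits(predictor, "nlsq_config")) {
    vals <- fit_batch(sub, cfg = predictor, cp_ref = cp_ref, grid = grid)
    uncs <- NULL
    prov <- list(predictor = "nlsq", n_mc = NA_integer_)
  } else abort("predictor must be an rnn_fit or an nlsq_config")

  expand <- function(v) {
    full <- rep(NA_real_, npix)
    full[idx] <- v
    reshape_map(full, img_dim)
  }
  value <- setNames(lapply(nm, function(p) expand(vals[[p]])), nm)
  uncertainty <- setNames(lapply(nm, function(p) {
    if (is.null(uncs)) expand(rep(NA_real_, length(idx)))
    else expand(uncs[[p]])
  }), nm)
  structure(list(value = value, uncertainty = uncertainty,
                 n_invalid = expand(n_invalid), mask = reshape_map(sel, img_dim),
                 provenance = prov),
            class = "parameter_maps")
}

dim_last <- function(x) {
  d <- dim(x)
  d[length(d)]
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> %s predictor, %d pixels mapped\n",
              x$provenance$predictor, sum(x$mask, na.rm = TRUE)))
  invisible(x)
}

#' Concordance between two parameter maps within a region
#'
#' Lin's CCC between the values of two maps over the pixels of a region of
#' interest (e.g. a user-supplied tumor mask), used to compare predictors.
#'
#' @param maps1,maps2 `parameter_maps` objects on the same geometry.
#' @param roi Logical mask.
#' @param params Parameters to compare.
#' @return Tibble with `parameter` and `ccc`.
#' @export
roi_ccc <- function(maps1, maps2, roi,
                    params = c("kep", "ve", "vp", "ktrans", "tau_bat")) {
  sel <- as.logical(roi)
  purrr::map(params, function(p) {
    a <- as.vector(maps1$value[[p]])[sel]
    b <- as.vector(maps2$value[[p]])[sel]
    keep <- is.finite(a) & is.finite(b)
    tibble::tibble(parameter = p, ccc = ccc(a[keep], b[keep]),
                   n = sum(keep))
  }) |> purrr::list_rbind()
}

#' Read a NIfTI volume as a plain array
#'
#' Thin wrapper over RNifti for feeding image data into the clinical chain.
#'
#' @param path NIfTI file path.
#' @export
read_nifti_array <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("RNifti is required to read NIfTI files")
  unclass(as.array(RNifti::readNifti(path)))
}

#' Write parameter maps to NIfTI volumes
#'
#' One volume per parameter for values and (when present) uncertainties:
#' `<prefix>_<param>.nii.gz` and `<prefix>_<param>_sd.nii.gz`, plus a JSON
#' provenance sidecar.
#'
#' @param maps A `parameter_maps`.
#' @param prefix Output path prefix.
#' @export
write_parameter_maps <- function(maps, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("RNifti is required to write NIfTI files")
  for (p in names(maps$value)) {
    RNifti::writeNifti(maps$value[[p]], sprintf("%s_%s.nii.gz", prefix, p))
    if (!all(is.na(maps$uncertainty[[p]])))
      RNifti::writeNifti(maps$uncertainty[[p]],
                         sprintf("%s_%s_sd.nii.gz", prefix, p))
  }
  jsonlite::write_json(maps$provenance, paste0(prefix, "_provenance.json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}
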