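#' Acquisition time grid
#'
#' Defines the frame times of a DCE-MRI acquisition together with an internal
#' oversampled ("fine") grid on which all convolutions are evaluated. The
#' default matches a 65-frame acquisition at 4.8 s per frame; the default
#' oversampling factor of 48 gives a 0.1 s fine step, far below the smallest
#' dispersion constant considered (0.1 s), so that exponential-kernel
#' convolutions are resolved rather than aliased by the frame spacing.
#'
#' @param n_frames Number of frames (>= 2).
#' @param dt Seconds per frame (> 0).
#' @param oversample Integer >= 1; the fine grid has `oversample` steps per
#'   frame interval.
#' @return An object of class `time_grid` with frame times `times`, fine times
#'   `fine_times`, and fine step `fine_dt`.
#' @examples
#' g <- time_grid()
#' range(g$times)
#' @export
time_grid <- function(n_frames = 65, dt = 4.8, oversample = 48) {
  stopifnot(n_frames >= 2, dt > 0, oversample >= 1)
  oversample <- as.integer(oversample)
  n_fine <- (n_frames - 1L) * oversample + 1L
  fine_dt <- dt / oversample
  structure(
    list(
      n_frames = as.integer(n_frames),
      dt = dt,
      oversample = oversample,
      times = (seq_len(n_frames) - 1) * dt,
      n_fine = n_fine,
      fine_dt = fine_dt,
      fine_times = (seq_len(n_fine) - 1) * fine_dt
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d frames x %.3g s (span %.1f s), fine step %.4g s\n",
    x$n_frames, x$dt, x$times[x$n_frames], x$fine_dt
  ))
  invisible(x)
}

#' Concentration curve
#'
#' A concentration-time curve on a [time_grid()]. Values are carried on the
#' fine (oversampled) grid internally; [conc_values()] and
#' [as_tibble.conc_curve()] expose the frame-resolution view.
#'
#' @param fine Numeric vector of concentrations (mM) on `grid$fine_times`.
#' @param grid A [time_grid()].
#' @return An object of class `conc_curve`.
#' @export
conc_curve <- function(fine, grid) {
  stopifnot(inherits(grid, "time_grid"), length(fine) == grid$n_fine,
            all(is.finite(fine)))
  structure(list(fine = as.numeric(fine), grid = grid), class = "conc_curve")
}

#' Build a concentration curve from frame-resolution values
#'
#' Frame values are linearly interpolated onto the fine grid, so curves read
#' back from columnar text round-trip through the forward model machinery.
#'
#' @param values Numeric vector of length `grid$n_frames`.
#' @inheritParams conc_curve
#' @export
conc_curve_from_frames <- function(values, grid) {
  stopifnot(length(values) == grid$n_frames)
  fine <- approx(grid$times, values, xout = grid$fine_times, rule = 2)$y
  conc_curve(fine, grid)
}

#' Frame-resolution values of a concentration curve
#'
#' @param curve A [conc_curve()].
#' @return Numeric vector of length `n_frames`.
#' @export
conc_values <- function(curve) {
  stopifnot(inherits(curve, "conc_curve"))
  g <- curve$grid
  curve$fine[seq(1L, g$n_fine, by = g$oversample)]
}

#' @export
as_tibble.conc_curve <- function(x, ...) {
  tibble::tibble(time = x$grid$times, conc = conc_values(x))
}

#' @export
print.conc_curve <- function(x, ...) {
  v <- conc_values(x)
  cat(sprintf("<conc_curve> %d frames, peak %.4g mM at t = %.1f s\n",
              x$grid$n_frames, max(v), x$grid$times[which.max(v)]))
  invisible(x)
}

#' Write / read a concentration curve as columnar text
#'
#' Two-column CSV (`time`, `conc`) at frame resolution.
#'
#' @param curve A [conc_curve()].
#' @param path File path.
#' @export
write_curve <- function(curve, path) {
  write.csv(as_tibble.conc_curve(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @param grid Optional [time_grid()]; inferred from the file's time column
#'   (with the default oversampling) when omitted.
#' @export
read_curve <- function(path, grid = NULL) {
  d <- read.csv(path)
  if (is.null(grid)) {
    dt <- diff(d$time[1:2])
    grid <- time_grid(n_frames = nrow(d), dt = dt)
  }
  conc_curve_from_frames(d$conc, grid)
}
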