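#' FFT-based impedance profile from voltage and current traces
#'
#' \eqn{Z(f) = \mathrm{FFT}(V - \bar V)/\mathrm{FFT}(I - \bar I)} at the
#' positive frequency bins up to `f_max`.  No window is applied (the chirp
#' occupies the full record and starts/ends near zero); only the means are
#' removed.  Bins where the current spectrum is below `floor_rel` times its
#' maximum are dropped (the transfer estimate is undefined there).
#'
#' @param V voltage trace (mV).
#' @param I current trace (nA), same length, same uniform grid.
#' @param dt sample interval (ms).
#' @param f_max upper analysis frequency (Hz).
#' @param floor_rel relative floor on `|FFT(I)|` below which bins are dropped.
#' @return An `impedance_profile`: data.frame with columns `f` (Hz, ascending),
#'   `Z` (complex, MΩ), `magnitude`, `phase` (radians, in (−π, π]).
#' @export
impedance_profile <- function(V, I, dt, f_max = 5, floor_rel = 1e-6) {
  if (length(V) != length(I)) stop("voltage and current traces differ in length")
  if (all(I == 0)) stop("all-zero current trace")
  n <- length(V)
  fs <- 1000 / dt                           # Hz
  f <- (seq_len(n) - 1) * fs / n
  FV <- stats::fft(V - mean(V))
  FI <- stats::fft(I - mean(I))
  keep <- f > 0 & f <= f_max & Mod(FI) > floor_rel * max(Mod(FI))
  Z <- FV[keep] / FI[keep]
  mp <- magnitude_phase(Z)
  out <- data.frame(f = f[keep], magnitude = mp$magnitude, phase = mp$phase)
  out$Z <- Z
  class(out) <- c("impedance_profile", "data.frame")
  out
}

#' Magnitude and phase of a complex impedance series
#'
#' @param Z complex vector.
#' @return list with `magnitude` (\eqn{\sqrt{Z_{Re}^2+Z_{Im}^2}}) and `phase`
#'   (`atan2(Im, Re)`, radians in (−π, π]).
#' @export
magnitude_phase <- function(Z) {
  stopifnot(all(is.finite(Re(Z))), all(is.finite(Im(Z))))
  list(magnitude = Mod(Z), phase = atan2(Im(Z), Re(Z)))
}

#' Local-regression smoothing of an impedance magnitude curve
#'
#' Locally weighted linear regression (lowess with zero robustness
#' iterations) over the frequency axis; window endpoints shrink at the
#' boundaries.  Constant and linear-in-f inputs pass through unchanged.
#'
#' @param magnitude magnitude series.
#' @param f frequency grid (same length); defaults to the sample index.
#' @param span fraction of points in each local window, in (0, 1].
#' @return smoothed series, same length and order as the input.
#' @export
smooth_magnitude <- function(magnitude, f = seq_along(magnitude), span = 0.1) {
  stopifnot(span > 0, span <= 1, length(f) == length(magnitude))
  if (length(magnitude) < 4L) return(magnitude)
  stats::lowess(f, magnitude, f = span, iter = 0)$y[rank(f)]
}

#' Resonance metrics of an impedance profile
#'
#' The resonance frequency is the argmax of the (optionally smoothed)
#' impedance magnitude over `f >= f_floor`, refined by parabolic
#' interpolation through the peak bin and its neighbours.  The Q-factor is
#' the ratio of the peak magnitude to the magnitude at 0.5 Hz (linearly
#' interpolated); the model is called resonant when `Q >= 1.01` (the peak is
#' at least 1% above the low-frequency impedance).  A profile whose maximum
#' sits at the left analysis boundary has no interior peak: `f_res` is `NA`
#' and `Q` is reported as 1.
#'
#' @param profile an `impedance_profile` (its grid must cover 0.5 Hz).
#' @param span smoothing span passed to [smooth_magnitude()]; `NULL` skips
#'   smoothing (appropriate for noise-free closed-form or circuit profiles).
#' @param f_floor lowest frequency (Hz) considered for the peak.
#' @return the profile with a `mag_smooth` column and attached metrics
#'   (also returned in `attr(x, "metrics")`): `f_res` (Hz), `Z_max` (MΩ),
#'   `Q`, `is_resonant`.
#' @export
resonance_metrics <- function(profile, span = 0.1, f_floor = 0.1) {
  f <- profile$f
  if (min(f) > 0.5 || max(f) < 0.5)
    stop("frequency grid does not cover 0.5 Hz; Q undefined")
  mag <- if (is.null(span)) profile$magnitude else
    smooth_magnitude(profile$magnitude, f, span)
  profile$mag_smooth <- mag
  sel <- which(f >= f_floor)
  i <- sel[which.max(mag[sel])]
  at_left <- i == sel[1L]
  if (at_left) {
    f_res <- NA_real_
    Z_max <- mag[i]
    Q <- 1
  } else if (i < length(f)) {
    # parabola through (f[i-1..i+1], mag[i-1..i+1])
    y1 <- mag[i - 1L]; y2 <- mag[i]; y3 <- mag[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(-1, min(1, delta))
    h <- f[i + 1L] - f[i]
    f_res <- f[i] + delta * h
    Z_max <- y2 - 0.25 * (y1 - y3) * delta
    Q <- Z_max / stats::approx(f, mag, xout = 0.5)$y
  } else {
    f_res <- f[i]; Z_max <- mag[i]
    Q <- Z_max / stats::approx(f, mag, xout = 0.5)$y
  }
  metrics <- list(f_res = f_res, Z_max = Z_max, Q = Q,
                  is_resonant = !at_left && Q >= 1.01)
  attr(profile, "metrics") <- metrics
  profile
}

#' Extract the metrics list from a profile
#' @param profile output of [resonance_metrics()].
#' @export
get_metrics <- function(profile) attr(profile, "metrics")

#' Write an impedance profile (CSV) and its metrics (JSON sidecar)
#'
#' @param profile an `impedance_profile`, ideally after
#'   [resonance_metrics()].
#' @param path CSV output path; metrics go to `<path>.metrics.json` when
#'   present.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(f_Hz = profile$f,
                   Re_MOhm = Re(profile$Z), Im_MOhm = Im(profile$Z),
                   mag_MOhm = profile$magnitude,
                   mag_smoothed = if (!is.null(profile$mag_smooth))
                     profile$mag_smooth else NA_real_,
                   phase_rad = profile$phase)
  utils::write.csv(df, path, row.names = FALSE)
  m <- attr(profile, "metrics")
  if (!is.null(m))
    jsonlite::write_json(m, paste0(path, ".metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Impedance profile of a simulated chirp response
#'
#' Convenience wrapper: runs [impedance_profile()] on a nonlinear
#' (`pd_trace`) or linear (`linear_trace`) chirp response and attaches
#' resonance metrics.  For the nonlinear model the magnitude is smoothed
#' (the HH-type response carries harmonic ripple); circuit responses are
#' analyzed unsmoothed by default.
#'
#' @param trace a `pd_trace` or `linear_trace`.
#' @param stimulus for `linear_trace`, the perturbation stimulus that
#'   produced it (a `pd_trace` carries its own input column).
#' @param span smoothing span (`NULL` to disable).
#' @param f_max upper analysis frequency (Hz).
#' @return an `impedance_profile` with metrics.
#' @export
trace_impedance <- function(trace, stimulus = NULL, span = NULL, f_max = 5) {
  dt <- attr(trace, "dt")
  if (inherits(trace, "pd_trace")) {
    pr <- impedance_profile(trace$V, trace$I_inp, dt, f_max = f_max)
  } else {
    if (is.null(stimulus)) stop("linear traces need the stimulus")
    pr <- impedance_profile(trace$v, stimulus$I, dt, f_max = f_max)
  }
  resonance_metrics(pr, span = span)
}
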