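#' Chirp (ZAP) input current
#'
#' A sinusoidal current whose frequency sweeps linearly across the band,
#' \deqn{I(t) = I_{amp}\,\sin(2\pi f(t)\,t), \qquad
#'       f(t) = f_0 + (f_{max}-f_0)\,\frac{t}{2T},}
#' so that the instantaneous frequency \eqn{\frac{d}{dt}[f(t)\,t]} sweeps
#' linearly from `f0` at \eqn{t = 0} to `f_max` at \eqn{t = T}.  (The /2T in
#' the phase-rate symbol is what makes the *instantaneous* frequency, not the
#' symbol \eqn{f(t)} itself, cover the stated band.)
#'
#' @param I_amp amplitude (nA).
#' @param f0 start frequency (Hz), `>= 0`.
#' @param f_max end frequency (Hz), `> f0`.
#' @param T_total total duration (s).
#' @param dt sample interval (ms).  Must resolve the fastest cycle
#'   (`f_max * dt < 50` with `dt` in ms, i.e. at least 20 samples/cycle).
#' @param pad trailing zero-input time (s) appended after the sweep.  The
#'   FFT transfer estimate divides spectra of the *whole* record; without a
#'   ring-down window the response still owed to the final sweep cycles is
#'   truncated, which biases every bin by a few percent.  Two seconds
#'   (several membrane and h-current time constants) makes the truncation
#'   error negligible; set `pad = 0` for the bare sweep.
#' @return data.frame of class `pd_stimulus` with columns `t` (ms) and
#'   `I` (nA), on a uniform grid starting at 0.
#' @examples
#' ch <- chirp_current(0.5, 0, 5, 10)
#' range(ch$I)  # ~ +/- 0.5 nA
#' @export
chirp_current <- function(I_amp, f0 = 0, f_max = 5, T_total = 10, dt = 0.05,
                          pad = 2) {
  stopifnot(f_max > f0, f0 >= 0, T_total > 0, dt > 0, pad >= 0)
  if (f_max * dt / 1000 >= 0.05)
    stop("dt too coarse for f_max: need >= 20 samples per fastest cycle")
  t_ms <- seq(0, T_total * 1000, by = dt)
  ts <- t_ms / 1000                               # sine phase is in seconds
  f_t <- f0 + (f_max - f0) * ts / (2 * T_total)
  I <- I_amp * sin(2 * pi * f_t * ts)
  if (pad > 0) I <- c(I, rep(0, round(pad * 1000 / dt)))
  structure(data.frame(t = seq_along(I) * dt - dt, I = I),
            class = c("pd_stimulus", "data.frame"),
            dt = dt, I_amp = I_amp, f0 = f0, f_max = f_max,
            T_total = T_total, pad = pad)
}

#' Constant (DC) current
#'
#' @param level current level (nA).
#' @param T_total duration (s).
#' @param dt sample interval (ms).
#' @return data.frame of class `pd_stimulus` with columns `t` (ms), `I` (nA).
#' @export
dc_current <- function(level, T_total, dt = 0.05) {
  stopifnot(T_total > 0, dt > 0)
  t_ms <- seq(0, T_total * 1000, by = dt)
  structure(data.frame(t = t_ms, I = rep(level, length(t_ms))),
            class = c("pd_stimulus", "data.frame"), dt = dt)
}

#' Add a DC offset to a stimulus (e.g. superimpose the holding current)
#' @param stim a `pd_stimulus`.
#' @param level DC offset (nA).
#' @return the shifted stimulus.
#' @export
offset_stimulus <- function(stim, level) {
  stim$I <- stim$I + level
  stim
}

#' Write a stimulus as a two-column CSV (t_ms, I_nA)
#' @param stim a `pd_stimulus`.
#' @param path output file.
#' @export
write_stimulus_csv <- function(stim, path) {
  utils::write.csv(data.frame(t_ms = stim$t, I_nA = stim$I), path,
                   row.names = FALSE)
  invisible(path)
}
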