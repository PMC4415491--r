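#' Reference RLC circuit with closed-form impedance
#'
#' A single-branch parallel RLC-with-leak circuit (capacitance `C`, leak
#' conductance `gL`, one series RL branch), used as a pipeline test oracle:
#' its impedance has a closed form evaluated directly here, independently of
#' [analytic_impedance()], and its resonance frequency is located numerically
#' from that closed form rather than from any FFT.
#'
#' The defaults put the resonance in the band probed by the default chirp
#' (about 1.9 Hz with a moderate Q of about 1.3).
#'
#' @param C capacitance (nF), positive.
#' @param gL leak conductance (µS), positive.
#' @param R branch resistance (MΩ), positive.
#' @param L branch inductance (MΩ·ms), positive.
#' @return A `reference_circuit` (also usable wherever a `linear_circuit`
#'   is accepted: fields `C`, `g_inst`, `branches`).
#' @examples
#' rc <- make_reference_rlc()
#' reference_impedance(rc, c(0.5, 1, 2))
#' reference_resonance(rc)
#' @export
make_reference_rlc <- function(C = 1, gL = 0.05, R = 10, L = 10000) {
  stopifnot(C > 0, gL > 0, R > 0, L > 0)
  structure(list(C = C, g_inst = c(leak = gL),
                 branches = list(rl_branch("ref", R, L, "ref")),
                 V_star = NA_real_),
            class = c("reference_circuit", "linear_circuit"))
}

#' Closed-form impedance of the reference circuit
#'
#' Direct evaluation of
#' \eqn{Z(f) = [\,j\omega C + g_L + 1/(R + j\omega L)\,]^{-1}} with
#' \eqn{\omega = 2\pi f/1000}; written out explicitly (real/imaginary parts
#' of the rationalized expression) so it shares no code with the module under
#' test.
#'
#' @param rc a `reference_circuit`.
#' @param f frequency vector (Hz).
#' @return complex impedance (MΩ).
#' @export
reference_impedance <- function(rc, f) {
  w <- 2 * pi * f / 1000
  gL <- rc$g_inst[["leak"]]; R <- rc$branches[[1]]$R; L <- rc$branches[[1]]$L
  den <- R^2 + (w * L)^2
  Yre <- gL + R / den
  Yim <- w * rc$C - w * L / den
  mag2 <- Yre^2 + Yim^2
  complex(real = Yre / mag2, imaginary = -Yim / mag2)
}

#' Resonance of the reference circuit located from the closed form
#'
#' Maximizes the closed-form magnitude on `[f_floor, f_max]` by golden-section
#' search ([stats::optimize()]); returns `f_res = NA` when the maximum sits
#' at the lower boundary (no interior peak).
#'
#' @param rc a `reference_circuit`.
#' @param f_floor,f_max search interval (Hz).
#' @return list with `f_res` (Hz), `Z_max` (MΩ) and `Q`
#'   (`Z_max / |Z(0.5)|`).
#' @export
reference_resonance <- function(rc, f_floor = 0.1, f_max = 5) {
  opt <- stats::optimize(function(f) Mod(reference_impedance(rc, f)),
                         c(f_floor, f_max), maximum = TRUE, tol = 1e-8)
  at_left <- opt$maximum - f_floor < 1e-4 &&
    Mod(reference_impedance(rc, f_floor)) >= opt$objective - 1e-12
  Z05 <- Mod(reference_impedance(rc, 0.5))
  if (at_left) list(f_res = NA_real_, Z_max = Mod(reference_impedance(rc, f_floor)),
                    Q = 1)
  else list(f_res = opt$maximum, Z_max = opt$objective, Q = opt$objective / Z05)
}

#' Seeded noisy magnitude series
#'
#' Adds i.i.d. Gaussian noise to a base magnitude curve under a fixed seed;
#' used to exercise [smooth_magnitude()] with a known noiseless argmax.
#'
#' @param seed integer seed (default 20150416; always caller-overridable).
#' @param base_profile numeric base magnitude series.
#' @param noise_sd noise standard deviation (same units as the base).
#' @return numeric series, reproducible for a fixed seed.
#' @export
generate_noisy_profile <- function(seed = 20150416, base_profile, noise_sd) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(base_profile)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base_profile + stats::rnorm(length(base_profile), sd = noise_sd)
}
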