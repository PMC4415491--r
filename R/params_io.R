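#' Read / write model parameters as a flat key-value config
#'
#' The config is a flat YAML mapping whose keys mirror the model tables:
#' conductances (`g_h`, `g_CaT`, `g_CaS`, `g_KCa`, `g_leak`), reversals
#' (`E_h`, `E_K`, `E_Ca`, optionally `E_leak`), capacitance `C`, calcium
#' constants (`tau_Ca`, `C0`, `F_Ca`, `Kd`), `V_rest`, and the h-activation
#' midpoint/slope (`h_half`, `h_slope`).  Keys not present fall back to the
#' control defaults of [pd_control_params()].  The bundled
#' `control.yaml` reproduces the control condition exactly:
#' `system.file("extdata", "control.yaml", package = "pdresonance")`.
#'
#' @param path file path of the YAML config.
#' @return `read_pd_params()` returns a `pd_params`; `write_pd_params()`
#'   writes `params` to `path` and returns `path` invisibly.
#' @export
read_pd_params <- function(path) {
  kv <- yaml::read_yaml(path)
  known <- names(formals(pd_control_params))
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pd_control_params, kv)
}

#' @rdname read_pd_params
#' @param params a `pd_params` object.
#' @export
write_pd_params <- function(params, path) {
  ch <- params$channels
  kv <- list(
    g_h = ch$h$gbar, g_CaT = ch$CaT$gbar, g_CaS = ch$CaS$gbar,
    g_KCa = ch$KCa$gbar, g_leak = params$g_leak,
    E_h = ch$h$reversal, E_K = ch$KCa$reversal, E_Ca = params$E_Ca,
    E_leak = params$E_leak, C = params$C,
    tau_Ca = params$calcium$tau_Ca, C0 = params$calcium$C0,
    F_Ca = params$calcium$F, Kd = params$calcium$Kd,
    V_rest = params$V_rest,
    h_half = ch$h$activation$half_voltage, h_slope = ch$h$activation$slope)
  yaml::write_yaml(kv, path)
  invisible(path)
}

#' Scale or zero maximal conductances
#'
#' Convenience used by the experiment drivers: returns `params` with the
#' named channels' maximal conductances multiplied by `factor` (0 knocks the
#' channel out).  `"Ca"` is shorthand for both calcium channels, CaT and CaS.
#' The leak reversal is kept as-is so the control equilibrium map is not
#' silently redefined; holding potentials are set by holding current.
#'
#' @param params a `pd_params` object.
#' @param channel channel name(s): `"h"`, `"CaT"`, `"CaS"`, `"KCa"` or `"Ca"`.
#' @param factor non-negative scale factor(s), recycled over `channel`.
#' @return modified `pd_params`.
#' @export
scale_conductance <- function(params, channel, factor) {
  stopifnot(all(factor >= 0))
  channel <- unlist(lapply(channel, function(x)
    if (x == "Ca") c("CaT", "CaS") else x))
  factor <- rep_len(rep(factor, length.out = length(channel)), length(channel))
  for (i in seq_along(channel)) {
    nm <- channel[[i]]
    if (is.null(params$channels[[nm]])) stop("unknown channel: ", nm)
    params$channels[[nm]]$gbar <- params$channels[[nm]]$gbar * factor[[i]]
  }
  params
}
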