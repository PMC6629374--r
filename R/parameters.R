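#' Model parameters for the single-compartment VIP interneuron
#'
#' Conductance densities, reversal potentials, membrane geometry and the
#' slow-potassium time constant of the Hodgkin-Huxley style model
#'
#' \deqn{c_m dV/dt = g_{leak}(E_l - V) + m^3 h\, g_{Na}(E_{Na} - V)
#'       + n^3 g_{KDR}(E_K - V) + s\, g_{KS}(E_K - V) + (I_{inj}+I_{noise})/A}
#'
#' Defaults are the published model values: `g_leak = 0.03`, `g_kdr = 5`,
#' `g_na = 65`, `g_ks = 2` mS/cm2; `e_leak = -70` (the chloride/leak
#' reversal), `e_k = -70`, `e_na = 50` mV; `tau_s = 300` ms; noise amplitude
#' 10 pA. Specific capacitance and membrane area are not part of the
#' published set; the defaults `c_m = 0.75` uF/cm2 and `area = 2e-5` cm2
#' are calibrated so that a 600 ms x 100 pA test pulse reproduces the
#' published firing phenotypes across the gNa x gKS plane (see the
#' package vignette for the calibration and its trade-offs).
#'
#' @param g_leak,g_na,g_kdr,g_ks conductance densities, mS/cm2.
#' @param e_leak,e_na,e_k reversal potentials, mV.
#' @param c_m specific membrane capacitance, uF/cm2.
#' @param area membrane area, cm2.
#' @param tau_s slow potassium (M-like) activation time constant, ms.
#' @param noise_amplitude maximal noise-current amplitude, pA. The per-step
#'   Gaussian noise draw has `sd = noise_amplitude/3` and is clipped at
#'   `+/- noise_amplitude`.
#' @param kdr_exponent exponent on the delayed-rectifier gate `n`
#'   (3 as published; 4 gives the classic squid formulation).
#' @param i_bias constant bias (holding) current, pA, added to every
#'   stimulus; used e.g. to emulate muscarinic depolarization.
#'
#' @return An object of class `vip_params` (a named list).
#' @examples
#' p <- model_parameters()
#' input_resistance(p)
#' @export
model_parameters <- function(g_leak = 0.03, g_na = 65, g_kdr = 5, g_ks = 2,
                             e_leak = -70, e_na = 50, e_k = -70,
                             c_m = 0.75, area = 2e-5, tau_s = 300,
                             noise_amplitude = 10, kdr_exponent = 3,
                             i_bias = 0) {
  p <- list(g_leak = g_leak, g_na = g_na, g_kdr = g_kdr, g_ks = g_ks,
            e_leak = e_leak, e_na = e_na, e_k = e_k,
            c_m = c_m, area = area, tau_s = tau_s,
            noise_amplitude = noise_amplitude,
            kdr_exponent = kdr_exponent, i_bias = i_bias)
  for (nm in c("g_leak", "g_na", "g_kdr", "g_ks"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("conductance density '%s' must be finite and >= 0", nm))
  if (p$c_m <= 0) stop("c_m must be > 0")
  if (p$area <= 0) stop("area must be > 0")
  if (p$tau_s <= 0) stop("tau_s must be > 0")
  if (p$noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  structure(p, class = "vip_params")
}

#' Input resistance implied by the leak conductance
#'
#' @param params a [model_parameters()] object.
#' @return Input resistance in MOhm, `1/(g_leak * area)`.
#' @export
input_resistance <- function(params) {
  # g mS/cm2 * area cm2 = mS; 1/mS = kOhm; -> MOhm
  1 / (params$g_leak * params$area) * 1e-3
}

#' @export
print.vip_params <- function(x, ...) {
  cat("VIP-IN model parameters\n")
  cat(sprintf("  conductances (mS/cm2): g_leak %.3g, g_Na %.3g, g_KDR %.3g, g_KS %.3g\n",
              x$g_leak, x$g_na, x$g_kdr, x$g_ks))
  cat(sprintf("  reversals (mV): E_leak %g, E_Na %g, E_K %g\n",
              x$e_leak, x$e_na, x$e_k))
  cat(sprintf("  c_m %g uF/cm2, area %.3g cm2 (R_in ~ %.0f MOhm), tau_s %g ms\n",
              x$c_m, x$area, input_resistance(x), x$tau_s))
  cat(sprintf("  noise amplitude %g pA, KDR exponent %g, bias %g pA\n",
              x$noise_amplitude, x$kdr_exponent, x$i_bias))
  invisible(x)
}

#' Read / write model configuration as YAML
#'
#' A round-trippable plain-text representation of [model_parameters()]
#' (section `parameters`) plus optional named protocol definitions
#' (section `protocols`, each a list with `kind`, `dt` and kind-specific
#' fields passed to [step_protocol()] or [ramp_protocol()]).
#'
#' @param path file path.
#' @param params a `vip_params` object.
#' @param protocols optional named list of protocol definitions.
#' @return `read_model_config()` returns a list with elements `params` and
#'   `protocols`; `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(model_parameters, cfg$parameters %||% list())
  protocols <- lapply(cfg$protocols %||% list(), function(pr) {
    kind <- pr$kind %||% "step"
    pr$kind <- NULL
    switch(kind,
           step = do.call(step_protocol, pr),
           ramp = do.call(ramp_protocol, pr),
           stop(sprintf("unknown protocol kind '%s'", kind)))
  })
  list(params = params, protocols = protocols)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(path, params, protocols = NULL) {
  stopifnot(inherits(params, "vip_params"))
  cfg <- list(parameters = unclass(params))
  if (!is.null(protocols)) cfg$protocols <- protocols
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
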