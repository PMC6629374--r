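#' Simulate the single-compartment VIP interneuron
#'
#' Forward-Euler integration of the Hodgkin-Huxley VIP-IN model with the
#' slow M-like potassium conductance (see [model_parameters()] for the
#' membrane equation). Gating variables follow
#' `dx/dt = (x_inf - x)/tau_x` with the rates of [rate_constants()];
#' the slow gate `s` relaxes to `s_inf(V)` with fixed time constant
#' `tau_s`. Noise, when enabled, is a per-step Gaussian current draw
#' (`sd = noise_amplitude/3`, clipped at `+/- noise_amplitude` pA)
#' injected at every step, including zero-current padding.
#'
#' With `noise = TRUE` the trace is reproducible from `seed`; with
#' `noise = FALSE` it is seed-invariant.
#'
#' @param params a [model_parameters()] object.
#' @param protocol a [step_protocol()]/[ramp_protocol()] object (its `dt`
#'   is used unless `dt` is given).
#' @param dt integration step, ms; must be positive and at most 0.05 ms
#'   (convergence-tested default 0.01 ms).
#' @param seed integer seed for the noise stream, or `NULL` to use the
#'   current RNG state.
#' @param noise logical; inject the noise current?
#' @param v0 initial membrane potential (mV), or `"steady"` to start from
#'   the resting state (root of the steady-state current; if no root is
#'   bracketed, falls back to -70 mV plus a 500 ms silent equilibration).
#' @param record_gating keep the gating-variable time series?
#' @return An object of class `voltage_trace`: list with `t` (ms), `v`
#'   (mV), `i` (injected command current, pA, noise-free), `dt`, `protocol`,
#'   `seed`, and optionally `gating` (data.frame m/h/n/s).
#' @examples
#' tr <- simulate_cell(model_parameters(), step_protocol(100), noise = FALSE)
#' length(detect_spikes(tr)$spike_times)
#' @export
simulate_cell <- function(params, protocol, dt = protocol$dt, seed = NULL,
                          noise = TRUE, v0 = "steady",
                          record_gating = FALSE) {
  stopifnot(inherits(params, "vip_params"), inherits(protocol, "stim_protocol"))
  if (!is.finite(dt) || dt <= 0 || dt > 0.05)
    stop("dt must be in (0, 0.05] ms")
  if (!identical(dt, protocol$dt)) {
    protocol$dt <- dt
  }
  i_inj <- protocol_waveform(protocol) + params$i_bias

  equilibrate_ms <- 0
  if (identical(v0, "steady")) {
    v0 <- resting_state(params)
    if (is.na(v0)) {
      v0 <- -70
      equilibrate_ms <- 500
    }
  }
  if (!is.numeric(v0) || !is.finite(v0)) stop("v0 must be finite or 'steady'")

  g0 <- steady_state_gating(v0)
  n_eq <- round(equilibrate_ms / dt)
  i_full <- if (n_eq > 0) c(rep(params$i_bias, n_eq), i_inj) else i_inj

  if (!is.null(seed)) set.seed(as.integer(seed))
  res <- .hh_euler_cpp(i_full, dt,
                       params$g_leak, params$g_na, params$g_kdr, params$g_ks,
                       params$e_leak, params$e_na, params$e_k,
                       params$c_m, params$area, params$tau_s,
                       params$kdr_exponent,
                       v0, g0[["m"]], g0[["h"]], g0[["n"]], g0[["s"]],
                       noise, params$noise_amplitude / 3,
                       params$noise_amplitude, record_gating)

  keep <- if (n_eq > 0) (n_eq + 1):length(i_full) else seq_along(i_full)
  n <- length(keep)
  out <- list(t = (seq_len(n) - 1) * dt,
              v = res$v[keep],
              i = i_inj,
              dt = dt,
              protocol = protocol,
              seed = seed)
  if (record_gating)
    out$gating <- data.frame(m = res$m[keep], h = res$h[keep],
                             n = res$n[keep], s = res$s[keep])
  structure(out, class = "voltage_trace")
}

#' Resting membrane potential of the model
#'
#' Solves `I_ss(V) = 0` (total membrane current with steady-state gating)
#' by root bracketing over -100 to -40 mV.
#'
#' @param params a [model_parameters()] object.
#' @param i_inj_pA constant injected current, pA.
#' @return Resting potential in mV, or `NA` if no root is bracketed in the
#'   subthreshold range.
#' @export
resting_state <- function(params, i_inj_pA = params$i_bias) {
  f <- function(v) steady_state_current(v, params, i_inj_pA)
  grid <- seq(-100, -40, by = 1)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flip)) return(NA_real_)
  i <- flip[1L]
  uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples, dt = %g ms (%.1f ms), protocol '%s'\n",
              length(x$v), x$dt, max(x$t), x$protocol$label))
  cat(sprintf("  V range [%.1f, %.1f] mV%s\n", min(x$v), max(x$v),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

# Index window (inclusive) of the stimulus pulse within a trace.
pulse_window_idx <- function(trace) {
  on <- trace$protocol$pulse_onset_ms
  off <- trace$protocol$pulse_end_ms
  c(floor(on / trace$dt) + 1L,
    min(length(trace$v), floor(off / trace$dt)))
}
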