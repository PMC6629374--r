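#' Voltage-dependent rate constants of the VIP-IN model
#'
#' The published alpha/beta expressions for the sodium activation (`m`) and
#' inactivation (`h`) gates and the delayed-rectifier gate (`n`), plus the
#' steady-state activation `s_inf` of the slow, M-like potassium gate
#' (whose time constant is fixed at `tau_s`, not voltage dependent):
#'
#' \deqn{\alpha_m = 0.1(V+38)/(1 - e^{-(V+38)/10}), \quad
#'       \beta_m = 4 e^{-(V+65)/17}}
#' \deqn{\alpha_h = 0.05 e^{-(V+55)/20}, \quad
#'       \beta_h = 1/(e^{-(V+35)/10} + 1)}
#' \deqn{\alpha_n = 0.01(V+55)/(1 - e^{-(V+55)/10}), \quad
#'       \beta_n = 0.125 e^{-(V+65)/80}}
#' \deqn{s_\infty = 1/(1 + e^{-(V+35)/5})}
#'
#' `alpha_m` and `alpha_n` have removable singularities at V = -38 and
#' V = -55 mV; within 1e-6 mV of those voltages the analytic limits
#' (1.0 and 0.1 per ms) are returned.
#'
#' @param v membrane potential(s), mV. Must be finite.
#' @return A named list of vectors (`alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, `s_inf`), each the length of `v`;
#'   rates in 1/ms, `s_inf` dimensionless.
#' @examples
#' rate_constants(-38)$alpha_m # 1, by the series limit
#' rate_constants(-35)$s_inf   # 0.5, sigmoid midpoint
#' @export
rate_constants <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("v must be finite numeric")
  lim <- function(x, coefficient) {
    # coefficient * x / (1 - exp(-x/10)) with limit 10*coefficient at x = 0
    out <- ifelse(abs(x) < 1e-6, 10 * coefficient,
                  coefficient * x / (1 - exp(-x / 10)))
    out
  }
  list(
    alpha_m = lim(v + 38, 0.1),
    beta_m  = 4 * exp(-(v + 65) / 17),
    alpha_h = 0.05 * exp(-(v + 55) / 20),
    beta_h  = 1 / (exp(-(v + 35) / 10) + 1),
    alpha_n = lim(v + 55, 0.01),
    beta_n  = 0.125 * exp(-(v + 65) / 80),
    s_inf   = 1 / (1 + exp(-(v + 35) / 5))
  )
}

#' Steady-state gating variables
#'
#' `x_inf = alpha/(alpha + beta)` for each Hodgkin-Huxley gate (and
#' `s = s_inf` for the slow potassium gate) at a given membrane potential.
#'
#' @inheritParams rate_constants
#' @return For scalar `v`, a named numeric vector `c(m, h, n, s)`; for
#'   vector `v`, a matrix with one row per voltage.
#' @examples
#' steady_state_gating(-35)[["s"]] # 0.5
#' @export
steady_state_gating <- function(v) {
  r <- rate_constants(v)
  out <- cbind(m = r$alpha_m / (r$alpha_m + r$beta_m),
               h = r$alpha_h / (r$alpha_h + r$beta_h),
               n = r$alpha_n / (r$alpha_n + r$beta_n),
               s = r$s_inf)
  if (length(v) == 1L) out[1L, ] else out
}

# Total steady-state membrane current (uA/cm2) at voltage v with
# steady-state gating; used to locate the resting potential.
steady_state_current <- function(v, params, i_inj_pA = 0) {
  g <- steady_state_gating(v)
  if (is.matrix(g)) stop("scalar v expected")
  params$g_leak * (params$e_leak - v) +
    g[["m"]]^3 * g[["h"]] * params$g_na * (params$e_na - v) +
    g[["n"]]^params$kdr_exponent * params$g_kdr * (params$e_k - v) +
    g[["s"]] * params$g_ks * (params$e_k - v) +
    i_inj_pA * 1e-6 / params$area
}
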