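# Independent reference implementations used to cross-check the package.

# Classic fourth-order Runge-Kutta integration of the same membrane
# equations, written against rate_constants() and independent of the
# package's Euler core. Noise-free only.
rk4_reference <- function(params, i_inj_pA, dt, v0) {
  g0 <- steady_state_gating(v0)
  state <- c(v = v0, m = g0[["m"]], h = g0[["h"]], n = g0[["n"]], s = g0[["s"]])
  i_scale <- 1e-6 / params$area
  deriv <- function(st, i_pA) {
    r <- rate_constants(st[["v"]])
    dv <- (params$g_leak * (params$e_leak - st[["v"]]) +
             st[["m"]]^3 * st[["h"]] * params$g_na * (params$e_na - st[["v"]]) +
             st[["n"]]^params$kdr_exponent * params$g_kdr * (params$e_k - st[["v"]]) +
             st[["s"]] * params$g_ks * (params$e_k - st[["v"]]) +
             i_pA * i_scale) / params$c_m
    c(dv,
      r$alpha_m * (1 - st[["m"]]) - r$beta_m * st[["m"]],
      r$alpha_h * (1 - st[["h"]]) - r$beta_h * st[["h"]],
      r$alpha_n * (1 - st[["n"]]) - r$beta_n * st[["n"]],
      (r$s_inf - st[["s"]]) / params$tau_s)
  }
  n_step <- length(i_inj_pA)
  v_out <- numeric(n_step)
  for (k in seq_len(n_step)) {
    v_out[k] <- state[["v"]]
    i_pA <- i_inj_pA[k]
    k1 <- deriv(state, i_pA)
    k2 <- deriv(state + dt / 2 * k1, i_pA)
    k3 <- deriv(state + dt / 2 * k2, i_pA)
    k4 <- deriv(state + dt * k3, i_pA)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v_out
}

# Local-maxima spike counter: peaks above -10 mV separated by >= 1 ms.
# Independent of the derivative-threshold detector.
peak_count_oracle <- function(v, dt, min_peak = -10, min_sep_ms = 1) {
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
               FALSE) & v > min_peak
  idx <- which(is_peak)
  if (!length(idx)) return(0L)
  keep <- idx[c(TRUE, diff(idx) * dt >= min_sep_ms)]
  # collapse plateaus / jitter within min_sep
  count <- 1L
  last <- idx[1]
  for (i in idx[-1]) {
    if ((i - last) * dt >= min_sep_ms) {
      count <- count + 1L
      last <- i
    }
  }
  count
}

# Brute-force Mann-Whitney: U statistics for every assignment of the
# pooled values to the x positions (midranks), two-sided doubled tail.
mwu_bruteforce <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
  list(U = u_obs, p_value = p)
}

# Piecewise-linear synthetic action potential for feature fixtures:
# baseline, linear rise to the peak, linear fall to `after` mV.
synthetic_ap_trace <- function(baseline = -70, peak = 20,
                               rise_ms = 1, fall_ms = 2, after = -70,
                               dt = 0.01, pad_ms = 20, total_ms = 60) {
  t <- seq(0, total_ms, by = dt)
  v <- rep(baseline, length(t))
  up <- t >= pad_ms & t < pad_ms + rise_ms
  v[up] <- baseline + (peak - baseline) * (t[up] - pad_ms) / rise_ms
  down <- t >= pad_ms + rise_ms & t < pad_ms + rise_ms + fall_ms
  v[down] <- peak + (after - peak) * (t[down] - pad_ms - rise_ms) / fall_ms
  v[t >= pad_ms + rise_ms + fall_ms] <- after
  structure(list(t = t, v = v, dt = dt,
                 protocol = list(label = "synthetic",
                                 pulse_onset_ms = 0, pulse_end_ms = total_ms)),
            class = "voltage_trace")
}

# pulse-relative spike times of a simulated sweep
spikes_in_train <- function(trace) {
  st <- detect_spikes(trace, window = c(trace$protocol$pulse_onset_ms,
                                        trace$protocol$pulse_end_ms))
  st$spike_times - trace$protocol$pulse_onset_ms
}

# small default-parameter simulations reused across tests (memoised)
cached_trace <- local({
  cache <- list()
  function(key, maker) {
    if (is.null(cache[[key]])) cache[[key]] <<- maker()
    cache[[key]]
  }
})
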