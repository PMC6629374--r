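#' Detect action potentials in a current-clamp trace
#'
#' Spike threshold is the first sample of each upstroke at which the
#' voltage derivative reaches `dvdt_threshold` (default 10 mV/ms; central
#' differences). A candidate event is a valid spike only if its amplitude
#' (peak minus threshold voltage) is at least `min_amplitude` (40 mV) and
#' its peak overshoots `min_overshoot` (-10 mV). Spike times are the
#' threshold-crossing times (located on the raw sample grid, no
#' sub-sample interpolation).
#'
#' @param trace a [simulate_cell()] `voltage_trace`, or any list with
#'   numeric `t` (ms) and `v` (mV) at uniform spacing `dt`.
#' @param window optional `c(start, end)` in ms; only spikes whose
#'   threshold time falls inside are kept.
#' @param dvdt_threshold threshold-crossing slope, mV/ms.
#' @param min_amplitude minimal peak-to-threshold amplitude, mV.
#' @param min_overshoot minimal absolute peak voltage, mV.
#' @return An object of class `spike_train`: list with `spike_times` (ms,
#'   threshold crossing), `thresholds` (mV), `peaks` (mV), `amplitudes`
#'   (mV), `peak_times` (ms), index vectors `threshold_idx`/`peak_idx`,
#'   plus `window` and `dt`.
#' @export
detect_spikes <- function(trace, window = NULL, dvdt_threshold = 10,
                          min_amplitude = 40, min_overshoot = -10) {
  v <- trace$v
  t <- trace$t
  dt <- trace$dt %||% (t[2] - t[1])
  if (dt > 0.1)
    warning("sampling interval > 0.1 ms is too coarse for reliable dV/dt spike detection")
  n <- length(v)
  if (n < 3) return(empty_spike_train(window, dt))

  dvdt <- c((v[2] - v[1]) / dt,
            (v[3:n] - v[1:(n - 2)]) / (2 * dt),
            (v[n] - v[n - 1]) / dt)
  up <- dvdt >= dvdt_threshold
  run_start <- which(up & !c(FALSE, up[-n]))
  if (!length(run_start)) return(empty_spike_train(window, dt))
  run_limit <- c(run_start[-1] - 1L, n)

  thr_idx <- integer(0); pk_idx <- integer(0)
  for (k in seq_along(run_start)) {
    j <- run_start[k]
    seg <- j:run_limit[k]
    p <- seg[which.max(v[seg])]
    if (length(pk_idx) && p == pk_idx[length(pk_idx)]) next  # shared peak
    if (v[p] <= min_overshoot) next
    if (v[p] - v[j] < min_amplitude) next
    thr_idx <- c(thr_idx, j)
    pk_idx <- c(pk_idx, p)
  }
  st <- list(spike_times = t[thr_idx],
             thresholds = v[thr_idx],
             peaks = v[pk_idx],
             amplitudes = v[pk_idx] - v[thr_idx],
             peak_times = t[pk_idx],
             threshold_idx = thr_idx,
             peak_idx = pk_idx,
             window = window %||% range(t),
             dt = dt)
  if (!is.null(window)) {
    keep <- st$spike_times >= window[1] & st$spike_times <= window[2]
    st <- subset_spike_train(st, keep)
  }
  structure(st, class = "spike_train")
}

empty_spike_train <- function(window, dt) {
  structure(list(spike_times = numeric(0), thresholds = numeric(0),
                 peaks = numeric(0), amplitudes = numeric(0),
                 peak_times = numeric(0), threshold_idx = integer(0),
                 peak_idx = integer(0), window = window, dt = dt),
            class = "spike_train")
}

subset_spike_train <- function(st, keep) {
  for (f in c("spike_times", "thresholds", "peaks", "amplitudes",
              "peak_times", "threshold_idx", "peak_idx"))
    st[[f]] <- st[[f]][keep]
  st
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d valid spikes", length(x$spike_times)))
  if (length(x$spike_times))
    cat(sprintf(" (%.1f-%.1f ms; mean amplitude %.1f mV)",
                min(x$spike_times), max(x$spike_times), mean(x$amplitudes)))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$spike_times)

#' Single-spike waveform features
#'
#' For each detected spike: threshold voltage, rise time (threshold to
#' peak), maximal rising slope, half-width (width at half-maximal
#' amplitude, i.e. at threshold + amplitude/2, with linear interpolation
#' between samples), amplitude (peak minus threshold), afterhyperpolarization
#' depth relative to threshold, and AHP time (peak to AHP minimum). The AHP
#' is searched from the peak to the next spike's threshold or 50 ms,
#' whichever comes first. Spikes truncated by the end of the trace (less
#' than 10 ms of trace past the peak and no following spike) get `NA`
#' features.
#'
#' @param trace the `voltage_trace` the spikes were detected in.
#' @param spikes a [detect_spikes()] `spike_train` from that trace.
#' @return A data.frame with one row per spike: `threshold`, `rise_time`,
#'   `max_rise_slope`, `halfwidth`, `amplitude`, `ahp_amplitude`,
#'   `ahp_time`, `truncated`.
#' @export
ap_waveform <- function(trace, spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  v <- trace$v; t <- trace$t; dt <- trace$dt
  n <- length(v)
  ns <- length(spikes$spike_times)
  out <- data.frame(threshold = rep(NA_real_, ns), rise_time = NA_real_,
                    max_rise_slope = NA_real_, halfwidth = NA_real_,
                    amplitude = NA_real_, ahp_amplitude = NA_real_,
                    ahp_time = NA_real_, truncated = FALSE)
  if (!ns) return(out)
  dvdt <- c((v[2] - v[1]) / dt, (v[3:n] - v[1:(n - 2)]) / (2 * dt),
            (v[n] - v[n - 1]) / dt)

  for (k in seq_len(ns)) {
    i0 <- spikes$threshold_idx[k]
    ip <- spikes$peak_idx[k]
    thr <- v[i0]; amp <- v[ip] - thr
    next_thr <- if (k < ns) spikes$threshold_idx[k + 1] else n + 1L
    if (ip + round(10 / dt) > n && next_thr > n) {
      out$truncated[k] <- TRUE
      next
    }
    half <- thr + amp / 2
    # rising crossing of the half level between threshold and peak
    ir <- i0
    while (ir < ip && v[ir + 1] < half) ir <- ir + 1L
    t_rise <- interp_crossing(t, v, ir, half)
    # falling crossing after the peak (bounded by next spike / trace end)
    stop_i <- min(n - 1L, next_thr - 1L)
    ifall <- ip
    while (ifall < stop_i && v[ifall + 1] > half) ifall <- ifall + 1L
    hw <- if (v[ifall + 1] <= half) interp_crossing(t, v, ifall, half) - t_rise
          else NA_real_
    # AHP window: peak -> min(next spike threshold, peak + 50 ms)
    ahp_end <- min(n, next_thr - 1L, ip + round(50 / dt))
    ahp_seg <- ip:ahp_end
    imin <- ahp_seg[which.min(v[ahp_seg])]
    out$threshold[k] <- thr
    out$rise_time[k] <- t[ip] - t[i0]
    out$max_rise_slope[k] <- max(dvdt[i0:ip])
    out$halfwidth[k] <- hw
    out$amplitude[k] <- amp
    out$ahp_amplitude[k] <- thr - v[imin]
    out$ahp_time[k] <- t[imin] - t[ip]
  }
  out
}

# linear interpolation of the time where v crosses `level` in [i, i+1]
interp_crossing <- function(t, v, i, level) {
  if (v[i + 1] == v[i]) return(t[i])
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Passive membrane properties from hyperpolarizing and resting sweeps
#'
#' Resting potential is the mean of a sweep with no current injection.
#' Input resistance is the mean over hyperpolarizing sweeps of
#' `R = dV/I` (steady-state deflection over injected current). The
#' membrane time constant comes from a single-exponential fit of the
#' onset relaxation (initialized by log-linear regression). Sag is
#' `100 (V_ss - V_min)/(V_baseline - V_min)` measured on the -50 pA sweep
#' (or the first sweep if none is at -50 pA): the rebound from the peak
#' hyperpolarization toward steady state, 0 for a passive RC membrane.
#'
#' @param hyper_traces list of `voltage_trace`s from hyperpolarizing
#'   steps (negative amplitudes).
#' @param resting_trace a `voltage_trace` with zero injected current.
#' @return List: `v_rest` (mV), `r_in` (MOhm), `time_constant` (ms),
#'   `sag_percent`.
#' @export
passive_properties <- function(hyper_traces, resting_trace) {
  if (inherits(hyper_traces, "voltage_trace")) hyper_traces <- list(hyper_traces)
  amps <- vapply(hyper_traces, step_amplitude, numeric(1))
  if (any(amps >= 0))
    stop("hyperpolarizing sweeps expected (negative step amplitude)")
  v_rest <- mean(resting_trace$v)

  rs <- numeric(0); taus <- numeric(0); sags <- numeric(0)
  sag_pick <- which(abs(amps + 50) < 1e-9)
  sag_pick <- if (length(sag_pick)) sag_pick[1] else 1L
  for (k in seq_along(hyper_traces)) {
    tr <- hyper_traces[[k]]
    w <- pulse_window_idx(tr)
    base <- mean(tr$v[1:max(1, w[1] - 1)])
    seg <- tr$v[w[1]:w[2]]
    n_ss <- max(1, round(100 / tr$dt))
    v_ss <- mean(seg[max(1, length(seg) - n_ss + 1):length(seg)])
    rs <- c(rs, 1000 * (v_ss - base) / amps[k])  # mV/pA -> GOhm -> MOhm
    taus <- c(taus, fit_onset_tau(tr, w, base, v_ss))
    if (k == sag_pick) {
      v_min <- min(seg)
      sags <- if (abs(base - v_min) < 1e-9) 0
              else 100 * (v_ss - v_min) / (base - v_min)
    }
  }
  list(v_rest = v_rest, r_in = mean(rs),
       time_constant = mean(taus, na.rm = TRUE), sag_percent = sags)
}

step_amplitude <- function(trace) {
  segs <- trace$protocol$segments
  segs$start[which.max(abs(segs$start))]
}

# single-exponential fit of the onset relaxation; log-linear init, nls refine
fit_onset_tau <- function(tr, w, base, v_ss) {
  dt <- tr$dt
  # rough tau from 1 - 1/e crossing
  seg <- tr$v[w[1]:w[2]]
  target <- base + (v_ss - base) * (1 - exp(-1))
  i_e <- which(seg <= target)[1]
  if (is.na(i_e)) return(NA_real_)
  tau0 <- i_e * dt
  n_fit <- min(length(seg), max(10, round(5 * tau0 / dt)))
  tt <- (seq_len(n_fit) - 1) * dt
  y <- seg[seq_len(n_fit)]
  # log-linear estimate on the normalized relaxation
  z <- (y - v_ss) / (base - v_ss)
  ok <- z > 1e-3
  if (sum(ok) < 5) return(tau0)
  est <- -1 / coef(stats::lm(log(z[ok]) ~ tt[ok]))[[2]]
  fit <- tryCatch(
    suppressWarnings(nls(y ~ vss + (base - vss) * exp(-tt / tau),
                         start = list(vss = v_ss, tau = est),
                         control = list(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) est else coef(fit)[["tau"]]
}

#' Rheobase from an ascending 600 ms step family
#'
#' The minimum current step eliciting at least one valid spike, and the
#' number of spikes at that step.
#'
#' @param family list of `voltage_trace`s, one per step, ascending
#'   amplitude (the standard family is 0-200 pA in 10 pA increments).
#' @param spike_args extra arguments passed to [detect_spikes()].
#' @return List `rheobase` (pA), `aps_at_rheobase` (count); both `NA` if
#'   no step elicits a spike (no-rheobase sentinel, not an error).
#' @export
rheobase <- function(family, spike_args = list()) {
  amps <- vapply(family, step_amplitude, numeric(1))
  if (is.unsorted(amps)) stop("step family must be ascending in amplitude")
  for (k in seq_along(family)) {
    st <- spikes_in_pulse(family[[k]], spike_args)
    if (length(st$spike_times) >= 1)
      return(list(rheobase = amps[k], aps_at_rheobase = length(st$spike_times)))
  }
  list(rheobase = NA_real_, aps_at_rheobase = NA_integer_)
}

spikes_in_pulse <- function(trace, spike_args = list()) {
  w <- c(trace$protocol$pulse_onset_ms, trace$protocol$pulse_end_ms)
  do.call(detect_spikes, c(list(trace = trace, window = w), spike_args))
}

#' Firing-frequency measures
#'
#' `steady_state_frequency()` counts valid spikes in the last 300 ms of the
#' step and divides by 0.3 s. `if_curve()` applies it to each sweep of a
#' step family (a cell that stops firing at higher steps keeps frequency 0
#' there). `f_steady_max()` is the maximum of the curve.
#' `instantaneous_max()` is `1/min(ISI)` at the near-maximal step, taken
#' as the step with maximal steady-state frequency (falling back to the
#' global minimum ISI over all suprathreshold steps when that step has
#' fewer than two spikes).
#'
#' @param trace a `voltage_trace` of a single step.
#' @param family list of `voltage_trace`s (ascending step family).
#' @param spike_args extra arguments for [detect_spikes()].
#' @param window_ms steady-state window length, ms.
#' @return Frequencies in Hz; `if_curve()` returns a data.frame
#'   (`current_pA`, `frequency_hz`) of class `if_curve`.
#' @export
steady_state_frequency <- function(trace, spike_args = list(),
                                   window_ms = 300) {
  st <- spikes_in_pulse(trace, spike_args)
  t_end <- trace$protocol$pulse_end_ms
  sum(st$spike_times >= t_end - window_ms & st$spike_times <= t_end) /
    (window_ms / 1000)
}

#' @rdname steady_state_frequency
#' @export
if_curve <- function(family, spike_args = list()) {
  amps <- vapply(family, step_amplitude, numeric(1))
  freqs <- vapply(family, steady_state_frequency, numeric(1),
                  spike_args = spike_args)
  structure(data.frame(current_pA = amps, frequency_hz = freqs),
            class = c("if_curve", "data.frame"))
}

#' @rdname steady_state_frequency
#' @export
f_steady_max <- function(family, spike_args = list()) {
  max(if_curve(family, spike_args)$frequency_hz)
}

#' @rdname steady_state_frequency
#' @export
instantaneous_max <- function(family, spike_args = list()) {
  ic <- if_curve(family, spike_args)
  trains <- lapply(family, spikes_in_pulse, spike_args = spike_args)
  best <- which.max(ic$frequency_hz)
  isis <- diff(trains[[best]]$spike_times)
  if (!length(isis)) {
    all_isis <- unlist(lapply(trains, function(s) diff(s$spike_times)))
    if (!length(all_isis)) return(0)
    return(1000 / min(all_isis))
  }
  1000 / min(isis)
}

#' Spike-amplitude rundown during repetitive firing
#'
#' Successive spike amplitudes normalized to the first spike, as measured
#' on a suprathreshold (3x rheobase) step. With at least 10 spikes the
#' summary ratio is the tenth amplitude over the first; with fewer, the
#' last available spike's ratio is reported and flagged partial.
#'
#' @param trace a `voltage_trace` at 3x rheobase (or any suprathreshold
#'   step).
#' @param spike_args extra arguments for [detect_spikes()].
#' @return List: `series` (normalized amplitudes), `tenth_to_first`,
#'   `partial` (logical).
#' @export
rundown <- function(trace, spike_args = list()) {
  st <- spikes_in_pulse(trace, spike_args)
  a <- st$amplitudes
  if (!length(a))
    return(list(series = numeric(0), tenth_to_first = NA_real_, partial = TRUE))
  series <- a / a[1]
  if (length(a) >= 10)
    list(series = series, tenth_to_first = series[10], partial = FALSE)
  else
    list(series = series, tenth_to_first = series[length(series)],
         partial = TRUE)
}

#' Coefficient of variation of the interspike intervals
#'
#' Sample standard deviation (n-1 denominator) over the mean of the ISIs
#' of one sweep; 0 for a perfectly regular train, near 1 for Poisson-like
#' irregular firing. Requires at least 3 spikes (2 ISIs); otherwise `NA`.
#'
#' @param x a `spike_train`, or a numeric vector of spike times (ms).
#' @return Dimensionless CoV, or `NA_real_` if fewer than 2 ISIs.
#' @export
isi_cov <- function(x) {
  times <- if (inherits(x, "spike_train")) x$spike_times else x
  if (length(times) < 3) return(NA_real_)
  isi <- diff(times)
  sd(isi) / mean(isi)
}

#' Population instantaneous-rate map
#'
#' For each current step, the instantaneous firing rate (1/ISI, held
#' piecewise-constant between consecutive spikes) is evaluated on a
#' `bin_ms` grid, smoothed with a `bin_ms` sliding average, and averaged
#' across cells.
#'
#' @param trains_by_cell list (one element per cell) of lists of
#'   `spike_train`s or spike-time vectors (one per current step, aligned
#'   across cells; times relative to the pulse, ms).
#' @param duration_ms pulse duration, ms.
#' @param bin_ms bin / sliding-window width, ms.
#' @return Matrix (steps x time bins) of rates in Hz.
#' @export
population_rate_map <- function(trains_by_cell, duration_ms, bin_ms = 20) {
  n_steps <- length(trains_by_cell[[1]])
  grid <- seq(0, duration_ms, by = bin_ms)
  maps <- lapply(trains_by_cell, function(cell) {
    t(vapply(cell, function(st) {
      times <- if (inherits(st, "spike_train")) st$spike_times else st
      rate_on_grid(times, grid)
    }, numeric(length(grid))))
  })
  Reduce(`+`, maps) / length(maps)
}

rate_on_grid <- function(times, grid) {
  if (length(times) < 2) return(numeric(length(grid)))
  isi <- diff(times)
  idx <- findInterval(grid, times)
  rate <- ifelse(idx >= 1 & idx < length(times), 1000 / isi[pmax(idx, 1)], 0)
  sm <- as.numeric(stats::filter(rate, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- rate[is.na(sm)]
  sm
}

#' Voltage-clamp sodium-current features
#'
#' Peak current (maximal absolute value of the response), persistent
#' current (mean current 80-100 ms after the step onset, as a percentage
#' of the peak), and the inactivation time constant from a
#' double-exponential fit of the decay from the peak (with offset), with
#' the dominant (larger-amplitude) component reported.
#'
#' @param t time axis, ms.
#' @param i current, pA.
#' @param onset_ms time of the voltage-step onset, ms.
#' @return List: `peak_current` (pA, signed), `persistent_percent`,
#'   `tau_inactivation` (ms; `NA` with a warning if the fit fails).
#' @export
vclamp_features <- function(t, i, onset_ms = 0) {
  if (max(t) < onset_ms + 100)
    stop("trace must cover at least 100 ms after the step onset")
  post <- t >= onset_ms
  tp <- t[post]; ip <- i[post]
  k_peak <- which.max(abs(ip))
  peak <- ip[k_peak]
  pers_win <- tp >= onset_ms + 80 & tp <= onset_ms + 100
  persistent <- 100 * mean(ip[pers_win]) / peak

  dec_t <- tp[k_peak:length(tp)] - tp[k_peak]
  dec_i <- ip[k_peak:length(ip)]
  tau <- fit_double_exp_tau(dec_t, dec_i)
  list(peak_current = peak, persistent_percent = persistent,
       tau_inactivation = tau)
}

fit_double_exp_tau <- function(tt, y) {
  # I(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2) + C; dominant = larger |A|
  C0 <- mean(y[tt >= max(tt) * 0.8])
  A0 <- y[1] - C0
  i_e <- which(abs(y - C0) <= abs(A0) / exp(1))[1]
  tau0 <- max(tt[i_e], tt[2])
  resid_fn <- function(p)
    y - (p[1] * exp(-tt / p[2]) + p[3] * exp(-tt / p[4]) + p[5])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A1 = A0 * 0.9, tau1 = tau0,
                               A2 = A0 * 0.1, tau2 = tau0 * 10, C = C0),
                       lower = c(-Inf, 1e-6, -Inf, 1e-6, -Inf),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # judge convergence by fit quality: the info code can flag the maximum
  # iteration count even when the dominant term is already resolved
  ok <- !is.null(fit) && all(is.finite(fit$par)) &&
    sqrt(mean(resid_fn(fit$par)^2)) <= 0.05 * abs(A0) + 1e-12
  if (!ok) {
    warning("double-exponential fit did not converge; tau unavailable")
    return(NA_real_)
  }
  cf <- fit$par
  if (abs(cf[["A1"]]) >= abs(cf[["A2"]])) cf[["tau1"]] else cf[["tau2"]]
}
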