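#' Firing-frequency map over the gNa x gKS plane
#'
#' For every combination of sodium and slow-potassium conductance
#' density, the model is driven with a test pulse (default 600 ms x
#' 100 pA) and the steady-state firing frequency (valid spikes in the
#' last 300 ms / 0.3 s) and mean spike height (peak voltage of valid
#' spikes) are averaged over `reps` noise seeds.
#'
#' @param gna_values,gks_values conductance densities, mS/cm2
#'   (nonnegative, non-empty).
#' @param params baseline [model_parameters()]; gNa/gKS overwritten per
#'   grid cell.
#' @param amplitude_pA,duration_ms test pulse.
#' @param reps noise repetitions per cell.
#' @param seed master seed (per-cell, per-rep seeds derive from it).
#' @param noise inject the noise current?
#' @param dt integration step, ms.
#' @return Object of class `sweep_grid`: `gna_values`, `gks_values`,
#'   `frequency` and `spike_height` matrices (rows = gKS, cols = gNa),
#'   `n_steady_spikes` (mean valid spikes in the steady-state window).
#' @export
parameter_sweep <- function(gna_values, gks_values,
                            params = model_parameters(),
                            amplitude_pA = 100, duration_ms = 600,
                            reps = 1, seed = 1, noise = TRUE, dt = 0.01) {
  if (!length(gna_values) || !length(gks_values))
    stop("conductance value lists must be non-empty")
  if (any(gna_values < 0) || any(gks_values < 0))
    stop("conductance densities must be nonnegative")
  protocol <- step_protocol(amplitude_pA, duration_ms = duration_ms, dt = dt)
  freq <- hgt <- nss <- matrix(NA_real_, length(gks_values), length(gna_values),
                               dimnames = list(gks = gks_values, gna = gna_values))
  seeds <- with_seed(seed,
    array(sample.int(.Machine$integer.max - 1,
                     length(gks_values) * length(gna_values) * reps),
          dim = c(length(gks_values), length(gna_values), reps)))
  for (i in seq_along(gks_values)) {
    for (j in seq_along(gna_values)) {
      p <- params
      p$g_ks <- gks_values[i]
      p$g_na <- gna_values[j]
      f <- h <- k <- numeric(reps)
      for (r in seq_len(reps)) {
        tr <- tryCatch(
          simulate_cell(p, protocol, seed = seeds[i, j, r], noise = noise),
          error = function(e) stop(sprintf(
            "simulation failed at grid cell gKS = %g, gNa = %g: %s",
            gks_values[i], gna_values[j], conditionMessage(e))))
        st <- spikes_in_pulse(tr)
        te <- protocol$pulse_end_ms
        in_ss <- st$spike_times >= te - 300 & st$spike_times <= te
        k[r] <- sum(in_ss)
        f[r] <- sum(in_ss) / 0.3
        h[r] <- if (length(st$peaks)) mean(st$peaks) else NA_real_
      }
      freq[i, j] <- mean(f)
      hgt[i, j] <- mean(h, na.rm = TRUE)
      nss[i, j] <- mean(k)
    }
  }
  structure(list(gna_values = gna_values, gks_values = gks_values,
                 frequency = freq, spike_height = hgt,
                 n_steady_spikes = nss,
                 amplitude_pA = amplitude_pA, duration_ms = duration_ms,
                 reps = reps, seed = seed),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Conductance sweep: %d gKS x %d gNa values, %g ms x %g pA pulse, %d rep(s)\n",
              length(x$gks_values), length(x$gna_values),
              x$duration_ms, x$amplitude_pA, x$reps))
  cat("Steady-state frequency (Hz):\n")
  print(round(x$frequency, 1))
  invisible(x)
}
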