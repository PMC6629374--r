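#' Specification of a synthetic four-group cohort
#'
#' The generator emulates the study's slice-recording dataset with four
#' groups (WT and Scn1a het genotype x CA and IS firing subtype). Each
#' cell's sodium conductance is `65 * genotype_scale * lognormal(1, gna_cv)`
#' (the Scn1a scale of 0.5 models loss of one gene copy) and its slow-K
#' conductance is drawn from a subtype-specific truncated normal: the
#' CA mode is low (0.25 +/- 0.15 mS/cm2), the IS mode high (2.0 +/- 0.4),
#' operationalizing the observation that roughly half of VIP-INs carry
#' enough M-current to spike irregularly.
#'
#' @param n_per_group cells per group.
#' @param seed master seed; all cohort randomness derives from it.
#' @param genotype_gna_scale named vector of gNa scale factors.
#' @param gks_ca_mean,gks_ca_sd,gks_is_mean,gks_is_sd subtype gKS
#'   distributions, mS/cm2 (normal, truncated at 0).
#' @param gna_cv relative SD of the per-cell gNa lognormal factor.
#' @param params baseline [model_parameters()] (gNa/gKS overwritten per
#'   cell).
#' @param family_amplitudes 600 ms step-family amplitudes, pA.
#' @param suprathreshold_multiples candidate 8 s sweep amplitudes, in
#'   multiples of the cell's measured rheobase. Sweeps are recorded in
#'   this order and classification uses the first whose pattern is
#'   measurable — at least `escalation_min_spikes` valid spikes and
#'   firing that continues into the last quarter of the pulse (a cell
#'   that ceases firing entirely is re-tested at higher current, as the
#'   experimenters did when a pattern was not clear at 2x rheobase); if
#'   no sweep qualifies, the one with the most spikes is used.
#' @param escalation_min_spikes minimum valid spikes for an 8 s sweep to
#'   count as a measurable firing pattern.
#' @param max_amplitude_pA cap on any injected amplitude.
#' @param dt integration step, ms.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 50, seed = 1,
                        genotype_gna_scale = c(WT = 1.0, Scn1a = 0.5),
                        gks_ca_mean = 0.25, gks_ca_sd = 0.15,
                        gks_is_mean = 2.0, gks_is_sd = 0.4,
                        gna_cv = 0.1,
                        params = model_parameters(),
                        family_amplitudes = seq(0, 200, by = 10),
                        suprathreshold_multiples = c(2, 3, 4),
                        escalation_min_spikes = 10,
                        max_amplitude_pA = 200,
                        dt = 0.01) {
  stopifnot(n_per_group >= 1, gna_cv >= 0,
            gks_ca_sd >= 0, gks_is_sd >= 0,
            all(c("WT", "Scn1a") %in% names(genotype_gna_scale)))
  structure(list(n_per_group = n_per_group, seed = seed,
                 genotype_gna_scale = genotype_gna_scale,
                 gks_ca_mean = gks_ca_mean, gks_ca_sd = gks_ca_sd,
                 gks_is_mean = gks_is_mean, gks_is_sd = gks_is_sd,
                 gna_cv = gna_cv, params = params,
                 family_amplitudes = family_amplitudes,
                 suprathreshold_multiples = suprathreshold_multiples,
                 escalation_min_spikes = escalation_min_spikes,
                 max_amplitude_pA = max_amplitude_pA, dt = dt),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d cells/group x 4 groups, seed %d\n",
              x$n_per_group, x$seed))
  cat(sprintf("  gKS: CA %g +/- %g, IS %g +/- %g mS/cm2; gNa CV %g; Scn1a scale %g\n",
              x$gks_ca_mean, x$gks_ca_sd, x$gks_is_mean, x$gks_is_sd,
              x$gna_cv, x$genotype_gna_scale[["Scn1a"]]))
  invisible(x)
}

#' Draw one cell's model parameters
#'
#' @param spec a [cohort_spec()].
#' @param genotype `"WT"` or `"Scn1a"`.
#' @param subtype `"CA"` or `"IS"`.
#' @return A [model_parameters()] object with sampled `g_na` and `g_ks`
#'   (uses the current RNG stream).
#' @export
sample_cell <- function(spec, genotype, subtype) {
  if (!genotype %in% names(spec$genotype_gna_scale))
    stop(sprintf("unknown genotype '%s'", genotype))
  if (!subtype %in% c("CA", "IS"))
    stop(sprintf("unknown subtype '%s'", subtype))
  scale <- spec$genotype_gna_scale[[genotype]]
  gna_factor <- if (spec$gna_cv > 0) {
    sdlog <- sqrt(log(1 + spec$gna_cv^2))
    rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
  } else 1
  mu <- if (subtype == "CA") spec$gks_ca_mean else spec$gks_is_mean
  sg <- if (subtype == "CA") spec$gks_ca_sd else spec$gks_is_sd
  gks <- if (sg > 0) {
    repeat {
      g <- rnorm(1, mu, sg)
      if (g >= 0) break
    }
    g
  } else mu
  p <- spec$params
  p$g_na <- 65 * scale * gna_factor
  p$g_ks <- gks
  p
}

#' Simulate the full recording battery for one cell
#'
#' The battery mirrors the slice protocol: a 1 s resting sweep, a -50 pA
#' hyperpolarizing 600 ms step, the ascending 600 ms family (rheobase,
#' I-f curve), a 600 ms sweep at 3x rheobase (spike rundown), and 8 s
#' sweeps at the spec's rheobase multiples with the escalation rule of
#' [cohort_spec()]. Raw traces are reduced to spike trains and features
#' on the fly (an 8 s trace at 0.01 ms resolution is ~13 MB, so whole
#' cohorts keep only the derived data unless `keep_traces = TRUE`).
#'
#' @param params the cell's [model_parameters()].
#' @param spec a [cohort_spec()].
#' @param seed per-cell seed for all of the cell's noise streams.
#' @param keep_traces keep the raw `voltage_trace`s?
#' @return List of class `synthetic_recording`: measured passive and
#'   firing features, pattern features of the classification (8 s) sweep
#'   and the matching 600 ms "apparent" sweep, per-sweep spike trains,
#'   and (optionally) traces.
#' @export
simulate_battery <- function(params, spec, seed, keep_traces = FALSE) {
  dt <- spec$dt
  sub_seed <- function(k) (seed + 7919L * k) %% .Machine$integer.max

  traces <- if (keep_traces) list() else NULL
  note <- function(name, tr) {
    if (keep_traces) traces[[name]] <<- tr
    tr
  }

  rest <- note("resting", simulate_cell(params, step_protocol(0, duration_ms = 1000, dt = dt,
                                                              pre_ms = 0, post_ms = 0,
                                                              label = "resting"),
                                        seed = sub_seed(1)))
  hyper <- note("hyper", simulate_cell(params, step_protocol(-50, dt = dt), seed = sub_seed(2)))
  fam <- vector("list", length(spec$family_amplitudes))
  fam_trains <- vector("list", length(spec$family_amplitudes))
  for (k in seq_along(spec$family_amplitudes)) {
    tr <- note(sprintf("step_%g", spec$family_amplitudes[k]),
               simulate_cell(params, step_protocol(spec$family_amplitudes[k], dt = dt),
                             seed = sub_seed(10 + k)))
    fam[[k]] <- tr
    fam_trains[[k]] <- spikes_in_pulse(tr)
  }
  amps <- spec$family_amplitudes
  counts <- vapply(fam_trains, length, integer(1))
  rheo_idx <- which(counts >= 1)[1]
  rheo <- if (is.na(rheo_idx)) NA_real_ else amps[rheo_idx]

  passive <- passive_properties(list(hyper), rest)
  ic <- data.frame(current_pA = amps,
                   frequency_hz = vapply(seq_along(fam), function(k) {
                     te <- fam[[k]]$protocol$pulse_end_ms
                     sum(fam_trains[[k]]$spike_times >= te - 300) / 0.3
                   }, numeric(1)))

  out <- list(params = params, seed = seed,
              rheobase = rheo,
              aps_at_rheobase = if (is.na(rheo)) NA_integer_ else counts[rheo_idx],
              no_rheobase = is.na(rheo),
              passive = passive, if_curve = ic,
              f_steady_max = max(ic$frequency_hz),
              family_trains = fam_trains)

  if (!is.na(rheo)) {
    # single-spike waveform features: first AP at rheobase
    wave <- ap_waveform(fam[[rheo_idx]], fam_trains[[rheo_idx]])[1, ]
    out$ap <- wave
    # instantaneous max: min ISI at the step with max steady-state rate
    best <- which.max(ic$frequency_hz)
    isis <- diff(fam_trains[[best]]$spike_times)
    if (!length(isis))
      isis <- unlist(lapply(fam_trains, function(s) diff(s$spike_times)))
    out$f_instant_max <- if (length(isis)) 1000 / min(isis) else 0

    # rundown at 3x rheobase
    rd_amp <- min(3 * rheo, spec$max_amplitude_pA)
    rd_tr <- note("rundown", simulate_cell(params, step_protocol(rd_amp, dt = dt),
                                           seed = sub_seed(60)))
    out$rundown <- rundown(rd_tr)

    # 8 s sweeps, escalating until the firing pattern is measurable;
    # fall back to the most informative (most spikes) sweep
    mult_used <- NA_real_
    long_train <- NULL
    long_amp <- NA_real_
    best_n <- -1L
    prev_amp <- -1
    for (m in spec$suprathreshold_multiples) {
      amp <- min(m * rheo, spec$max_amplitude_pA)
      if (amp == prev_amp) break  # amplitude cap reached, nothing new
      prev_amp <- amp
      pr <- step_protocol(amp, duration_ms = 8000, dt = dt,
                          label = sprintf("long_%gx", m))
      tr <- note(sprintf("long_%gx", m),
                 simulate_cell(params, pr, seed = sub_seed(70 + m)))
      st <- spikes_in_pulse(tr)
      st$spike_times <- st$spike_times - pr$pulse_onset_ms
      if (length(st) > best_n) {
        long_train <- st; long_amp <- amp; mult_used <- m
        best_n <- length(st)
      }
      keeps_firing <- length(st) > 0 && max(st$spike_times) >= 0.75 * 8000
      if (length(st) >= spec$escalation_min_spikes && keeps_firing) {
        long_train <- st; long_amp <- amp; mult_used <- m
        break
      }
    }
    out$long_train <- long_train
    out$long_amplitude <- long_amp
    out$long_multiple <- mult_used
    out$pattern <- pattern_features(long_train, 8000,
                                    current_multiple = mult_used)

    # matching 600 ms sweep for the "apparent" features
    ap_idx <- which(abs(amps - long_amp) < 1e-9)
    short_train <- if (length(ap_idx)) {
      st <- fam_trains[[ap_idx[1]]]
      st$spike_times <- st$spike_times - fam[[ap_idx[1]]]$protocol$pulse_onset_ms
      st
    } else {
      tr <- note("short_apparent",
                 simulate_cell(params, step_protocol(long_amp, dt = dt),
                               seed = sub_seed(90)))
      st <- spikes_in_pulse(tr)
      st$spike_times <- st$spike_times - tr$protocol$pulse_onset_ms
      st
    }
    out$apparent <- apparent_features(short_train,
                                      current_multiple = mult_used)
    out$short_train <- short_train
  }
  if (keep_traces) out$traces <- traces
  structure(out, class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("Synthetic recording: gNa %.1f, gKS %.2f mS/cm2; rheobase %s pA\n",
              x$params$g_na, x$params$g_ks,
              if (x$no_rheobase) "none <= family max" else sprintf("%g", x$rheobase)))
  if (!is.null(x$pattern))
    cat(sprintf("  8 s (%gx rheobase): %d spikes, burst %.2f s, ISI CoV %s\n",
                x$long_multiple, x$pattern$n_spikes, x$pattern$burst_length,
                if (is.na(x$pattern$isi_cov)) "NA" else sprintf("%.2f", x$pattern$isi_cov)))
  invisible(x)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_per_group` cells for each of WT-CA, WT-IS, Scn1a-CA and
#' Scn1a-IS, simulates the full battery per cell, and assembles a tidy
#' feature table plus a separate ground-truth table (kept apart so that
#' downstream analysis can stay blinded). Reproducible from
#' `spec$seed`: per-cell seeds and parameter draws all derive from it.
#'
#' @param spec a [cohort_spec()].
#' @param keep_traces keep raw voltage traces (memory-heavy; only
#'   sensible for small cohorts).
#' @param progress print a dot per simulated cell?
#' @return Object of class `vip_cohort`: `features` (one row per cell),
#'   `truth` (cell_id, genotype, subtype, drawn conductances, seed),
#'   `recordings` (list of `synthetic_recording`), `spec`.
#' @export
generate_cohort <- function(spec, keep_traces = FALSE, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- expand.grid(genotype = c("WT", "Scn1a"), subtype = c("CA", "IS"),
                        stringsAsFactors = FALSE)
  n_cells <- nrow(groups) * spec$n_per_group

  draws <- with_seed(spec$seed, {
    seeds <- sample.int(.Machine$integer.max - 1, n_cells)
    cells <- vector("list", n_cells)
    i <- 0
    for (g in seq_len(nrow(groups))) {
      for (k in seq_len(spec$n_per_group)) {
        i <- i + 1
        cells[[i]] <- list(
          genotype = groups$genotype[g], subtype = groups$subtype[g],
          params = sample_cell(spec, groups$genotype[g], groups$subtype[g]),
          seed = seeds[i])
      }
    }
    cells
  })

  recs <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell <- draws[[i]]
    id <- sprintf("cell_%03d", i)
    rec <- simulate_battery(cell$params, spec, cell$seed,
                            keep_traces = keep_traces)
    rec$cell_id <- id
    recs[[i]] <- rec
    rows[[i]] <- recording_features_row(id, rec)
    truth[[i]] <- data.frame(cell_id = id, genotype = cell$genotype,
                             subtype = cell$subtype,
                             g_na = cell$params$g_na, g_ks = cell$params$g_ks,
                             seed = cell$seed)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(features = do.call(rbind, rows),
                 truth = do.call(rbind, truth),
                 recordings = recs, spec = spec),
            class = "vip_cohort")
}

recording_features_row <- function(id, rec) {
  has_long <- !is.null(rec$pattern)
  data.frame(
    cell_id = id,
    v_rest = rec$passive$v_rest,
    r_in = rec$passive$r_in,
    time_constant = rec$passive$time_constant,
    sag_percent = rec$passive$sag_percent,
    rheobase = rec$rheobase,
    aps_at_rheobase = rec$aps_at_rheobase,
    ap_threshold = if (is.null(rec$ap)) NA_real_ else rec$ap$threshold,
    ap_amplitude = if (is.null(rec$ap)) NA_real_ else rec$ap$amplitude,
    ap_halfwidth = if (is.null(rec$ap)) NA_real_ else rec$ap$halfwidth,
    ap_rise_time = if (is.null(rec$ap)) NA_real_ else rec$ap$rise_time,
    max_rise_slope = if (is.null(rec$ap)) NA_real_ else rec$ap$max_rise_slope,
    ahp_amplitude = if (is.null(rec$ap)) NA_real_ else rec$ap$ahp_amplitude,
    ahp_time = if (is.null(rec$ap)) NA_real_ else rec$ap$ahp_time,
    f_steady_max = rec$f_steady_max,
    f_instant_max = if (is.null(rec$f_instant_max)) NA_real_ else rec$f_instant_max,
    rundown_10th = if (is.null(rec$rundown)) NA_real_ else rec$rundown$tenth_to_first,
    rundown_partial = if (is.null(rec$rundown)) NA else rec$rundown$partial,
    burst_length = if (has_long) rec$pattern$burst_length else NA_real_,
    isi_cov = if (has_long) rec$pattern$isi_cov else NA_real_,
    n_spikes_long = if (has_long) rec$pattern$n_spikes else NA_integer_,
    long_multiple = if (has_long) rec$long_multiple else NA_real_,
    long_amplitude = if (has_long) rec$long_amplitude else NA_real_,
    apparent_burst_length = if (has_long) rec$apparent$burst_length else NA_real_,
    apparent_isi_cov = if (has_long) rec$apparent$isi_cov else NA_real_,
    no_rheobase = rec$no_rheobase)
}

#' @export
print.vip_cohort <- function(x, ...) {
  cat(sprintf("Synthetic VIP-IN cohort: %d cells (%d/group), seed %d\n",
              nrow(x$features), x$spec$n_per_group, x$spec$seed))
  print(table(x$truth$genotype, x$truth$subtype))
  invisible(x)
}

#' Pooled interspike intervals of a cohort's classification sweeps
#'
#' @param cohort a [generate_cohort()] result.
#' @return Numeric vector of ISIs (ms) pooled over all cells' 8 s sweeps;
#'   input for [gap_cutoff()].
#' @export
cohort_isis <- function(cohort) {
  unlist(lapply(cohort$recordings, function(r) {
    if (is.null(r$long_train)) numeric(0) else diff(r$long_train$spike_times)
  }))
}

#' Classify a cohort's cells from its 8 s (or 600 ms) sweeps
#'
#' Applies [classify_cells()] to the cohort feature table, using the
#' standard 150 ms firing-gap cutoff (the published dataset-derived
#' value). Pass `cutoff_ms = NULL` to re-derive the cutoff from this
#' cohort's own pooled ISI distribution (mean + 2 SD, the published
#' procedure); on default synthetic cohorts that gives ~190 ms.
#'
#' @param cohort a [generate_cohort()] result.
#' @param sweep `"8s"` (classification sweeps) or `"600ms"` (apparent
#'   features).
#' @param cutoff_ms firing-gap cutoff, ms; `NULL` derives it from the
#'   cohort via [gap_cutoff()].
#' @param seed,restarts passed to [classify_cells()].
#' @return A `classification_result` (see [classify_cells()]); the
#'   cutoff used is attached as `$cutoff_ms`.
#' @export
classify_cohort <- function(cohort, sweep = c("8s", "600ms"),
                            cutoff_ms = 150, seed = 1, restarts = 25) {
  sweep <- match.arg(sweep)
  if (is.null(cutoff_ms)) cutoff_ms <- gap_cutoff(cohort_isis(cohort))
  feats <- lapply(cohort$recordings, function(r) {
    if (is.null(r$long_train)) return(NULL)
    if (sweep == "8s") {
      pf <- pattern_features(r$long_train, 8000, cutoff_ms = cutoff_ms)
    } else {
      pf <- apparent_features(r$short_train, cutoff_ms = cutoff_ms)
    }
    data.frame(cell_id = r$cell_id, burst_length = pf$burst_length,
               isi_cov = pf$isi_cov)
  })
  df <- do.call(rbind, feats)
  res <- classify_cells(df, seed = seed, restarts = restarts)
  res$cutoff_ms <- cutoff_ms
  res
}

#' Emulate KCNQ-channel / cholinergic pharmacology
#'
#' Scales the slow-K conductance the way the study's drugs act on
#' M-current: linopirdine (KCNQ blocker) zeroes `g_ks`; retigabine (KCNQ
#' opener) multiplies it (default 2.5x); carbachol (cholinomimetic,
#' muscarinic M-current suppression plus depolarization) scales `g_ks`
#' to 10% and adds a constant bias current calibrated through the input
#' resistance to depolarize rest by about `carbachol_depolarization_mV`.
#'
#' @param params a [model_parameters()] object.
#' @param drug one of `"linopirdine"`, `"retigabine"`, `"carbachol"`.
#' @param retigabine_factor g_ks multiplier for retigabine.
#' @param carbachol_gks_factor residual g_ks fraction under carbachol.
#' @param carbachol_depolarization_mV target resting-potential shift.
#' @return Modified `vip_params`.
#' @export
apply_pharmacology <- function(params, drug,
                               retigabine_factor = 2.5,
                               carbachol_gks_factor = 0.1,
                               carbachol_depolarization_mV = 12) {
  stopifnot(inherits(params, "vip_params"))
  drug <- match.arg(drug, c("linopirdine", "retigabine", "carbachol"))
  p <- params
  if (drug == "linopirdine") {
    p$g_ks <- 0
  } else if (drug == "retigabine") {
    p$g_ks <- p$g_ks * retigabine_factor
  } else {
    v0 <- resting_state(params)
    if (is.na(v0)) v0 <- params$e_leak
    p$g_ks <- p$g_ks * carbachol_gks_factor
    # bias current that moves the steady state to v0 + target, solved on
    # the full steady-state I-V (the delayed rectifier is partly open
    # near rest, so a leak-only R_in estimate under-depolarizes)
    target <- v0 + carbachol_depolarization_mV
    p$i_bias <- -steady_state_current(target, p, 0) * p$area * 1e6
  }
  p
}
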