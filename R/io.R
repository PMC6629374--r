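#' Read and write voltage traces as long-format CSV
#'
#' The on-disk layout is one row per sample: `sweep_id, t_ms, v_mV, i_pA`,
#' with per-sweep metadata (`dt`, `seed`, label) recoverable from the
#' data. Written with data.table for speed (an 8 s sweep is 8e5 rows).
#'
#' @param traces named list of `voltage_trace`s (names become sweep ids).
#' @param path CSV path.
#' @return `write_traces_csv()` returns `path` invisibly;
#'   `read_traces_csv()` returns a named list of `voltage_trace`-like
#'   objects (t, v, i, dt; protocol reduced to a label).
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "voltage_trace")) traces <- list(sweep_1 = traces)
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- sprintf("sweep_%d", seq_along(traces))
  parts <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.table::data.table(sweep_id = id, t_ms = tr$t, v_mV = tr$v,
                           i_pA = tr$i)
  })
  data.table::fwrite(data.table::rbindlist(parts), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sweep_id", "t_ms", "v_mV", "i_pA")
  if (!all(need %in% names(dt)))
    stop("trace CSV must have columns sweep_id, t_ms, v_mV, i_pA")
  out <- lapply(split(dt, by = "sweep_id", sorted = FALSE), function(d) {
    structure(list(t = d$t_ms, v = d$v_mV, i = d$i_pA,
                   dt = d$t_ms[2] - d$t_ms[1],
                   protocol = list(label = d$sweep_id[1])),
              class = "voltage_trace")
  })
  out
}

#' Write / read a cohort feature table
#'
#' One row per cell, mirroring the intrinsic-property table of a patch
#' clamp study (resting potential, input resistance, rheobase, AP
#' waveform, firing rates, burst/CoV classification variables, ...).
#'
#' @param features the `features` data.frame of a [generate_cohort()]
#'   result (or any data.frame).
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write per-sweep spike tables as JSON
#'
#' @param trains named list of `spike_train`s.
#' @param path JSON path.
#' @export
write_spikes_json <- function(trains, path) {
  payload <- lapply(trains, function(st) {
    list(spike_times_ms = st$spike_times, thresholds_mV = st$thresholds,
         peaks_mV = st$peaks, amplitudes_mV = st$amplitudes)
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
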