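#' Stimulus protocols
#'
#' Constructors for the current-clamp protocols used throughout: rectangular
#' current steps with zero-current padding, ascending step families, and
#' slow ramps. A protocol is an ordered list of piecewise-linear segments
#' `(duration_ms, start_pA, end_pA)` sampled at interval `dt`.
#'
#' @param amplitude_pA step amplitude, pA (negative for hyperpolarizing
#'   steps).
#' @param duration_ms pulse (or ramp) duration, ms.
#' @param dt sample interval, ms.
#' @param pre_ms,post_ms zero-current padding before/after the pulse, ms.
#' @param label protocol label.
#' @return An object of class `stim_protocol` with fields `kind`, `dt`,
#'   `segments` (data.frame), `label`, and the pulse window
#'   `pulse_onset_ms` / `pulse_end_ms`.
#' @examples
#' p <- step_protocol(100) # 600 ms x 100 pA with 100 ms padding
#' length(protocol_waveform(p)) # (100 + 600 + 100) / 0.01 samples
#' @export
step_protocol <- function(amplitude_pA, duration_ms = 600, dt = 0.01,
                          pre_ms = 100, post_ms = 100,
                          label = sprintf("step_%gpA", amplitude_pA)) {
  if (!is.finite(amplitude_pA)) stop("amplitude must be finite")
  if (duration_ms <= 0) stop("pulse duration must be > 0")
  if (pre_ms < 0 || post_ms < 0) stop("padding durations must be >= 0")
  segs <- data.frame(
    duration = c(pre_ms, duration_ms, post_ms),
    start = c(0, amplitude_pA, 0),
    end = c(0, amplitude_pA, 0))
  segs <- segs[segs$duration > 0, , drop = FALSE]
  new_protocol("step", dt, segs, label,
               pulse_onset_ms = pre_ms, pulse_end_ms = pre_ms + duration_ms)
}

#' @rdname step_protocol
#' @param from_pA,to_pA ramp start/end current, pA.
#' @export
ramp_protocol <- function(from_pA = 0, to_pA = 200, duration_ms = 8000,
                          dt = 0.01, pre_ms = 100, post_ms = 100,
                          label = sprintf("ramp_%g-%gpA", from_pA, to_pA)) {
  if (duration_ms <= 0) stop("ramp duration must be > 0")
  if (pre_ms < 0 || post_ms < 0) stop("padding durations must be >= 0")
  segs <- data.frame(
    duration = c(pre_ms, duration_ms, post_ms),
    start = c(0, from_pA, 0),
    end = c(0, to_pA, 0))
  segs <- segs[segs$duration > 0, , drop = FALSE]
  new_protocol("ramp", dt, segs, label,
               pulse_onset_ms = pre_ms, pulse_end_ms = pre_ms + duration_ms)
}

#' @rdname step_protocol
#' @param amplitudes_pA vector of step amplitudes, pA (default the standard
#'   rheobase family, 0 to 200 pA in 10 pA increments).
#' @return `step_family()` returns a list of `stim_protocol` objects, named
#'   by amplitude.
#' @export
step_family <- function(amplitudes_pA = seq(0, 200, by = 10),
                        duration_ms = 600, dt = 0.01,
                        pre_ms = 100, post_ms = 100) {
  out <- lapply(amplitudes_pA, step_protocol, duration_ms = duration_ms,
                dt = dt, pre_ms = pre_ms, post_ms = post_ms)
  names(out) <- sprintf("%g", amplitudes_pA)
  out
}

new_protocol <- function(kind, dt, segments, label,
                         pulse_onset_ms, pulse_end_ms) {
  if (any(!is.finite(unlist(segments)))) stop("non-finite protocol segment")
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(kind = kind, dt = dt, segments = segments, label = label,
                 pulse_onset_ms = pulse_onset_ms,
                 pulse_end_ms = pulse_end_ms),
            class = "stim_protocol")
}

#' Sampled current waveform of a protocol
#'
#' @param protocol a `stim_protocol`.
#' @return Numeric vector of injected current (pA), one value per sample of
#'   duration `dt`; sample `k` covers time `[(k-1) dt, k dt)`.
#' @export
protocol_waveform <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  dt <- protocol$dt
  parts <- lapply(seq_len(nrow(protocol$segments)), function(i) {
    seg <- protocol$segments[i, ]
    n <- round(seg$duration / dt)
    if (n < 1) return(numeric(0))
    if (seg$start == seg$end) rep(seg$start, n)
    else seg$start + (seg$end - seg$start) * (seq_len(n) - 0.5) / n
  })
  unlist(parts, use.names = FALSE)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol '%s' (%s), dt = %g ms\n",
              x$label, x$kind, x$dt))
  cat(sprintf("  total %g ms; pulse %g-%g ms\n",
              sum(x$segments$duration), x$pulse_onset_ms, x$pulse_end_ms))
  invisible(x)
}

total_duration_ms <- function(protocol) sum(protocol$segments$duration)
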