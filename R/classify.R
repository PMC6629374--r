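#' Firing-gap cutoff from a pooled ISI distribution
#'
#' The burst-terminating gap is defined, as in the source analysis, as the
#' mean plus two standard deviations of all interspike intervals in the
#' dataset. With no data, the default cutoff of 150 ms is returned with a
#' warning.
#'
#' @param all_isis pooled ISIs (ms) across the dataset's sweeps.
#' @param fallback_ms cutoff used when `all_isis` is empty.
#' @return Gap cutoff, ms.
#' @examples
#' gap_cutoff(c(rep(50, 5), rep(50 + 50 * sqrt(2), 0))) # mean + 2 sd
#' @export
gap_cutoff <- function(all_isis, fallback_ms = 150) {
  all_isis <- all_isis[is.finite(all_isis)]
  if (!length(all_isis)) {
    warning("no ISIs supplied; using the fallback gap cutoff")
    return(fallback_ms)
  }
  if (length(all_isis) < 10)
    warning("fewer than 10 ISIs; gap cutoff estimate is unstable")
  mean(all_isis) + 2 * sd(all_isis)
}

#' Initial burst length of a sweep
#'
#' The time (from stimulus onset) of the last spike before the first
#' firing gap exceeding `cutoff_ms`. The trailing silence after the final
#' spike counts as a gap, so a cell firing once early in a long sweep has
#' a short burst, not a full-sweep one. If no gap exceeds the cutoff the
#' burst extends to the final spike.
#'
#' @param spike_times spike times relative to stimulus onset, ms (or a
#'   `spike_train` whose times are pulse-relative).
#' @param sweep_duration_ms stimulus duration, ms.
#' @param cutoff_ms firing-gap cutoff, ms (see [gap_cutoff()]).
#' @return Burst length in seconds (0 for an empty train).
#' @examples
#' burst_length(seq(100, 1000, by = 100), 8000) # next gap > 150 ms -> 1 s
#' @export
burst_length <- function(spike_times, sweep_duration_ms, cutoff_ms = 150) {
  times <- if (inherits(spike_times, "spike_train")) spike_times$spike_times
           else spike_times
  if (!length(times)) return(0)
  times <- sort(times)
  gaps <- c(diff(times), sweep_duration_ms - times[length(times)])
  first_gap <- which(gaps > cutoff_ms)[1]
  if (is.na(first_gap)) times[length(times)] / 1000
  else times[first_gap] / 1000
}

#' Burst-length / ISI-CoV features of one sweep
#'
#' The two classification variables of the IS/CA split: initial burst
#' length and ISI coefficient of variation, from a single suprathreshold
#' sweep. `apparent_features()` is the 600 ms variant ("apparent" because
#' short sweeps truncate the pattern and blur the IS/CA distinction).
#'
#' @inheritParams burst_length
#' @param current_multiple stimulus amplitude in multiples of rheobase.
#' @return List of class `pattern_features`: `burst_length` (s),
#'   `isi_cov`, `n_spikes`, `sweep_duration` (s), `current_multiple`.
#' @export
pattern_features <- function(spike_times, sweep_duration_ms = 8000,
                             cutoff_ms = 150, current_multiple = 2) {
  times <- if (inherits(spike_times, "spike_train")) spike_times$spike_times
           else spike_times
  structure(list(burst_length = burst_length(times, sweep_duration_ms, cutoff_ms),
                 isi_cov = isi_cov(times),
                 n_spikes = length(times),
                 sweep_duration = sweep_duration_ms / 1000,
                 current_multiple = current_multiple),
            class = "pattern_features")
}

#' @rdname pattern_features
#' @export
apparent_features <- function(spike_times, cutoff_ms = 150,
                              current_multiple = 2) {
  pattern_features(spike_times, sweep_duration_ms = 600,
                   cutoff_ms = cutoff_ms, current_multiple = current_multiple)
}

#' IS/CA classification by k-means on burst length and ISI CoV
#'
#' Cells are clustered into two groups with k-means (Lloyd's algorithm,
#' multiple restarts) on z-scored burst length and ISI CoV. The cluster
#' with the higher mean (raw) ISI CoV is labelled `IS`, the other `CA`.
#' Cells with too few spikes for a CoV (fewer than 3) are kept
#' classifiable by imputing the cohort's 95th percentile CoV, and are
#' flagged.
#'
#' @param features data.frame with columns `cell_id`, `burst_length`
#'   (s) and `isi_cov` (possibly `NA`).
#' @param seed RNG seed for the k-means restarts.
#' @param restarts number of random restarts.
#' @return Object of class `classification_result`: `cells` (data.frame
#'   with `cell_id`, features, `imputed`, `label`, `dist_to_center`),
#'   `centers` (2 x 2, standardized space, rows named IS/CA), `inertia`
#'   (total within-cluster sum of squares), `silhouette` (mean silhouette
#'   width in standardized space), `seed`.
#' @export
classify_cells <- function(features, seed = 1, restarts = 25) {
  stopifnot(is.data.frame(features),
            all(c("cell_id", "burst_length", "isi_cov") %in% names(features)))
  if (nrow(features) < 4) stop("at least 4 cells required for clustering")
  x <- features
  x$imputed <- !is.finite(x$isi_cov)
  if (all(x$imputed)) stop("no cell has a measurable ISI CoV")
  imput <- quantile(x$isi_cov[!x$imputed], 0.95, names = FALSE)
  x$isi_cov[x$imputed] <- imput

  if (sd(x$burst_length) == 0 && sd(x$isi_cov) == 0)
    stop("degenerate features: all cells identical, no two-cluster structure")
  z <- scale(cbind(burst_length = x$burst_length, isi_cov = x$isi_cov))
  z[, apply(z, 2, function(col) any(!is.finite(col)))] <- 0

  km <- with_seed(seed, kmeans(z, centers = 2, nstart = restarts,
                               algorithm = "Lloyd", iter.max = 100))
  mean_cov <- tapply(x$isi_cov, km$cluster, mean)
  is_cluster <- as.integer(names(mean_cov)[which.max(mean_cov)])
  x$label <- ifelse(km$cluster == is_cluster, "IS", "CA")
  x$dist_to_center <- sqrt(rowSums((z - km$centers[km$cluster, ])^2))

  centers <- km$centers[c(is_cluster, 3 - is_cluster), , drop = FALSE]
  rownames(centers) <- c("IS", "CA")
  sil <- mean(cluster::silhouette(km$cluster, dist(z))[, "sil_width"])
  structure(list(cells = x, centers = centers, inertia = km$tot.withinss,
                 silhouette = sil, seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  tab <- table(x$cells$label)
  cat(sprintf("IS/CA classification of %d cells: %d IS, %d CA\n",
              nrow(x$cells), tab["IS"], tab["CA"]))
  cat(sprintf("  mean silhouette %.2f, inertia %.2f, %d CoV-imputed cells\n",
              x$silhouette, x$inertia, sum(x$cells$imputed)))
  invisible(x)
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}
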