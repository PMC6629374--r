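#' Pearson chi-square test on a 2x2 contingency table
#'
#' Genotype x firing-pattern association test. No continuity correction
#' by default: the uncorrected Pearson statistic is what the source
#' analysis reports (Yates' correction is available behind `correct`).
#'
#' @param counts 2x2 matrix (or something coercible) of nonnegative
#'   counts; rows = genotype, columns = firing pattern.
#' @param correct apply Yates' continuity correction?
#' @return List: `statistic`, `df` (1), `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(51, 41, 63, 31), 2)) # ~2.63, p ~0.10
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("a 2x2 table is required")
  if (any(counts < 0) || sum(counts) == 0) stop("invalid counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: the test is undefined")
  ht <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = 1,
       p_value = unname(ht$p.value))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. `U` is computed from
#' midranks (ties allowed). The two-sided p value doubles the smaller
#' exact tail (capped at 1). Small samples are handled exactly: by
#' complete enumeration of the rank assignments (works with ties) when
#' `choose(n + m, n)` is manageable, by the exact Wilcoxon distribution
#' for tie-free samples with `n * m <= 400`, and otherwise by the normal
#' approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p value;
#'   default `NULL` chooses as described.
#' @return List: `U` (for `x`; `U_x + U_y = n*m`), `p_value` (two-sided),
#'   `method`.
#' @examples
#' mann_whitney_u(1:3, 4:6) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (!n || !m) stop("both samples must contain at least one value")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  ties <- anyDuplicated(c(x, y)) > 0
  n_assign <- choose(n + m, n)
  use_enum <- if (is.null(exact)) n_assign <= 2e5 else (exact && n_assign <= 2e5)
  use_pwilcox <- !use_enum && !ties && n * m <= 400 &&
    (is.null(exact) || exact)

  if (use_enum) {
    p <- mwu_enum_p(r, n, u)
    method <- "exact enumeration"
  } else if (use_pwilcox) {
    lower <- pwilcox(u, n, m)
    upper <- 1 - pwilcox(u - 1, n, m)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact distribution"
  } else {
    mu <- n * m / 2
    nt <- table(r)
    sigma2 <- n * m / 12 * ((n + m + 1) - sum(nt^3 - nt) / ((n + m) * (n + m - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = u, p_value = p, method = method)
}

# exact two-sided p by complete enumeration of which ranks go to x
mwu_enum_p <- function(r, n, u_obs) {
  combos <- utils::combn(length(r), n)
  offset <- n * (n + 1) / 2
  us <- colSums(matrix(r[combos], nrow = n)) - offset
  eps <- 1e-9
  lower <- mean(us <= u_obs + eps)
  upper <- mean(us >= u_obs - eps)
  min(1, 2 * min(lower, upper))
}

#' Group summary table (mean +/- SEM)
#'
#' Per-group mean, standard error of the mean and n for one measured
#' variable, optionally aggregating to one value per animal first (each
#' animal's cells averaged, so the animal is the unit of analysis).
#'
#' @param data data.frame of per-cell measurements.
#' @param value name of the value column.
#' @param group name of the grouping column.
#' @param animal optional name of an animal-id column for per-animal
#'   aggregation.
#' @return data.frame: `group`, `mean`, `sem`, `n`.
#' @export
group_summary <- function(data, value, group, animal = NULL) {
  for (col in c(value, group, animal))
    if (!col %in% names(data)) stop(sprintf("missing column '%s'", col))
  if (!is.null(animal)) {
    agg <- stats::aggregate(data[[value]],
                            by = list(group = data[[group]], animal = data[[animal]]),
                            FUN = mean, na.rm = TRUE)
    data <- data.frame(g = agg$group, v = agg$x)
  } else {
    data <- data.frame(g = data[[group]], v = data[[value]])
  }
  data <- data[is.finite(data$v), ]
  out <- do.call(rbind, lapply(split(data$v, data$g), function(v) {
    data.frame(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}
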