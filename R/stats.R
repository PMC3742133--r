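#' Round half away from zero
#'
#' Reported percentages and fold enrichments are rounded half-up to one
#' decimal (e.g. 99.55 -> 99.6), matching how the validation table is
#' conventionally printed, rather than R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' 2x2 contingency table of model fits by training set
#'
#' Rows are the training sets (positive, negative), columns fit / no-fit.
#'
#' @param pos_hit,pos_miss,neg_hit,neg_miss Non-negative integer counts.
#' @return A 2x2 integer matrix with dimnames.
#' @export
contingency_table <- function(pos_hit, pos_miss, neg_hit, neg_miss) {
  cells <- c(pos_hit, pos_miss, neg_hit, neg_miss)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  matrix(as.integer(cells), nrow = 2L, byrow = TRUE,
         dimnames = list(set = c("positive", "negative"),
                         model = c("fit", "no_fit")))
}

#' Fold enrichment of a feature between two sets
#'
#' `(pos_hit/pos_n) / (neg_hit/neg_n)`. When the negative set has zero hits
#' the ratio is reported as `Inf` (flagged, not an error).
#'
#' @param pos_hit,pos_n Hits and size of the positive set.
#' @param neg_hit,neg_n Hits and size of the negative set.
#' @return A double; `Inf` when `neg_hit == 0`.
#' @export
fold_enrichment <- function(pos_hit, pos_n, neg_hit, neg_n) {
  if (pos_n <= 0 || neg_n <= 0) stop("set sizes must be positive", call. = FALSE)
  (pos_hit / pos_n) / (neg_hit / neg_n)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value defined as the sum of hypergeometric probabilities, at
#' fixed margins, of all tables whose point probability does not exceed the
#' observed table's (ties within relative tolerance 1e-7). Any zero margin
#' gives p = 1.
#'
#' @param table A 2x2 matrix (see [contingency_table()]).
#' @return The p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Lower bound solves `P(X >= k | n, p) = alpha/2` (0 when `k = 0`); upper
#' bound solves `P(X <= k | n, p) = alpha/2` (1 when `k = n`); computed via
#' beta quantiles.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n <= 0 || k < 0 || k > n) {
    stop("need 0 <= k <= n with n > 0", call. = FALSE)
  }
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Sensitivity and specificity with exact binomial confidence intervals
#'
#' Sensitivity is the positive-set fit rate `pos_hit/pos_n`; specificity the
#' negative-set no-fit rate `neg_miss/neg_n`. Confidence intervals are exact
#' Clopper-Pearson. Percentages are also given rounded half-up to one
#' decimal in the `*_pct` columns.
#'
#' @param table A 2x2 matrix (see [contingency_table()]).
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble with raw proportions, CI bounds, and rounded
#'   percentage columns.
#' @export
sensitivity_specificity <- function(table, conf = 0.95) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(rowSums(table) == 0)) stop("row sums must be positive", call. = FALSE)
  pos_n <- sum(table[1L, ]); neg_n <- sum(table[2L, ])
  sens <- table[1L, 1L] / pos_n
  spec <- table[2L, 2L] / neg_n
  sci <- clopper_pearson(table[1L, 1L], pos_n, conf)
  pci <- clopper_pearson(table[2L, 2L], neg_n, conf)
  tibble::tibble(
    sensitivity = sens, sens_lower = sci[["lower"]], sens_upper = sci[["upper"]],
    specificity = spec, spec_lower = pci[["lower"]], spec_upper = pci[["upper"]],
    sensitivity_pct = round_half_up(100 * sens),
    sens_lower_pct = round_half_up(100 * sci[["lower"]]),
    sens_upper_pct = round_half_up(100 * sci[["upper"]]),
    specificity_pct = round_half_up(100 * spec),
    spec_lower_pct = round_half_up(100 * pci[["lower"]]),
    spec_upper_pct = round_half_up(100 * pci[["upper"]])
  )
}

#' Chi-squared test with Yates continuity correction on a 2x2 table
#'
#' The statistic is `sum((|O - E| - 0.5)^2 / E)` with the correction floored
#' at zero when `|O - E| < 0.5`; p from the chi-squared distribution with
#' 1 df. Used for pathway over-representation against a gene universe.
#'
#' @param table A 2x2 matrix of counts with all margins positive.
#' @return One-row tibble with `statistic` and `p_value`.
#' @export
chi2_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins must be positive; use Fisher's exact test instead",
         call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("zero expected cell; use Fisher's exact test instead", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = unname(res$p.value))
}
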