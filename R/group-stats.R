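#' Group summary: mean and standard error
#'
#' @param values Numeric vector, length >= 1, no NAs.
#' @param group Group label.
#' @return A one-row data.frame: `group`, `n`, `mean`, `sem` (sample s.d.
#'   with n-1 denominator over sqrt(n); `sem` is 0 for n = 1).
#' @export
summarize_group <- function(values, group = NA_character_) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop_input("`values` must be a non-empty numeric vector without NAs")
  }
  n <- length(values)
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else 0
  data.frame(group = as.character(group), n = n,
             mean = mean(values), sem = sem, stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p by enumeration over group assignments,
# valid with ties (midranks). Used when the combination count is small.
ranksum_exact_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  combs <- utils::combn(na + nb, na)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- na * (na + nb + 1) / 2
  obs <- sum(r[seq_len(na)])
  p <- mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
  u <- obs - na * (na + 1) / 2
  list(statistic = u, p.value = p)
}

#' Two-group comparison (rank-sum or t test)
#'
#' `method = "rank_sum"` performs a two-sided Mann-Whitney/Wilcoxon test:
#' exact when both groups have n <= 20 (via the exact null distribution, or
#' full enumeration over assignments when ties make the standard exact
#' distribution inapplicable and the enumeration is small), otherwise the
#' tie-corrected normal approximation. `method = "t_test"` is Welch's
#' two-sided t test.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param method `"rank_sum"` or `"t_test"`.
#' @return A list with `statistic` (U for group `a`, or t), `p_value`, and
#'   `method`.
#' @export
compare_groups <- function(a, b, method = c("rank_sum", "t_test")) {
  method <- match.arg(method)
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2L || length(b) < 2L) {
    stop_input("each group needs at least 2 numeric observations")
  }
  if (method == "t_test") {
    ht <- stats::t.test(a, b)
    return(list(statistic = unname(ht$statistic),
                p_value = ht$p.value, method = "t_test"))
  }
  small <- length(a) <= 20L && length(b) <= 20L
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (small && !has_ties) {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    return(list(statistic = unname(ht$statistic),
                p_value = ht$p.value, method = "rank_sum_exact"))
  }
  if (small && has_ties && choose(length(a) + length(b), length(a)) <= 2e5) {
    res <- ranksum_exact_enum(a, b)
    return(list(statistic = res$statistic, p_value = res$p.value,
                method = "rank_sum_exact"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "rank_sum_normal")
}

#' Chemokine-induced transmigration
#'
#' Induced transmigration is total migration with chemokine minus random
#' migration without chemokine; the difference is reported as-is and may
#' be negative.
#'
#' @param total_with_chemokine,random_without Non-negative cell counts
#'   (vectorized, equal length or scalar).
#' @return `total_with_chemokine - random_without`.
#' @export
induced_transmigration <- function(total_with_chemokine, random_without) {
  if (!is.numeric(total_with_chemokine) || !is.numeric(random_without) ||
      any(total_with_chemokine < 0) || any(random_without < 0) ||
      anyNA(total_with_chemokine) || anyNA(random_without)) {
    stop_input("counts must be non-negative numbers")
  }
  total_with_chemokine - random_without
}

#' Normalize values to a reference group's mean
#'
#' Divides every value by the mean of the reference group (e.g. per-gram
#' cell counts normalized to the wild-type group of each experiment), so
#' the reference group's normalized mean is exactly 1.
#'
#' @param values data.frame with columns `group` and `value`.
#' @param reference_group Label of the reference group.
#' @return The input with an added `normalized` column.
#' @export
normalize_to_reference <- function(values, reference_group) {
  if (!is.data.frame(values) || !all(c("group", "value") %in% names(values))) {
    stop_input("`values` must be a data.frame with columns group, value")
  }
  ref <- values$value[values$group == reference_group]
  if (length(ref) == 0L) {
    stop_input("reference group '%s' is empty", reference_group)
  }
  m <- mean(ref)
  if (m == 0) stop_compute("reference group mean is zero; cannot normalize")
  values$normalized <- values$value / m
  values
}
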