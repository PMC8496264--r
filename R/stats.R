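# Rank-based tests and Bonferroni correction used by the sector-enrichment
# and expression modules. Kruskal-Wallis and the unpaired rank-sum test are
# the base-R implementations; Dunn's post hoc z test is authored here from
# the standard tie-corrected formula.

#' @noRd
rank_test_result <- function(statistic, p_raw, method, family_size = 1L) {
  p_raw <- min(max(p_raw, 0), 1)
  structure(list(statistic = unname(statistic),
                 p_raw = p_raw,
                 p_adj = min(1, p_raw * family_size),
                 method = method,
                 family_size = as.integer(family_size)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (adjusted %.4g, family %d)\n",
              x$method, x$statistic, x$p_raw, x$p_adj, x$family_size))
  invisible(x)
}

#' Kruskal-Wallis rank test over k groups
#'
#' Tie-corrected H with a chi-square (k-1 df) p-value, via
#' [stats::kruskal.test()]. When every observation is identical the tie
#' correction degenerates; by convention H = 0 and p = 1. The chi-square
#' approximation is weak for very small groups; a warning is emitted when
#' any group has fewer than 5 observations.
#'
#' @param groups list of >= 2 numeric vectors, all non-empty.
#' @param family_size Bonferroni family for the adjusted p (default 1).
#' @return a `rank_test` result (statistic, p_raw, p_adj, method,
#'   family_size).
#' @export
kruskal_wallis <- function(groups, family_size = 1L) {
  pr_assert(is.list(groups) && length(groups) >= 2,
            "need a list of at least two groups")
  sizes <- lengths(groups)
  pr_assert(all(sizes > 0), "empty group(s) at position(s): %s",
            paste(which(sizes == 0), collapse = ", "))
  pr_assert(sum(sizes) >= 3, "need at least 3 observations in total")
  if (any(sizes < 5)) {
    warning("group size below 5; the chi-square approximation is rough",
            call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(rank_test_result(0, 1, "kruskal_wallis", family_size))
  }
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  rank_test_result(kt$statistic, kt$p.value, "kruskal_wallis", family_size)
}

#' Dunn's post hoc test for all group pairs
#'
#' For groups i and j with mean ranks computed on the pooled sample of size
#' n, `z = (Rbar_i - Rbar_j) / sqrt((n(n+1)/12 - T/(12(n-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values,
#' Bonferroni-adjusted over the `k(k-1)/2` pairs.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return data.frame with columns group_i, group_j, z, p_raw, p_adj.
#' @export
dunn_posthoc <- function(groups) {
  pr_assert(is.list(groups) && length(groups) >= 2,
            "need a list of at least two groups")
  sizes <- lengths(groups)
  pr_assert(all(sizes > 0), "empty group(s) at position(s): %s",
            paste(which(sizes == 0), collapse = ", "))
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  pr_assert(n >= 3, "need at least 3 observations in total")
  r <- rank(x)
  g <- rep(seq_len(k), sizes)
  rbar <- tapply(r, g, mean)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  z <- p_raw <- numeric(n_pairs)
  for (m in seq_len(n_pairs)) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
    z[m] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_raw[m] <- if (se > 0) 2 * stats::pnorm(-abs(z[m])) else 1
  }
  data.frame(group_i = names(groups)[pairs[1, ]],
             group_j = names(groups)[pairs[2, ]],
             z = z, p_raw = p_raw,
             p_adj = bonferroni(p_raw, n_pairs),
             stringsAsFactors = FALSE)
}

#' Unpaired rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples have at most 8 untied observations,
#' otherwise the tie-corrected normal approximation with continuity
#' correction — the [stats::wilcox.test()] machinery in both branches.
#'
#' @param a,b non-empty numeric samples.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (a vs b).
#' @param family_size Bonferroni family for the adjusted p (default 1).
#' @return a `rank_test` result; the statistic is the Mann-Whitney U of
#'   sample `a`.
#' @export
mann_whitney <- function(a, b, alternative = c("two_sided", "greater", "less"),
                         family_size = 1L) {
  alternative <- match.arg(alternative)
  pr_assert(length(a) > 0 && length(b) > 0, "both samples must be non-empty")
  alt <- sub("two_sided", "two.sided", alternative)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alt, exact = exact,
                       correct = TRUE))
  rank_test_result(wt$statistic, wt$p.value, "mann_whitney", family_size)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * family_size)`; order-preserving.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param family_size number of comparisons; `"auto"` uses
#'   `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, family_size = "auto") {
  pr_assert(all(!is.na(p_values) & p_values >= 0 & p_values <= 1),
            "p-values must lie in [0, 1]")
  m <- if (identical(family_size, "auto")) length(p_values)
       else as.integer(family_size)
  pr_assert(m >= length(p_values),
            "family_size must be at least the number of p-values")
  pmin(1, p_values * m)
}
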