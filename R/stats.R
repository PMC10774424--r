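#' Compare two groups with a nonparametric two-sample test
#'
#' Runs the chosen two-sided nonparametric test and reports, alongside the
#' test statistic and p-value, the effect size as the absolute difference of
#' group medians in the metric's native units (never the test statistic).
#' No multiple-testing correction is applied.
#'
#' @param a,b Numeric samples (each with >= 2 values).
#' @param test_name `"ks_two_sided"` (Kolmogorov-Smirnov, default),
#'   `"mann_whitney"` (Wilcoxon rank-sum), or `"kruskal_wallis"`.
#' @return A one-row tibble of class `comparison_result`: `test_name`,
#'   `statistic`, `p_value`, `effect_size_abs_median_diff`, `n_a`, `n_b`.
#' @examples
#' compare_two_groups(rnorm(20), rnorm(20, 1), "mann_whitney")
#' @export
compare_two_groups <- function(a, b,
                               test_name = c("ks_two_sided", "mann_whitney",
                                             "kruskal_wallis")) {
  test_name <- match.arg(test_name)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 non-missing samples")
  }
  res <- switch(
    test_name,
    ks_two_sided = suppressWarnings(
      ks.test(a, b, alternative = "two.sided")),
    mann_whitney = suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided")),
    kruskal_wallis = kruskal.test(list(a, b))
  )
  out <- tibble(
    test_name = test_name,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    effect_size_abs_median_diff = abs(median(a) - median(b)),
    n_a = length(a),
    n_b = length(b)
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Omnibus comparison across multiple groups (Kruskal-Wallis)
#'
#' @param groups A list of numeric samples (>= 2 groups, each >= 2 values),
#'   or a data frame with columns `value` and `group`.
#' @return A one-row tibble of class `comparison_result`: `test_name`,
#'   `statistic`, `p_value`, `effect_size_abs_median_diff` (largest absolute
#'   pairwise difference of group medians), `n_groups`, `n_total`.
#' @export
compare_multi_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 non-missing samples each")
  }
  res <- kruskal.test(groups)
  med <- vapply(groups, median, numeric(1))
  out <- tibble(
    test_name = "kruskal_wallis",
    statistic = unname(res$statistic),
    p_value = res$p.value,
    effect_size_abs_median_diff = max(dist(med)),
    n_groups = length(groups),
    n_total = sum(lengths(groups))
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Median and quartiles of a sample
#'
#' Group summaries throughout the package are median plus interquartile
#' range. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention documented for all figure-style
#' summaries.
#'
#' @param samples Numeric vector (>= 1 non-missing value).
#' @return A one-row tibble: `n`, `median`, `q25`, `q75`.
#' @examples
#' summarize_group(1:5)  # median 3, quartiles 2 and 4
#' @export
summarize_group <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 1) abort("need at least one non-missing sample")
  tibble(
    n = length(samples),
    median = median(samples),
    q25 = quantile(samples, 0.25, names = FALSE, type = 7),
    q75 = quantile(samples, 0.75, names = FALSE, type = 7)
  )
}

#' @importFrom stats dist
NULL
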