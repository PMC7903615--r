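#' Two-sample group comparison
#'
#' Two-sided comparison of two replicate groups, as used per gene and per
#' timepoint by the screen: Welch's unequal-variance t test or the
#' Mann-Whitney (Wilcoxon rank-sum) test. The Mann-Whitney p-value is exact
#' (enumeration over rank splits) for small untied samples, matching
#' `stats::wilcox.test`. The p-value is invariant under swapping the two
#' groups.
#'
#' Degenerate inputs never error: when both groups have zero variance,
#' Welch's statistic is undefined and the function returns `p = 1` for
#' equal means or `p = 0` for unequal means, with `degenerate = TRUE`.
#'
#' @param values_a,values_b Numeric vectors of replicate measurements
#'   (log2 scale in the screen). Welch's t needs >= 2 values per group;
#'   Mann-Whitney needs >= 1.
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return A list with `statistic`, `p_value` (two-sided, in [0, 1]) and
#'   `degenerate` (logical).
#' @export
#' @examples
#' group_compare(c(1, 2, 3), c(4, 5, 6), "welch_t")
group_compare <- function(values_a, values_b,
                          method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (any(!is.finite(c(a, b))))
    stop("group values must be finite", call. = FALSE)
  if (method == "welch_t") {
    if (length(a) < 2 || length(b) < 2)
      stop("welch_t needs at least 2 values per group", call. = FALSE)
    if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b))
        return(list(statistic = 0, p_value = 1, degenerate = TRUE))
      return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                  degenerate = TRUE))
    }
    ht <- t.test(a, b, var.equal = FALSE)
    return(list(statistic = unname(ht$statistic),
                p_value = unname(ht$p.value), degenerate = FALSE))
  }
  if (length(a) < 1 || length(b) < 1)
    stop("mann_whitney needs at least 1 value per group", call. = FALSE)
  if (length(unique(c(a, b))) == 1)
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                degenerate = TRUE))
  ht <- suppressWarnings(wilcox.test(a, b))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       degenerate = FALSE)
}
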