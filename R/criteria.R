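#' Screen criteria
#'
#' All thresholds of the temporal screen in one object. Defaults encode the
#' discovery criterion: a gene is transiently induced when its fold change
#' is >= `induction_fold` (2) at every induction timepoint (12 h and 24 h),
#' significant at `alpha` (0.01, Welch's t on log2 values), and back within
#' `return_band` (+/-20%, i.e. FC in [0.80, 1.20], both ends inclusive) of
#' baseline at `return_timepoint_h` (72 h = 3 days). Sustained
#' upregulation requires FC >= `sustained_fold` with significance at every
#' treated timepoint.
#'
#' @param induction_fold Fold-change threshold for induction (> 1);
#'   inclusive (FC >= threshold passes).
#' @param induction_timepoints_h Hours at which induction is required.
#' @param induction_policy `"all"` (default: every induction timepoint must
#'   pass) or `"any"`.
#' @param return_timepoint_h Hour of the baseline-return test; must exceed
#'   the largest induction timepoint.
#' @param return_band Half-width of the return band on the fold-change
#'   scale, in (0, 1); 0.20 means FC within [0.80, 1.20].
#' @param sustained_fold Fold threshold for persistent upregulation (> 1).
#' @param alpha Per-test significance level in (0, 1).
#' @param require_significance Gate induction calls on `p < alpha`?
#' @param test_method `"welch_t"` or `"mann_whitney"`.
#' @param p_adjust `"none"` (default; the screen applies no multiple-testing
#'   correction) or `"BH"` for Benjamini-Hochberg across genes per
#'   timepoint.
#' @return A list of class `ScreenCriteria`.
#' @export
#' @examples
#' screen_criteria(induction_fold = 3, alpha = 0.001)
screen_criteria <- function(induction_fold = 2.0,
                            induction_timepoints_h = c(12, 24),
                            induction_policy = c("all", "any"),
                            return_timepoint_h = 72,
                            return_band = 0.20,
                            sustained_fold = 2.0,
                            alpha = 0.01,
                            require_significance = TRUE,
                            test_method = c("welch_t", "mann_whitney"),
                            p_adjust = c("none", "BH")) {
  induction_policy <- match.arg(induction_policy)
  test_method <- match.arg(test_method)
  p_adjust <- match.arg(p_adjust)
  if (!length(induction_timepoints_h))
    stop("induction_timepoints_h must be non-empty", call. = FALSE)
  if (induction_fold <= 1 || sustained_fold <= 1)
    stop("fold thresholds must be > 1", call. = FALSE)
  if (return_timepoint_h <= max(induction_timepoints_h))
    stop("return_timepoint_h must exceed every induction timepoint",
         call. = FALSE)
  if (return_band <= 0 || return_band >= 1)
    stop("return_band must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(induction_fold = induction_fold,
                 induction_timepoints_h = as.numeric(induction_timepoints_h),
                 induction_policy = induction_policy,
                 return_timepoint_h = as.numeric(return_timepoint_h),
                 return_band = return_band,
                 sustained_fold = sustained_fold,
                 alpha = alpha,
                 require_significance = require_significance,
                 test_method = test_method,
                 p_adjust = p_adjust),
            class = "ScreenCriteria")
}

#' Read screen criteria from a YAML config section
#'
#' Accepts a flat key-value mapping with any subset of the
#' [screen_criteria()] arguments; hours may be given as strings like
#' `"3d"` (days) or `"12h"`, normalized to hours at load.
#'
#' @param x Path to a YAML file, or an already-parsed named list.
#' @return A `ScreenCriteria` object.
#' @export
read_criteria <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x$screen)) x <- x$screen
  hours <- function(v) {
    if (is.numeric(v)) return(v)
    v <- as.character(v)
    n <- suppressWarnings(as.numeric(sub("[hd]$", "", v)))
    if (any(is.na(n))) stop("cannot parse timepoint: ",
                            paste(v, collapse = ", "), call. = FALSE)
    ifelse(grepl("d$", v), n * 24, n)
  }
  args <- x[intersect(names(x), names(formals(screen_criteria)))]
  for (f in c("induction_timepoints_h", "return_timepoint_h"))
    if (!is.null(args[[f]])) args[[f]] <- hours(unlist(args[[f]]))
  do.call(screen_criteria, args)
}
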