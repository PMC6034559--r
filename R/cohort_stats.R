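#' Age-stratified colonization prevalence
#'
#' Counts subjects and positives per age bin and reports the percentage
#' positive, rounded to 2 decimals. Bins are closed intervals in months
#' (the conventional `0-36, 37-72, ...` strata); a subject falling in no
#' bin is an error, and an empty bin reports a missing percentage rather
#' than 0.
#'
#' @param cohort data frame with columns `age_months` and `sfb_status`
#'   (`"positive"`/`"negative"`).
#' @param bins list of length-2 numeric vectors `c(lower, upper)`, both
#'   ends included; defaults to the standard strata up to 181 months.
#' @return a tibble with `age_bin`, `n_total`, `n_positive`,
#'   `percent_positive`.
#' @export
prevalence_table <- function(cohort,
                             bins = list(c(0, 36), c(37, 72),
                                         c(73, 108), c(109, 181))) {
  cohort <- as_tibble(cohort)
  stopifnot(all(c("age_months", "sfb_status") %in% names(cohort)))
  if (any(cohort$age_months <= 0)) stop("ages must be > 0", call. = FALSE)
  assigned <- rep(FALSE, nrow(cohort))
  rows <- lapply(bins, function(b) {
    stopifnot(length(b) == 2, b[1] <= b[2])
    in_bin <- cohort$age_months >= b[1] & cohort$age_months <= b[2]
    assigned <<- assigned | in_bin
    n_total <- sum(in_bin)
    n_pos <- sum(in_bin & cohort$sfb_status == "positive")
    tibble(age_bin = paste0(b[1], "-", b[2]),
           n_total = n_total,
           n_positive = n_pos,
           percent_positive = if (n_total == 0) NA_real_
                              else round(100 * n_pos / n_total, 2))
  })
  if (!all(assigned)) {
    stop(sum(!assigned), " subject(s) fall in no age bin", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare a measurement between two groups
#'
#' Two-sided comparison of two groups of values with Student's t-test
#' (the default), Welch's t-test, or the Mann-Whitney (Wilcoxon rank-sum)
#' test, reporting group medians and means alongside the test statistic
#' and p-value.
#'
#' @param values_a,values_b numeric vectors (>= 2 values per group for the
#'   t-tests, >= 1 for Mann-Whitney).
#' @param test `"student_t"`, `"welch_t"`, or `"mann_whitney"`.
#' @return a list of class `group_comparison`: `test`, `median_a`,
#'   `median_b`, `mean_a`, `mean_b`, `n_a`, `n_b`, `statistic`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("student_t", "welch_t", "mann_whitney")) {
  test <- match.arg(test)
  min_n <- if (test == "mann_whitney") 1L else 2L
  if (length(values_a) < min_n || length(values_b) < min_n) {
    stop("insufficient group sizes for ", test, call. = FALSE)
  }
  res <- switch(test,
    student_t = t.test(values_a, values_b, var.equal = TRUE),
    welch_t = t.test(values_a, values_b, var.equal = FALSE),
    mann_whitney = wilcox.test(values_a, values_b, exact = FALSE))
  structure(list(test = test,
                 median_a = median(values_a), median_b = median(values_b),
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 n_a = length(values_a), n_b = length(values_b),
                 statistic = unname(res$statistic),
                 p_value = res$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: medians %.4g vs %.4g (n = %d/%d), p = %.4g\n",
              x$test, x$median_a, x$median_b, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), in the
#' input order. Delegates to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes by fold change and FDR
#'
#' The conventional two-filter rule: at least a twofold change in either
#' direction (`fold >= 2` or `fold <= 0.5`, boundaries included) and
#' BH-adjusted p below `alpha`.
#'
#' @param fold_changes named numeric vector of fold changes.
#' @param adjusted_p named numeric vector of adjusted p-values over the
#'   same gene names.
#' @param min_fold fold-change cutoff (default 2).
#' @param alpha significance cutoff on the adjusted p (default 0.05,
#'   strict inequality).
#' @return character vector of selected gene names.
#' @export
select_differential <- function(fold_changes, adjusted_p, min_fold = 2,
                                alpha = 0.05) {
  if (is.null(names(fold_changes)) || is.null(names(adjusted_p)) ||
      !setequal(names(fold_changes), names(adjusted_p))) {
    stop("fold_changes and adjusted_p must be named over the same genes",
         call. = FALSE)
  }
  adjusted_p <- adjusted_p[names(fold_changes)]
  sel <- (fold_changes >= min_fold | fold_changes <= 1 / min_fold) &
    adjusted_p < alpha
  names(fold_changes)[sel]
}

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the normalized abundance vector, with
#' `0 log 0 = 0`; natural log by default (nats), base 2 via `base`.
#' Delegates to [vegan::diversity()].
#'
#' @param abundances non-negative abundance vector with positive sum
#'   (counts or proportions; rescaling does not change H).
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon_index <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (sum(abundances) <= 0) stop("all-zero abundance vector", call. = FALSE)
  unname(vegan::diversity(abundances, index = "shannon", base = base))
}
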