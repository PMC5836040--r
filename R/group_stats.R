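#' Construct a test result
#'
#' Light container for the battery's outputs, shared by every test in the
#' package: the statistic, degrees of freedom (a number, a pair, or `NA`
#' when the reference distribution has none), the two-tailed p-value, the
#' test's name and the group sizes.
#'
#' @param statistic test statistic.
#' @param df degrees of freedom (may be `NA` or a length-2 vector).
#' @param p_value two-tailed p-value.
#' @param test_name label.
#' @param n_per_group integer vector of group sizes.
#' @param estimate optional effect estimate (mean difference, r, ...).
#' @return An object of class `dd_test`.
#' @export
test_result <- function(statistic, df, p_value, test_name, n_per_group,
                        estimate = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), test_name = test_name,
         n_per_group = unname(n_per_group), estimate = unname(estimate)),
    class = "dd_test"
  )
}

#' @export
print.dd_test <- function(x, ...) {
  cat(sprintf("<dd_test> %s: statistic = %.4g, df = %s, p = %.4g (n = %s)\n",
              x$test_name, x$statistic,
              paste(signif(x$df, 4), collapse = ","), x$p_value,
              paste(x$n_per_group, collapse = " vs ")))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' Student's paired t-test on matched per-subject values (e.g. a subject's
#' AUC with stimulation on vs off), `df = n - 1`.
#'
#' @param values_a,values_b matched numeric vectors, length `>= 3`.
#' @return A [test_result()].
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (length(values_a) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- values_a - values_b
  if (sd(d) == 0) {
    stop("zero variance of paired differences; t undefined", call. = FALSE)
  }
  ht <- t.test(values_a, values_b, paired = TRUE)
  test_result(ht$statistic, ht$parameter, ht$p.value, "paired_t",
              length(values_a), estimate = mean(d))
}

#' Independent two-tailed t-test (pooled variance)
#'
#' Student's t-test with pooled variance, `df = nA + nB - 2` (so 9
#' patients vs 18 controls give `df = 25`).
#'
#' @param group_a,group_b numeric vectors, each of length `>= 2`.
#' @return A [test_result()].
#' @export
independent_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need >= 2 observations per group", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    stop("zero pooled variance; t undefined", call. = FALSE)
  }
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  test_result(ht$statistic, ht$parameter, ht$p.value, "independent_t",
              c(length(group_a), length(group_b)),
              estimate = mean(group_a) - mean(group_b))
}

#' Compare groups on session-averaged AUC
#'
#' Averages each subject's AUC over their two sessions and compares
#' patients to controls with [independent_t()]. This mirrors the
#' counterbalance-robust comparison: averaging over the on/off (or
#' session 1/2) pair removes any order confound before the between-group
#' test. Subjects lacking one of the two sessions are dropped with a
#' warning.
#'
#' @param auc_table data frame from [auc_cohort()] (needs `subject_id`,
#'   `group`, `session`, `auc`).
#' @return A [test_result()] with attribute `averages`: the per-subject
#'   mean AUC table.
#' @export
session_average_compare <- function(auc_table) {
  n_sessions <- tapply(auc_table$session, auc_table$subject_id,
                       function(s) length(unique(s)))
  incomplete <- names(n_sessions)[n_sessions < 2]
  if (length(incomplete) > 0) {
    warning("excluding subject(s) without both sessions: ",
            paste(incomplete, collapse = ", "))
    auc_table <- auc_table[!auc_table$subject_id %in% incomplete, ,
                           drop = FALSE]
  }
  avg <- aggregate(auc ~ subject_id + group, data = auc_table, FUN = mean)
  res <- independent_t(avg$auc[avg$group == "patient"],
                       avg$auc[avg$group == "control"])
  res$test_name <- "session_average_independent_t"
  attr(res, "averages") <- avg
  res
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Uses exact enumeration
#' when both groups have at most 8 observations and the data are tie-free;
#' otherwise the tie-corrected normal approximation. The reported
#' statistic is U for the first group (the number of pairwise wins,
#' counting ties as one half).
#'
#' @param group_a,group_b numeric vectors, non-empty.
#' @return A [test_result()] (df is `NA`; U has no classical df).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- !has_ties && max(length(group_a), length(group_b)) <= 8
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = use_exact, correct = !use_exact)
  )
  test_result(ht$statistic, NA_real_, ht$p.value, "mann_whitney_u",
              c(length(group_a), length(group_b)))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, `df = 1`. Used for
#' the demographic 2x2 comparisons (sex, handedness) reconstructed from
#' group counts.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A [test_result()].
#' @export
#' @examples
#' chi_square_2x2(matrix(c(8, 1, 11, 7), nrow = 2, byrow = TRUE))
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin; chi-square undefined", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  test_result(ht$statistic, ht$parameter, ht$p.value, "chi_square_2x2",
              rowSums(counts))
}

#' Test-retest correlation of fitted parameters
#'
#' Pearson correlation of a fitted parameter (`log_k` or `temp_hat`)
#' between a subject's two sessions, with the two-tailed p-value from the
#' t transform `r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param fits_s1,fits_s2 data frames of fits (as rows of [fit_cohort()]
#'   output) matched by `subject_id`.
#' @param parameter `"log_k"` or `"temp"`.
#' @return A [test_result()] with `estimate = r`.
#' @export
retest_correlation <- function(fits_s1, fits_s2,
                               parameter = c("log_k", "temp")) {
  parameter <- match.arg(parameter)
  col <- if (parameter == "log_k") "log_k" else "temp_hat"
  m <- match(fits_s1$subject_id, fits_s2$subject_id)
  if (anyNA(m)) {
    stop("sessions are not matched: missing subject(s) ",
         paste(fits_s1$subject_id[is.na(m)], collapse = ", "),
         call. = FALSE)
  }
  x <- fits_s1[[col]]
  y <- fits_s2[[col]][m]
  if (length(x) < 3) stop("need n >= 3 matched subjects", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in one session; correlation undefined",
         call. = FALSE)
  }
  ht <- cor.test(x, y, method = "pearson")
  test_result(ht$statistic, ht$parameter, ht$p.value,
              paste0("retest_correlation_", parameter), length(x),
              estimate = unname(ht$estimate))
}

#' Between-group comparison of absolute session differences in log k
#'
#' Computes each subject's `|log k(session 1) - log k(session 2)|` from
#' their ML fits and compares patients to controls with
#' [independent_t()] (plus a Mann-Whitney U robustness check). A group
#' difference here would indicate that one group's parameters moved more
#' between sessions, regardless of direction.
#'
#' @param fits_s1,fits_s2 matched fit tables as in
#'   [retest_correlation()].
#' @param groups character vector of group labels aligned with
#'   `fits_s1` rows (defaults to `fits_s1$group`).
#' @return A list of class `dd_abs_diff`: `table` (per-subject absolute
#'   differences), `t_test` and `mann_whitney` results.
#' @export
abs_logk_difference <- function(fits_s1, fits_s2,
                                groups = fits_s1$group) {
  m <- match(fits_s1$subject_id, fits_s2$subject_id)
  if (anyNA(m)) {
    stop("sessions are not matched: missing subject(s) ",
         paste(fits_s1$subject_id[is.na(m)], collapse = ", "),
         call. = FALSE)
  }
  tab <- data.frame(
    subject_id = fits_s1$subject_id,
    group = groups,
    abs_logk_diff = abs(fits_s1$log_k - fits_s2$log_k[m]),
    stringsAsFactors = FALSE
  )
  a <- tab$abs_logk_diff[tab$group == "patient"]
  b <- tab$abs_logk_diff[tab$group == "control"]
  # degenerate inputs (e.g. identical sessions) leave the table usable and
  # mark the undefined test rather than failing
  structure(
    list(table = tab,
         t_test = tryCatch(independent_t(a, b), error = function(e) e),
         mann_whitney = tryCatch(mann_whitney_u(a, b),
                                 error = function(e) e)),
    class = "dd_abs_diff"
  )
}

#' @export
print.dd_abs_diff <- function(x, ...) {
  cat("<dd_abs_diff> |log k| session difference, patients vs controls\n")
  print(x$t_test)
  print(x$mann_whitney)
  invisible(x)
}
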