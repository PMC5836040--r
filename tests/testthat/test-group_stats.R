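test_that("paired t matches closed-form arithmetic", {
  a <- c(1.2, 0.8, 1.5, 1.1)
  b <- c(1.0, 0.9, 1.2, 1.0)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  # symmetric differences around zero give t = 0
  expect_equal(paired_t(c(1, 2, 3), c(3, 2, 1))$statistic, 0)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("independent t uses pooled variance with df = nA + nB - 2", {
  a <- c(0.5, 0.7, 0.6, 0.9)
  b <- c(0.4, 0.8, 0.5)
  res <- independent_t(a, b)
  sp2 <- ((4 - 1) * var(a) + (3 - 1) * var(b)) / (4 + 3 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 5)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)
  expect_equal(independent_t(a, a)$statistic, 0)
  # 9 patients vs 18 controls -> df 25
  set.seed(4)
  expect_equal(independent_t(rnorm(9), rnorm(18))$df, 25)
  expect_error(independent_t(rep(1, 3), rep(1, 4)), "zero pooled variance")
})

test_that("session averaging reduces to the single-session test when equal", {
  set.seed(11)
  auc_tab <- data.frame(
    subject_id = rep(c(sprintf("p%d", 1:4), sprintf("c%d", 1:6)), each = 2),
    group = rep(c(rep("patient", 4), rep("control", 6)), each = 2),
    session = rep(c("s1", "s2"), 10),
    auc = NA_real_
  )
  per_subject <- runif(10, 0.3, 0.9)
  auc_tab$auc <- rep(per_subject, each = 2)  # identical sessions
  res <- session_average_compare(auc_tab)
  direct <- independent_t(per_subject[1:4], per_subject[5:10])
  expect_equal(res$statistic, direct$statistic)
  expect_equal(res$p_value, direct$p_value)
  # averaging is order-invariant across the two sessions
  flipped <- auc_tab
  flipped$session <- rep(c("s2", "s1"), 10)
  expect_equal(session_average_compare(flipped)$statistic, res$statistic)
  # a subject with one session is excluded with a warning
  expect_warning(res2 <- session_average_compare(auc_tab[-1, ]), "p1")
  expect_equal(res2$n_per_group, c(3, 6))
})

test_that("Mann-Whitney U counts pairwise wins", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(res$p_value, 0.99)
  set.seed(12)
  for (i in 1:10) {
    a <- round(runif(sample(3:12, 1), 0, 10), 1)
    b <- round(runif(sample(3:12, 1), 0, 10), 1)
    u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney_u(a, b)$statistic, u_brute)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("2x2 chi-square reproduces textbook values", {
  # proportional rows are exactly independent
  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), 2, byrow = TRUE))$statistic, 0)
  tab <- matrix(c(8, 1, 11, 7), 2, byrow = TRUE)
  res <- chi_square_2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(1, 0, 2, 0), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("retest correlation follows the Pearson t transform", {
  f1 <- data.frame(subject_id = sprintf("s%d", 1:5),
                   log_k = c(-4.2, -3.1, -5.0, -2.8, -3.9),
                   temp_hat = c(1.5, 2.2, 0.9, 3.0, 1.8))
  f2 <- f1
  expect_equal(retest_correlation(f1, f2, "log_k")$estimate, 1)
  f2$log_k <- -f1$log_k
  expect_equal(retest_correlation(f1, f2, "log_k")$estimate, -1)
  f2$log_k <- c(-4.0, -3.3, -4.6, -3.0, -3.5)
  res <- retest_correlation(f1, f2, "log_k")
  r_hand <- cor(f1$log_k, f2$log_k)
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 3), tolerance = 1e-10)
  # temp parameter routes to temp_hat
  expect_equal(retest_correlation(f1, f1, "temp")$estimate, 1)
  f2$log_k <- rep(-3, 5)
  expect_error(retest_correlation(f1, f2, "log_k"), "zero variance")
})

test_that("absolute log-k session differences behave symmetrically", {
  set.seed(21)
  f1 <- data.frame(subject_id = sprintf("s%d", 1:10),
                   group = rep(c("patient", "control"), each = 5),
                   log_k = rnorm(10, -4, 0.8))
  f2 <- f1
  f2$log_k <- f1$log_k + rnorm(10, 0, 0.3)
  res <- abs_logk_difference(f1, f2)
  expect_true(all(res$table$abs_logk_diff >= 0))
  flipped <- abs_logk_difference(f2, f1, groups = f1$group)
  expect_equal(flipped$table$abs_logk_diff, res$table$abs_logk_diff)
  expect_equal(res$t_test$n_per_group, c(5, 5))
  # identical sessions give all-zero differences
  same <- abs_logk_difference(f1, f1)$table
  expect_true(all(same$abs_logk_diff == 0))
})

test_that("equal within-subject noise rarely flags a group difference", {
  cfg <- study_config()
  set.seed(33)
  n_sig <- 0L
  for (r in 1:10) {
    f1 <- data.frame(subject_id = sprintf("s%d", 1:27),
                     group = rep(c("patient", "control"), c(9, 18)),
                     log_k = rnorm(27, -4.6, 0.8))
    f2 <- f1
    f2$log_k <- f1$log_k + rnorm(27, 0, 0.4)  # same noise in both groups
    res <- abs_logk_difference(f1, f2)
    if (res$t_test$p_value < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2)
})
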