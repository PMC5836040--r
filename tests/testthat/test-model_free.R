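test_that("indifference points land within one grid step of truth", {
  cfg <- study_config()
  step <- (80 - 20.5) / 19
  ds <- deterministic_dataset(1 / 90, cfg)
  ind <- indifference_points(ds, cfg)
  # true indifference at delay 90: 20 * (1 + 90/90) = 40
  est <- ind$indifference_amount[ind$delay_days == 90]
  expect_lt(abs(est - 40), step)
  expect_identical(ind$censoring[ind$delay_days == 90], "ok")
})

test_that("one-sided choice patterns are censored at the grid edges", {
  cfg <- study_config()
  trials <- build_trial_set(cfg)
  trials$choice <- "delayed"
  all_acc <- choice_dataset("a", "control", "s1", "none", trials)
  ind <- indifference_points(all_acc, cfg)
  expect_true(all(ind$censoring == "censored_low"))
  expect_true(all(ind$indifference_amount == 20.5))
  trials$choice <- "immediate"
  all_rej <- choice_dataset("r", "control", "s1", "none", trials)
  ind <- indifference_points(all_rej, cfg)
  expect_true(all(ind$censoring == "censored_high"))
  expect_true(all(ind$indifference_amount == 80))
  # a delay with a single amount cannot be located
  one_amt <- data.frame(trial_index = 1:2, immediate_amount = 20,
                        delayed_amount = 50, delay_days = 30,
                        choice = c("delayed", "immediate"))
  ds <- choice_dataset("x", "control", "s1", "none", one_amt)
  expect_error(indifference_points(ds, cfg), "delay 30")
})

test_that("profiles normalize value and delay with the (0,1) anchor", {
  ind <- data.frame(delay_days = c(90, 180),
                    indifference_amount = c(40, 80))
  prof <- build_profile(ind, immediate_amount = 20, max_delay = 180)
  expect_equal(prof$points$x, c(0, 0.5, 1))
  expect_equal(prof$points$y, c(1, 0.5, 0.25))
  flat <- build_profile(data.frame(delay_days = c(30, 180),
                                   indifference_amount = c(20, 20)), 20)
  expect_true(all(flat$points$y == 1))
  no_anchor <- build_profile(ind, 20, anchor = FALSE)
  expect_equal(nrow(no_anchor$points), 2)
  expect_warning(
    build_profile(data.frame(delay_days = 30, indifference_amount = 10),
                  20), "clipped")
})

test_that("trapezoid AUC matches hand arithmetic and stays in (0, 1]", {
  prof <- build_profile(data.frame(delay_days = c(90, 180),
                                   indifference_amount = c(40, 80)),
                        20, max_delay = 180)
  # (0,1) -> (0.5,0.5) -> (1,0.25): 0.5*0.75 + 0.5*0.375
  expect_equal(auc(prof), 0.5625)
  bad <- prof
  bad$points <- bad$points[c(2, 1, 3), ]
  expect_error(auc(bad), "increasing")
  set.seed(9)
  for (i in 1:20) {
    amounts <- sort(runif(4, 20.5, 80))
    prof <- build_profile(data.frame(delay_days = c(7, 30, 90, 180),
                                     indifference_amount = amounts), 20)
    expect_gt(auc(prof), 0)
    expect_lte(auc(prof), 1)
  }
})

test_that("deterministic-agent AUC matches the analytic hyperbolic curve", {
  cfg <- study_config()
  delays <- cfg$task$delays
  step <- (80 - 20.5) / 19
  for (k in c(0.005, 0.01, 1 / 60)) {
    ds <- deterministic_dataset(k, cfg)
    ind <- indifference_points(ds, cfg)
    prof <- build_profile(ind, 20)
    got <- auc(prof)
    y_true <- 1 / (1 + k * delays)
    x <- c(0, delays / 180)
    y <- c(1, y_true)
    analytic <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
    # tolerance implied by one amount-grid step in every indifference point
    a_true <- 20 * (1 + k * delays)
    dy <- 20 * step / (a_true * pmax(a_true - step, 20))
    y_tol <- c(0, dy)
    n <- length(x)
    tol <- sum(diff(x) * (y_tol[-n] + y_tol[-1]) / 2)
    expect_lt(abs(got - analytic), tol)
  }
})

test_that("AUC decreases with the discount rate and batches deterministically", {
  cfg <- study_config()
  ks <- c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1)
  aucs <- vapply(ks, function(k) {
    ds <- deterministic_dataset(k, cfg)
    auc(build_profile(indifference_points(ds, cfg), 20))
  }, numeric(1))
  expect_true(all(diff(aucs) <= 0))

  coh <- simulate_cohort(cohort_spec(n_patients = 2, n_controls = 2,
                                     seed = 77), cfg)
  tab1 <- auc_cohort(coh, cfg)
  expect_equal(nrow(tab1), 8)
  expect_identical(tab1, auc_cohort(coh, cfg))
  # failure collection: a dataset with one amount per delay
  broken <- coh[[1]]
  broken$trials <- broken$trials[!duplicated(broken$trials$delay_days), ]
  tab2 <- auc_cohort(c(coh[-1], list(broken)), cfg)
  expect_equal(nrow(tab2), 7)
  expect_equal(nrow(attr(tab2, "failures")), 1)
})
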