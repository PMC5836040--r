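# Sampler tests run on reduced chain lengths: long enough for the checks'
# Monte-Carlo tolerances, short enough to keep the suite quick.

make_cell_datasets <- function(n, cell_seed, logk_mean, logk_sd = 0.4,
                               temp = 2, session = "s1",
                               prefix = "sub", trials = NULL,
                               cfg = study_config()) {
  if (is.null(trials)) trials <- build_trial_set(cfg)
  set.seed(cell_seed)
  ks <- exp(rnorm(n, logk_mean, logk_sd))
  seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    simulate_agent(list(k = ks[i], temp = temp), trials,
                   subject_id = sprintf("%s%02d", prefix, i),
                   group = "control", session = session,
                   condition = "none", seed = seeds[i])
  })
}

test_that("draws are seed-deterministic and respect the support", {
  cfg <- short_mcmc_cfg()
  coh <- simulate_cohort(cohort_spec(n_patients = 2, n_controls = 2,
                                     seed = 15), cfg)
  p1 <- sample_posterior(coh, cfg, seed = 77)
  p2 <- sample_posterior(coh, cfg, seed = 77)
  expect_identical(p1$draws, p2$draws)
  p3 <- sample_posterior(coh, cfg, seed = 78)
  expect_false(identical(p1$draws, p3$draws))
  for (nm in names(p1$draws)) {
    expect_true(all(p1$draws[[nm]] > 0), label = nm)
  }
  for (cell in p1$cells) {
    mk <- p1$draws[[paste0("mu_k.", cell)]]
    expect_true(all(mk >= cfg$priors$k_mean$lower &
                      mk <= cfg$priors$k_mean$upper))
    sk <- p1$draws[[paste0("sigma_k.", cell)]]
    expect_true(all(sk >= cfg$priors$k_sd$lower &
                      sk <= cfg$priors$k_sd$upper))
  }
  expect_equal(dim(p1$draws[[1]]), c(200L, 2L))  # 400 retained over 2 chains
  expect_error(group_posterior_summary(p1, "nonexistent"), "unknown group")
  expect_error(compare_conditions(p1, "patient_on", "nope"), "unknown group")
  expect_warning(null_cmp <- compare_conditions(p1, "patient_on",
                                                "patient_on"), "itself")
  expect_equal(null_cmp["k_mean", "p_a_greater"], 0.5)
  expect_equal(null_cmp["k_mean", "overlap"], 1)
})

test_that("with no likelihood the posterior reproduces the priors", {
  cfg <- study_config(mcmc = list(burn_in = 2000L, n_retained = 40000L,
                                  thinning = 1L, init = "prior"))
  # study-shaped cohort whose responses are all missing
  trials <- build_trial_set(cfg)[1:4, ]
  trials$choice <- "missing"
  cells <- list(c("patient", "s1", "dbs_on", 9), c("patient", "s2", "dbs_off", 9),
                c("control", "s1", "none", 18), c("control", "s2", "none", 18))
  datasets <- unlist(lapply(cells, function(cl) {
    lapply(seq_len(as.integer(cl[4])), function(i) {
      choice_dataset(sprintf("%s_%s_%02d", cl[1], cl[2], i), cl[1], cl[2],
                     cl[3], trials)
    })
  }), recursive = FALSE)
  post <- sample_posterior(datasets, cfg, seed = 5)

  pr <- cfg$priors
  # analytic prior means (uniforms; truncated normal via closed form)
  a <- -pr$temp_mean$mean / sqrt(pr$temp_mean$var)
  lam <- dnorm(a) / (1 - pnorm(a))
  tn_mean <- pr$temp_mean$mean + sqrt(pr$temp_mean$var) * lam
  tn_sd <- sqrt(pr$temp_mean$var * (1 + a * lam - lam^2))
  unif_sd <- function(p) (p$upper - p$lower) / sqrt(12)
  targets <- list(
    mu_k = c(mean(c(pr$k_mean$lower, pr$k_mean$upper)),       # 1.000005
             unif_sd(pr$k_mean)),
    sigma_k = c(mean(c(pr$k_sd$lower, pr$k_sd$upper)), unif_sd(pr$k_sd)),
    mu_temp = c(tn_mean, tn_sd),
    sigma_temp = c(mean(c(pr$temp_sd$lower, pr$temp_sd$upper)),
                   unif_sd(pr$temp_sd))
  )
  for (cell in post$cells) {
    for (par in names(targets)) {
      mat <- post$draws[[paste0(par, ".", cell)]]
      tol <- 6 * mcse(mat)
      expect_lt(abs(mean(mat) - targets[[par]][1]), tol,
                label = paste(par, cell))
      # the run must mix well enough that the check can tell the prior
      # apart from a substantially different distribution
      expect_lt(tol, 0.5 * targets[[par]][2], label = paste(par, cell))
    }
  }
  # 95% interval of the k-mean ~ central 95% of its uniform prior
  s <- group_posterior_summary(post, "control_s1")
  expect_lt(abs(s["k_mean", "q2.5"] - 0.05), 0.06)
  expect_lt(abs(s["k_mean", "q97.5"] - 1.95), 0.06)
  # Jensen: mean of log draws below log of mean draw
  expect_lte(s["log_k_mean", "mean"], log(s["k_mean", "mean"]))
})

test_that("a 1-unit log-k group difference is resolved by the posterior", {
  cfg <- study_config(mcmc = list(burn_in = 800L, n_retained = 4000L,
                                  thinning = 1L))
  trials <- build_trial_set(cfg)
  a <- make_cell_datasets(18, 61, log(0.01), session = "s1", prefix = "a",
                          trials = trials, cfg = cfg)
  b <- make_cell_datasets(18, 62, log(0.01) + 1, session = "s2",
                          prefix = "b", trials = trials, cfg = cfg)
  post <- sample_posterior(c(a, b), cfg, seed = 9)
  cmp <- compare_conditions(post, "control_s1", "control_s2")
  # group B discounts more steeply: difference A - B below zero
  expect_lt(cmp["k_mean", "diff_q97.5"], 0)
  expect_lt(cmp["k_mean", "p_a_greater"], 0.05)
  expect_lt(cmp["k_mean", "overlap"], 0.5)
})

test_that("identical data in two cells gives symmetric posteriors", {
  cfg <- study_config(mcmc = list(burn_in = 600L, n_retained = 4000L,
                                  thinning = 1L))
  a <- make_cell_datasets(6, 71, log(0.015), session = "s1",
                          prefix = "dup", cfg = cfg)
  b <- lapply(a, function(ds) {
    choice_dataset(ds$subject_id, ds$group, "s2", ds$condition, ds$trials)
  })
  post <- sample_posterior(c(a, b), cfg, seed = 13)
  cmp <- compare_conditions(post, "control_s1", "control_s2")
  expect_gt(cmp["k_mean", "p_a_greater"], 0.3)
  expect_lt(cmp["k_mean", "p_a_greater"], 0.7)
  expect_gt(cmp["k_mean", "overlap"], 0.7)
})

test_that("sampler agrees with an independent JAGS fit and shrinks", {
  cfg <- study_config(mcmc = list(burn_in = 1000L, n_retained = 6000L,
                                  thinning = 1L))
  datasets <- make_cell_datasets(8, 81, log(0.02), cfg = cfg)
  post <- sample_posterior(datasets, cfg, seed = 17)

  # independent reference fit of the same model via JAGS
  model <- "
  model {
    for (i in 1:S) {
      k[i] ~ dnorm(mu_k, 1 / (sigma_k^2)) T(0,)
      temp[i] ~ dnorm(mu_t, 1 / (sigma_t^2)) T(0,)
      for (t in 1:Tn) {
        logit(p[i, t]) <- (A[i, t] / (1 + k[i] * D[i, t]) - imm) / temp[i]
        y[i, t] ~ dbern(p[i, t])
      }
    }
    mu_k ~ dunif(0.00001, 2)
    sigma_k ~ dunif(0.001, 2)
    mu_t ~ dnorm(20, 0.001) T(0,)
    sigma_t ~ dunif(0.01, 100)
  }"
  S <- length(datasets)
  Tn <- nrow(datasets[[1]]$trials)
  A <- t(vapply(datasets, function(d) d$trials$delayed_amount, numeric(Tn)))
  D <- t(vapply(datasets, function(d) d$trials$delay_days, numeric(Tn)))
  y <- t(vapply(datasets, function(d) {
    as.numeric(d$trials$choice == "delayed")
  }, numeric(Tn)))
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(S = S, Tn = Tn, A = A, D = D, y = y, imm = 20),
    inits = list(
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)),
    n.chains = 2, n.adapt = 1000, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("mu_k", "sigma_k", "mu_t"), 3000,
                            progress.bar = "none")
  jags_mat <- function(par) {
    vapply(js, function(ch) as.numeric(ch[, par]), numeric(nrow(js[[1]])))
  }
  for (pair in list(c("mu_k.control_s1", "mu_k"),
                    c("sigma_k.control_s1", "sigma_k"),
                    c("mu_temp.control_s1", "mu_t"))) {
    mine <- post$draws[[pair[1]]]
    ref <- jags_mat(pair[2])
    tol <- 6 * sqrt(mcse(mine)^2 + mcse(ref)^2)
    expect_lt(abs(mean(mine) - mean(ref)), tol, label = pair[1])
  }

  # hierarchical pooling: subject k estimates move toward the group mean
  fits <- fit_cohort(datasets, cfg)
  mu_hat <- mean(post$draws[["mu_k.control_s1"]])
  k_post <- vapply(fits$subject_id, function(id) {
    mean(post$draws[[paste0("k.", id, ".s1")]])
  }, numeric(1))
  k_ml <- fits$k_hat
  expect_lt(mean(abs(k_post - mu_hat)), mean(abs(k_ml - mu_hat)))
})

test_that("convergence report flags disagreeing chains", {
  set.seed(91)
  good <- matrix(rnorm(4000), 2000, 2)
  stuck <- cbind(rnorm(2000, 0), rnorm(2000, 3))
  fake <- structure(
    list(draws = list(stationary = good, copy = cbind(good[, 1], good[, 1]),
                      split_means = stuck),
         cells = "control_s1",
         acceptance = c(k = 0.3),
         mcmc = list(n_chains = 2)),
    class = "dd_posterior")
  rep <- convergence_report(fake)
  expect_lt(rep$rhat[rep$parameter == "stationary"], 1.05)
  expect_lt(abs(rep$rhat[rep$parameter == "copy"] - 1), 0.02)
  expect_gt(rep$rhat[rep$parameter == "split_means"], 1.05)
  expect_true(rep$flagged[rep$parameter == "split_means"])
  expect_false(rep$flagged[rep$parameter == "stationary"])
  expect_true(all(rep$ess <= 4000))
  single <- fake
  single$draws <- lapply(single$draws, function(m) m[, 1, drop = FALSE])
  expect_match(attr(convergence_report(single), "note"), "single chain")
})

test_that("the log-scale hyper-model variant runs and exposes mu_k", {
  cfg <- short_mcmc_cfg(scale = "log")
  datasets <- make_cell_datasets(4, 99, log(0.02), cfg = cfg)
  post <- sample_posterior(datasets, cfg, seed = 21)
  expect_true("mu_logk.control_s1" %in% names(post$draws))
  expect_true("mu_k.control_s1" %in% names(post$draws))
  expect_true(all(post$draws[["mu_k.control_s1"]] > 0))
  lk <- post$draws[["mu_logk.control_s1"]]
  expect_true(all(lk >= cfg$priors$logk_mean$lower &
                    lk <= cfg$priors$logk_mean$upper))
})
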