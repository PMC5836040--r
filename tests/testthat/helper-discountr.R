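# Shared fixtures, all built in code.

default_cfg <- study_config()

# A short MCMC schedule for sampler tests that only need a valid chain,
# not a converged one.
short_mcmc_cfg <- function(...) {
  study_config(mcmc = modifyList(
    list(burn_in = 200L, n_retained = 400L, thinning = 1L), list(...)))
}

# Noiseless responder following the normalized hyperbolic curve: accepts
# the delayed offer iff its discounted value exceeds the immediate amount.
hyperbolic_responder <- function(k) {
  function(trial) {
    sv <- trial$delayed_amount / (1 + k * trial$delay_days)
    if (sv > trial$immediate_amount) "delayed" else "immediate"
  }
}

# Deterministic agent dataset: choices are the sign of the SV difference.
deterministic_dataset <- function(k, config = default_cfg,
                                  subject_id = "det", group = "control",
                                  session = "s1", condition = "none") {
  trials <- build_trial_set(config)
  sv <- trials$delayed_amount / (1 + k * trials$delay_days)
  trials$choice <- ifelse(sv > trials$immediate_amount,
                          "delayed", "immediate")
  choice_dataset(subject_id, group, session, condition, trials)
}

# Small hand-built dataset for likelihood arithmetic.
tiny_dataset <- function(choices = c("delayed", "immediate", "delayed"),
                         amounts = c(30, 50, 70),
                         delays = c(7, 30, 90)) {
  choice_dataset("tiny", "control", "s1", "none", data.frame(
    trial_index = seq_along(choices), immediate_amount = 20,
    delayed_amount = amounts, delay_days = delays, choice = choices))
}

# Independent brute-force grid search over a log-spaced (k, temp) lattice;
# the oracle against which the simplex optimum is checked.
grid_oracle <- function(dataset, n = 200, k_range = c(1e-5, 2),
                        temp_range = c(1e-3, 1e3)) {
  tr <- dataset$trials[dataset$trials$choice != "missing", , drop = FALSE]
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n))
  ts <- exp(seq(log(temp_range[1]), log(temp_range[2]), length.out = n))
  sv <- outer(tr$delayed_amount, rep(1, n)) /
    (1 + outer(tr$delay_days, ks))
  sgn <- ifelse(tr$choice == "delayed", 1, -1)
  best <- Inf
  best_k <- NA_real_
  for (j in seq_along(ts)) {
    x <- sgn * (sv - tr$immediate_amount) / ts[j]
    nll <- -colSums(pmax(plogis(x, log.p = TRUE), log(1e-12)))
    jmin <- which.min(nll)
    if (nll[jmin] < best) {
      best <- nll[jmin]
      best_k <- ks[jmin]
    }
  }
  list(neg_loglik = best, k = best_k)
}

# Markov-chain Monte Carlo standard error of a posterior mean.
mcse <- function(draws_mat) {
  v <- as.vector(draws_mat)
  ess <- sum(vapply(seq_len(ncol(draws_mat)), function(j) {
    unname(coda::effectiveSize(coda::mcmc(draws_mat[, j])))
  }, numeric(1)))
  sd(v) / sqrt(max(ess, 1))
}
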