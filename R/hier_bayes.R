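# Hierarchical Bayesian model of delay discounting.
#
# Four group-level cells (patients on/off stimulation, controls session
# 1/2), each with normal hyper-distributions for the discount rate k and
# the softmax noise temp, truncated to (0, Inf) at the subject level.
# Priors: k-mean ~ U(0.00001, 2); temp-mean ~ N(20, var 1000) truncated at
# 0; group SDs uniform. Sampling is componentwise random-walk Metropolis
# within Gibbs with log-scale proposals for positive parameters; proposal
# scales adapt only during burn-in (target acceptance 0.2-0.5) so the
# retained chain is a valid Markov chain.

log_tnorm0_normalizer <- function(mu, sigma) {
  # log P(X > 0) for X ~ N(mu, sigma)
  pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE)
}

#' Sample the hierarchical posterior
#'
#' Fits all subject-sessions jointly: each dataset's (k, temp) is drawn
#' from the normal hyper-distribution of its cell (`patient_on`,
#' `patient_off`, `control_s1`, `control_s2`, as assigned by
#' [dataset_cell()]), truncated to positive values, and the cell means and
#' SDs carry the priors described in [study_config()]. The sampler is a
#' componentwise random-walk Metropolis-within-Gibbs: subject parameters
#' are updated jointly across subjects in two vectorized sweeps (log-scale
#' proposals), then each cell's four hyper-parameters are updated in turn.
#' Proposal scales adapt during burn-in only and are frozen afterwards.
#' With `config$mcmc$scale = "log"` the k hyper-distribution is placed on
#' log k instead (untruncated normal), and draws of the implied k-mean
#' `exp(mu + sigma^2/2)` are recorded under the same `mu_k` names so the
#' comparison surface is unchanged.
#'
#' Datasets with zero non-missing records are admitted (their likelihood
#' contribution is empty), which makes prior-recovery runs possible; every
#' cell present must contain at least one dataset.
#'
#' @param datasets list of `dd_dataset` covering one to four cells.
#' @param config a [study_config()]; its `priors` and `mcmc` sections
#'   control the model.
#' @param seed integer seed (defaults to `config$seeds$mcmc`); draws are
#'   fully determined by it.
#' @param verbose print progress.
#' @return An object of class `dd_posterior`: `draws` (named list,
#'   parameter -> retained-iteration x chain matrix), `cells`, `subjects`
#'   (registry data frame), `acceptance` (post-burn-in acceptance rate per
#'   parameter block), `mcmc`, `scale`, `seed`.
#' @export
sample_posterior <- function(datasets, config = study_config(),
                             seed = NULL, verbose = FALSE) {
  validate_config(config)
  if (length(datasets) == 0) stop("no datasets", call. = FALSE)
  for (ds in datasets) validate_dataset(ds)
  if (is.null(seed)) seed <- config$seeds$mcmc
  mc <- config$mcmc
  pr <- config$priors
  log_scale <- mc$scale == "log"

  cell_order <- c("patient_on", "patient_off", "control_s1", "control_s2")
  subj_cells <- vapply(datasets, dataset_cell, character(1))
  cells <- cell_order[cell_order %in% subj_cells]
  cell_idx <- match(subj_cells, cells)
  S <- length(datasets)
  G <- length(cells)
  group_n <- tabulate(cell_idx, nbins = G)
  if (any(group_n == 0)) {
    stop("empty group: ", paste(cells[group_n == 0], collapse = ", "),
         call. = FALSE)
  }

  # flatten all trials for vectorized subject-level likelihood sweeps
  terms <- lapply(datasets, dataset_lik_terms)
  allA <- unlist(lapply(terms, `[[`, "A"))
  allD <- unlist(lapply(terms, `[[`, "D"))
  allImm <- unlist(lapply(terms, `[[`, "imm"))
  allSign <- unlist(lapply(terms, `[[`, "sign"))
  trial_subj <- rep(seq_len(S), vapply(terms, `[[`, 0L, "n"))
  has_trials <- length(trial_subj) > 0
  loglik_all <- function(k, temp) {
    ll <- numeric(S)
    if (!has_trials) return(ll)
    x <- allSign * (allA / (1 + k[trial_subj] * allD) - allImm) /
      temp[trial_subj]
    lp <- pmax(plogis(x, log.p = TRUE), .log_p_floor)
    agg <- rowsum(lp, trial_subj)
    ll[as.integer(rownames(agg))] <- agg[, 1]
    ll
  }

  retained_per_chain <- if (mc$retained_per_chain) {
    mc$n_retained
  } else {
    mc$n_retained %/% mc$n_chains
  }
  n_post <- retained_per_chain * mc$thinning
  total_iter <- mc$burn_in + n_post

  # ML-based initialization center (shared across chains, jittered per chain)
  init_k <- rep(0.02, S)
  init_t <- rep(5, S)
  if (mc$init == "ml" && has_trials) {
    for (i in seq_len(S)) {
      if (terms[[i]]$n >= config$fit$min_trials) {
        f <- tryCatch(fit_subject(datasets[[i]], config),
                      error = function(e) NULL)
        if (!is.null(f)) {
          init_k[i] <- f$k_hat
          init_t[i] <- f$temp_hat
        }
      }
    }
  }

  k_mean_lo <- pr$k_mean$lower
  k_mean_hi <- pr$k_mean$upper
  k_sd_lo <- pr$k_sd$lower
  k_sd_hi <- pr$k_sd$upper
  t_mean_mu <- pr$temp_mean$mean
  t_mean_sd <- sqrt(pr$temp_mean$var)
  t_sd_lo <- pr$temp_sd$lower
  t_sd_hi <- pr$temp_sd$upper
  lk_mean_lo <- pr$logk_mean$lower
  lk_mean_hi <- pr$logk_mean$upper
  lk_sd_lo <- pr$logk_sd$lower
  lk_sd_hi <- pr$logk_sd$upper

  subj_labels <- vapply(datasets, function(d) {
    paste0(d$subject_id, ".", d$session)
  }, character(1))
  hyper_names <- c(
    paste0(if (log_scale) "mu_logk." else "mu_k.", cells),
    paste0(if (log_scale) "sigma_logk." else "sigma_k.", cells),
    paste0("mu_temp.", cells), paste0("sigma_temp.", cells)
  )
  param_names <- c(hyper_names, paste0("k.", subj_labels),
                   paste0("temp.", subj_labels))
  P <- length(param_names)

  run_chain <- function(chain) {
    set.seed(seed + 1000L * chain)
    jitter <- function(x, s) x * exp(rnorm(length(x), 0, s))
    # dispersed starts: larger jitter for later chains
    disp <- 0.3 + 0.4 * (chain - 1)
    k <- pmin(pmax(jitter(init_k, disp), 1e-6), 5)
    tmp <- pmin(pmax(jitter(init_t, disp), 0.01), 200)
    mu_k <- numeric(G)
    sd_k <- numeric(G)
    mu_t <- numeric(G)
    sd_t <- numeric(G)
    for (g in seq_len(G)) {
      kg <- k[cell_idx == g]
      tg <- tmp[cell_idx == g]
      if (log_scale) {
        mu_k[g] <- min(max(mean(log(kg)), lk_mean_lo), lk_mean_hi)
        sd_k[g] <- min(max(if (length(kg) > 1) sd(log(kg)) else 0.5,
                           lk_sd_lo), lk_sd_hi)
      } else {
        mu_k[g] <- min(max(mean(kg), k_mean_lo), k_mean_hi)
        sd_k[g] <- min(max(if (length(kg) > 1) sd(kg) else 0.01,
                           k_sd_lo), k_sd_hi)
      }
      mu_t[g] <- min(max(mean(tg), 0.1), 200)
      sd_t[g] <- min(max(if (length(tg) > 1) sd(tg) else 1,
                         t_sd_lo), t_sd_hi)
    }
    ll <- loglik_all(k, tmp)

    # proposal scales (log-scale random walks except the means)
    sc_k <- rep(0.5, S)
    sc_t <- rep(0.5, S)
    sc_mu_k <- rep(if (log_scale) 0.3 else 0.05, G)
    sc_sd_k <- rep(0.5, G)
    sc_mu_t <- rep(2, G)
    sc_sd_t <- rep(0.5, G)
    acc_k <- numeric(S); acc_t <- numeric(S)
    acc_mu_k <- numeric(G); acc_sd_k <- numeric(G)
    acc_mu_t <- numeric(G); acc_sd_t <- numeric(G)
    post_acc <- setNames(numeric(6), c("k", "temp", "mu_k", "sigma_k",
                                       "mu_temp", "sigma_temp"))
    post_n <- 0L

    # log density of the subject-level prior for the k block
    subj_k_logprior <- function(kv) {
      if (log_scale) {
        dnorm(log(kv), mu_k[cell_idx], sd_k[cell_idx], log = TRUE) - log(kv)
      } else {
        dnorm(kv, mu_k[cell_idx], sd_k[cell_idx], log = TRUE)
        # truncation normalizer constant within a subject update
      }
    }

    draws <- matrix(NA_real_, retained_per_chain, P)
    kept <- 0L
    for (iter in seq_len(total_iter)) {
      adapting <- iter <= mc$burn_in

      # --- subject k sweep (joint vectorized proposal) ---
      k_new <- k * exp(rnorm(S, 0, sc_k))
      ll_new <- loglik_all(k_new, tmp)
      la <- (ll_new - ll) + subj_k_logprior(k_new) - subj_k_logprior(k) +
        log(k_new) - log(k)
      acc <- log(runif(S)) < la
      k[acc] <- k_new[acc]
      ll[acc] <- ll_new[acc]
      acc_k <- acc_k + acc

      # --- subject temp sweep ---
      t_new <- tmp * exp(rnorm(S, 0, sc_t))
      ll_new <- loglik_all(k, t_new)
      la <- (ll_new - ll) +
        dnorm(t_new, mu_t[cell_idx], sd_t[cell_idx], log = TRUE) -
        dnorm(tmp, mu_t[cell_idx], sd_t[cell_idx], log = TRUE) +
        log(t_new) - log(tmp)
      acc <- log(runif(S)) < la
      tmp[acc] <- t_new[acc]
      ll[acc] <- ll_new[acc]
      acc_t <- acc_t + acc

      # --- hyper-parameter updates per cell ---
      for (g in seq_len(G)) {
        kg <- if (log_scale) log(k[cell_idx == g]) else k[cell_idx == g]
        tg <- tmp[cell_idx == g]
        ng <- group_n[g]
        mlo <- if (log_scale) lk_mean_lo else k_mean_lo
        mhi <- if (log_scale) lk_mean_hi else k_mean_hi
        slo <- if (log_scale) lk_sd_lo else k_sd_lo
        shi <- if (log_scale) lk_sd_hi else k_sd_hi

        # k-mean: flat prior on its support
        prop <- mu_k[g] + rnorm(1, 0, sc_mu_k[g])
        if (prop >= mlo && prop <= mhi) {
          la <- sum(dnorm(kg, prop, sd_k[g], log = TRUE)) -
            sum(dnorm(kg, mu_k[g], sd_k[g], log = TRUE))
          if (!log_scale) {
            la <- la - ng * (log_tnorm0_normalizer(prop, sd_k[g]) -
                               log_tnorm0_normalizer(mu_k[g], sd_k[g]))
          }
          if (log(runif(1)) < la) {
            mu_k[g] <- prop
            acc_mu_k[g] <- acc_mu_k[g] + 1
          }
        }

        # k-SD: flat prior, log-scale proposal
        prop <- sd_k[g] * exp(rnorm(1, 0, sc_sd_k[g]))
        if (prop >= slo && prop <= shi) {
          la <- sum(dnorm(kg, mu_k[g], prop, log = TRUE)) -
            sum(dnorm(kg, mu_k[g], sd_k[g], log = TRUE)) +
            log(prop) - log(sd_k[g])
          if (!log_scale) {
            la <- la - ng * (log_tnorm0_normalizer(mu_k[g], prop) -
                               log_tnorm0_normalizer(mu_k[g], sd_k[g]))
          }
          if (log(runif(1)) < la) {
            sd_k[g] <- prop
            acc_sd_k[g] <- acc_sd_k[g] + 1
          }
        }

        # temp-mean: truncated-normal prior
        prop <- mu_t[g] + rnorm(1, 0, sc_mu_t[g])
        if (prop > 0) {
          la <- sum(dnorm(tg, prop, sd_t[g], log = TRUE)) -
            sum(dnorm(tg, mu_t[g], sd_t[g], log = TRUE)) -
            ng * (log_tnorm0_normalizer(prop, sd_t[g]) -
                    log_tnorm0_normalizer(mu_t[g], sd_t[g])) +
            dnorm(prop, t_mean_mu, t_mean_sd, log = TRUE) -
            dnorm(mu_t[g], t_mean_mu, t_mean_sd, log = TRUE)
          if (log(runif(1)) < la) {
            mu_t[g] <- prop
            acc_mu_t[g] <- acc_mu_t[g] + 1
          }
        }

        # temp-SD: flat prior, log-scale proposal
        prop <- sd_t[g] * exp(rnorm(1, 0, sc_sd_t[g]))
        if (prop >= t_sd_lo && prop <= t_sd_hi) {
          la <- sum(dnorm(tg, mu_t[g], prop, log = TRUE)) -
            sum(dnorm(tg, mu_t[g], sd_t[g], log = TRUE)) -
            ng * (log_tnorm0_normalizer(mu_t[g], prop) -
                    log_tnorm0_normalizer(mu_t[g], sd_t[g])) +
            log(prop) - log(sd_t[g])
          if (log(runif(1)) < la) {
            sd_t[g] <- prop
            acc_sd_t[g] <- acc_sd_t[g] + 1
          }
        }
      }

      if (adapting && iter %% mc$adapt_interval == 0) {
        tune <- function(scale, acc_count) {
          rate <- acc_count / mc$adapt_interval
          scale * ifelse(rate > 0.5, 1.25, ifelse(rate < 0.2, 0.8, 1))
        }
        sc_k <- tune(sc_k, acc_k); acc_k[] <- 0
        sc_t <- tune(sc_t, acc_t); acc_t[] <- 0
        sc_mu_k <- tune(sc_mu_k, acc_mu_k); acc_mu_k[] <- 0
        sc_sd_k <- tune(sc_sd_k, acc_sd_k); acc_sd_k[] <- 0
        sc_mu_t <- tune(sc_mu_t, acc_mu_t); acc_mu_t[] <- 0
        sc_sd_t <- tune(sc_sd_t, acc_sd_t); acc_sd_t[] <- 0
      }
      if (iter == mc$burn_in) {
        acc_k[] <- 0; acc_t[] <- 0
        acc_mu_k[] <- 0; acc_sd_k[] <- 0
        acc_mu_t[] <- 0; acc_sd_t[] <- 0
      }

      if (!adapting && (iter - mc$burn_in) %% mc$thinning == 0) {
        kept <- kept + 1L
        draws[kept, ] <- c(mu_k, sd_k, mu_t, sd_t, k, tmp)
      }
    }
    n_post_iter <- total_iter - mc$burn_in
    list(
      draws = draws,
      acceptance = c(
        k = mean(acc_k) / n_post_iter,
        temp = mean(acc_t) / n_post_iter,
        mu_k = mean(acc_mu_k) / n_post_iter,
        sigma_k = mean(acc_sd_k) / n_post_iter,
        mu_temp = mean(acc_mu_t) / n_post_iter,
        sigma_temp = mean(acc_sd_t) / n_post_iter
      )
    )
  }

  chains <- lapply(seq_len(mc$n_chains), function(ch) {
    if (verbose) message("chain ", ch, "/", mc$n_chains)
    run_chain(ch)
  })
  draws <- setNames(vector("list", P), param_names)
  for (p in seq_len(P)) {
    draws[[p]] <- vapply(chains, function(ch) ch$draws[, p],
                         numeric(retained_per_chain))
    if (retained_per_chain == 1) {
      draws[[p]] <- matrix(draws[[p]], nrow = 1)
    }
  }
  if (log_scale) {
    # record the implied mean of the (lognormal) k distribution under the
    # usual names so summaries and comparisons work on either scale
    for (cell in cells) {
      m <- draws[[paste0("mu_logk.", cell)]]
      s <- draws[[paste0("sigma_logk.", cell)]]
      draws[[paste0("mu_k.", cell)]] <- exp(m + s^2 / 2)
    }
  }
  acceptance <- Reduce(`+`, lapply(chains, `[[`, "acceptance")) /
    length(chains)
  structure(
    list(
      draws = draws,
      cells = cells,
      subjects = data.frame(
        subject_id = vapply(datasets, `[[`, "", "subject_id"),
        session = vapply(datasets, `[[`, "", "session"),
        condition = vapply(datasets, `[[`, "", "condition"),
        cell = subj_cells,
        stringsAsFactors = FALSE
      ),
      acceptance = acceptance,
      mcmc = mc,
      scale = mc$scale,
      seed = seed
    ),
    class = "dd_posterior"
  )
}

#' @export
print.dd_posterior <- function(x, ...) {
  d <- dim(x$draws[[1]])
  cat(sprintf("<dd_posterior> %d parameters, %d retained draws x %d chains\n",
              length(x$draws), d[1], d[2]))
  cat("  cells:", paste(x$cells, collapse = ", "), "\n")
  cat("  mean acceptance:",
      paste(sprintf("%s=%.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

split_rhat <- function(mat) {
  # mat: retained-iteration x chain; split each chain in half
  n <- nrow(mat)
  if (n < 4 || ncol(mat) < 1) return(NA_real_)
  half <- n %/% 2
  seqs <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[half + seq_len(half), j])
  }))
  m <- ncol(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for a posterior sample
#'
#' Per parameter: split R-hat (each chain halved, Gelman-Rubin statistic
#' over the resulting sequences), effective sample size (sum over chains
#' of [coda::effectiveSize()]), and a flag for R-hat >= the threshold.
#' Acceptance rates of the sampler's proposal blocks are attached as an
#' attribute. With a single chain R-hat is still defined through the two
#' half-sequences, but a note is attached that between-chain mixing was
#' not assessed.
#'
#' @param samples a [sample_posterior()] result.
#' @param threshold R-hat flag threshold.
#' @return Data frame `parameter`, `rhat`, `ess`, `flagged`; attributes
#'   `acceptance` and (for single-chain input) `note`.
#' @export
convergence_report <- function(samples, threshold = 1.05) {
  out <- data.frame(
    parameter = names(samples$draws),
    rhat = vapply(samples$draws, split_rhat, numeric(1)),
    ess = vapply(samples$draws, function(mat) {
      ess <- sum(vapply(seq_len(ncol(mat)), function(j) {
        unname(coda::effectiveSize(coda::mcmc(mat[, j])))
      }, numeric(1)))
      min(ess, length(mat))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$flagged <- !is.na(out$rhat) & out$rhat >= threshold
  attr(out, "acceptance") <- samples$acceptance
  if (ncol(samples$draws[[1]]) < 2) {
    attr(out, "note") <-
      "single chain: R-hat from split halves only, between-chain mixing not assessed"
  }
  out
}

pooled_draws <- function(samples, name) {
  mat <- samples$draws[[name]]
  if (is.null(mat)) {
    stop("unknown parameter '", name, "'; available cells: ",
         paste(samples$cells, collapse = ", "), call. = FALSE)
  }
  as.vector(mat)
}

#' Posterior summary of one cell's group-level parameters
#'
#' Posterior mean, median and 95% central interval of the cell's k-mean,
#' of log(k-mean) (the display scale conventional for discount rates),
#' and of the temp-mean.
#'
#' @param samples a [sample_posterior()] result.
#' @param group one of the sampled cells (see `samples$cells`).
#' @return Data frame with rows `k_mean`, `log_k_mean`, `temp_mean` and
#'   columns `mean`, `median`, `q2.5`, `q97.5`.
#' @export
group_posterior_summary <- function(samples, group) {
  if (!group %in% samples$cells) {
    stop("unknown group '", group, "'; sampled cells: ",
         paste(samples$cells, collapse = ", "), call. = FALSE)
  }
  k <- pooled_draws(samples, paste0("mu_k.", group))
  tm <- pooled_draws(samples, paste0("mu_temp.", group))
  summarize <- function(v) {
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    c(mean = mean(v), median = q[2], q2.5 = q[1], q97.5 = q[3])
  }
  out <- rbind(k_mean = summarize(k), log_k_mean = summarize(log(k)),
               temp_mean = summarize(tm))
  as.data.frame(out)
}

overlap_coefficient <- function(a, b, n_bins = 512) {
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(1)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE),
                 nbins = n_bins) / length(a)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE),
                 nbins = n_bins) / length(b)
  sum(pmin(pa, pb))
}

#' Posterior comparison of two cells
#'
#' For the k-mean and the temp-mean: the posterior of the difference
#' A - B, its 95% central interval, the posterior probability
#' `P(A > B)`, and the overlap coefficient of the two marginal posteriors
#' (mass of the pointwise minimum of the two histograms on a common
#' grid; 1 = indistinguishable, 0 = disjoint).
#'
#' @param samples a [sample_posterior()] result.
#' @param group_a,group_b sampled cell labels.
#' @return Data frame with rows `k_mean`, `temp_mean` and columns
#'   `diff_mean`, `diff_q2.5`, `diff_q97.5`, `p_a_greater`, `overlap`.
#' @export
compare_conditions <- function(samples, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!g %in% samples$cells) {
      stop("unknown group '", g, "'; sampled cells: ",
           paste(samples$cells, collapse = ", "), call. = FALSE)
    }
  }
  if (group_a == group_b) {
    warning("comparing a group with itself; returning symmetric nulls")
    out <- data.frame(diff_mean = c(0, 0), diff_q2.5 = c(0, 0),
                      diff_q97.5 = c(0, 0), p_a_greater = c(0.5, 0.5),
                      overlap = c(1, 1))
    rownames(out) <- c("k_mean", "temp_mean")
    return(out)
  }
  one <- function(par) {
    a <- pooled_draws(samples, paste0(par, ".", group_a))
    b <- pooled_draws(samples, paste0(par, ".", group_b))
    d <- a - b
    q <- quantile(d, c(0.025, 0.975), names = FALSE)
    c(diff_mean = mean(d), diff_q2.5 = q[1], diff_q97.5 = q[2],
      p_a_greater = mean(d > 0) + 0.5 * mean(d == 0),
      overlap = overlap_coefficient(a, b))
  }
  out <- rbind(k_mean = one("mu_k"), temp_mean = one("mu_temp"))
  as.data.frame(out)
}
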