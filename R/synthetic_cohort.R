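#' Specification of a synthetic study cohort
#'
#' Collects the generative ground truth for a two-group, two-session
#' study: 9 patients tested with stimulation on and off (counterbalanced
#' order) and 18 controls tested twice, by default. Each subject's two
#' session-level log discount rates are drawn from a bivariate normal with
#' correlation `rho`; `session_effect` shifts the second condition
#' (DBS-off for patients, session 2 for controls) additively on the log-k
#' scale. Softmax noise is drawn once per subject and shared across
#' sessions. Defaults (`log k` mean `ln 0.01`, SD 0.8; temp mean 2 EUR,
#' SD 1; `rho = 0.7`) describe a moderately discounting, highly
#' retest-stable population.
#'
#' @param n_patients,n_controls group sizes.
#' @param logk_mean_patient,logk_mean_control group means of log k.
#' @param logk_sd between-subject SD of log k (both groups).
#' @param temp_mean,temp_sd mean and SD of the softmax noise (EUR);
#'   draws are truncated below at 0.05 to keep agents stochastic.
#' @param rho cross-session correlation of true log k, in `[-1, 1]`.
#' @param session_effect additive shift of log k in the DBS-off condition
#'   (patients) / session 2 (controls).
#' @param counterbalance alternate patients between on-first and
#'   off-first orders.
#' @param missing_rate per-trial probability of a missing (timed-out)
#'   response.
#' @param seed integer seed.
#' @return An object of class `dd_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 9L, n_controls = 18L,
                        logk_mean_patient = log(0.01),
                        logk_mean_control = log(0.01),
                        logk_sd = 0.8, temp_mean = 2, temp_sd = 1,
                        rho = 0.7, session_effect = 0,
                        counterbalance = TRUE, missing_rate = 0,
                        seed = 1L) {
  if (abs(rho) > 1) {
    stop("cross-session correlation rho must be in [-1, 1]", call. = FALSE)
  }
  if (logk_sd < 0 || temp_sd < 0) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         logk_mean_patient = logk_mean_patient,
         logk_mean_control = logk_mean_control,
         logk_sd = logk_sd, temp_mean = temp_mean, temp_sd = temp_sd,
         rho = rho, session_effect = session_effect,
         counterbalance = isTRUE(counterbalance),
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "dd_cohort_spec"
  )
}

#' Simulate one agent's choices on a trial list
#'
#' Generates binary choices from the same model the pipeline fits: on each
#' trial the delayed option is chosen with probability
#' [choice_probability()] of its hyperbolic subjective value against the
#' immediate amount. Draws are independent across trials and fully
#' determined by the seed.
#'
#' @param params list with `k` and `temp` (both `> 0`).
#' @param trials trial data frame as from [build_trial_set()].
#' @param subject_id,group,session,condition dataset labels (see
#'   [choice_dataset()]).
#' @param missing_rate per-trial probability that the response is
#'   recorded as `"missing"`.
#' @param seed integer seed.
#' @return A `dd_dataset`.
#' @export
simulate_agent <- function(params, trials, subject_id = "sim",
                           group = "control", session = "s1",
                           condition = "none", missing_rate = 0,
                           seed = 1L) {
  if (params$k <= 0 || params$temp <= 0) {
    stop("params k and temp must be positive", call. = FALSE)
  }
  sv_delayed <- subjective_value(trials$delayed_amount, trials$delay_days,
                                 params$k)
  p_delayed <- choice_probability(sv_delayed, trials$immediate_amount,
                                  params$temp)
  set.seed(seed)
  choice <- ifelse(rbinom(nrow(trials), 1, p_delayed) == 1,
                   "delayed", "immediate")
  if (missing_rate > 0) {
    drop <- runif(nrow(trials)) < missing_rate
    choice[drop] <- "missing"
  }
  tr <- trials
  tr$choice <- choice
  choice_dataset(subject_id, group, session, condition, tr)
}

#' Simulate a full two-group, two-session cohort
#'
#' Draws per-subject true parameters according to a [cohort_spec()] and
#' generates one [choice_dataset()] per subject-session with
#' [simulate_agent()]. Each subject keeps the same trial list in both
#' sessions. When `counterbalance` is set, odd-numbered patients are
#' tested on-first, even-numbered patients off-first; controls always run
#' sessions 1 and 2.
#'
#' @param spec a [cohort_spec()].
#' @param config a [study_config()] providing the trial grid.
#' @return A list of `dd_dataset` (2 per subject), with attribute `truth`:
#'   a data frame of `subject_id`, `group`, `session`, `condition`,
#'   `order`, `true_k`, `true_logk`, `true_temp`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = study_config()) {
  validate_config(config)
  trials <- build_trial_set(config)
  set.seed(spec$seed)
  subjects <- data.frame(
    subject_id = c(sprintf("pat%02d", seq_len(spec$n_patients)),
                   sprintf("con%02d", seq_len(spec$n_controls))),
    group = c(rep("patient", spec$n_patients),
              rep("control", spec$n_controls)),
    stringsAsFactors = FALSE
  )
  n <- nrow(subjects)
  # bivariate normal on log k across the two conditions, correlation rho
  z1 <- rnorm(n)
  z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * rnorm(n)
  mu <- ifelse(subjects$group == "patient",
               spec$logk_mean_patient, spec$logk_mean_control)
  logk_c1 <- mu + spec$logk_sd * z1
  logk_c2 <- mu + spec$session_effect + spec$logk_sd * z2
  temp <- pmax(rnorm(n, spec$temp_mean, spec$temp_sd), 0.05)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  datasets <- vector("list", 2L * n)
  truth <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    is_patient <- subjects$group[i] == "patient"
    on_first <- !spec$counterbalance || i %% 2L == 1L
    for (s in 1:2) {
      if (is_patient) {
        # condition 1 = DBS on, condition 2 = DBS off; order counterbalanced
        cond_idx <- if ((s == 1L) == on_first) 1L else 2L
        condition <- c("dbs_on", "dbs_off")[cond_idx]
      } else {
        cond_idx <- s
        condition <- "none"
      }
      logk <- if (cond_idx == 1L) logk_c1[i] else logk_c2[i]
      idx <- 2L * (i - 1L) + s
      datasets[[idx]] <- simulate_agent(
        list(k = exp(logk), temp = temp[i]), trials,
        subject_id = subjects$subject_id[i], group = subjects$group[i],
        session = c("s1", "s2")[s], condition = condition,
        missing_rate = spec$missing_rate, seed = agent_seeds[idx])
      truth[[idx]] <- data.frame(
        subject_id = subjects$subject_id[i], group = subjects$group[i],
        session = c("s1", "s2")[s], condition = condition,
        order = if (is_patient) {
          if (on_first) "on_first" else "off_first"
        } else "na",
        true_k = exp(logk), true_logk = logk, true_temp = temp[i],
        stringsAsFactors = FALSE)
    }
  }
  structure(datasets, truth = do.call(rbind, truth))
}

#' Simulation-based validation of the whole pipeline
#'
#' Repeatedly simulates a cohort, runs the requested analysis stages and
#' summarizes how well the pipeline recovers the generative truth:
#' bias/RMSE and true-vs-fitted correlation of log k from the ML fits,
#' the rejection rate of the model-free AUC group comparison
#' ([session_average_compare()]), and optionally coverage of the
#' hierarchical model's 95% interval for each cell's k-mean.
#'
#' @param spec a [cohort_spec()]; its seed spawns one sub-seed per
#'   replicate.
#' @param config a [study_config()].
#' @param n_replicates number of simulated studies.
#' @param methods subset of `c("ml", "auc", "hb")`.
#' @param alpha significance level for the AUC group test.
#' @return A list of class `dd_recovery`: per-replicate results
#'   (`replicates`) and aggregate `summary` (logk_bias, logk_rmse,
#'   logk_cor, auc_reject_rate, hb_coverage when requested).
#' @export
recovery_experiment <- function(spec = cohort_spec(),
                                config = study_config(),
                                n_replicates = 10L,
                                methods = c("ml", "auc"),
                                alpha = 0.05) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  methods <- match.arg(methods, c("ml", "auc", "hb"), several.ok = TRUE)
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sp <- spec
    sp$seed <- rep_seeds[r]
    datasets <- simulate_cohort(sp, config)
    truth <- attr(datasets, "truth")
    out <- list(seed = rep_seeds[r])
    if ("ml" %in% methods) {
      fits <- fit_cohort(datasets, config)
      key <- paste(fits$subject_id, fits$session)
      tkey <- paste(truth$subject_id, truth$session)
      tl <- truth$true_logk[match(key, tkey)]
      out$logk_bias <- mean(fits$log_k - tl)
      out$logk_rmse <- sqrt(mean((fits$log_k - tl)^2))
      out$logk_cor <- if (sd(tl) > 0 && sd(fits$log_k) > 0) {
        cor(tl, fits$log_k)
      } else NA_real_
      out$fits <- fits
    }
    if ("auc" %in% methods) {
      auc_tab <- auc_cohort(datasets, config)
      test <- tryCatch(session_average_compare(auc_tab),
                       error = function(e) NULL)
      out$auc_p <- if (is.null(test)) NA_real_ else test$p_value
      out$auc_reject <- !is.null(test) && test$p_value < alpha
    }
    if ("hb" %in% methods) {
      post <- sample_posterior(datasets, config = config,
                               seed = rep_seeds[r])
      cells <- post$cells
      cover <- vapply(cells, function(cell) {
        ci <- quantile(as.vector(post$draws[[paste0("mu_k.", cell)]]),
                       c(0.025, 0.975))
        true_mean <- mean(truth$true_k[paste0(
          ifelse(truth$group == "patient",
                 ifelse(truth$condition == "dbs_on", "patient_on",
                        "patient_off"),
                 ifelse(truth$session == "s1", "control_s1",
                        "control_s2"))) == cell])
        ci[1] <= true_mean && true_mean <= ci[2]
      }, logical(1))
      out$hb_coverage <- mean(cover)
    }
    reps[[r]] <- out
  }
  summarize <- function(field) {
    v <- vapply(reps, function(x) {
      if (is.null(x[[field]])) NA_real_ else as.numeric(x[[field]])
    }, numeric(1))
    if (all(is.na(v))) NULL else mean(v, na.rm = TRUE)
  }
  structure(
    list(
      replicates = reps,
      summary = Filter(Negate(is.null), list(
        logk_bias = summarize("logk_bias"),
        logk_rmse = summarize("logk_rmse"),
        logk_cor = summarize("logk_cor"),
        auc_reject_rate = summarize("auc_reject"),
        hb_coverage = summarize("hb_coverage")
      )),
      n_replicates = n_replicates
    ),
    class = "dd_recovery"
  )
}

#' @export
print.dd_recovery <- function(x, ...) {
  cat(sprintf("<dd_recovery> %d replicates\n", x$n_replicates))
  for (nm in names(x$summary)) {
    cat(sprintf("  %s: %.4f\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}
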