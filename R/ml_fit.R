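#' Maximum-likelihood fit of (k, temp) for one subject-session
#'
#' Minimizes the negative log-likelihood of [dataset_loglik()] over
#' `(log k, log temp)` with the Nelder-Mead simplex, restarted from a grid
#' of starting values (`fit$k_starts` x `fit$temp_starts`, nine restarts by
#' default) and keeping the best restart. Optimizing on the log scale
#' enforces positivity without a constrained solver; the objective clamps
#' parameters to the admissible box (`fit$k_bounds`, `fit$temp_bounds`), so
#' degenerate datasets (e.g. a subject who always chose the delayed
#' option) come back as flagged boundary fits rather than errors.
#'
#' @param dataset a [choice_dataset()] with at least `fit$min_trials`
#'   non-missing records.
#' @param config a [study_config()].
#' @return A list of class `dd_fit`: `subject_id`, `session`, `condition`,
#'   `group`, `k_hat`, `temp_hat`, `log_k`, `neg_loglik`, `n_trials_used`,
#'   `converged`, `at_bound`.
#' @export
fit_subject <- function(dataset, config = study_config()) {
  validate_dataset(dataset)
  ft <- config$fit
  terms <- dataset_lik_terms(dataset)
  if (terms$n < ft$min_trials) {
    stop("subject ", dataset$subject_id, " session ", dataset$session,
         ": only ", terms$n, " usable trials (need >= ", ft$min_trials, ")",
         call. = FALSE)
  }
  lb <- log(c(ft$k_bounds[1], ft$temp_bounds[1]))
  ub <- log(c(ft$k_bounds[2], ft$temp_bounds[2]))
  clamp <- function(theta) pmin(pmax(theta, lb), ub)
  nll <- function(theta) {
    theta <- clamp(theta)
    -loglik_terms(terms, exp(theta[1]), exp(theta[2]))
  }
  starts <- expand.grid(k = ft$k_starts, temp = ft$temp_starts)
  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- optim(log(c(starts$k[i], starts$temp[i])), nll,
                 method = "Nelder-Mead",
                 control = list(reltol = ft$reltol, maxit = ft$maxit))
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) any_converged <- TRUE
  }
  theta <- clamp(best$par)
  at_bound <- any(theta <= lb + 1e-6) || any(theta >= ub - 1e-6)
  structure(
    list(
      subject_id = dataset$subject_id,
      group = dataset$group,
      session = dataset$session,
      condition = dataset$condition,
      k_hat = exp(theta[1]),
      temp_hat = exp(theta[2]),
      log_k = theta[1],
      neg_loglik = best$value,
      n_trials_used = terms$n,
      converged = any_converged,
      at_bound = at_bound
    ),
    class = "dd_fit"
  )
}

#' @export
print.dd_fit <- function(x, ...) {
  cat(sprintf(
    "<dd_fit> %s %s/%s: k = %.5g (log k = %.3f), temp = %.3g, -LL = %.2f%s\n",
    x$subject_id, x$session, x$condition, x$k_hat, x$log_k, x$temp_hat,
    x$neg_loglik, if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}

#' Fit every subject-session in a cohort
#'
#' Runs [fit_subject()] independently on each dataset. Per-dataset
#' failures (too few trials, invalid records) are collected and reported
#' as an attribute instead of aborting the batch.
#'
#' @param datasets list of `dd_dataset`.
#' @param config a [study_config()].
#' @return Data frame with one row per successful fit (columns
#'   `subject_id`, `group`, `session`, `condition`, `k_hat`, `temp_hat`,
#'   `log_k`, `neg_loglik`, `n_trials_used`, `converged`, `at_bound`) and
#'   attribute `failures`: a data frame of `subject_id`, `session`,
#'   `message` for datasets that could not be fit.
#' @export
fit_cohort <- function(datasets, config = study_config()) {
  fits <- list()
  failures <- list()
  for (ds in datasets) {
    res <- tryCatch(fit_subject(ds, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        subject_id = ds$subject_id, session = ds$session,
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      fits[[length(fits) + 1L]] <- as.data.frame(unclass(res),
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- if (length(fits) == 0) {
    data.frame(subject_id = character(0), group = character(0),
               session = character(0), condition = character(0),
               k_hat = numeric(0), temp_hat = numeric(0),
               log_k = numeric(0), neg_loglik = numeric(0),
               n_trials_used = integer(0), converged = logical(0),
               at_bound = logical(0))
  } else {
    do.call(rbind, fits)
  }
  out <- out[order(out$subject_id, out$session), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures) == 0) {
    data.frame(subject_id = character(0), session = character(0),
               message = character(0))
  } else {
    do.call(rbind, failures)
  }
  out
}
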