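#' Per-delay indifference amounts from binary choices
#'
#' For each delay, fits a logistic acceptance curve (probability of
#' choosing the delayed option as a function of the delayed amount) by
#' maximum likelihood and reads off the amount at acceptance probability
#' 0.5 as the indifference amount. When the logistic is degenerate
#' (perfect separation, flat or decreasing acceptance) the estimator falls
#' back to the midpoint between the largest rejected and smallest accepted
#' amount. Subjects who accept (reject) every offer at a delay are flagged
#' `censored_low` (`censored_high`) and assigned the smallest (largest)
#' offered amount.
#'
#' @param dataset a [choice_dataset()]; every delay needs at least two
#'   distinct delayed amounts with non-missing responses.
#' @param config a [study_config()] supplying the amount range used for
#'   clamping out-of-range estimates.
#' @return Data frame with one row per delay: `delay_days`,
#'   `indifference_amount`, `censoring` (`"ok"`, `"censored_low"`,
#'   `"censored_high"`).
#' @export
indifference_points <- function(dataset, config = study_config()) {
  validate_dataset(dataset)
  tr <- dataset$trials[dataset$trials$choice != "missing", , drop = FALSE]
  delays <- sort(unique(tr$delay_days))
  rows <- lapply(delays, function(d) {
    part <- tr[tr$delay_days == d, , drop = FALSE]
    amounts <- part$delayed_amount
    if (length(unique(amounts)) < 2) {
      stop("delay ", d, ": need >= 2 distinct delayed amounts to locate an ",
           "indifference point", call. = FALSE)
    }
    accepted <- part$choice == "delayed"
    lo <- min(amounts)
    hi <- max(amounts)
    if (all(accepted)) {
      return(data.frame(delay_days = d, indifference_amount = lo,
                        censoring = "censored_low"))
    }
    if (!any(accepted)) {
      return(data.frame(delay_days = d, indifference_amount = hi,
                        censoring = "censored_high"))
    }
    est <- NA_real_
    fit <- suppressWarnings(tryCatch(
      glm(accepted ~ amounts, family = binomial()),
      error = function(e) NULL))
    if (!is.null(fit) && fit$converged) {
      b <- coef(fit)
      # require a rising acceptance curve; otherwise the crossing point is
      # meaningless and the midpoint rule applies
      if (is.finite(b[2]) && b[2] > 0) est <- -b[1] / b[2]
    }
    if (!is.finite(est)) {
      max_rejected <- max(amounts[!accepted])
      min_accepted <- min(amounts[accepted])
      est <- (max_rejected + min_accepted) / 2
    }
    censoring <- "ok"
    if (est < config$task$amount_min) {
      est <- config$task$amount_min
      censoring <- "censored_low"
    } else if (est > config$task$amount_max) {
      est <- config$task$amount_max
      censoring <- "censored_high"
    }
    data.frame(delay_days = d, indifference_amount = est,
               censoring = censoring)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a normalized discounting profile
#'
#' Converts per-delay indifference amounts into the normalized curve
#' underlying the AUC statistic: each delay is expressed as a proportion of
#' the maximum delay (`x = D / max_delay`) and each indifference amount as
#' the normalized subjective value `y = immediate_amount /
#' indifference_amount` (the proportion of the delayed amount's face value
#' at which the subject is indifferent). The anchor point `(0, 1)` — a
#' reward now is worth its face value — is prepended by default.
#'
#' @param indiff data frame from [indifference_points()] (columns
#'   `delay_days`, `indifference_amount`, optionally `censoring`).
#' @param immediate_amount the fixed immediate amount (EUR).
#' @param max_delay normalization constant in days (defaults to the
#'   largest delay present).
#' @param anchor include the `(0, 1)` anchor point.
#' @return An object of class `dd_profile`: data frame `points` with
#'   columns `x`, `y`, `censoring`, plus `max_delay` and `anchor` fields.
#' @export
build_profile <- function(indiff, immediate_amount = 20,
                          max_delay = max(indiff$delay_days),
                          anchor = TRUE) {
  if (any(duplicated(indiff$delay_days))) {
    stop("one indifference amount per delay required", call. = FALSE)
  }
  ind <- indiff[order(indiff$delay_days), , drop = FALSE]
  y <- immediate_amount / ind$indifference_amount
  if (any(y > 1)) {
    warning("indifference amount below the immediate amount; ",
            "normalized value clipped to 1")
    y <- pmin(y, 1)
  }
  pts <- data.frame(
    x = ind$delay_days / max_delay,
    y = y,
    censoring = if ("censoring" %in% names(ind)) ind$censoring else "ok",
    stringsAsFactors = FALSE
  )
  if (anchor) {
    pts <- rbind(data.frame(x = 0, y = 1, censoring = "anchor"), pts)
  }
  structure(list(points = pts, max_delay = max_delay, anchor = anchor),
            class = "dd_profile")
}

#' Area under the discounting curve
#'
#' Trapezoid-rule area of a normalized discounting profile: the sum over
#' consecutive points of `(x2 - x1) * (y1 + y2) / 2`. An AUC of 1 means no
#' discounting (the subjective value stays at face value out to the
#' maximum delay); smaller values mean steeper discounting.
#'
#' @param profile a [build_profile()] result.
#' @return AUC in `(0, 1]`.
#' @export
#' @examples
#' flat <- build_profile(data.frame(delay_days = c(30, 180),
#'                                  indifference_amount = c(20, 20)),
#'                       immediate_amount = 20)
#' auc(flat)  # 1
auc <- function(profile) {
  pts <- profile$points
  if (is.unsorted(pts$x, strictly = TRUE)) {
    stop("profile x values must be strictly increasing", call. = FALSE)
  }
  n <- nrow(pts)
  sum(diff(pts$x) * (pts$y[-n] + pts$y[-1]) / 2)
}

#' AUC for every subject-session in a cohort
#'
#' Runs [indifference_points()], [build_profile()] and [auc()] on each
#' dataset. Per-dataset failures are collected into an attribute instead
#' of aborting the batch.
#'
#' @param datasets list of `dd_dataset`.
#' @param config a [study_config()].
#' @param anchor include the `(0, 1)` anchor (see [build_profile()]).
#' @return Data frame with columns `subject_id`, `group`, `session`,
#'   `condition`, `auc`, `n_censored`; attribute `failures` as in
#'   [fit_cohort()].
#' @export
auc_cohort <- function(datasets, config = study_config(), anchor = TRUE) {
  rows <- list()
  failures <- list()
  for (ds in datasets) {
    res <- tryCatch({
      ind <- indifference_points(ds, config)
      prof <- build_profile(ind, config$task$immediate_amount,
                            anchor = anchor)
      data.frame(subject_id = ds$subject_id, group = ds$group,
                 session = ds$session, condition = ds$condition,
                 auc = auc(prof),
                 n_censored = sum(ind$censoring != "ok"),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        subject_id = ds$subject_id, session = ds$session,
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(subject_id = character(0), group = character(0),
               session = character(0), condition = character(0),
               auc = numeric(0), n_censored = integer(0))
  } else {
    do.call(rbind, rows)
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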