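#' Build the fixed trial grid for one session
#'
#' Constructs the session's offer list: for every delay in
#' `config$task$delays`, `n_amounts_per_delay` delayed amounts uniformly
#' spaced from `amount_min` to `amount_max` inclusive, each paired with the
#' fixed immediate amount. With the defaults this yields the 140-trial
#' session (7 delays x 20 amounts, 20 EUR now vs 20.5--80 EUR delayed).
#' The grid is generated in deterministic delay-major order; when
#' `config$task$shuffle` is `TRUE` the rows are permuted with the seed so
#' the presentation order is reproducible.
#'
#' @param config a [study_config()].
#' @param seed optional integer overriding `config$seeds$task` for the
#'   shuffle.
#' @return Data frame of trials with columns `trial_index`,
#'   `immediate_amount`, `delayed_amount`, `delay_days`.
#' @export
#' @examples
#' nrow(build_trial_set(study_config()))  # 140
build_trial_set <- function(config = study_config(), seed = NULL) {
  validate_config(config)
  tk <- config$task
  amounts <- seq(tk$amount_min, tk$amount_max,
                 length.out = tk$n_amounts_per_delay)
  grid <- expand.grid(delayed_amount = amounts, delay_days = tk$delays,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$delay_days, grid$delayed_amount), , drop = FALSE]
  if (isTRUE(tk$shuffle)) {
    if (is.null(seed)) seed <- config$seeds$task
    ord <- local({
      set.seed(seed)
      sample.int(nrow(grid))
    })
    grid <- grid[ord, , drop = FALSE]
  }
  data.frame(
    trial_index = seq_len(nrow(grid)),
    immediate_amount = tk$immediate_amount,
    delayed_amount = grid$delayed_amount,
    delay_days = grid$delay_days
  )
}

#' Normalized hyperbolic subjective value
#'
#' The unit-amount hyperbolic discount curve `1 / (1 + k * D)`: the value
#' of a delayed reward as a proportion of its nominal amount. This is the
#' form used by the adaptive pretest; the amount-scaled variant used in
#' likelihoods is [subjective_value()].
#'
#' @param delay_days delay in days (vectorized, `>= 0`).
#' @param k discount rate in 1/days (`>= 0`).
#' @return Numeric vector of values in `(0, 1]`.
#' @export
#' @examples
#' normalized_sv(30, 0.01)  # 1 / 1.3
normalized_sv <- function(delay_days, k) {
  if (any(delay_days < 0)) stop("delay_days must be non-negative",
                                call. = FALSE)
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  1 / (1 + k * delay_days)
}

#' Adaptive pretest for a provisional discount rate
#'
#' Runs a per-delay bisection staircase on the delayed amount: each probe
#' offers the immediate amount against the midpoint of the current
#' bracket; accepting the delayed offer lowers the upper bracket edge,
#' rejecting raises the lower edge. After `config$pretest$n_steps` steps
#' the bracket midpoint estimates the indifference amount for that delay.
#' A provisional rate `k0` is then obtained by least-squares fitting the
#' normalized hyperbolic curve ([normalized_sv()]) to the normalized
#' indifference values `immediate_amount / indifference_amount`. Delays
#' whose staircase saturated at the amount range's edge (the subject
#' accepted or rejected every probe at that delay) carry no gradient
#' information and are excluded from the fit.
#'
#' @param responder function taking a one-row trial data frame (columns as
#'   in [build_trial_set()]) and returning `"immediate"` or `"delayed"`.
#' @param config a [study_config()].
#' @return A list of class `dd_pretest`: `k0` (clamped to
#'   `[k_floor, k_ceiling]`), `converged` (FALSE when k0 sits at a bound or
#'   too few delays were informative), `indifference` (per-delay estimates),
#'   `saturated` (per-delay flags) and `staircase_trace` (every probe:
#'   delay, offered amount, response).
#' @export
adaptive_pretest <- function(responder, config = study_config()) {
  validate_config(config)
  tk <- config$task
  pt <- config$pretest
  delays <- tk$delays
  trace <- vector("list", length(delays))
  indiff <- numeric(length(delays))
  saturated <- logical(length(delays))
  for (j in seq_along(delays)) {
    lo <- tk$amount_min
    hi <- tk$amount_max
    n_acc <- 0L
    n_rej <- 0L
    probes <- data.frame(delay_days = numeric(0), delayed_amount = numeric(0),
                         response = character(0))
    for (step in seq_len(pt$n_steps)) {
      amount <- (lo + hi) / 2
      trial <- data.frame(trial_index = NA_integer_,
                          immediate_amount = tk$immediate_amount,
                          delayed_amount = amount, delay_days = delays[j])
      resp <- tryCatch(responder(trial), error = function(e) {
        stop("pretest responder failed at delay ", delays[j], ", amount ",
             round(amount, 2), ": ", conditionMessage(e), call. = FALSE)
      })
      if (!resp %in% c("immediate", "delayed")) {
        stop("pretest responder returned '", resp,
             "'; expected 'immediate' or 'delayed'", call. = FALSE)
      }
      probes <- rbind(probes, data.frame(delay_days = delays[j],
                                         delayed_amount = amount,
                                         response = resp))
      if (resp == "delayed") {
        hi <- amount
        n_acc <- n_acc + 1L
      } else {
        lo <- amount
        n_rej <- n_rej + 1L
      }
    }
    indiff[j] <- (lo + hi) / 2
    # all-accept or all-reject: true indifference lies outside the bracket
    saturated[j] <- n_acc == 0L || n_rej == 0L
    trace[[j]] <- probes
  }
  usable <- !saturated
  k0 <- NA_real_
  converged <- FALSE
  if (sum(usable) >= 2) {
    y <- tk$immediate_amount / indiff[usable]
    d <- delays[usable]
    sse <- function(logk) sum((y - normalized_sv(d, exp(logk)))^2)
    opt <- tryCatch(
      optimize(sse, interval = log(c(pt$k_floor, pt$k_ceiling))),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$objective)) {
      k0 <- exp(opt$minimum)
      at_edge <- opt$minimum <= log(pt$k_floor) + 1e-4 ||
        opt$minimum >= log(pt$k_ceiling) - 1e-4
      converged <- !at_edge
    }
  }
  if (!is.finite(k0)) {
    # saturation direction decides which bound is the honest summary
    k0 <- if (sum(saturated) > 0 &&
              mean(indiff[saturated] > mean(c(tk$amount_min, tk$amount_max)))
              >= 0.5) {
      pt$k_ceiling
    } else {
      pt$k_floor
    }
    converged <- FALSE
  }
  k0 <- min(max(k0, pt$k_floor), pt$k_ceiling)
  structure(
    list(k0 = k0, converged = converged,
         indifference = data.frame(delay_days = delays,
                                   indifference_amount = indiff,
                                   saturated = saturated),
         staircase_trace = do.call(rbind, trace)),
    class = "dd_pretest"
  )
}

#' @export
print.dd_pretest <- function(x, ...) {
  cat(sprintf("<dd_pretest> k0 = %.5g (%s)\n", x$k0,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Subject-specific trial grid centered on predicted indifference
#'
#' Alternative to the fixed grid of [build_trial_set()]: for each delay the
#' delayed amounts are placed symmetrically around the indifference amount
#' predicted from a pretest rate, `immediate_amount * (1 + k0 * D)`, then
#' clipped to `[amount_min, amount_max]`. The spread of the grid equals half
#' the configured amount range, so a subject discounting near the middle of
#' the range receives offers that straddle their indifference point at
#' every delay.
#'
#' @param k0 provisional discount rate from [adaptive_pretest()].
#' @param config a [study_config()].
#' @return Data frame of trials, same shape and count as
#'   [build_trial_set()].
#' @export
subject_specific_trials <- function(k0, config = study_config()) {
  validate_config(config)
  tk <- config$task
  pt <- config$pretest
  if (k0 < 0 || k0 > pt$k_ceiling) {
    stop("k0 outside admissible range [0, ", pt$k_ceiling, "]",
         call. = FALSE)
  }
  half_width <- (tk$amount_max - tk$amount_min) / 2
  offsets <- seq(-half_width, half_width,
                 length.out = tk$n_amounts_per_delay)
  rows <- lapply(tk$delays, function(d) {
    center <- tk$immediate_amount * (1 + k0 * d)
    amounts <- pmin(pmax(center + offsets, tk$amount_min), tk$amount_max)
    data.frame(delayed_amount = amounts, delay_days = d)
  })
  grid <- do.call(rbind, rows)
  data.frame(
    trial_index = seq_len(nrow(grid)),
    immediate_amount = tk$immediate_amount,
    delayed_amount = grid$delayed_amount,
    delay_days = grid$delay_days
  )
}
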