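#' Hyperbolic subjective value of a delayed reward
#'
#' The amount-scaled hyperbolic discount model `SV = A / (1 + k * D)`,
#' where `A` is the nominal delayed amount in euros, `D` the delay in days
#' and `k` the subject's discount rate (1/days). The immediate option's
#' subjective value is simply its nominal amount (`D = 0`). SV is in euros
#' throughout the package, so the softmax noise parameter `temp` carries
#' euro units as well.
#'
#' @param amount nominal amount in EUR (vectorized, `> 0`).
#' @param delay_days delay in days (`>= 0`).
#' @param k discount rate (`>= 0`).
#' @return Subjective value in EUR.
#' @export
#' @examples
#' subjective_value(40, 100, 0.01)  # 20
subjective_value <- function(amount, delay_days, k) {
  if (any(amount <= 0)) stop("amount must be positive", call. = FALSE)
  if (any(delay_days < 0)) stop("delay_days must be non-negative",
                                call. = FALSE)
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  amount / (1 + k * delay_days)
}

# probability clamp: keeps log-likelihoods finite for near-deterministic
# choices at tiny temp
.p_floor <- 1e-12

#' Softmax probability of the chosen option
#'
#' Two-option softmax over subjective values,
#' `P(chosen) = exp(SV_chosen / temp) / (exp(SV_chosen / temp) +
#' exp(SV_other / temp))`, evaluated through the numerically stable
#' logistic of `(SV_chosen - SV_other) / temp`. Larger `temp` means
#' noisier choice; as `temp -> Inf` the probability tends to 0.5.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` so that downstream
#' log-likelihoods stay finite for effectively deterministic choosers.
#'
#' @param sv_chosen subjective value of the chosen option (EUR).
#' @param sv_other subjective value of the unchosen option (EUR).
#' @param temp softmax noise parameter (EUR, `> 0`).
#' @return Choice probability in `(0, 1)`.
#' @export
#' @examples
#' choice_probability(40, 20, 20)  # plogis(1)
choice_probability <- function(sv_chosen, sv_other, temp) {
  if (any(temp <= 0)) stop("temp must be positive", call. = FALSE)
  p <- plogis((sv_chosen - sv_other) / temp)
  pmin(pmax(p, .p_floor), 1 - .p_floor)
}

# Internal: compact likelihood view of a dataset. Precomputes the delayed
# amounts, delays and the choice sign so the sampler and optimizer evaluate
# the log-likelihood with a handful of vectorized operations.
dataset_lik_terms <- function(ds) {
  tr <- ds$trials[ds$trials$choice != "missing", , drop = FALSE]
  list(
    A = tr$delayed_amount,
    D = tr$delay_days,
    imm = tr$immediate_amount,
    sign = ifelse(tr$choice == "delayed", 1, -1),
    n = nrow(tr)
  )
}

.log_p_floor <- log(.p_floor)

loglik_terms <- function(terms, k, temp) {
  if (terms$n == 0) return(0)
  x <- terms$sign * (terms$A / (1 + k * terms$D) - terms$imm) / temp
  sum(pmax(plogis(x, log.p = TRUE), .log_p_floor))
}

#' Log-likelihood of a choice dataset under the hyperbolic softmax model
#'
#' Sums, over all non-missing records, the log softmax probability of the
#' recorded choice, with the delayed option valued by
#' [subjective_value()] and the immediate option at its nominal amount.
#'
#' @param dataset a [choice_dataset()] with at least one non-missing
#'   record.
#' @param params list or named vector with elements `k` (`> 0`) and `temp`
#'   (`> 0`).
#' @return Log-likelihood in nats (a single finite number).
#' @export
#' @examples
#' tr <- data.frame(trial_index = 1, immediate_amount = 20,
#'                  delayed_amount = 26, delay_days = 30,
#'                  choice = "delayed")
#' ds <- choice_dataset("s", "control", "s1", "none", tr)
#' dataset_loglik(ds, list(k = 0.01, temp = 2))  # log(0.5): SV_delayed = 20
dataset_loglik <- function(dataset, params) {
  validate_dataset(dataset)
  k <- params[["k"]]
  temp <- params[["temp"]]
  if (is.null(k) || is.null(temp)) {
    stop("params must contain 'k' and 'temp'", call. = FALSE)
  }
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (temp <= 0) stop("temp must be positive", call. = FALSE)
  terms <- dataset_lik_terms(dataset)
  if (terms$n == 0) {
    stop("dataset has no non-missing records; likelihood undefined",
         call. = FALSE)
  }
  loglik_terms(terms, k, temp)
}
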