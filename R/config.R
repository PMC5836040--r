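#' Study configuration
#'
#' A `dd_config` object bundles every tunable of the pipeline: the task grid
#' (delays, amount range, trials per delay), admissible parameter ranges,
#' prior and MCMC settings for the hierarchical model, maximum-likelihood
#' fitting controls, and simulation defaults. All values default to the
#' study design this package models: 140 trials per session, delays
#' 1--180 days, a fixed 20 EUR immediate option and delayed amounts
#' uniformly spaced between 20.5 and 80 EUR.
#'
#' @param task list overriding task fields: `delays` (strictly increasing
#'   integer days), `amount_min`, `amount_max`, `immediate_amount` (EUR),
#'   `n_amounts_per_delay`, `shuffle` (logical), `subject_specific`
#'   (logical; use pretest-centered amount grids instead of the fixed grid).
#' @param priors list overriding hierarchical prior fields, see Details.
#' @param mcmc list overriding MCMC fields: `n_chains`, `burn_in`,
#'   `thinning`, `n_retained` (total retained draws across chains unless
#'   `retained_per_chain` is `TRUE`), `adapt_interval`, `scale`
#'   (`"natural"` or `"log"`: scale on which the k hyper-distribution
#'   lives), `init` (`"ml"` or `"prior"`).
#' @param fit list overriding ML-fit fields: `min_trials`, `k_bounds`,
#'   `temp_bounds`, `k_starts`, `temp_starts`, `reltol`, `maxit`.
#' @param pretest list overriding pretest fields: `n_steps` (bisection
#'   steps per delay), `k_floor`, `k_ceiling`.
#' @param simulate list overriding cohort-simulation defaults, see
#'   [cohort_spec()].
#' @param seeds named list of integer seeds (`simulate`, `fit`, `mcmc`,
#'   `task`).
#'
#' @details
#' Hierarchical priors (all on the natural parameter scale): the group mean
#' of the discount rate k has a uniform prior on `[0.00001, 2]`; the group
#' mean of the softmax noise temp has a normal prior with mean 20 and
#' variance 1000 truncated at 0; group standard deviations have uniform
#' priors (`[0.001, 2]` for k, `[0.01, 100]` for temp). The MCMC schedule
#' defaults to 2 chains, burn-in 2000, thinning 2 and 20000 retained
#' samples in total.
#'
#' @return An object of class `dd_config` (a named list).
#' @export
#' @examples
#' cfg <- study_config()
#' length(cfg$task$delays) * cfg$task$n_amounts_per_delay  # 140
study_config <- function(task = list(), priors = list(), mcmc = list(),
                         fit = list(), pretest = list(), simulate = list(),
                         seeds = list()) {
  defaults <- list(
    task = list(
      delays = c(1L, 2L, 7L, 14L, 30L, 90L, 180L),
      amount_min = 20.5,
      amount_max = 80,
      immediate_amount = 20,
      n_amounts_per_delay = 20L,
      shuffle = FALSE,
      subject_specific = FALSE
    ),
    priors = list(
      k_mean = list(lower = 0.00001, upper = 2),
      temp_mean = list(mean = 20, var = 1000),
      k_sd = list(lower = 0.001, upper = 2),
      temp_sd = list(lower = 0.01, upper = 100),
      # log-scale alternative for the k hyper-distribution
      logk_mean = list(lower = log(0.00001), upper = log(2)),
      logk_sd = list(lower = 0.01, upper = 5)
    ),
    mcmc = list(
      n_chains = 2L,
      burn_in = 2000L,
      thinning = 2L,
      n_retained = 20000L,
      retained_per_chain = FALSE,
      adapt_interval = 50L,
      scale = "natural",
      init = "ml"
    ),
    fit = list(
      min_trials = 10L,
      k_bounds = c(1e-5, 2),
      temp_bounds = c(1e-3, 1e3),
      k_starts = c(0.001, 0.01, 0.1),
      temp_starts = c(0.5, 2, 10),
      reltol = 1e-8,
      maxit = 2000L
    ),
    pretest = list(
      n_steps = 6L,
      k_floor = 1e-5,
      k_ceiling = 2
    ),
    simulate = list(
      n_patients = 9L,
      n_controls = 18L,
      logk_mean_patient = log(0.01),
      logk_mean_control = log(0.01),
      logk_sd = 0.8,
      temp_mean = 2,
      temp_sd = 1,
      rho = 0.7,
      session_effect = 0,
      counterbalance = TRUE,
      missing_rate = 0
    ),
    seeds = list(simulate = 1L, fit = 1L, mcmc = 1L, task = 1L)
  )
  cfg <- defaults
  for (section in c("task", "priors", "mcmc", "fit", "pretest",
                    "simulate", "seeds")) {
    override <- get(section)
    if (!is.list(override)) {
      stop("config section '", section, "' must be a list", call. = FALSE)
    }
    unknown <- setdiff(names(override), names(defaults[[section]]))
    if (length(unknown) > 0) {
      stop("unknown config key", if (length(unknown) > 1) "s", " in '",
           section, "': ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[[section]] <- modifyList(defaults[[section]], override)
  }
  out <- structure(cfg, class = "dd_config")
  validate_config(out)
  out
}

#' Validate a study configuration
#'
#' Checks every invariant the pipeline relies on (increasing delays,
#' delayed amounts above the immediate amount, positive trial counts,
#' positive-length prior supports, a positive MCMC schedule) and stops with
#' a message naming the offending key.
#'
#' @param config a `dd_config` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "dd_config")) {
    stop("not a dd_config object", call. = FALSE)
  }
  tk <- config$task
  if (length(tk$delays) < 1 || any(diff(tk$delays) <= 0)) {
    stop("config error in 'task$delays': must be strictly increasing",
         call. = FALSE)
  }
  if (any(tk$delays < 1)) {
    stop("config error in 'task$delays': delayed offers need delay >= 1 day",
         call. = FALSE)
  }
  if (tk$amount_min <= tk$immediate_amount) {
    stop("config error in 'task$amount_min': must exceed immediate_amount (",
         tk$immediate_amount, ")", call. = FALSE)
  }
  if (tk$amount_max <= tk$amount_min) {
    stop("config error in 'task$amount_max': must exceed amount_min",
         call. = FALSE)
  }
  if (tk$n_amounts_per_delay < 2) {
    stop("config error in 'task$n_amounts_per_delay': need at least 2",
         call. = FALSE)
  }
  pr <- config$priors
  for (nm in c("k_mean", "k_sd", "temp_sd", "logk_mean", "logk_sd")) {
    if (pr[[nm]]$upper <= pr[[nm]]$lower) {
      stop("config error in 'priors$", nm, "': zero-length support",
           call. = FALSE)
    }
  }
  if (pr$temp_mean$var <= 0) {
    stop("config error in 'priors$temp_mean': variance must be positive",
         call. = FALSE)
  }
  mc <- config$mcmc
  for (nm in c("n_chains", "burn_in", "thinning", "n_retained",
               "adapt_interval")) {
    if (mc[[nm]] < if (nm == "burn_in") 0 else 1) {
      stop("config error in 'mcmc$", nm, "'", call. = FALSE)
    }
  }
  if (!mc$scale %in% c("natural", "log")) {
    stop("config error in 'mcmc$scale': must be 'natural' or 'log'",
         call. = FALSE)
  }
  sm <- config$simulate
  if (abs(sm$rho) > 1) {
    stop("config error in 'simulate$rho': correlation must be in [-1, 1]",
         call. = FALSE)
  }
  if (sm$logk_sd < 0 || sm$temp_sd < 0) {
    stop("config error in 'simulate': SDs must be non-negative",
         call. = FALSE)
  }
  if (sm$missing_rate < 0 || sm$missing_rate >= 1) {
    stop("config error in 'simulate$missing_rate': must be in [0, 1)",
         call. = FALSE)
  }
  invisible(config)
}

#' Load a study configuration from a YAML file
#'
#' Reads a YAML file with any subset of the sections `task`, `priors`,
#' `mcmc`, `fit`, `pretest`, `simulate`, `seeds`; keys not present fall
#' back to the package defaults (see [study_config()]). An empty file (or
#' `NULL` path) yields the full default configuration.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated `dd_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    return(study_config())
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("malformed config file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("malformed config file '", path, "': top level must be a mapping",
         call. = FALSE)
  }
  known <- c("task", "priors", "mcmc", "fit", "pretest", "simulate", "seeds")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("config error: unknown section", if (length(unknown) > 1) "s",
         " ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- lapply(setNames(known, known), function(s) {
    if (is.null(raw[[s]])) list() else raw[[s]]
  })
  # nested prior specs arrive as lists already; coerce delay vector to integer
  if (!is.null(args$task$delays)) {
    args$task$delays <- as.integer(args$task$delays)
  }
  do.call(study_config, args)
}

#' @export
print.dd_config <- function(x, ...) {
  tk <- x$task
  cat("Delay discounting study configuration\n")
  cat(sprintf("  task : %d delays (%s days), %d amounts/delay -> %d trials\n",
              length(tk$delays), paste(range(tk$delays), collapse = "-"),
              tk$n_amounts_per_delay,
              length(tk$delays) * tk$n_amounts_per_delay))
  cat(sprintf("  offer: %.1f EUR now vs %.1f-%.1f EUR delayed\n",
              tk$immediate_amount, tk$amount_min, tk$amount_max))
  cat(sprintf("  mcmc : %d chains, burn-in %d, thin %d, %d retained (%s)\n",
              x$mcmc$n_chains, x$mcmc$burn_in, x$mcmc$thinning,
              x$mcmc$n_retained,
              if (x$mcmc$retained_per_chain) "per chain" else "total"))
  invisible(x)
}
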