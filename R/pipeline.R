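# End-to-end orchestration: simulate -> fit -> analyze, with file outputs
# and a run manifest per output directory. These functions are also the
# backend of the command-line wrapper in inst/scripts/dd_pipeline.R.

write_manifest <- function(out_dir, command, config, seed, inputs = list(),
                           outputs = list()) {
  manifest <- list(
    command = command,
    package_version = as.character(packageVersion("discountr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = unname(md5sum(write_config_snapshot(out_dir, config))),
    inputs = inputs,
    outputs = outputs
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

write_config_snapshot <- function(out_dir, config) {
  path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(unclass(config), path)
  path
}

#' Simulate a study and write its files
#'
#' Generates a synthetic cohort ([simulate_cohort()]) and writes
#' `choices.csv` (trial-level choices), `truth.csv` (the generative
#' ground truth) and a run manifest to `out_dir`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding `config$seeds$simulate`.
#' @return Invisibly, a list with the written paths and the datasets.
#' @export
run_simulate <- function(config = study_config(), out_dir, seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$seeds$simulate
  sm <- config$simulate
  spec <- cohort_spec(
    n_patients = sm$n_patients, n_controls = sm$n_controls,
    logk_mean_patient = sm$logk_mean_patient,
    logk_mean_control = sm$logk_mean_control,
    logk_sd = sm$logk_sd, temp_mean = sm$temp_mean, temp_sd = sm$temp_sd,
    rho = sm$rho, session_effect = sm$session_effect,
    counterbalance = sm$counterbalance, missing_rate = sm$missing_rate,
    seed = seed
  )
  datasets <- simulate_cohort(spec, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  choices_path <- file.path(out_dir, "choices.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_choice_table(datasets, choices_path)
  write.csv(attr(datasets, "truth"), truth_path, row.names = FALSE)
  write_manifest(out_dir, "simulate", config, seed,
                 outputs = list(choices = "choices.csv",
                                truth = "truth.csv"))
  invisible(list(choices = choices_path, truth = truth_path,
                 datasets = datasets))
}

#' Fit a choice table and write the results
#'
#' Runs the maximum-likelihood fits (`fits.csv`), the hierarchical
#' Bayesian model (`posterior.json`: cell summaries, condition contrasts
#' and convergence diagnostics), or both, on a trial-level choice table.
#'
#' @param choices_path path to a `choices.csv` (see
#'   [read_choice_table()]).
#' @param method `"ml"`, `"hb"` or `"both"`.
#' @param out_dir output directory.
#' @param config a [study_config()].
#' @param seed integer seed for the MCMC (defaults to
#'   `config$seeds$mcmc`).
#' @return Invisibly, a list with `fits` (data frame) and/or `posterior`
#'   (`dd_posterior`).
#' @export
run_fit <- function(choices_path, method = c("ml", "hb", "both"), out_dir,
                    config = study_config(), seed = NULL) {
  method <- match.arg(method)
  validate_config(config)
  datasets <- read_choice_table(choices_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  outputs <- list()
  if (method %in% c("ml", "both")) {
    fits <- fit_cohort(datasets, config)
    failures <- attr(fits, "failures")
    if (nrow(failures) > 0) {
      warning("fit failures for ", nrow(failures), " dataset(s): ",
              paste(failures$subject_id, collapse = ", "))
    }
    write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    out$fits <- fits
    outputs$fits <- "fits.csv"
  }
  if (method %in% c("hb", "both")) {
    post <- sample_posterior(datasets, config, seed = seed)
    summaries <- lapply(setNames(post$cells, post$cells), function(cell) {
      s <- group_posterior_summary(post, cell)
      cbind(parameter = rownames(s), s)
    })
    diag <- convergence_report(post)
    contrasts <- list()
    if (all(c("patient_on", "patient_off") %in% post$cells)) {
      contrasts$on_vs_off <-
        compare_conditions(post, "patient_on", "patient_off")
    }
    if (all(c("patient_on", "control_s1") %in% post$cells)) {
      contrasts$patients_on_vs_controls_s1 <-
        compare_conditions(post, "patient_on", "control_s1")
    }
    if (all(c("patient_off", "control_s2") %in% post$cells)) {
      contrasts$patients_off_vs_controls_s2 <-
        compare_conditions(post, "patient_off", "control_s2")
    }
    jsonlite::write_json(
      list(
        cells = post$cells,
        summaries = summaries,
        contrasts = lapply(contrasts, function(x) {
          cbind(parameter = rownames(x), x)
        }),
        diagnostics = diag,
        acceptance = as.list(post$acceptance),
        max_rhat = max(diag$rhat, na.rm = TRUE),
        seed = post$seed
      ),
      file.path(out_dir, "posterior.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    out$posterior <- post
    outputs$posterior <- "posterior.json"
  }
  write_manifest(out_dir, paste0("fit:", method), config,
                 if (is.null(seed)) config$seeds$mcmc else seed,
                 inputs = list(choices = choices_path), outputs = outputs)
  invisible(out)
}

#' Run the full group-analysis battery and write report.json
#'
#' Computes the model-free AUC table and every group comparison of the
#' analysis battery: paired t (stimulation on vs off), independent t
#' (patients vs controls per session pairing), the session-averaged
#' comparison, test-retest correlations of log k and temp per group, the
#' absolute log-k session-difference comparison, and (when a posterior is
#' supplied) the posterior condition contrasts.
#'
#' @param choices_path path to `choices.csv`.
#' @param out_dir output directory for `auc.csv` and `report.json`.
#' @param fits optional precomputed fit table (else fitted here).
#' @param posterior optional `dd_posterior` for the contrasts.
#' @param config a [study_config()].
#' @param anchor include the `(0, 1)` anchor in AUC profiles.
#' @return Invisibly, the report list.
#' @export
run_analyze <- function(choices_path, out_dir, fits = NULL,
                        posterior = NULL, config = study_config(),
                        anchor = TRUE) {
  validate_config(config)
  datasets <- read_choice_table(choices_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fits)) fits <- fit_cohort(datasets, config)
  auc_tab <- auc_cohort(datasets, config, anchor = anchor)
  write.csv(auc_tab, file.path(out_dir, "auc.csv"), row.names = FALSE)

  as_row <- function(tr) {
    list(statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
         test_name = tr$test_name, n_per_group = tr$n_per_group,
         estimate = tr$estimate)
  }
  safe <- function(expr) {
    tryCatch(as_row(expr), error = function(e) {
      list(error = conditionMessage(e))
    })
  }
  pat <- auc_tab[auc_tab$group == "patient", , drop = FALSE]
  con <- auc_tab[auc_tab$group == "control", , drop = FALSE]
  on_auc <- pat$auc[pat$condition == "dbs_on"][
    order(pat$subject_id[pat$condition == "dbs_on"])]
  off_auc <- pat$auc[pat$condition == "dbs_off"][
    order(pat$subject_id[pat$condition == "dbs_off"])]
  s1_auc <- con$auc[con$session == "s1"][
    order(con$subject_id[con$session == "s1"])]
  s2_auc <- con$auc[con$session == "s2"][
    order(con$subject_id[con$session == "s2"])]

  report <- list(
    auc_on_vs_off = safe(paired_t(on_auc, off_auc)),
    auc_on_vs_s1 = safe(independent_t(on_auc, s1_auc)),
    auc_off_vs_s2 = safe(independent_t(off_auc, s2_auc)),
    auc_averaged = safe(session_average_compare(auc_tab))
  )

  # retest correlations and |delta log k| need matched session fits
  split_fits <- function(group) {
    f <- fits[fits$group == group, , drop = FALSE]
    s1 <- f[f$session == "s1", , drop = FALSE]
    s2 <- f[f$session == "s2", , drop = FALSE]
    common <- intersect(s1$subject_id, s2$subject_id)
    list(s1 = s1[match(common, s1$subject_id), , drop = FALSE],
         s2 = s2[match(common, s2$subject_id), , drop = FALSE])
  }
  pf <- split_fits("patient")
  cf <- split_fits("control")
  report$retest_logk_patients <-
    safe(retest_correlation(pf$s1, pf$s2, "log_k"))
  report$retest_logk_controls <-
    safe(retest_correlation(cf$s1, cf$s2, "log_k"))
  report$retest_temp_patients <-
    safe(retest_correlation(pf$s1, pf$s2, "temp"))
  report$retest_temp_controls <-
    safe(retest_correlation(cf$s1, cf$s2, "temp"))

  all_s1 <- rbind(pf$s1, cf$s1)
  all_s2 <- rbind(pf$s2, cf$s2)
  abs_diff <- tryCatch(abs_logk_difference(all_s1, all_s2),
                       error = function(e) NULL)
  report$abs_logk_diff <- if (is.null(abs_diff)) {
    list(error = "absolute log-k comparison unavailable")
  } else {
    list(t_test = as_row(abs_diff$t_test),
         mann_whitney = as_row(abs_diff$mann_whitney))
  }

  if (!is.null(posterior)) {
    add_contrast <- function(a, b) {
      if (all(c(a, b) %in% posterior$cells)) {
        x <- compare_conditions(posterior, a, b)
        cbind(parameter = rownames(x), x)
      } else NULL
    }
    report$posterior_contrasts <- Filter(Negate(is.null), list(
      on_vs_off = add_contrast("patient_on", "patient_off"),
      on_vs_controls_s1 = add_contrast("patient_on", "control_s1"),
      off_vs_controls_s2 = add_contrast("patient_off", "control_s2")
    ))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "analyze", config, config$seeds$fit,
                 inputs = list(choices = choices_path),
                 outputs = list(auc = "auc.csv", report = "report.json"))
  invisible(report)
}
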