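#' Construct a choice dataset
#'
#' A `dd_dataset` holds one subject-session of a binary intertemporal-choice
#' task: the offered trials (fixed immediate amount vs a larger delayed
#' amount) together with the recorded choices. It is the unit on which
#' likelihoods, maximum-likelihood fits and indifference-point estimates
#' operate.
#'
#' @param subject_id subject label (coerced to character).
#' @param group `"patient"` or `"control"`.
#' @param session `"s1"` or `"s2"`.
#' @param condition `"dbs_on"` or `"dbs_off"` for patients, `"none"` for
#'   controls.
#' @param trials data frame with columns `trial_index`, `immediate_amount`,
#'   `delayed_amount`, `delay_days`, `choice` (one of `"immediate"`,
#'   `"delayed"`, `"missing"`) and optionally `rt_ms` (recorded metadata,
#'   ignored by all analyses).
#' @return An object of class `dd_dataset`.
#' @export
#' @examples
#' tr <- data.frame(trial_index = 1:2, immediate_amount = 20,
#'                  delayed_amount = c(30, 60), delay_days = c(7, 30),
#'                  choice = c("immediate", "delayed"))
#' choice_dataset("s01", "control", "s1", "none", tr)
choice_dataset <- function(subject_id, group, session, condition, trials) {
  ds <- structure(
    list(
      subject_id = as.character(subject_id),
      group = as.character(group),
      session = as.character(session),
      condition = as.character(condition),
      trials = as.data.frame(trials)
    ),
    class = "dd_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a choice dataset
#'
#' Enforces the structural invariants of a subject-session: recognized
#' group/session/condition labels (patients carry `dbs_on`/`dbs_off`,
#' controls `none`), `delayed_amount > immediate_amount`, `delay_days >= 1`,
#' unique trial indices, and choices restricted to
#' `"immediate"`/`"delayed"`/`"missing"`.
#'
#' @param ds a `dd_dataset`.
#' @param context optional string prefixed to error messages (e.g. a file
#'   and row reference).
#' @return `ds` invisibly, if valid.
#' @export
validate_dataset <- function(ds, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(context, ": ")
  fail <- function(...) stop(ctx, ..., call. = FALSE)
  if (!inherits(ds, "dd_dataset")) fail("not a dd_dataset")
  if (!ds$group %in% c("patient", "control")) {
    fail("unknown group label '", ds$group, "'")
  }
  if (!ds$session %in% c("s1", "s2")) {
    fail("unknown session label '", ds$session, "'")
  }
  ok_cond <- if (ds$group == "patient") c("dbs_on", "dbs_off") else "none"
  if (!ds$condition %in% ok_cond) {
    fail("subject ", ds$subject_id, " (", ds$group, ") has condition '",
         ds$condition, "'; expected one of ",
         paste(ok_cond, collapse = "/"))
  }
  tr <- ds$trials
  needed <- c("trial_index", "immediate_amount", "delayed_amount",
              "delay_days", "choice")
  miss <- setdiff(needed, names(tr))
  if (length(miss) > 0) {
    fail("missing trial column", if (length(miss) > 1) "s", ": ",
         paste(miss, collapse = ", "))
  }
  if (nrow(tr) == 0) fail("subject ", ds$subject_id, ": no trials")
  for (col in c("immediate_amount", "delayed_amount", "delay_days")) {
    if (!is.numeric(tr[[col]]) || anyNA(tr[[col]])) {
      fail("column '", col, "' must be numeric and complete")
    }
  }
  bad <- which(tr$delayed_amount <= tr$immediate_amount)
  if (length(bad) > 0) {
    fail("subject ", ds$subject_id, " session ", ds$session,
         ", trial_index ", tr$trial_index[bad[1]],
         ": delayed_amount (", tr$delayed_amount[bad[1]],
         ") must exceed immediate_amount (", tr$immediate_amount[bad[1]], ")")
  }
  bad <- which(tr$delay_days < 1)
  if (length(bad) > 0) {
    fail("subject ", ds$subject_id, ", trial_index ", tr$trial_index[bad[1]],
         ": delayed offers require delay_days >= 1")
  }
  if (anyDuplicated(tr$trial_index)) {
    fail("subject ", ds$subject_id, " session ", ds$session,
         ": duplicated trial_index")
  }
  bad <- which(!tr$choice %in% c("immediate", "delayed", "missing"))
  if (length(bad) > 0) {
    fail("subject ", ds$subject_id, ", trial_index ", tr$trial_index[bad[1]],
         ": unknown choice label '", tr$choice[bad[1]], "'")
  }
  invisible(ds)
}

#' Number of analyzable (non-missing) trials
#'
#' @param ds a `dd_dataset`.
#' @return Integer count of records whose choice is not `"missing"`.
#' @export
n_usable_trials <- function(ds) {
  sum(ds$trials$choice != "missing")
}

#' @export
print.dd_dataset <- function(x, ...) {
  cat(sprintf("<dd_dataset> subject %s | %s | %s | %s\n", x$subject_id,
              x$group, x$session, x$condition))
  cat(sprintf("  %d trials (%d usable), delays %s days\n", nrow(x$trials),
              n_usable_trials(x),
              paste(sort(unique(x$trials$delay_days)), collapse = ", ")))
  invisible(x)
}

choice_table_columns <- c(
  "subject_id", "group", "session", "condition", "trial_index",
  "immediate_amount", "delayed_amount", "delay_days", "choice"
)

#' Read a trial-level choice table
#'
#' Reads a comma-separated choice table (UTF-8, header required, decimal
#' point) with columns `subject_id`, `group`, `session`, `condition`,
#' `trial_index`, `immediate_amount`, `delayed_amount`, `delay_days`,
#' `choice` and optionally `rt_ms` (carried along, never analyzed). Rows
#' are grouped into one [choice_dataset()] per `(subject_id, session)` and
#' every dataset is validated.
#'
#' @param path path to a CSV file.
#' @return A list of `dd_dataset`, ordered by subject then session.
#' @export
read_choice_table <- function(path) {
  if (!file.exists(path)) {
    stop("choice table not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(choice_table_columns, names(df))
  if (length(miss) > 0) {
    stop("schema error in '", path, "': missing column",
         if (length(miss) > 1) "s", " ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("trial_index", "immediate_amount", "delayed_amount",
                "delay_days")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (anyNA(v)) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
      stop("parse error in '", path, "', line ", row + 1L,
           ": non-numeric value '", df[[col]][row], "' in column '", col,
           "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  key <- interaction(df$subject_id, df$session, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(part) {
    part <- part[order(part$trial_index), , drop = FALSE]
    meta <- unique(part[, c("subject_id", "group", "session", "condition")])
    if (nrow(meta) > 1) {
      stop("validation error in '", path, "': subject ", part$subject_id[1],
           " session ", part$session[1],
           " has inconsistent group/condition labels", call. = FALSE)
    }
    cols <- c("trial_index", "immediate_amount", "delayed_amount",
              "delay_days", "choice", intersect("rt_ms", names(part)))
    choice_dataset(meta$subject_id, meta$group, meta$session,
                   meta$condition, part[, cols, drop = FALSE])
  })
  names(out) <- NULL
  out
}

#' Write choice datasets to a trial-level CSV table
#'
#' Inverse of [read_choice_table()]: writes all datasets into a single
#' UTF-8 CSV with a deterministic row order (subject, session, trial
#' index), so that two writes of the same input are byte-identical and a
#' read-after-write round trip reproduces the datasets.
#'
#' @param datasets list of `dd_dataset` (may be empty: header-only file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(datasets, path) {
  rows <- lapply(datasets, function(ds) {
    validate_dataset(ds)
    tr <- ds$trials[order(ds$trials$trial_index), , drop = FALSE]
    cbind(
      data.frame(subject_id = ds$subject_id, group = ds$group,
                 session = ds$session, condition = ds$condition,
                 stringsAsFactors = FALSE),
      tr[, c("trial_index", "immediate_amount", "delayed_amount",
             "delay_days", "choice"), drop = FALSE],
      row.names = NULL
    )
  })
  df <- if (length(rows) == 0) {
    as.data.frame(setNames(rep(list(character(0)), 9), choice_table_columns))
  } else {
    df <- do.call(rbind, rows)
    df[order(df$subject_id, df$session, df$trial_index), , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            eol = "\n")
  invisible(path)
}

#' Four-cell group label of a dataset
#'
#' Maps a dataset to the hierarchical model's group-level cell:
#' `patient_on`, `patient_off`, `control_s1` or `control_s2`.
#'
#' @param ds a `dd_dataset`.
#' @return A length-1 character label.
#' @export
dataset_cell <- function(ds) {
  if (ds$group == "patient") {
    if (ds$condition == "dbs_on") "patient_on" else "patient_off"
  } else {
    if (ds$session == "s1") "control_s1" else "control_s2"
  }
}
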