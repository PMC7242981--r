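# Session file formats: versioned CSV tables for trials, reaction times
# and covariates, plus the run manifest. All files are UTF-8
# comma-separated with a schema comment line; item sequences are
# pipe-separated within a cell (phonemes space-separated within an item).

SCHEMA_VERSION <- "vocospan-schema 1"

write_vs_table <- function(df, path, what) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", SCHEMA_VERSION, what), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_vs_table <- function(path, what) {
  first <- readLines(path, n = 1, encoding = "UTF-8")
  if (!grepl(SCHEMA_VERSION, first, fixed = TRUE)) {
    stop_domain(path, ": missing or mismatched schema line (expected '",
                SCHEMA_VERSION, "')")
  }
  if (!grepl(what, first, fixed = TRUE)) {
    stop_domain(path, ": schema line does not declare a '", what, "' table")
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and validate a recall trial table
#'
#' Trial logs are CSV with columns participant, condition, kind, trial,
#' target, response, n_slots, n_correct. Every row is validated (known
#' kind, well-formed item lists, consistent slot counts); errors are
#' collected and reported with line numbers. With `skip_bad = TRUE`
#' offending rows are dropped with a warning instead of aborting.
#'
#' @param path CSV file path.
#' @param conditions permitted condition labels; NULL accepts any.
#' @param skip_bad drop invalid rows instead of raising an error.
#' @return validated data.frame of trial records.
#' @export
read_trial_table <- function(path, conditions = NULL, skip_bad = FALSE) {
  df <- read_vs_table(path, "trials")
  need <- c("participant", "condition", "kind", "trial", "target",
            "response", "n_slots", "n_correct")
  if (!all(need %in% names(df))) {
    stop_domain("trial table must have columns: ",
                paste(need, collapse = ", "))
  }
  errs <- character(0)
  bad <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 2L  # schema + header lines
    if (!df$kind[i] %in% c("digit", "word", "sentence")) {
      errs <- c(errs, sprintf("line %d: unknown kind '%s'", line,
                              df$kind[i]))
      bad[i] <- TRUE
    }
    if (!is.null(conditions) && !df$condition[i] %in% conditions) {
      errs <- c(errs, sprintf("line %d: unknown condition label '%s'",
                              line, df$condition[i]))
      bad[i] <- TRUE
    }
    if (is.na(df$n_slots[i]) || df$n_slots[i] < 1 ||
        is.na(df$n_correct[i]) || df$n_correct[i] < 0 ||
        df$n_correct[i] > df$n_slots[i]) {
      errs <- c(errs, sprintf("line %d: inconsistent slot counts (%s/%s)",
                              line, df$n_correct[i], df$n_slots[i]))
      bad[i] <- TRUE
    }
    if (!nzchar(df$target[i])) {
      errs <- c(errs, sprintf("line %d: malformed (empty) target item list",
                              line))
      bad[i] <- TRUE
    }
  }
  if (length(errs)) {
    if (skip_bad) {
      warning(sprintf("dropping %d invalid trial row(s):\n%s",
                      sum(bad), paste(errs, collapse = "\n")))
      df <- df[!bad, , drop = FALSE]
    } else {
      stop_domain("invalid trial table rows:\n", paste(errs, collapse = "\n"))
    }
  }
  df
}

#' @rdname read_trial_table
#' @param trials data.frame of trial records.
#' @export
write_trial_table <- function(trials, path) {
  write_vs_table(trials, path, "trials")
}

#' Read and validate a reaction-time trial table
#'
#' Columns: participant, task, condition, trial, rt_ms, correct.
#' Non-positive or missing reaction times are reported with line numbers.
#'
#' @inheritParams read_trial_table
#' @return validated data.frame.
#' @export
read_rt_table <- function(path, skip_bad = FALSE) {
  df <- read_vs_table(path, "rt")
  need <- c("participant", "task", "condition", "trial", "rt_ms", "correct")
  if (!all(need %in% names(df))) {
    stop_domain("RT table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- is.na(df$rt_ms) | df$rt_ms <= 0
  if (any(bad)) {
    errs <- sprintf("line %d: non-positive RT (%s)", which(bad) + 2L,
                    df$rt_ms[bad])
    if (skip_bad) {
      warning(sprintf("dropping %d invalid RT row(s):\n%s", sum(bad),
                      paste(errs, collapse = "\n")))
      df <- df[!bad, , drop = FALSE]
    } else {
      stop_domain("invalid RT table rows:\n", paste(errs, collapse = "\n"))
    }
  }
  df$correct <- as.logical(df$correct)
  df
}

#' @rdname read_rt_table
#' @param rt_trials data.frame of RT records.
#' @export
write_rt_table <- function(rt_trials, path) {
  write_vs_table(rt_trials, path, "rt")
}

#' Read or write a participant covariate table
#'
#' Columns: participant, reasoning_index, tova_rt_cns, tova_var_cns,
#' tova_com_cns, tova_omi_cns, complete.
#'
#' @inheritParams read_trial_table
#' @export
read_covariate_table <- function(path) {
  df <- read_vs_table(path, "covariates")
  if (!"participant" %in% names(df)) {
    stop_domain("covariate table must have a participant column")
  }
  if (!"complete" %in% names(df)) df$complete <- TRUE
  df$complete <- as.logical(df$complete)
  df
}

#' @rdname read_covariate_table
#' @param covariates data.frame of covariates.
#' @export
write_covariate_table <- function(covariates, path) {
  write_vs_table(covariates, path, "covariates")
}

#' Write or read a complete session directory
#'
#' A session directory holds `trials.csv`, `rt_trials.csv` and
#' `covariates.csv` in the schemas above (the same schemas a real-data
#' session would use).
#'
#' @param session a `synthetic_session` or a list with `trials`,
#'   `rt_trials`, `covariates`.
#' @param dir directory path (created if needed).
#' @return `read_session` returns a list with the three tables.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_table(session$trials, file.path(dir, "trials.csv"))
  write_rt_table(session$rt_trials, file.path(dir, "rt_trials.csv"))
  write_covariate_table(session$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  list(trials = read_trial_table(file.path(dir, "trials.csv")),
       rt_trials = read_rt_table(file.path(dir, "rt_trials.csv")),
       covariates = read_covariate_table(file.path(dir, "covariates.csv")))
}

#' Build a run manifest
#'
#' Records the configuration snapshot, seeds, input checksums and package
#' version so a rerun with the same manifest reproduces every
#' deterministic stage bit for bit.
#'
#' @param config list or `cohort_config` used for the run.
#' @param inputs named character vector of input file paths (may be
#'   empty).
#' @param seed top-level seed.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), inputs = character(0), seed = NA) {
  checksums <- vapply(inputs, function(p) {
    if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_
  }, character(1))
  structure(list(
    package = "vocospan",
    version = as.character(utils::packageVersion("vocospan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = as.list(checksums)),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
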