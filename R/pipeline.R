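# The full analysis pipeline: score -> aggregate -> composites ->
# correlation tables -> reaction-time analysis, mirroring the planned
# individual-differences analysis of the study.

#' Aggregate trial records to participant-by-condition accuracies
#'
#' @param trials trial data.frame (see [read_trial_table()]).
#' @param weights pooling rule passed to [aggregate_condition_accuracy()].
#' @return data.frame: participant, condition, kind, mean_proportion,
#'   n_slots, n_correct.
#' @export
summarize_accuracy <- function(trials, weights = "slots") {
  key <- interaction(trials$participant, trials$condition, trials$kind,
                     drop = TRUE)
  parts <- split(trials, key)
  out <- lapply(parts, function(d) {
    s <- aggregate_condition_accuracy(d, participant = d$participant[1],
                                      condition = d$condition[1],
                                      kind = d$kind[1], weights = weights)
    data.frame(participant = d$participant[1], condition = d$condition[1],
               kind = d$kind[1], mean_proportion = s$mean_proportion,
               n_slots = s$n_slots, n_correct = s$n_correct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant, out$kind, out$condition), ]
}

#' Pivot accuracy summaries to a participants-by-conditions matrix
#'
#' @param summaries output of [summarize_accuracy()].
#' @param kind stimulus kind to extract.
#' @param conditions condition column order.
#' @return numeric matrix with participant rownames.
#' @export
accuracy_wide <- function(summaries, kind, conditions) {
  d <- summaries[summaries$kind == kind, ]
  participants <- sort(unique(d$participant))
  m <- matrix(NA_real_, length(participants), length(conditions),
              dimnames = list(participants, conditions))
  for (i in seq_len(nrow(d))) {
    m[d$participant[i], d$condition[i]] <- d$mean_proportion[i]
  }
  m
}

#' Reaction-time analysis for one session
#'
#' Screens out incorrect trials, trims slow outliers iteratively per
#' participant and condition (4 SDs above the mean), computes geometric
#' mean reaction times and condition costs, tests each cost across
#' participants with the tie-corrected Wilcoxon signed-rank Z, and fits
#' an ex-Gaussian to each participant-by-condition RT distribution.
#'
#' @param rt_trials RT data.frame (see [read_rt_table()]).
#' @param min_fit_n minimum trials for an ex-Gaussian fit (default 50).
#' @return list with `geometric_means` (participant x condition),
#'   `costs` (per-participant cost table), `tests` (Wilcoxon Z/p per
#'   cost), `fits` (per participant x condition parameter table),
#'   `fit_means` (per-participant mean RT and mean mu/sigma/tau across
#'   all conditions of both tasks), `trim` (removal counts).
#' @export
analyze_rt <- function(rt_trials, min_fit_n = 50) {
  ok <- rt_trials[rt_trials$correct & rt_trials$rt_ms > 0, ]
  key <- interaction(ok$participant, ok$task, ok$condition, drop = TRUE)
  parts <- split(ok, key)
  gm_rows <- list(); fit_rows <- list(); trim_rows <- list()
  for (d in parts) {
    tr <- trim_outliers(d$rt_ms)
    gm_rows[[length(gm_rows) + 1L]] <- data.frame(
      participant = d$participant[1], task = d$task[1],
      condition = d$condition[1], gm_rt = geometric_mean_rt(tr$kept),
      mean_rt = mean(tr$kept), n = length(tr$kept),
      stringsAsFactors = FALSE)
    trim_rows[[length(trim_rows) + 1L]] <- data.frame(
      participant = d$participant[1], task = d$task[1],
      condition = d$condition[1], n_raw = nrow(d),
      n_removed = tr$n_removed, stringsAsFactors = FALSE)
    if (length(tr$kept) >= min_fit_n) {
      f <- fit_exgaussian(tr$kept, min_n = min_fit_n)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        participant = d$participant[1], task = d$task[1],
        condition = d$condition[1], mu = f$mu, sigma = f$sigma,
        tau = f$tau, converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  gm <- do.call(rbind, gm_rows)
  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL
  pick <- function(task, cond) {
    d <- gm[gm$task == task & gm$condition == cond, ]
    stats::setNames(d$gm_rt, d$participant)
  }
  costs <- list(
    switch_cost = pick("colour_shape", "switch") -
      pick("colour_shape", "repeat"),
    stroop_incongruent_neutral = pick("stroop", "incongruent") -
      pick("stroop", "neutral"),
    stroop_incongruent_congruent = pick("stroop", "incongruent") -
      pick("stroop", "congruent"),
    stroop_congruent_neutral = pick("stroop", "congruent") -
      pick("stroop", "neutral"))
  tests <- do.call(rbind, lapply(names(costs), function(nm) {
    x <- costs[[nm]]
    w <- wilcoxon_signed_rank(x, rep(0, length(x)))
    data.frame(cost = nm, median_ms = stats::median(x), Z = w$Z, p = w$p,
               n = w$n_used, stringsAsFactors = FALSE)
  }))
  fit_means <- NULL
  if (!is.null(fits)) {
    mean_rt_all <- tapply(gm$mean_rt, gm$participant, mean)
    fm <- data.frame(participant = names(mean_rt_all),
                     mean_rt = as.numeric(mean_rt_all),
                     stringsAsFactors = FALSE)
    for (par in c("mu", "sigma", "tau")) {
      v <- tapply(fits[[par]], fits$participant, mean)
      fm[[paste0("mean_", par)]] <- as.numeric(v[fm$participant])
    }
    fit_means <- fm
  }
  list(geometric_means = gm, costs = costs, tests = tests, fits = fits,
       fit_means = fit_means, trim = do.call(rbind, trim_rows))
}

#' Run the full individual-differences pipeline
#'
#' Executes the analysis chain on a session: accuracy aggregation,
#' the sentence-recognition composite (PCA over the three
#' spectral-resolution accuracies, eigenvalue > 1 retention), the serial
#' recall composite (PCA over the six stimulus-by-resolution accuracies,
#' components 1-2 retained), serial-recall versus sentence correlation
#' tables with Bonferroni families of 6 and 8, cross-resolution sentence
#' correlations, balanced condition contrasts, attention correlation
#' tables, and the reaction-time analysis.
#'
#' @param session a `synthetic_session`, a list with `trials`,
#'   `rt_trials`, `covariates`, or a session directory path.
#' @param conditions condition labels ordered most to fewest channels.
#' @param out_dir optional output directory: tables are written as CSV
#'   with a JSON manifest.
#' @param seed seed recorded in the manifest.
#' @return object of class `vocospan_analysis`.
#' @export
run_pipeline <- function(session, conditions = c("ch16", "ch8", "ch4"),
                         out_dir = NULL, seed = NA) {
  if (is.character(session)) session <- read_session(session)
  trials <- session$trials
  covariates <- session$covariates
  complete_ids <- covariates$participant[covariates$complete]
  trials <- trials[trials$participant %in% complete_ids, ]
  summaries <- summarize_accuracy(trials)

  sent <- accuracy_wide(summaries, "sentence", conditions)
  digit <- accuracy_wide(summaries, "digit", conditions)
  word <- accuracy_wide(summaries, "word", conditions)
  if (anyNA(sent) || anyNA(digit) || anyNA(word)) {
    stop_domain("incomplete accuracy data: every complete participant ",
                "needs every condition and task")
  }

  # sentence composite: first component retained by the eigenvalue rule
  sentence_pca <- pca_composite(sent)
  sentence_composite <- sentence_pca$scores[, 1]

  # serial-recall composite over 6 columns; components 1-2 retained on
  # prior grounds even though the second eigenvalue falls below 1
  serial6 <- cbind(digit, word)
  colnames(serial6) <- c(paste0("digit_", conditions),
                         paste0("word_", conditions))
  serial_pca <- pca_composite(serial6, retain = 1:2)
  serial_ability <- serial_pca$scores[, 1]
  vocoder_sensitivity <- serial_pca$scores[, 2]

  ids <- rownames(sent)
  cov <- covariates[match(ids, covariates$participant), ]

  # matched-resolution serial vs sentence correlations (family of 6)
  fam6 <- do.call(rbind, lapply(seq_along(conditions), function(ci) {
    do.call(rbind, lapply(c("digit", "word"), function(k) {
      m <- if (k == "digit") digit else word
      cell <- correlate(m[, ci], sent[, ci], method = "spearman",
                        family_size = 6,
                        labels = c(paste0(k, "_", conditions[ci]),
                                   paste0("sentence_", conditions[ci])))
      data.frame(predictor = cell$pair[1], outcome = cell$pair[2],
                 coefficient = cell$coefficient, p_value = cell$p_value,
                 significant_bonferroni = cell$significant_bonferroni,
                 stringsAsFactors = FALSE)
    }))
  }))

  # component scores vs sentence accuracy and composite (family of 8)
  outcomes8 <- cbind(sent, composite = sentence_composite)
  fam8 <- do.call(rbind, lapply(c("serial_ability", "vocoder_sensitivity"),
                                function(pn) {
    p <- if (pn == "serial_ability") serial_ability else vocoder_sensitivity
    do.call(rbind, lapply(colnames(outcomes8), function(on) {
      cell <- correlate(p, outcomes8[, on], method = "spearman",
                        family_size = 8, labels = c(pn, on))
      data.frame(predictor = pn, outcome = on,
                 coefficient = cell$coefficient, p_value = cell$p_value,
                 significant_bonferroni = cell$significant_bonferroni,
                 stringsAsFactors = FALSE)
    }))
  }))

  # cross-resolution sentence correlations (Pearson)
  cross <- do.call(rbind, lapply(utils::combn(seq_along(conditions), 2,
                                              simplify = FALSE),
                                 function(pr) {
    cell <- correlate(sent[, pr[1]], sent[, pr[2]], method = "pearson",
                      labels = paste0("sentence_", conditions[pr]))
    data.frame(a = cell$pair[1], b = cell$pair[2], r = cell$coefficient,
               p = cell$p_value, stringsAsFactors = FALSE)
  }))

  # balanced condition contrasts (reference: most channels)
  contrasts <- lapply(c(digit = "digit", word = "word"), function(k) {
    condition_contrasts(summaries[summaries$kind == k, ],
                        reference = conditions[1])
  })

  # reasoning correlations
  reasoning <- list(
    serial = correlate(serial_ability, cov$reasoning_index,
                       method = "spearman",
                       labels = c("serial_ability", "reasoning_index")),
    sentence = correlate(sentence_composite, cov$reasoning_index,
                         method = "spearman",
                         labels = c("sentence_composite", "reasoning_index")))

  # reaction-time stage (full recruited sample)
  rt <- analyze_rt(session$rt_trials)

  # attention correlation tables
  att_pred <- data.frame(
    colour_shape_cost = rt$costs$switch_cost[ids],
    stroop_inc_con = rt$costs$stroop_incongruent_congruent[ids],
    stroop_inc_neu = rt$costs$stroop_incongruent_neutral[ids],
    tova_rt = cov$tova_rt_cns, tova_var = cov$tova_var_cns,
    tova_com = cov$tova_com_cns, tova_omi = cov$tova_omi_cns)
  out_sent <- as.data.frame(outcomes8)
  attention_sentence <- build_correlation_table(att_pred, out_sent,
                                                method = "spearman")
  out_cog <- data.frame(reasoning = cov$reasoning_index,
                        serial_ability = serial_ability,
                        vocoder_sensitivity = vocoder_sensitivity)
  attention_cognition <- build_correlation_table(att_pred, out_cog,
                                                 method = "spearman")
  rt_tables <- NULL
  if (!is.null(rt$fit_means)) {
    fm <- rt$fit_means[match(ids, rt$fit_means$participant), ]
    rt_pred <- fm[, c("mean_rt", "mean_mu", "mean_sigma", "mean_tau")]
    rt_tables <- build_correlation_table(
      rt_pred, cbind(out_sent, out_cog),
      method = "spearman",
      family_size = 4 * (ncol(out_sent) + ncol(out_cog)))
  }

  res <- structure(list(
    conditions = conditions,
    summaries = summaries,
    sentence_accuracy = sent,
    digit_accuracy = digit,
    word_accuracy = word,
    sentence_pca = sentence_pca,
    serial_pca = serial_pca,
    sentence_composite = sentence_composite,
    serial_ability = serial_ability,
    vocoder_sensitivity = vocoder_sensitivity,
    serial_sentence_matched = fam6,
    component_sentence = fam8,
    cross_resolution = cross,
    contrasts = contrasts,
    reasoning = reasoning,
    rt = rt,
    attention_sentence = attention_sentence,
    attention_cognition = attention_cognition,
    rt_fit_correlations = rt_tables,
    covariates = cov),
    class = "vocospan_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries, file.path(out_dir, "accuracy_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(fam6, file.path(out_dir, "serial_vs_sentence.csv"),
                     row.names = FALSE)
    utils::write.csv(fam8, file.path(out_dir, "components_vs_sentence.csv"),
                     row.names = FALSE)
    utils::write.csv(rt$tests, file.path(out_dir, "rt_cost_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(attention_sentence,
                     file.path(out_dir, "attention_vs_sentence.csv"),
                     row.names = FALSE)
    if (!is.null(rt_tables)) {
      utils::write.csv(rt_tables, file.path(out_dir, "rt_fits_vs_outcomes.csv"),
                       row.names = FALSE)
    }
    write_manifest(run_manifest(config = list(conditions = conditions),
                                seed = seed),
                   file.path(out_dir, "manifest.json"))
  }
  res
}

#' @export
print.vocospan_analysis <- function(x, ...) {
  cat("Vocoded sentence recognition / serial recall analysis\n")
  sm <- 100 * colMeans(x$sentence_accuracy)
  ssd <- 100 * apply(x$sentence_accuracy, 2, stats::sd)
  cat(sprintf("  sentence key words correct: %s\n",
              paste(sprintf("%s %.1f%% (SD %.1f)", x$conditions, sm, ssd),
                    collapse = ", ")))
  cat(sprintf("  digit recall: %s\n",
              paste(sprintf("%s %.0f%%", x$conditions,
                            100 * colMeans(x$digit_accuracy)),
                    collapse = ", ")))
  cat(sprintf("  word recall (phonemes): %s\n",
              paste(sprintf("%s %.0f%%", x$conditions,
                            100 * colMeans(x$word_accuracy)),
                    collapse = ", ")))
  cat(sprintf("  sentence composite: first eigenvalue %.2f (%.0f%% variance)\n",
              x$sentence_pca$eigenvalues[1],
              100 * x$sentence_pca$variance_explained[1]))
  cat(sprintf("  serial recall: first eigenvalue %.2f (%.0f%% variance)\n",
              x$serial_pca$eigenvalues[1],
              100 * x$serial_pca$variance_explained[1]))
  comp <- x$component_sentence
  cc <- comp$coefficient[comp$predictor == "serial_ability" &
                           comp$outcome == "composite"]
  cat(sprintf("  serial ability ~ sentence composite: rho = %.2f\n", cc))
  cat(sprintf("  serial ability ~ reasoning: rho = %.2f (p = %.3f)\n",
              x$reasoning$serial$coefficient, x$reasoning$serial$p_value))
  for (i in seq_len(nrow(x$rt$tests))) {
    cat(sprintf("  %s: median %.0f ms, Z = %.2f\n", x$rt$tests$cost[i],
                x$rt$tests$median_ms[i], x$rt$tests$Z[i]))
  }
  invisible(x)
}
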