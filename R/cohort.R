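# Synthetic study cohort with known latent structure.
#
# Generates a complete two-session study: correlated participant latents
# (serial-recall ability, sentence-specific skill, fluid reasoning,
# vocoder sensitivity, processing speed), slot-level recall outcomes for
# digit span, word span and sentence key words across three spectral
# resolutions, ex-Gaussian reaction-time trials for the attentional
# switching and Stroop tasks, and a covariate table. Defaults are
# calibrated so the simulated group statistics match the study
# conditions: sentence key-word accuracy near 88/77/39% at 16/8/4
# channels, digit recall near 81% in every condition, word recall near
# 86/82/65%, and a 145 ms switch cost with 153/137 ms Stroop costs.
# Attention tasks are completed by the full recruited sample (default
# 38); the six who drop out before session 2 leave 32 participants with
# complete recall data.

#' Cohort configuration
#'
#' All tunable parameters of the synthetic cohort. Intercepts are on the
#' logit scale per scoring slot; loadings multiply standard-normal
#' latents. The default values are the package's calibrated study
#' conditions; see the methods vignette for their derivation.
#'
#' @param n_participants participants with complete data (default 32).
#' @param n_rt_participants participants completing the session-1
#'   reaction-time tasks (default 38; the recruited sample).
#' @param conditions spectral-resolution labels, most channels first.
#' @param sentence_intercepts per-condition logit intercepts for key-word
#'   recall.
#' @param sentence_loadings per-condition logit loading of the sentence
#'   skill latent.
#' @param sentence_noise_sd per-condition-block logit noise SD.
#' @param digit_intercepts,word_intercepts per-condition logit intercepts
#'   at the reference list length.
#' @param digit_loading,word_loading logit loading of serial ability.
#' @param recall_noise_sd participant-by-condition logit noise SD for the
#'   recall tasks.
#' @param length_penalty_digit,length_penalty_word logit decrement per
#'   item beyond the reference length (2 digits, 1 word).
#' @param vocoder_penalty_word per-condition loading of the vocoder
#'   sensitivity latent on word recall (0 for digits: digit recall is
#'   insensitive to spectral resolution).
#' @param sentence_skill_on_serial correlation-generating weight of
#'   serial ability inside the sentence-skill latent.
#' @param reasoning_cor latent correlation of serial ability and the
#'   reasoning index (default 0.45, chosen so the observed Spearman
#'   correlation at n = 32 centres on 0.35 after measurement
#'   attenuation).
#' @param speed_cor_reasoning,speed_cor_serial latent correlations of
#'   processing speed with reasoning and serial ability (negative: faster
#'   responders score higher).
#' @param reasoning_mean,reasoning_sd normed reasoning index mean and SD.
#' @param rt_mu,rt_sigma,rt_tau baseline ex-Gaussian parameters (ms) of
#'   the colour-shape repeat condition.
#' @param rt_speed_shift mu shift (ms) per SD of the speed latent.
#' @param rt_scale_speed exponential scaling of sigma and tau per SD of
#'   speed.
#' @param switch_cost_ms,switch_cost_sd mean and between-participant SD
#'   of the attentional switch cost (ms, on mu).
#' @param stroop_incongruent_neutral_ms,stroop_congruent_neutral_ms mean
#'   Stroop shifts relative to the neutral condition (ms).
#' @param stroop_cost_sd between-participant SD of the incongruent cost.
#' @param rt_trials_per_condition trials per task condition (default 80).
#' @param rt_accuracy probability a trial is answered correctly.
#' @param contaminant_rate fraction of RT trials replaced by slow
#'   contaminants uniform on mean + 5 to 10 SDs, exercising the trimmer.
#' @param digit_trials_per_length digit-span trials per length per block.
#' @param word_trials_per_length word-span trials per length per block.
#' @param keywords_per_condition sentence key words per condition
#'   (default 152: two 18-sentence lists with 76 key words each).
#' @param seed integer seed; all stages draw from named substreams.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 32,
                          n_rt_participants = 38,
                          conditions = c("ch16", "ch8", "ch4"),
                          sentence_intercepts = c(2.08, 1.23, -0.45),
                          sentence_loadings = c(0.47, 0.30, 0.235),
                          sentence_noise_sd = 0.04,
                          digit_intercepts = c(3.40, 3.40, 3.40),
                          word_intercepts = c(3.23, 2.88, 1.90),
                          digit_loading = 0.55,
                          word_loading = 0.55,
                          recall_noise_sd = 0.30,
                          length_penalty_digit = 0.38,
                          length_penalty_word = 0.35,
                          vocoder_penalty_word = c(0, 0.15, 0.35),
                          sentence_skill_on_serial = 0.80,
                          reasoning_cor = 0.45,
                          speed_cor_reasoning = -0.45,
                          speed_cor_serial = -0.35,
                          reasoning_mean = 103, reasoning_sd = 10.8,
                          rt_mu = 550, rt_sigma = 60, rt_tau = 150,
                          rt_speed_shift = 60,
                          rt_scale_speed = 0.2,
                          switch_cost_ms = 145, switch_cost_sd = 40,
                          stroop_incongruent_neutral_ms = 149,
                          stroop_congruent_neutral_ms = 20,
                          stroop_cost_sd = 40,
                          rt_trials_per_condition = 80,
                          rt_accuracy = 0.985,
                          contaminant_rate = 0.01,
                          digit_trials_per_length = 2,
                          word_trials_per_length = 10,
                          keywords_per_condition = 152,
                          seed = 1) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$sentence_intercepts) == length(cfg$conditions),
            length(cfg$vocoder_penalty_word) == length(cfg$conditions),
            cfg$rt_sigma > 0, cfg$rt_tau > 0,
            cfg$n_rt_participants >= cfg$n_participants)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d participants (%d with RT data), %s\n",
              x$n_participants, x$n_rt_participants,
              paste(x$conditions, collapse = "/")))
  cat(sprintf("  seed %d; %d key words, digit lengths 2-9 x%d, word lengths 1-6 x%d\n",
              x$seed, x$keywords_per_condition, x$digit_trials_per_length,
              x$word_trials_per_length))
  invisible(x)
}

#' Sample participant latent profiles
#'
#' Draws multivariate-normal latents: serial ability, sentence-specific
#' skill, reasoning, vocoder sensitivity, processing speed, plus four
#' independent sustained-attention (TOVA-style) latents. The correlation
#' structure is taken from the config; an error is raised if it is not
#' positive definite.
#'
#' @param config a [cohort_config()].
#' @param n number of participants (default: `config$n_rt_participants`,
#'   so the session-1 tasks cover the full recruited sample).
#' @return data.frame of latents with `participant` ids.
#' @export
sample_cohort <- function(config = cohort_config(),
                          n = config$n_rt_participants) {
  r_sr <- config$reasoning_cor
  r_pr <- config$speed_cor_reasoning
  r_ps <- config$speed_cor_serial
  # order: serial, sentence_extra, reasoning, vocoder, speed
  R <- diag(5)
  R[1, 3] <- R[3, 1] <- r_sr
  R[3, 5] <- R[5, 3] <- r_pr
  R[1, 5] <- R[5, 1] <- r_ps
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) {
    stop_domain("latent correlation matrix is not positive definite")
  }
  with_seed(substream_seed(config$seed, "cohort"), {
    z <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = R)
    tova <- matrix(stats::rnorm(n * 4), n, 4)
    a <- config$sentence_skill_on_serial
    data.frame(
      participant = sprintf("P%02d", seq_len(n)),
      serial_ability = z[, 1],
      sentence_skill = a * z[, 1] + sqrt(1 - a^2) * z[, 2],
      reasoning = z[, 3],
      vocoder_sensitivity = z[, 4],
      speed = z[, 5],
      tova_rt = tova[, 1], tova_var = tova[, 2],
      tova_com = tova[, 3], tova_omi = tova[, 4],
      stringsAsFactors = FALSE)
  })
}

logistic <- function(x) 1 / (1 + exp(-x))

# Draw a response sequence given per-slot success probabilities: correct
# slots copy the target, errors draw a different item.
respond_items <- function(target, p, alphabet) {
  ok <- stats::runif(length(target)) < p
  resp <- target
  for (i in which(!ok)) {
    alt <- alphabet[alphabet != target[i]]
    resp[i] <- alt[sample.int(length(alt), 1)]
  }
  resp
}

#' Build the fixed stimulus materials of a study
#'
#' Generates the digit lists, balanced word lists, presentation orders
#' and synthetic sentence key-word tokens shared by every participant of
#' a study (all participants hear the same materials). Word-list
#' balancing is a constrained search that can occasionally fail for a
#' given random substream; in that case the next derived substream is
#' tried, deterministically, up to `max_tries` times.
#'
#' @param config a [cohort_config()].
#' @param inventory optional `word_inventory`; default a
#'   [synthetic_word_inventory()] under the config's list substream.
#' @param max_tries word-list generation attempts over derived
#'   substreams (default 10).
#' @return list with elements `digit`, `words`, `word_order`,
#'   `keywords`.
#' @export
study_stimuli <- function(config = cohort_config(), inventory = NULL,
                          max_tries = 10) {
  n_cond <- length(config$conditions)
  list_seed <- substream_seed(config$seed, "lists")
  if (is.null(inventory)) {
    inventory <- synthetic_word_inventory(seed = list_seed)
  }
  digit_lengths <- rep(2:9, each = config$digit_trials_per_length)
  word_lengths <- rep(1:6, each = config$word_trials_per_length)
  wl <- NULL
  last <- NULL
  for (k in seq_len(max_tries)) {
    wl <- tryCatch(
      generate_word_lists(inventory, lengths_per_block = word_lengths,
                          n_blocks = n_cond,
                          seed = substream_seed(list_seed, paste0("w", k))),
      error = function(e) { last <<- e; NULL })
    if (!is.null(wl)) break
  }
  if (is.null(wl)) stop(last)
  with_seed(list_seed, {
    digit_lists <- lapply(seq_len(n_cond), function(b) {
      ord <- order_block(digit_lengths, kind = "digit")
      lapply(digit_lengths[ord], function(L) generate_digit_list(L)$items)
    })
    word_order <- lapply(seq_len(n_cond), function(b) {
      order_block(word_lengths, kind = "word")
    })
    # sentence key words: two lists of 18 sentences per condition with 76
    # key words each; synthetic tokens stand in for the real key words
    kw <- lapply(seq_len(n_cond), function(b) {
      sprintf("kw%02d_%03d", b, seq_len(config$keywords_per_condition))
    })
    list(digit = digit_lists, words = wl, word_order = word_order,
         keywords = kw)
  })
}

#' Simulate recall trials for a cohort
#'
#' Produces trial-level digit-span, word-span and sentence key-word
#' records for every participant and condition. Each scoring slot (digit
#' position, phoneme, key word) is a Bernoulli draw with success
#' probability `logistic(intercept - length_penalty - condition noise +
#' loading x ability - vocoding penalty x sensitivity)`. Digit conditions
#' carry no vocoding penalty: digit recall is insensitive to spectral
#' resolution. Stimulus lists are generated once (as in the study, where
#' all participants heard the same lists) with the list-generation
#' constraints enforced.
#'
#' @param profiles data.frame from [sample_cohort()]; only the first
#'   `config$n_participants` rows (the completers) are simulated.
#' @param config a [cohort_config()].
#' @param inventory optional `word_inventory`; default
#'   [synthetic_word_inventory()] under the config seed.
#' @return list with `trials` (data.frame: participant, condition, kind,
#'   trial, target, response, n_slots, n_correct) and `lists` (the
#'   generated stimulus lists).
#' @export
simulate_recall_trials <- function(profiles, config = cohort_config(),
                                   inventory = NULL, stimuli = NULL) {
  conds <- config$conditions
  n_cond <- length(conds)
  completers <- profiles[seq_len(min(config$n_participants,
                                     nrow(profiles))), ]
  stim <- if (!is.null(stimuli)) stimuli else {
    study_stimuli(config, inventory = inventory)
  }
  # column accumulators: one pass, no per-row data.frames
  col_participant <- character(0); col_condition <- character(0)
  col_kind <- character(0); col_trial <- integer(0)
  col_target <- character(0); col_response <- character(0)
  col_slots <- integer(0); col_correct <- integer(0)
  add <- function(participant, condition, kind, trial, target, response,
                  slots, correct) {
    col_participant <<- c(col_participant, participant)
    col_condition <<- c(col_condition, condition)
    col_kind <<- c(col_kind, kind)
    col_trial <<- c(col_trial, trial)
    col_target <<- c(col_target, target)
    col_response <<- c(col_response, response)
    col_slots <<- c(col_slots, slots)
    col_correct <<- c(col_correct, correct)
  }
  ph <- span_phonemes()
  sim_seed <- substream_seed(config$seed, "recall")
  with_seed(sim_seed, {
    for (pi in seq_len(nrow(completers))) {
      pr <- completers[pi, ]
      for (ci in seq_len(n_cond)) {
        noise_d <- stats::rnorm(1, 0, config$recall_noise_sd)
        noise_w <- stats::rnorm(1, 0, config$recall_noise_sd)
        noise_s <- stats::rnorm(1, 0, config$sentence_noise_sd)
        # digits
        n_dig <- length(stim$digit[[ci]])
        tg <- rs <- character(n_dig); ns <- nc <- integer(n_dig)
        for (ti in seq_len(n_dig)) {
          tgt <- stim$digit[[ci]][[ti]]
          eta <- config$digit_intercepts[ci] -
            config$length_penalty_digit * (length(tgt) - 2) +
            config$digit_loading * pr$serial_ability + noise_d
          resp <- respond_items(tgt, logistic(eta), 1:9)
          tg[ti] <- paste(tgt, collapse = "|")
          rs[ti] <- paste(resp, collapse = "|")
          ns[ti] <- length(tgt)
          nc[ti] <- sum(resp == tgt)
        }
        add(rep(pr$participant, n_dig), rep(conds[ci], n_dig),
            rep("digit", n_dig), seq_len(n_dig), tg, rs, ns, nc)
        # words: per-phoneme Bernoulli slots
        ord <- stim$word_order[[ci]]
        n_wrd <- length(ord)
        tg <- rs <- character(n_wrd); ns <- nc <- integer(n_wrd)
        for (ti in seq_len(n_wrd)) {
          idx <- stim$words$blocks[[ci]][[ord[ti]]]
          w <- stim$words$inventory[idx, , drop = FALSE]
          eta <- config$word_intercepts[ci] -
            config$length_penalty_word * (nrow(w) - 1) +
            config$word_loading * pr$serial_ability -
            config$vocoder_penalty_word[ci] * pr$vocoder_sensitivity +
            noise_w
          p <- logistic(eta)
          r_ini <- respond_items(w$initial, p, ph$initial)
          r_vow <- respond_items(w$vowel, p, ph$vowel)
          r_fin <- respond_items(w$final, p, ph$final)
          tg[ti] <- paste(paste(w$initial, w$vowel, w$final),
                          collapse = "|")
          rs[ti] <- paste(paste(r_ini, r_vow, r_fin), collapse = "|")
          ns[ti] <- 3L * nrow(w)
          nc[ti] <- sum(r_ini == w$initial) + sum(r_vow == w$vowel) +
            sum(r_fin == w$final)
        }
        add(rep(pr$participant, n_wrd), rep(conds[ci], n_wrd),
            rep("word", n_wrd), seq_len(n_wrd), tg, rs, ns, nc)
        # sentences: key words pooled over the condition's two lists
        kws <- stim$keywords[[ci]]
        eta <- config$sentence_intercepts[ci] +
          config$sentence_loadings[ci] * pr$sentence_skill + noise_s
        heard <- stats::runif(length(kws)) < logistic(eta)
        add(pr$participant, conds[ci], "sentence", 1L,
            paste(kws, collapse = "|"),
            paste(kws[heard], collapse = "|"),
            length(kws), sum(heard))
      }
    }
  })
  trials <- data.frame(participant = col_participant,
                       condition = col_condition, kind = col_kind,
                       trial = col_trial, target = col_target,
                       response = col_response, n_slots = col_slots,
                       n_correct = col_correct, stringsAsFactors = FALSE)
    list(trials = trials, lists = stim)
}

#' Simulate reaction-time trials for a cohort
#'
#' Ex-Gaussian trials for the colour-shape categorization task (repeat
#' and switch conditions) and the colour Stroop task (neutral, congruent,
#' incongruent), with per-participant speed shifts, per-participant
#' condition costs, occasional slow contaminants, and a per-trial correct
#' flag. All recruited participants (rows of `profiles`) are simulated.
#'
#' @param profiles data.frame from [sample_cohort()].
#' @param config a [cohort_config()].
#' @return data.frame: participant, task, condition, trial, rt_ms,
#'   correct.
#' @export
simulate_rt_trials <- function(profiles, config = cohort_config()) {
  n_tr <- config$rt_trials_per_condition
  rows <- list()
  with_seed(substream_seed(config$seed, "rt"), {
    for (pi in seq_len(nrow(profiles))) {
      pr <- profiles[pi, ]
      scale_i <- exp(config$rt_scale_speed * pr$speed)
      mu_i <- config$rt_mu + config$rt_speed_shift * pr$speed
      sig_i <- config$rt_sigma * scale_i
      tau_i <- config$rt_tau * scale_i
      switch_i <- stats::rnorm(1, config$switch_cost_ms,
                               config$switch_cost_sd)
      stroop_i <- stats::rnorm(1, config$stroop_incongruent_neutral_ms,
                               config$stroop_cost_sd)
      cond_mu <- list(
        colour_shape = c(repeat_ = mu_i, switch = mu_i + switch_i),
        stroop = c(neutral = mu_i + 70,
                   congruent = mu_i + 70 + config$stroop_congruent_neutral_ms,
                   incongruent = mu_i + 70 + stroop_i))
      for (task in names(cond_mu)) {
        for (cc in names(cond_mu[[task]])) {
          rt <- rexgauss(n_tr, cond_mu[[task]][cc], sig_i, tau_i)
          m <- mean(rt); s <- stats::sd(rt)
          contaminate <- stats::runif(n_tr) < config$contaminant_rate
          rt[contaminate] <- stats::runif(sum(contaminate),
                                          m + 5 * s, m + 10 * s)
          correct <- stats::runif(n_tr) < config$rt_accuracy
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pr$participant, task = task,
            condition = sub("_$", "", cc), trial = seq_len(n_tr),
            rt_ms = round(rt, 1), correct = correct,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic study session
#'
#' Draws the cohort, simulates recall and reaction-time trials, and
#' builds the covariate table (normed reasoning index, TOVA-style
#' percentiles, completion flag). The result feeds [run_pipeline()]
#' directly or can be written out with [write_session()].
#'
#' @param config a [cohort_config()].
#' @param stimuli optional precomputed stimulus lists (the `lists`
#'   element of an earlier [simulate_recall_trials()] result); fixed
#'   study materials can be reused across replicate cohorts.
#' @return object of class `synthetic_session`: list with `profiles`,
#'   `trials`, `rt_trials`, `covariates`, `config` and `lists`.
#' @export
#' @examples
#' \donttest{
#' sess <- simulate_session(cohort_config(seed = 7))
#' head(sess$covariates)
#' }
simulate_session <- function(config = cohort_config(), stimuli = NULL) {
  profiles <- sample_cohort(config)
  recall <- simulate_recall_trials(profiles, config, stimuli = stimuli)
  rt <- simulate_rt_trials(profiles, config)
  covariates <- data.frame(
    participant = profiles$participant,
    reasoning_index = round(config$reasoning_mean +
                              config$reasoning_sd * profiles$reasoning),
    tova_rt_cns = round(100 * stats::pnorm(profiles$tova_rt)),
    tova_var_cns = round(100 * stats::pnorm(profiles$tova_var)),
    tova_com_cns = round(100 * stats::pnorm(profiles$tova_com)),
    tova_omi_cns = round(100 * stats::pnorm(profiles$tova_omi)),
    complete = seq_len(nrow(profiles)) <= config$n_participants,
    stringsAsFactors = FALSE)
  structure(list(profiles = profiles, trials = recall$trials,
                 lists = recall$lists, rt_trials = rt,
                 covariates = covariates, config = config),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic study session: %d participants (%d complete), seed %d\n",
              nrow(x$profiles), sum(x$covariates$complete), x$config$seed))
  cat(sprintf("  %d recall trials, %d RT trials\n", nrow(x$trials),
              nrow(x$rt_trials)))
  invisible(x)
}
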