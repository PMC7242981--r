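test_that("latent profiles carry the configured correlation structure", {
  cfg <- cohort_config(seed = 11)
  big <- sample_cohort(cfg, n = 10000)
  expect_lt(abs(stats::cor(big$serial_ability, big$reasoning) -
                  cfg$reasoning_cor), 0.03)
  # a config with a 0.35 population correlation realises exactly that
  cfg35 <- cohort_config(seed = 11, reasoning_cor = 0.35)
  big35 <- sample_cohort(cfg35, n = 10000)
  expect_lt(abs(stats::cor(big35$serial_ability, big35$reasoning) - 0.35),
            0.03)
  expect_lt(abs(stats::cor(big$serial_ability, big$vocoder_sensitivity)),
            0.05)
  expect_lt(abs(stats::cor(big$tova_rt, big$serial_ability)), 0.05)
  # a zero-correlation config produces null structure
  cfg0 <- cohort_config(seed = 11, reasoning_cor = 0,
                        speed_cor_reasoning = 0, speed_cor_serial = 0)
  big0 <- sample_cohort(cfg0, n = 10000)
  cors <- stats::cor(big0[, c("serial_ability", "reasoning", "speed")])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  # determinism
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  expect_error(sample_cohort(cohort_config(reasoning_cor = 0.99,
                                           speed_cor_reasoning = -0.99,
                                           speed_cor_serial = 0.9)),
               "positive definite")
})

test_that("simulated trials pass the scoring and table validators", {
  sess <- fixture_session()
  path <- tempfile(fileext = ".csv")
  write_trial_table(sess$trials, path)
  back <- read_trial_table(path, conditions = c("ch16", "ch8", "ch4"))
  expect_equal(nrow(back), nrow(sess$trials))
  # recomputing scores from target/response sequences reproduces the
  # stored counts for digit trials
  dig <- sess$trials[sess$trials$kind == "digit", ][1:50, ]
  for (i in seq_len(nrow(dig))) {
    tgt <- as.integer(strsplit(dig$target[i], "|", fixed = TRUE)[[1]])
    rsp <- as.integer(strsplit(dig$response[i], "|", fixed = TRUE)[[1]])
    expect_true(validate_list(recall_list("digit", tgt))$valid)
    expect_equal(score_serial_positions(tgt, rsp)$n_correct,
                 dig$n_correct[i])
  }
})

test_that("group accuracies land on the study conditions", {
  an <- fixture_analysis()
  sent <- 100 * colMeans(an$sentence_accuracy)
  expect_lt(abs(sent[1] - 88.1), 3)
  expect_lt(abs(sent[2] - 77.1), 3)
  expect_lt(abs(sent[3] - 39.1), 3)
  # digit recall is insensitive to spectral resolution
  dig <- 100 * colMeans(an$digit_accuracy)
  expect_lt(max(dig) - min(dig), 2)
  expect_lt(abs(mean(dig) - 81), 4)
  # word recall declines with channels; a single cohort of 32 carries
  # a between-cohort SD near 3 points at 4 channels, hence the band
  wrd <- 100 * colMeans(an$word_accuracy)
  expect_true(all(diff(wrd) < 0))
  expect_lt(abs(wrd[3] - 65), 7)
})

test_that("zeroing the ability loading collapses between-participant spread", {
  stim <- fixture_stimuli()
  cfg <- cohort_config(seed = 21)
  cfg0 <- cohort_config(seed = 21, digit_loading = 0, word_loading = 0,
                        recall_noise_sd = 0)
  pr <- sample_cohort(cfg)
  tr1 <- simulate_recall_trials(pr, cfg, stimuli = stim)$trials
  tr0 <- simulate_recall_trials(pr, cfg0, stimuli = stim)$trials
  sd_of <- function(tr) {
    s <- summarize_accuracy(tr[tr$kind == "digit" & tr$condition == "ch16", ])
    stats::sd(s$mean_proportion)
  }
  expect_lt(sd_of(tr0), sd_of(tr1))
  # binomial-only level: sqrt(p(1-p)/n_slots) with ~88 slots
  s0 <- summarize_accuracy(tr0[tr0$kind == "digit" &
                                 tr0$condition == "ch16", ])
  p_hat <- mean(s0$mean_proportion)
  expect_lt(sd_of(tr0), 2.5 * sqrt(p_hat * (1 - p_hat) / 88))
})

test_that("reaction-time costs centre on the configured study values", {
  an <- fixture_analysis()
  tests <- an$rt$tests
  sw <- tests[tests$cost == "switch_cost", ]
  expect_lt(abs(sw$median_ms - 145), 25)
  expect_gt(sw$Z, 4.5)
  inc_neu <- tests[tests$cost == "stroop_incongruent_neutral", ]
  expect_lt(abs(inc_neu$median_ms - 153), 30)
  inc_con <- tests[tests$cost == "stroop_incongruent_congruent", ]
  expect_lt(abs(inc_con$median_ms - 137), 30)
})

test_that("contaminant trials exercise the trimmer", {
  sess <- fixture_session()
  expect_gt(sum(an <- fixture_analysis()$rt$trim$n_removed), 0)
})
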