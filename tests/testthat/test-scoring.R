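test_that("serial position scoring credits exact positions only", {
  expect_equal(score_serial_positions(c(1, 2, 3), c(1, 2, 3))$proportion, 1)
  expect_equal(score_serial_positions(c(2, 7, 5, 9), c(2, 5, 7, 9))$proportion,
               0.5)
  s <- score_serial_positions(c(3, 8), c(3))
  expect_equal(c(s$n_correct, s$n_slots), c(1, 2))
  # surplus response items are ignored
  expect_equal(score_serial_positions(c(3, 8), c(3, 8, 5, 5))$proportion, 1)
  expect_error(score_serial_positions(integer(0), 1), "non-empty")
})

test_that("word scoring gives phoneme-level partial credit", {
  expect_equal(score_word_phonemes(list(c("m", "ae", "p")),
                                   list(c("s", "ae", "p")))$proportion, 2 / 3)
  tgt <- list(c("sh", "iy", "p"), c("m", "ae", "p"))
  expect_equal(score_word_phonemes(tgt, tgt)$proportion, 1)
  resp <- list(c("sh", "iy", "p"), c("m", "ae", "ch"))
  expect_equal(score_word_phonemes(tgt, resp)$proportion, 5 / 6)
  # malformed response word: aligned slots scored, flagged
  s <- score_word_phonemes(tgt, list(c("sh", "iy"), c("m", "ae", "ch")))
  expect_equal(s$n_correct, 4)
  expect_true(any(grepl("2 phonemes", s$flags)))
})

test_that("key-word scoring is order-free, one-to-one and exact-form", {
  expect_equal(score_keywords(c("dog", "ran", "park"),
                              "the dog ran to the park")$proportion, 1)
  expect_equal(score_keywords(c("red", "red"), c("one", "red"))$proportion,
               0.5)
  expect_equal(score_keywords("walked", "walk")$proportion, 0)
  expect_equal(score_keywords(c("Dog."), c("dog"))$proportion, 1)
})

test_that("scorers agree with an independent slot-by-slot oracle", {
  oracle_serial <- function(target, response) {
    hits <- 0
    for (i in seq_along(target)) {
      if (i <= length(response) && response[i] == target[i]) hits <- hits + 1
    }
    hits
  }
  withr::with_seed(7, {
    for (i in 1:3000) {
      n <- sample(2:9, 1)
      tgt <- sample(1:9, n, replace = TRUE)
      k <- sample(0:(n + 1), 1)
      resp <- sample(1:9, k, replace = TRUE)
      s <- score_serial_positions(tgt, resp)
      expect_identical(s$n_correct, as.integer(oracle_serial(tgt, resp)))
    }
  })
})

test_that("pooled aggregation weights by slots and stays bounded", {
  t1 <- trial_score(4, 2)
  t2 <- trial_score(4, 4)
  agg <- aggregate_condition_accuracy(list(t1, t2))
  expect_equal(agg$mean_proportion, 0.75)
  # unweighted alternative
  t3 <- trial_score(10, 10)
  pooled <- aggregate_condition_accuracy(list(t1, t3))$mean_proportion
  trialwise <- aggregate_condition_accuracy(list(t1, t3),
                                            weights = "trial")$mean_proportion
  expect_equal(pooled, 12 / 14)
  expect_equal(trialwise, 0.75)
  expect_error(aggregate_condition_accuracy(list()), "at least one")
  # bounds: pooled proportion lies between the extreme trial proportions
  withr::with_seed(3, {
    for (i in 1:200) {
      ts <- lapply(1:5, function(j) {
        n <- sample(1:20, 1)
        trial_score(n, sample(0:n, 1))
      })
      p <- aggregate_condition_accuracy(ts)$mean_proportion
      props <- vapply(ts, function(t) t$proportion, numeric(1))
      expect_gte(p, min(props))
      expect_lte(p, max(props))
    }
  })
})

test_that("shuffling a correct response never raises the serial score", {
  withr::with_seed(9, {
    for (i in 1:300) {
      n <- sample(3:9, 1)
      tgt <- sample(1:9, n, replace = TRUE)
      base <- score_serial_positions(tgt, tgt)$n_correct
      shuf <- score_serial_positions(tgt, sample(tgt))$n_correct
      expect_lte(shuf, base)
    }
  })
})

test_that("each sentence condition carries 152 key-word slots", {
  sess <- fixture_session()
  sent <- sess$trials[sess$trials$kind == "sentence", ]
  expect_true(all(sent$n_slots == 152))
})
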