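test_that("digit lists exclude runs and repeats, uniformly", {
  # enumeration oracle: valid length-2 sequences over digits 1-9
  valid_pairs <- expand.grid(a = 1:9, b = 1:9)
  valid_pairs <- valid_pairs[abs(valid_pairs$a - valid_pairs$b) > 1, ]
  expect_equal(nrow(valid_pairs), 56)

  withr::with_seed(1, {
    for (i in 1:200) {
      L <- sample(2:9, 1)
      d <- generate_digit_list(L)$items
      expect_true(all(abs(diff(d)) > 1))
    }
  })
  expect_identical(generate_digit_list(7, seed = 3)$items,
                   generate_digit_list(7, seed = 3)$items)
  expect_error(generate_digit_list(1), "between 2 and 9")
  expect_error(generate_digit_list(10), "between 2 and 9")
})

test_that("length-2 digit draws are uniform over the 56 valid pairs", {
  n <- 50000
  draws <- withr::with_seed(42, {
    vapply(seq_len(n), function(i) {
      d <- generate_digit_list(2)$items
      paste(d, collapse = "-")
    }, character(1))
  })
  counts <- table(draws)
  expect_equal(length(counts), 56)
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 0.01)
})

test_that("the validator reports each violated rule by name", {
  v <- validate_list(recall_list("digit", c(2, 3, 7)))
  expect_false(v$valid)
  expect_true(any(grepl("±1 transition", v$violations)))
  v2 <- validate_list(recall_list("digit", c(4, 2, 9, 6)))
  expect_true(v2$valid)
  expect_length(v2$violations, 0)
  # repeated vowel across words in a list
  w <- data.frame(orthography = c("dip", "mip"),
                  initial = c("d", "m"), vowel = c("iy", "iy"),
                  final = c("p", "w"), stringsAsFactors = FALSE)
  v3 <- validate_list(recall_list("word", w))
  expect_false(v3$valid)
  expect_true(any(grepl("vowel repeated in position 2", v3$violations)))
  # conforming hand-built word list
  w4 <- data.frame(orthography = c("dap", "mees"),
                   initial = c("d", "m"), vowel = c("ae", "iy"),
                   final = c("p", "s"), stringsAsFactors = FALSE)
  expect_true(validate_list(recall_list("word", w4))$valid)
})

test_that("generated word lists satisfy every design constraint", {
  wl <- fixture_word_lists()
  u <- word_usage(wl)
  n_blocks <- length(wl$blocks)
  expect_true(all(u[, seq_len(n_blocks)] %in% 3:4))
  expect_true(all(u[, "total"] %in% c(10, 11)))
  for (b in seq_len(n_blocks)) {
    for (li in seq_along(wl$blocks[[b]])) {
      expect_true(validate_list(word_list_at(wl, b, li))$valid)
    }
  }
  # a length-6 list uses six of the seven vowels
  six <- which(wl$lengths == 6)[1]
  expect_equal(length(unique(word_list_at(wl, 1, six)$items$vowel)), 6)
})

test_that("equal-length word lists are balanced on lexical attributes", {
  wl <- fixture_word_lists()
  inv <- wl$inventory
  for (L in sort(unique(wl$lengths))) {
    md <- mf <- numeric(0)
    for (b in seq_along(wl$blocks)) {
      for (li in which(wl$lengths == L)) {
        idx <- wl$blocks[[b]][[li]]
        md <- c(md, mean(inv$neighborhood_density[idx]))
        mf <- c(mf, mean(inv$log_frequency[idx]))
      }
    }
    expect_lt(diff(range(md)) / stats::sd(inv$neighborhood_density), 0.5)
    expect_lt(diff(range(mf)) / stats::sd(inv$log_frequency), 0.5)
  }
})

test_that("infeasible usage constraints fail with a diagnostic", {
  inv <- fixture_inventory()
  expect_error(generate_word_lists(inv, lengths_per_block = rep(1:6, 2)),
               "infeasible usage")
})

test_that("presentation orders respect adjacency and first-trial rules", {
  lens <- rep(1:6, each = 10)
  ord <- order_block(lens, kind = "word", seed = 1)
  expect_setequal(ord, seq_along(lens))
  out <- lens[ord]
  expect_true(all(diff(out) != 0))
  expect_lte(out[1], 4)
  dl <- rep(2:9, each = 2)
  od <- order_block(dl, kind = "digit", seed = 2)
  expect_true(all(diff(dl[od]) != 0))
  expect_lte(dl[od][1], 6)
  # enumeration oracle: {2,2,3} only admits 2,3,2
  for (s in 1:10) {
    o <- order_block(c(2, 2, 3), kind = "digit", seed = s)
    expect_equal(c(2, 2, 3)[o], c(2, 3, 2))
  }
  expect_error(order_block(c(5, 5), kind = "digit"), "no valid")
})

test_that("word inventories load with homophone resolution", {
  inv <- fixture_inventory()
  expect_equal(nrow(inv), 60)
  path <- tempfile(fileext = ".csv")
  write_word_inventory(inv, path)
  inv2 <- read_word_inventory(path)
  expect_equal(nrow(inv2), 60)
  expect_setequal(inv2$orthography, inv$orthography)
  # duplicate phoneme triple: the higher-frequency homophone wins
  dup <- as.data.frame(inv)[c(1, 1), ]
  dup$log_frequency <- c(1.0, 3.0)
  dup$orthography <- c("lowfreq", "highfreq")
  both <- rbind(as.data.frame(inv)[-1, ], dup)
  write.csv(both, path, row.names = FALSE)
  inv3 <- read_word_inventory(path)
  expect_equal(nrow(inv3), 60)
  expect_true("highfreq" %in% inv3$orthography)
  expect_false("lowfreq" %in% inv3$orthography)
})
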