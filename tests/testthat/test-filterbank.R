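test_that("channel presets merge the printed master edges", {
  fb16 <- build_filterbank(16)
  expect_equal(c(fb16$low[1], fb16$high[1]), c(100, 164))
  expect_equal(c(fb16$low, fb16$high[16]), study_edges())
  fb8 <- build_filterbank(8)
  expect_equal(c(fb8$low, fb8$high[8]),
               c(100, 245, 475, 842, 1425, 2352, 3828, 6175, 10000))
  fb4 <- build_filterbank(4)
  expect_equal(c(fb4$low, fb4$high[4]),
               c(100, 475, 1425, 3828, 10000))
})

test_that("filterbanks tile the analysis range without gaps or overlap", {
  for (n in c(1, 2, 4, 8, 16)) {
    fb <- build_filterbank(n)
    expect_equal(fb$low[1], 100)
    expect_equal(fb$high[n], 10000)
    if (n > 1) expect_equal(fb$low[-1], fb$high[-n])
  }
})

test_that("impossible merges and bad specs are rejected", {
  expect_error(build_filterbank(3), "divisible")
  expect_error(build_filterbank(0), "positive")
  expect_error(vocoder_spec(edges = c(100, 100, 200)), "increasing")
  expect_error(vocoder_spec(8, envelope_cutoff = -1), "positive")
})

test_that("vocoder specs round-trip through JSON", {
  spec <- vocoder_spec(8, seed = 42, envelope_cutoff = 250)
  path <- tempfile(fileext = ".json")
  write_vocoder_spec(spec, path)
  spec2 <- read_vocoder_spec(path)
  expect_equal(spec2$edges, spec$edges)
  expect_equal(spec2$envelope_cutoff, 250)
  expect_equal(spec2$seed, 42L)
})
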