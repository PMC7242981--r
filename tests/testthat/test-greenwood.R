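test_that("frequency-place map inverts and increases monotonically", {
  x <- seq(0, 1, by = 0.05)
  expect_equal(greenwood_position(greenwood_frequency(x)), x,
               tolerance = 1e-9)
  f <- greenwood_frequency(x)
  expect_true(all(diff(f) > 0))
  # apex frequency with the standard human constants
  expect_equal(greenwood_frequency(0), 165.4 * (1 - 0.88), tolerance = 1e-9)
  expect_lt(abs(greenwood_frequency(0) - 19.85), 0.01)
  expect_error(greenwood_frequency(-0.1), "0, 1")
  expect_error(greenwood_frequency(1.5), "0, 1")
})

test_that("study filter edges cover equal cochlear extent", {
  sp <- greenwood_spacing(study_edges())
  expect_lt(sp$max_deviation, 0.05)
  # the alternative map constant k = 1 does not satisfy the check
  sp1 <- greenwood_spacing(study_edges(), k = 1)
  expect_gt(sp1$max_deviation, 0.05)
})
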