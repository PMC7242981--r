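test_that("WAV files round-trip at every supported bit depth", {
  x <- audio_signal(sin(2 * pi * 440 * (0:7999) / 8000) * 0.8, 8000)
  for (bits in c(16, 24, 32)) {
    path <- tempfile(fileext = ".wav")
    write_wav(x, path, bits = bits)
    y <- read_wav(path)
    expect_equal(y$rate, 8000)
    expect_equal(length(y$samples), 8000)
    # 32-bit float carries ~7 significant digits
    tol <- switch(as.character(bits), "16" = 1e-4, "24" = 1e-6, "32" = 1e-6)
    expect_equal(y$samples, x$samples, tolerance = tol)
  }
})

test_that("malformed audio input is rejected", {
  expect_error(audio_signal(c(0, NA), 8000), "finite")
  expect_error(audio_signal(0, -1), "positive")
  path <- tempfile(fileext = ".wav")
  writeBin(as.raw(1:32), path)
  expect_error(read_wav(path), "RIFF")
})
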