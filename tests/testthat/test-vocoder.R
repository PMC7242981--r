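fs <- 44100
t1 <- seq(0, 1, length.out = fs)

test_that("slow amplitude modulation survives envelope extraction", {
  am <- (1 + sin(2 * pi * 10 * t1)) / 2
  x <- audio_signal(sin(2 * pi * 1000 * t1) * am, fs)
  env <- extract_envelope(x, c(842, 1099))
  core <- seq(5000, fs - 5000)
  expect_gt(stats::cor(env[core], am[core]), 0.95)
  # spectral peak of the envelope sits at the imposed modulation rate
  spec <- Mod(stats::fft(env - mean(env)))[2:100]
  expect_equal(which.max(spec), 10, tolerance = 1)
  # recovered modulation depth
  e <- env[core]
  expect_gt((max(e) - min(e)) / (max(e) + min(e)), 0.9)
})

test_that("modulation above the envelope cutoff is attenuated", {
  # 650 Hz AM on a 5 kHz carrier keeps both sidebands inside the wide
  # (3828, 6175) band, so any residual modulation reflects the 300 Hz
  # envelope low-pass, not band-edge filtering
  am <- (1 + sin(2 * pi * 650 * t1)) / 2
  x <- audio_signal(sin(2 * pi * 5000 * t1) * am, fs)
  env <- extract_envelope(x, c(3828, 6175))
  e <- env[seq(5000, fs - 5000)]
  expect_lt((max(e) - min(e)) / (max(e) + min(e)), 0.2)
})

test_that("an unmodulated in-band tone has a flat envelope", {
  x <- audio_signal(sin(2 * pi * 1000 * t1), fs)
  env <- extract_envelope(x, c(842, 1099))
  e <- env[seq(5000, fs - 5000)]
  expect_lt(stats::sd(e) / mean(e), 0.05)
})

test_that("silence vocodes to silence and envelopes are non-negative", {
  s <- audio_signal(rep(0, fs / 2), fs)
  expect_equal(max(abs(vocode(s, vocoder_spec(4, seed = 1))$samples)), 0)
  x <- audio_signal(rnorm(fs / 2), fs)
  env <- extract_envelope(x, c(475, 842))
  expect_true(all(env >= 0))
})

test_that("identical signal, spec and seed give bit-identical output", {
  x <- audio_signal(rnorm(fs / 2), fs)
  spec <- vocoder_spec(8, seed = 5)
  expect_identical(vocode(x, spec)$samples, vocode(x, spec)$samples)
  # a different carrier seed changes the waveform
  expect_false(identical(vocode(x, spec)$samples,
                         vocode(x, vocoder_spec(8, seed = 6))$samples))
})

test_that("channel energy stays in the channel and level is preserved", {
  fb <- build_filterbank(8)
  set.seed(11)
  x <- audio_signal(rnorm(fs), fs)
  en_in <- band_energies(x, fb)
  nb <- audio_signal(x$samples - x$samples + 0, fs)  # placeholder
  # confine input noise to channel 4 and vocode
  confined <- vocode(x, vocoder_spec(edges = c(fb$low[4], fb$high[4]),
                                     seed = 2), confine = TRUE)
  nb <- audio_signal(confined$samples, fs)
  v <- vocode(nb, vocoder_spec(8, seed = 9))
  en <- band_energies(v, fb)
  expect_gt(en[4] / sum(en), 0.9)
  expect_equal(rms(v$samples), rms(nb$samples), tolerance = 1e-9)
})

test_that("out-of-range leakage of an impulse train is below 1 percent", {
  imp <- numeric(fs)
  imp[seq(1, fs, by = 441)] <- 1
  v <- vocode(audio_signal(imp, fs), vocoder_spec(16, seed = 3))
  X <- Mod(stats::fft(v$samples))^2
  f <- 0:(fs - 1)
  f <- ifelse(f > fs / 2, fs - f, f)
  expect_lt(sum(X[f < 100 | f > 10000]) / sum(X), 0.01)
})

test_that("merging adjacent analysis bands adds their energies", {
  set.seed(21)
  x <- audio_signal(rnorm(fs / 2), fs)
  e16 <- band_energies(x, build_filterbank(16))
  e8 <- band_energies(x, build_filterbank(8))
  e4 <- band_energies(x, build_filterbank(4))
  expect_equal(e16[c(TRUE, FALSE)] + e16[c(FALSE, TRUE)], e8,
               tolerance = 1e-10)
  expect_equal(e8[c(TRUE, FALSE)] + e8[c(FALSE, TRUE)], e4,
               tolerance = 1e-10)
})

test_that("domain errors are raised for impossible inputs", {
  x <- audio_signal(rnorm(8000), 8000)
  expect_error(extract_envelope(x, c(3828, 6175)), "Nyquist")
  expect_error(vocode(x, vocoder_spec(16, seed = 1)), "too low")
  expect_error(vocode(audio_signal(numeric(0), fs), vocoder_spec(4)),
               "finite|empty")
})

test_that("recording preprocessing is zero-phase and normalized", {
  tone <- audio_signal(sin(2 * pi * 1000 * t1), fs)
  p <- preprocess_recording(tone)
  expect_equal(max(abs(p$samples)), 0.9, tolerance = 1e-6)
  # zero-phase: cross-correlation peaks at zero lag
  core <- seq(2000, fs - 2000)
  cc <- stats::ccf(p$samples[core], tone$samples[core], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # a 50 Hz tone below the 80 Hz edge is strongly attenuated
  low <- audio_signal(sin(2 * pi * 50 * t1), fs)
  bf <- signal::butter(4, c(80, 20000) / (fs / 2), "pass")
  y <- as.numeric(signal::filtfilt(bf, low$samples))
  expect_lt(rms(y) / rms(low$samples), 0.15)
  expect_error(preprocess_recording(tone, high = fs), "Nyquist")
})
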