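# Noise-band channel vocoder.
#
# Analysis bands are "rectangular" filters: frequency-domain brick-wall
# masks (FFT, zero bins outside the band, inverse FFT), so channel
# boundaries are exact and adjacent channels tile the analysis range with
# no overlap. Band envelopes are extracted with the Hilbert transform
# (magnitude of the band-limited analytic signal), smoothed with a causal
# low-pass Butterworth filter, and re-imposed on band-limited unit-RMS
# Gaussian noise carriers. Channel products are summed, confined to the
# full analysis range, and RMS-matched to the input.

# Positive-frequency bin selector for an n-point FFT at rate fs.
# Bands use the half-open convention [low, high) so that tiling bands
# partition the spectrum exactly; `top` closes the interval at `high`
# for the last channel of a bank.
band_bins <- function(n, fs, low, high, top = FALSE) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f <- ifelse(f > fs / 2, f - fs, f)  # signed frequency of each bin
  af <- abs(f)
  if (top) af >= low & af <= high else af >= low & af < high
}

# Real brick-wall band-limited component of x.
brickwall_band <- function(x, fs, low, high, top = FALSE) {
  n <- length(x)
  X <- stats::fft(x)
  X[!band_bins(n, fs, low, high, top)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Hilbert envelope of the band-limited component: magnitude of the analytic
# signal whose spectrum keeps (doubled) positive in-band bins only.
band_hilbert_envelope <- function(x, fs, low, high, top = FALSE) {
  n <- length(x)
  X <- stats::fft(x)
  keep <- band_bins(n, fs, low, high, top)
  k <- 0:(n - 1)
  f <- k * fs / n
  positive <- f > 0 & f < fs / 2
  Y <- complex(real = rep(0, n))
  Y[keep & positive] <- 2 * X[keep & positive]
  # DC and Nyquist bins, if in band, enter once (real-valued components)
  special <- keep & !positive & (f == 0 | abs(f - fs / 2) < 1e-9)
  Y[special] <- X[special]
  Mod(stats::fft(Y, inverse = TRUE) / n)
}

check_band <- function(band, rate) {
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0) {
    stop_domain("band must be an ascending (low, high) pair in Hz")
  }
  if (band[2] > rate / 2) {
    stop_domain(sprintf("band edge %.0f Hz exceeds the Nyquist frequency %.0f Hz",
                        band[2], rate / 2))
  }
}

#' Extract the smoothed amplitude envelope of one analysis band
#'
#' Band-limits the signal with a rectangular (brick-wall) mask, takes the
#' Hilbert-transform magnitude, low-pass filters it with a causal
#' Butterworth filter at the spec's envelope cutoff, and clamps any small
#' negative filter output to zero.
#'
#' @param signal an [audio_signal()].
#' @param band numeric `(low, high)` pair in Hz.
#' @param spec a [vocoder_spec()]; supplies the envelope cutoff and order.
#' @param top logical; treat `high` as a closed (inclusive) edge, as for
#'   the highest channel of a bank.
#' @return non-negative numeric envelope, same length as the input.
#' @export
extract_envelope <- function(signal, band, spec = vocoder_spec(edges = band),
                             top = FALSE) {
  stopifnot(inherits(signal, "audio_signal"))
  check_band(band, signal$rate)
  if (length(signal$samples) < 8 * spec$envelope_order) {
    stop_domain("signal too short for envelope filtering")
  }
  env <- band_hilbert_envelope(signal$samples, signal$rate,
                               band[1], band[2], top)
  bf <- signal::butter(spec$envelope_order,
                       spec$envelope_cutoff / (signal$rate / 2), "low")
  sm <- as.numeric(signal::filter(bf, env))
  pmax(sm, 0)
}

#' Vocode a speech signal
#'
#' Applies the noise-band channel vocoder defined by `spec`: per channel,
#' band-limit, extract and smooth the Hilbert envelope, multiply with an
#' independent band-limited unit-RMS Gaussian noise carrier, then sum the
#' channel products, confine the sum to the full analysis range, and
#' rescale to the input RMS level. Carriers are drawn from one generator
#' seeded with `spec$seed`, in channel order, so identical
#' (signal, spec) pairs give bit-identical output.
#'
#' @param signal an [audio_signal()]; the rate must exceed twice the top
#'   analysis edge.
#' @param spec a [vocoder_spec()].
#' @param confine logical; brick-wall the summed output to the analysis
#'   range so no energy falls outside it (default TRUE).
#' @return an [audio_signal()] of the same length and rate.
#' @export
#' @examples
#' x <- audio_signal(rnorm(22050), 22050)
#' y <- vocode(x, vocoder_spec(4, seed = 7))
vocode <- function(signal, spec, confine = TRUE) {
  stopifnot(inherits(signal, "audio_signal"), inherits(spec, "vocoder_spec"))
  x <- signal$samples
  if (length(x) == 0) stop_domain("empty signal")
  edges <- spec$edges
  n_ch <- length(edges) - 1L
  top_edge <- edges[length(edges)]
  if (signal$rate <= 2 * top_edge) {
    stop_domain(sprintf(
      "sample rate %g Hz too low for top analysis edge %g Hz", signal$rate,
      top_edge))
  }
  n <- length(x)
  carriers <- with_seed(spec$seed, {
    lapply(seq_len(n_ch), function(ch) rnorm(n))
  })
  out <- numeric(n)
  for (ch in seq_len(n_ch)) {
    band <- c(edges[ch], edges[ch + 1])
    is_top <- ch == n_ch
    env <- extract_envelope(signal, band, spec, top = is_top)
    car <- brickwall_band(carriers[[ch]], signal$rate, band[1], band[2],
                          top = is_top)
    cr <- rms(car)
    if (cr > 0) car <- car / cr
    out <- out + env * car
  }
  if (confine) {
    out <- brickwall_band(out, signal$rate, edges[1], top_edge, top = TRUE)
  }
  in_rms <- rms(x)
  out_rms <- rms(out)
  if (in_rms > 0 && out_rms > 0) out <- out * (in_rms / out_rms)
  audio_signal(out, signal$rate)
}

#' Preprocess a raw recording
#'
#' Zero-phase (forward-and-reverse) Butterworth band-pass filtering
#' followed by peak normalization, the standard cleanup applied to recorded
#' stimulus tokens before use.
#'
#' @param signal an [audio_signal()].
#' @param low,high band-pass edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth design order per edge (default 4).
#' @param target_peak peak absolute amplitude after normalization
#'   (default 0.9 full scale).
#' @return an [audio_signal()].
#' @export
preprocess_recording <- function(signal, low = 80, high = 20000, order = 4,
                                 target_peak = 0.9) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!(low < high)) stop_domain("low must be below high")
  if (high >= signal$rate / 2) {
    stop_domain(sprintf("high edge %.0f Hz must be below Nyquist %.0f Hz",
                        high, signal$rate / 2))
  }
  bf <- signal::butter(order, c(low, high) / (signal$rate / 2), "pass")
  y <- as.numeric(signal::filtfilt(bf, signal$samples))
  peak <- max(abs(y))
  if (peak > 0) y <- y * (target_peak / peak)
  audio_signal(y, signal$rate)
}

#' Band energies of the analysis stage
#'
#' Energy (sum of squares) of the brick-wall band-limited component of a
#' signal in each channel of a filterbank. Because the bands tile the
#' analysis range exactly, merging adjacent channels adds their energies.
#'
#' @param signal an [audio_signal()].
#' @param filterbank data.frame from [build_filterbank()].
#' @return numeric vector of per-channel energies.
#' @export
band_energies <- function(signal, filterbank) {
  stopifnot(inherits(signal, "audio_signal"))
  n_ch <- nrow(filterbank)
  vapply(seq_len(n_ch), function(ch) {
    y <- brickwall_band(signal$samples, signal$rate,
                        filterbank$low[ch], filterbank$high[ch],
                        top = ch == n_ch)
    sum(y^2)
  }, numeric(1))
}
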