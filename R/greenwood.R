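# Greenwood cochlear frequency-place map.
#
# The human cochlea maps place of maximal excitation to characteristic
# frequency approximately as F = A * (10^(a*x) - k), with x the proportional
# distance from apex (0) to base (1). The standard human constants
# A = 165.4 Hz, a = 2.1, k = 0.88 are used by default. Channel edges spaced
# equally in x cover equal cochlear extent, which is the rationale for the
# vocoder filterbank spacing.

#' Greenwood frequency-place map
#'
#' Convert a proportional cochlear place (0 = apex, 1 = base) to
#' characteristic frequency in Hz, or back.
#'
#' @param position cochlear place proportion(s) in \[0, 1\].
#' @param frequency frequency value(s) in Hz.
#' @param A,a,k Greenwood map constants for the human cochlea.
#' @return `greenwood_frequency` returns frequency in Hz;
#'   `greenwood_position` returns place proportion.
#' @examples
#' greenwood_frequency(0.5)
#' greenwood_position(greenwood_frequency(0.5))
#' @export
greenwood_frequency <- function(position, A = 165.4, a = 2.1, k = 0.88) {
  if (any(!is.finite(position)) || any(position < 0) || any(position > 1)) {
    stop_domain("cochlear position must lie in [0, 1]")
  }
  A * (10^(a * position) - k)
}

#' @rdname greenwood_frequency
#' @export
greenwood_position <- function(frequency, A = 165.4, a = 2.1, k = 0.88) {
  if (any(!is.finite(frequency)) || any(frequency / A + k <= 0)) {
    stop_domain("frequency out of the range of the Greenwood map")
  }
  log10(frequency / A + k) / a
}

#' Check that filter edges are approximately equally spaced on the cochlea
#'
#' Maps a set of edge frequencies to cochlear place and reports the maximum
#' deviation from exact equal spacing, as a fraction of one spacing step.
#'
#' @param edges ascending edge frequencies in Hz.
#' @inheritParams greenwood_frequency
#' @return list with `positions`, `step` and `max_deviation` (fraction of a
#'   step).
#' @export
greenwood_spacing <- function(edges, A = 165.4, a = 2.1, k = 0.88) {
  x <- greenwood_position(edges, A = A, a = a, k = k)
  n <- length(x)
  step <- (x[n] - x[1]) / (n - 1)
  ideal <- x[1] + (seq_len(n) - 1) * step
  list(positions = x, step = step,
       max_deviation = max(abs(x - ideal)) / step)
}
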