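# Vocoder analysis filterbank: the normative 17-edge table and band merging.

#' Study master filter edges
#'
#' The 17 edge frequencies (Hz) delimiting the 16 analysis channels of the
#' high-resolution vocoder. Edges are approximately equally spaced on the
#' Greenwood cochlear map between 100 Hz and 10 kHz; lower channel counts
#' merge adjacent bands of this table.
#'
#' @return numeric vector of 17 ascending edge frequencies in Hz.
#' @export
#' @examples
#' study_edges()
study_edges <- function() {
  c(100, 164, 245, 346, 475, 637, 842, 1099, 1425, 1835,
    2352, 3005, 3828, 4866, 6175, 7826, 10000)
}

#' Build a channel filterbank by merging master edges
#'
#' Divides the full analysis range into `n_channels` contiguous bands by
#' keeping every (len-1)/n-th edge of the master table. The bands tile the
#' range exactly: each band's upper edge is the next band's lower edge.
#'
#' @param n_channels number of channels; must divide the number of master
#'   bands.
#' @param master_edges ascending edge frequencies; default [study_edges()].
#' @return data.frame with columns `low` and `high` (Hz), one row per channel.
#' @export
#' @examples
#' build_filterbank(8)
build_filterbank <- function(n_channels, master_edges = study_edges()) {
  if (!is_scalar_num(n_channels) || n_channels < 1 ||
      n_channels != round(n_channels)) {
    stop_domain("n_channels must be a positive integer")
  }
  if (length(master_edges) < 2 || any(diff(master_edges) <= 0) ||
      master_edges[1] < 0) {
    stop_domain("master_edges must be ascending and non-negative")
  }
  n_master <- length(master_edges) - 1L
  if (n_master %% n_channels != 0) {
    stop_domain(sprintf(
      "cannot merge %d master bands into %d channels: %d is not divisible by %d",
      n_master, n_channels, n_master, n_channels))
  }
  keep <- seq(1L, length(master_edges), by = n_master %/% n_channels)
  edges <- master_edges[keep]
  data.frame(low = edges[-length(edges)], high = edges[-1])
}

#' Vocoder specification
#'
#' Bundles the parameters defining one spectral-resolution condition:
#' analysis band edges, envelope low-pass cutoff and order, carrier type,
#' and the seed governing carrier noise.
#'
#' @param n_channels number of channels; used with `master_edges` to derive
#'   `edges` when `edges` is not given. The study presets are 4, 8 and 16.
#' @param edges explicit ascending edge vector (n_channels + 1 entries);
#'   overrides `n_channels`.
#' @param envelope_cutoff envelope low-pass cutoff in Hz (default 300).
#' @param envelope_order Butterworth order of the envelope low-pass
#'   (default 4).
#' @param carrier carrier type; only `"noise"` is supported.
#' @param seed integer seed for carrier generation.
#' @param master_edges master table used when deriving edges from
#'   `n_channels`.
#' @return an object of class `vocoder_spec`.
#' @export
#' @examples
#' vocoder_spec(8, seed = 1)
vocoder_spec <- function(n_channels = NULL, edges = NULL,
                         envelope_cutoff = 300, envelope_order = 4,
                         carrier = "noise", seed = 1,
                         master_edges = study_edges()) {
  if (is.null(edges)) {
    if (is.null(n_channels)) stop_domain("give either n_channels or edges")
    fb <- build_filterbank(n_channels, master_edges)
    edges <- c(fb$low, fb$high[nrow(fb)])
  }
  if (any(diff(edges) <= 0) || edges[1] < 0) {
    stop_domain("edges must be strictly increasing and non-negative")
  }
  if (!is_scalar_num(envelope_cutoff) || envelope_cutoff <= 0) {
    stop_domain("envelope_cutoff must be positive")
  }
  carrier <- match.arg(carrier, "noise")
  structure(list(edges = as.numeric(edges),
                 envelope_cutoff = envelope_cutoff,
                 envelope_order = as.integer(envelope_order),
                 carrier = carrier,
                 seed = as.integer(seed)),
            class = "vocoder_spec")
}

#' @export
print.vocoder_spec <- function(x, ...) {
  cat(sprintf("Noise-band vocoder spec: %d channels, %.0f-%.0f Hz\n",
              length(x$edges) - 1L, x$edges[1], x$edges[length(x$edges)]))
  cat(sprintf("  envelope low-pass: %.0f Hz Butterworth order %d (causal)\n",
              x$envelope_cutoff, x$envelope_order))
  cat(sprintf("  carrier: %s, seed %d\n", x$carrier, x$seed))
  invisible(x)
}

#' Read or write a vocoder spec as JSON
#'
#' @param path file path.
#' @param spec a [vocoder_spec()] object.
#' @return `read_vocoder_spec` returns a `vocoder_spec`;
#'   `write_vocoder_spec` returns `path` invisibly.
#' @export
read_vocoder_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocoder_spec(edges = cfg$edges,
               envelope_cutoff = cfg$envelope_cutoff %||% 300,
               envelope_order = cfg$envelope_order %||% 4,
               carrier = cfg$carrier %||% "noise",
               seed = cfg$seed %||% 1)
}

#' @rdname read_vocoder_spec
#' @export
write_vocoder_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
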