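# Word inventory for word-span lists.
#
# Span words are single-syllable consonant-vowel-consonant (CVC) items drawn
# from a restricted phoneme set chosen to minimize phonetic confusions under
# vocoding. Phonemes are written here in an ASCII transcription:
#   initial consonants: w d p s sh m f v ch h
#   final consonants:   w d p s sh m f v ch z
#   vowels:             ae aa ey eh iy ow uw
# ("sh" and "ch" are the postalveolar fricative/affricate; "h" occurs
# initially only and "z" finally only.)

#' Allowed phoneme sets for span words
#' @return named list with `initial`, `vowel`, `final` character vectors.
#' @export
span_phonemes <- function() {
  list(initial = c("w", "d", "p", "s", "sh", "m", "f", "v", "ch", "h"),
       vowel   = c("ae", "aa", "ey", "eh", "iy", "ow", "uw"),
       final   = c("w", "d", "p", "s", "sh", "m", "f", "v", "ch", "z"))
}

new_word_inventory <- function(df) {
  ph <- span_phonemes()
  need <- c("orthography", "initial", "vowel", "final",
            "neighborhood_density", "log_frequency")
  if (!all(need %in% names(df))) {
    stop_domain("inventory must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !(df$initial %in% ph$initial) | !(df$vowel %in% ph$vowel) |
    !(df$final %in% ph$final)
  if (any(bad)) {
    stop_domain("inventory rows with phonemes outside the allowed sets: ",
                paste(which(bad), collapse = ", "))
  }
  structure(df, class = c("word_inventory", "data.frame"))
}

#' Generate a synthetic CVC word inventory
#'
#' Builds a synthetic stand-in for a span-word inventory: unique CVC
#' phoneme triples from the allowed sets with balanced phoneme coverage,
#' pseudo-orthographies, and lexical attributes (neighborhood density,
#' log frequency) drawn from compact distributions so that attribute
#' balancing across lists is feasible, as it is for a curated real
#' inventory.
#'
#' @param n number of words (default 60).
#' @param seed integer seed.
#' @return a `word_inventory` data.frame.
#' @export
#' @examples
#' head(synthetic_word_inventory(seed = 1))
synthetic_word_inventory <- function(n = 60, seed = 1) {
  ph <- span_phonemes()
  spell <- c(ae = "a", aa = "o", ey = "ay", eh = "e", iy = "ee",
             ow = "oa", uw = "oo")
  with_seed(seed, {
    repeat {
      ini <- sample(rep(ph$initial, length.out = n))
      vow <- sample(rep(ph$vowel, length.out = n))
      fin <- sample(rep(ph$final, length.out = n))
      if (!anyDuplicated(paste(ini, vow, fin))) break
    }
    # a curated span inventory is selected for balance (the study picked
    # its 60 words from a larger candidate set precisely so lists could
    # be balanced), which this stand-in encodes as attribute symmetry:
    # deviations from the inventory centre come in antipodal pairs, so
    # every word has a near-mirror partner, and a core of
    # attribute-typical words sits near the centre
    half <- n %/% 2L
    ddev <- stats::rnorm(half, 0, 2.2)
    fdev <- stats::rnorm(half, 0, 0.35)
    core <- seq_len(max(1L, round(half / 5)))
    ddev[core] <- stats::runif(length(core), 0, 0.5)
    fdev[core] <- stats::runif(length(core), 0, 0.05)
    dens <- pmax(8, pmin(22, round(15 + c(ddev, -ddev))))
    lfrq <- round(pmax(1.2, pmin(3.8, 2.5 + c(fdev, -fdev))), 2)
    if (n %% 2L) {  # odd inventory: one exactly central word
      dens <- c(dens, 15)
      lfrq <- c(lfrq, 2.5)
    }
    ord <- seq_len(n)
    df <- data.frame(
      orthography = paste0(ini, spell[vow], fin),
      initial = ini, vowel = vow, final = fin,
      neighborhood_density = dens[ord],
      log_frequency = lfrq[ord],
      stringsAsFactors = FALSE)
    new_word_inventory(df)
  })
}

#' Read or write a word inventory
#'
#' Delimited text (CSV) with a schema comment line, columns orthography,
#' initial, vowel, final, neighborhood_density, log_frequency. On read,
#' duplicate phoneme triples (homophones) are resolved by keeping the
#' highest-frequency entry.
#'
#' @param path file path.
#' @param inventory a `word_inventory`.
#' @return `read_word_inventory` returns a `word_inventory`.
#' @export
read_word_inventory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  key <- paste(df$initial, df$vowel, df$final)
  if (anyDuplicated(key)) {
    # homophones: retain the highest-frequency member of each triple
    df <- df[order(key, -df$log_frequency), ]
    df <- df[!duplicated(paste(df$initial, df$vowel, df$final)), ]
    rownames(df) <- NULL
  }
  new_word_inventory(df)
}

#' @rdname read_word_inventory
#' @export
write_word_inventory <- function(inventory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vocospan word inventory; phonemes: ascii transcription", con)
  utils::write.csv(as.data.frame(inventory), con, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
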