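# Trial scoring: strict position-wise serial recall for digits, phoneme-
# level position-wise recall for CVC words, and order-free one-to-one
# key-word matching for sentences. Aggregation pools correct counts over
# slots, so longer lists carry proportionally more weight.

#' A scored trial
#'
#' @param n_slots number of scoreable slots in the trial.
#' @param n_correct number of slots scored correct.
#' @param flags optional character notes (e.g. malformed response tokens).
#' @return object of class `trial_score` with fields `n_slots`,
#'   `n_correct`, `proportion`.
#' @export
trial_score <- function(n_slots, n_correct, flags = character(0)) {
  stopifnot(n_correct <= n_slots, n_slots >= 1)
  structure(list(n_slots = as.integer(n_slots),
                 n_correct = as.integer(n_correct),
                 proportion = n_correct / n_slots,
                 flags = flags),
            class = "trial_score")
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf("trial score: %d/%d = %.3f\n", x$n_correct, x$n_slots,
              x$proportion))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Score a serial-recall trial position by position
#'
#' Slot i is correct exactly when the response has an item at position i
#' equal to the target's item there. Missing positions are incorrect;
#' surplus response items are ignored. Every target position is a slot.
#'
#' @param target item sequence presented (non-empty vector).
#' @param response item sequence reported (may be shorter, longer, empty).
#' @return a [trial_score()].
#' @export
#' @examples
#' score_serial_positions(c(2, 7, 5, 9), c(2, 5, 7, 9))  # 2/4
score_serial_positions <- function(target, response) {
  if (length(target) == 0) stop_domain("target must be non-empty")
  n <- length(target)
  k <- min(n, length(response))
  correct <- if (k > 0) sum(target[seq_len(k)] == response[seq_len(k)]) else 0L
  trial_score(n, correct)
}

#' Score a word-recall trial phoneme by phoneme
#'
#' Words are consonant-vowel-consonant triples; each of the three phoneme
#' positions of each target word is a slot, so partially correct words earn
#' partial credit. The response word at position i is compared
#' phoneme-by-phoneme against the target word there; missing words score
#' zero, malformed response tokens (not 3 phonemes) are scored against
#' their aligned slots only and flagged.
#'
#' @param target list of character vectors of length 3 (initial, vowel,
#'   final), or a data.frame with columns `initial`, `vowel`, `final`.
#' @param response same structure as `target`.
#' @return a [trial_score()].
#' @export
#' @examples
#' score_word_phonemes(list(c("m", "ae", "p")), list(c("s", "ae", "p")))
score_word_phonemes <- function(target, response) {
  as_phoneme_list <- function(x) {
    if (is.data.frame(x)) {
      lapply(seq_len(nrow(x)),
             function(i) c(x$initial[i], x$vowel[i], x$final[i]))
    } else x
  }
  target <- as_phoneme_list(target)
  response <- as_phoneme_list(response)
  if (length(target) == 0) stop_domain("target must be non-empty")
  if (any(lengths(target) != 3)) {
    stop_domain("target words must have exactly 3 phonemes")
  }
  flags <- character(0)
  n_slots <- 3L * length(target)
  correct <- 0L
  for (i in seq_along(target)) {
    if (i > length(response)) break
    resp <- response[[i]]
    if (length(resp) != 3) {
      flags <- c(flags, sprintf("response word %d has %d phonemes", i,
                                length(resp)))
    }
    k <- min(3L, length(resp))
    if (k > 0) correct <- correct + sum(target[[i]][seq_len(k)] ==
                                          resp[seq_len(k)])
  }
  trial_score(n_slots, correct, flags)
}

normalize_token <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9']", "", x)
}

#' Score a sentence trial by key words
#'
#' Order-free, one-to-one matching: after case folding and punctuation
#' stripping, each key word is matched against at most one response token
#' and each response token can satisfy at most one key word. Matching is
#' exact in form; no credit for morphological variants.
#'
#' @param keywords character vector of scoring key words (non-empty).
#' @param response character vector of response tokens, or a single string
#'   that is split on whitespace.
#' @return a [trial_score()].
#' @export
#' @examples
#' score_keywords(c("dog", "ran", "park"), "the dog ran to the park")
score_keywords <- function(keywords, response) {
  if (length(keywords) == 0) stop_domain("keywords must be non-empty")
  if (length(response) == 1 && grepl("\\s", response)) {
    response <- strsplit(response, "\\s+")[[1]]
  }
  kw <- normalize_token(keywords)
  rsp <- normalize_token(response)
  rsp <- rsp[nzchar(rsp)]
  correct <- 0L
  for (w in kw) {
    hit <- match(w, rsp)
    if (!is.na(hit)) {
      correct <- correct + 1L
      rsp <- rsp[-hit]
    }
  }
  trial_score(length(kw), correct)
}

#' Aggregate trial scores into a condition summary
#'
#' Pools correct counts over all slots of all trials in a condition:
#' the summary proportion is sum(n_correct) / sum(n_slots), so each slot
#' carries equal weight regardless of list length. A mean of per-trial
#' proportions is available behind `weights = "trial"`.
#'
#' @param trials a list of [trial_score()] objects, or a data.frame with
#'   columns `n_slots` and `n_correct`.
#' @param participant,condition,kind optional labels stored in the result.
#' @param weights `"slots"` (pooled counts, default) or `"trial"`
#'   (unweighted mean of trial proportions).
#' @return object of class `condition_summary` with `mean_proportion`,
#'   `n_trials`, `n_slots`, `n_correct` and the labels.
#' @export
#' @examples
#' t1 <- trial_score(4, 2); t2 <- trial_score(4, 4)
#' aggregate_condition_accuracy(list(t1, t2))$mean_proportion  # 0.75
aggregate_condition_accuracy <- function(trials, participant = NA,
                                         condition = NA, kind = NA,
                                         weights = c("slots", "trial")) {
  weights <- match.arg(weights)
  if (inherits(trials, "trial_score")) trials <- list(trials)
  if (is.data.frame(trials)) {
    slots <- trials$n_slots; corr <- trials$n_correct
  } else {
    if (length(trials) == 0) stop_domain("at least one trial is required")
    slots <- vapply(trials, function(t) t$n_slots, numeric(1))
    corr <- vapply(trials, function(t) t$n_correct, numeric(1))
  }
  if (length(slots) == 0) stop_domain("at least one trial is required")
  mp <- if (weights == "slots") sum(corr) / sum(slots)
        else mean(corr / slots)
  structure(list(participant = participant, condition = condition,
                 kind = kind, mean_proportion = mp,
                 n_trials = length(slots), n_slots = sum(slots),
                 n_correct = sum(corr), weights = weights),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition summary [%s/%s/%s]: %.3f over %d trials (%d/%d slots)\n",
              x$participant, x$condition, x$kind, x$mean_proportion,
              x$n_trials, x$n_correct, x$n_slots))
  invisible(x)
}
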