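# Constrained recall-list generation.
#
# Digit lists (2-9 items, digits 1-9) exclude all adjacent transitions of
# |difference| <= 1, including immediate repeats, to discourage chunking of
# runs. Word lists (1-6 CVC words) never repeat a phoneme in the same
# word-level position within a list, reuse each inventory word 3 or 4 times
# per block (10 or 11 times across three blocks), and are balanced so that
# lists of equal length have similar mean neighborhood density and log
# frequency. Presentation orders never repeat a list length twice in a row
# and start each block with an easy trial.

#' A recall trial list
#'
#' @param kind `"digit"` or `"word"`.
#' @param items for digits, an integer vector; for words, a data.frame of
#'   inventory rows (columns orthography, initial, vowel, final).
#' @param condition optional spectral-resolution label.
#' @return object of class `recall_list`.
#' @export
recall_list <- function(kind = c("digit", "word"), items, condition = NA) {
  kind <- match.arg(kind)
  structure(list(kind = kind, items = items, condition = condition),
            class = "recall_list")
}

#' @export
print.recall_list <- function(x, ...) {
  lab <- if (x$kind == "digit") paste(x$items, collapse = " ")
         else paste(x$items$orthography, collapse = " ")
  cat(sprintf("%s list (%d items): %s\n", x$kind,
              if (x$kind == "digit") length(x$items) else nrow(x$items), lab))
  invisible(x)
}

#' Generate a digit-span list
#'
#' Rejection-samples uniformly over digit sequences of the requested length
#' in which no adjacent pair differs by one or less (runs like 4,5 and
#' immediate repeats are both excluded).
#'
#' @param length list length, 2 to 9.
#' @param digits digit alphabet (default 1:9).
#' @param seed optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return a `recall_list` of kind `"digit"`.
#' @export
#' @examples
#' generate_digit_list(5, seed = 1)
generate_digit_list <- function(length, digits = 1:9, seed = NULL) {
  if (!is_scalar_num(length) || length < 2 || length > 9) {
    stop_domain("digit list length must be between 2 and 9")
  }
  draw <- function() {
    repeat {
      x <- sample(digits, length, replace = TRUE)
      if (all(abs(diff(x)) > 1)) return(x)
    }
  }
  items <- if (is.null(seed)) draw() else with_seed(seed, draw())
  recall_list("digit", items)
}

# ---- word-list generation ------------------------------------------------

# Assign per-block usage quotas: each word used `per_block` (3 or 4) times
# in every block and `total` (10 or 11) times overall. Returns an
# n_words x n_blocks integer matrix.
assign_quotas <- function(n_words, slots_per_block, n_blocks,
                          per_block = c(3L, 4L), total = c(10L, 11L)) {
  lo_b <- min(per_block); hi_b <- max(per_block)
  lo_t <- min(total); hi_t <- max(total)
  total_slots <- slots_per_block * n_blocks
  if (total_slots < lo_t * n_words || total_slots > hi_t * n_words ||
      slots_per_block < lo_b * n_words || slots_per_block > hi_b * n_words) {
    stop_domain(sprintf(
      paste0("infeasible usage constraints: %d slots/block x %d blocks for ",
             "%d words cannot give per-block counts in {%d,%d} and totals ",
             "in {%d,%d}"),
      slots_per_block, n_blocks, n_words, lo_b, hi_b, lo_t, hi_t))
  }
  n_hi_total <- total_slots - lo_t * n_words       # words receiving hi_t uses
  base_extra <- lo_t - lo_b * n_blocks             # fours owed per word
  extras <- rep(base_extra, n_words)
  if (n_hi_total > 0) extras[sample.int(n_words, n_hi_total)] <- base_extra + 1L
  need_b <- rep(slots_per_block - lo_b * n_words, n_blocks)  # fours per block
  q <- matrix(lo_b, n_words, n_blocks)
  for (w in sample.int(n_words)) {
    k <- extras[w]
    if (k == 0) next
    pick <- order(-(need_b + stats::runif(n_blocks, 0, 0.5)))[seq_len(k)]
    if (any(need_b[pick] <= 0)) stop_domain("quota assignment failed")
    q[w, pick] <- hi_b
    need_b[pick] <- need_b[pick] - 1L
  }
  if (any(need_b != 0)) stop_domain("quota assignment failed")
  q
}

# Build the lists of one block by constrained, balance-aware random
# assignment. Order of construction: singletons cluster around a shared
# central seed word; length-2 lists pair medium-extremity anchors with
# antipodal partners; length-3 lists close an anchored pair with a
# compensating word; 6- and 5-item lists are then built greedily -- each
# anchored on an extreme remaining word and completed by near-mirror
# picks that cancel the running deviation, so attribute outliers are
# burned in pairs while the pool is rich. The 4-item lists are dealt
# LAST, jointly, from the leftover quota multiset: a word with k
# remaining uses goes to k different lists, so leftover concentration
# can never dead-end, and 4-item lists need only 4 distinct phonemes per
# position, the loosest distinctness constraint of any class. A phoneme
# budget guard keeps the leftover pool feasible (no phoneme may exceed
# one unit per dealt list), and a final exchange polish clears residual
# clashes and tightens the dealt list means.
build_block_lists <- function(inventory, lengths, quota, centrality,
                              max_list_restarts = 25) {
  dens <- inventory$neighborhood_density
  freq <- inventory$log_frequency
  dev_d <- (dens - mean(dens)) / stats::sd(dens)
  dev_f <- (freq - mean(freq)) / stats::sd(freq)
  extremity <- pmax(abs(dev_d), abs(dev_f))
  lists <- vector("list", length(lengths))
  q <- quota
  phon_cols <- c("initial", "vowel", "final")
  pcount <- lapply(phon_cols, function(col) {
    vals <- unique(inventory[[col]])
    cnt <- vapply(vals, function(v) sum(q[inventory[[col]] == v]),
                  numeric(1))
    names(cnt) <- vals
    cnt
  })
  names(pcount) <- phon_cols
  take <- function(w) {
    q[w] <<- q[w] - 1L
    for (col in phon_cols) {
      pcount[[col]][inventory[[col]][w]] <<-
        pcount[[col]][inventory[[col]][w]] - 1
    }
  }
  untake <- function(ws) {
    q[ws] <<- q[ws] + 1L
    for (w in ws) for (col in phon_cols) {
      pcount[[col]][inventory[[col]][w]] <<-
        pcount[[col]][inventory[[col]][w]] + 1
    }
  }
  n_clash <- function(w, chosen) {
    sum(inventory$initial[w] == inventory$initial[chosen]) +
      sum(inventory$vowel[w] == inventory$vowel[chosen]) +
      sum(inventory$final[w] == inventory$final[chosen])
  }
  dealt <- which(lengths == 4L)
  deal_units <- sum(lengths[dealt])
  # phoneme budget guard: the dealt lists can host at most one unit of
  # any phoneme value each, so when remaining non-dealt picks only just
  # cover a phoneme surplus, candidates are steered to surplus phonemes
  burn_filter <- function(cand) {
    if (!length(dealt) || !length(cand)) return(cand)
    R <- sum(q) - deal_units
    keep_any <- rep(FALSE, length(cand))
    engaged <- FALSE
    for (col in phon_cols) {
      surplus <- pmax(pcount[[col]] - length(dealt), 0)
      if (sum(surplus) > 0 && sum(surplus) >= R - 20) {
        engaged <- TRUE
        keep_any <- keep_any |
          pcount[[col]][inventory[[col]][cand]] > length(dealt)
      }
    }
    if (engaged && any(keep_any)) cand[keep_any] else cand
  }
  medium_anchor <- function(cand) {
    pool <- cand[extremity[cand] <= 0.8]
    if (!length(pool)) pool <- cand
    pool[order(-extremity[pool], stats::runif(length(pool)))[1]]
  }
  # --- singletons: quota units clustered around the shared seed word
  for (li in which(lengths == 1L)) {
    cand <- which(q > 0)
    if (!length(cand)) stop_domain("word quota exhausted early")
    pick <- cand[order(centrality[cand], stats::runif(length(cand)))[1]]
    lists[[li]] <- pick
    take(pick)
  }
  # --- pairs: medium-extremity anchor + antipodal partner
  pairs <- which(lengths == 2L)
  for (li in if (length(pairs)) pairs[sample.int(length(pairs))] else pairs) {
    cand <- which(q > 0)
    if (length(cand) < 2) stop_domain("word quota exhausted early")
    w1 <- medium_anchor(burn_filter(cand))
    partners <- burn_filter(cand[cand != w1])
    if (!length(partners)) stop_domain("word quota exhausted early")
    cl <- vapply(partners, n_clash, numeric(1), chosen = w1)
    mis <- pmax(abs(dev_d[w1] + dev_d[partners]),
                abs(dev_f[w1] + dev_f[partners]))
    w2 <- partners[order(cl * 10 + mis, stats::runif(length(partners)))[1]]
    lists[[li]] <- c(w1, w2)
    take(w1); take(w2)
  }
  # --- triples: anchored pair closed by a compensating third word
  triples <- which(lengths == 3L)
  for (li in if (length(triples)) triples[sample.int(length(triples))] else triples) {
    cand <- which(q > 0)
    if (length(cand) < 3) stop_domain("word quota exhausted early")
    w1 <- medium_anchor(burn_filter(cand))
    chosen <- w1
    take(w1)
    for (slot in 2:3) {
      cand <- burn_filter(which(q > 0 & !(seq_along(q) %in% chosen)))
      if (!length(cand)) stop_domain("word quota exhausted early")
      cl <- vapply(cand, n_clash, numeric(1), chosen = chosen)
      rem <- 3L - slot + 1L
      mis <- pmax(abs(dev_d[cand] + sum(dev_d[chosen]) / rem),
                  abs(dev_f[cand] + sum(dev_f[chosen]) / rem))
      w <- cand[order(cl * 10 + mis, stats::runif(length(cand)))[1]]
      chosen <- c(chosen, w)
      take(w)
    }
    lists[[li]] <- chosen
  }
  # --- 6- then 5-item lists: extreme anchor, near-mirror completion
  longs <- which(lengths >= 5L)
  for (li in longs[order(-lengths[longs])]) {
    L <- lengths[li]
    best <- NULL; best_score <- Inf
    for (attempt in seq_len(max_list_restarts)) {
      chosen <- integer(0)
      acc_d <- 0; acc_f <- 0
      clashes <- 0
      for (slot in seq_len(L)) {
        free <- which(q > 0 & !(seq_along(q) %in% chosen))
        if (!length(free)) { clashes <- Inf; break }
        cand <- free[!(inventory$initial[free] %in% inventory$initial[chosen]) &
                       !(inventory$vowel[free] %in% inventory$vowel[chosen]) &
                       !(inventory$final[free] %in% inventory$final[chosen])]
        cand <- burn_filter(cand)
        balanced <- max(abs(acc_d), abs(acc_f)) < 0.3
        pick <- if (!length(cand)) {
          # quota-forced clash: take the least-clashing word, repair later
          cl <- vapply(free, n_clash, numeric(1), chosen = chosen)
          clashes <- clashes + min(cl)
          free[order(cl, stats::runif(length(free)))[1]]
        } else if (balanced && slot < L) {
          # running mean on target: anchor on an extreme word while a
          # compensating slot remains, so outliers are burned in pairs
          top <- cand[order(-extremity[cand], stats::runif(length(cand)))]
          top <- top[seq_len(min(3L, length(top)))]
          if (length(top) == 1) top else {
            top[sample.int(length(top), 1, prob = q[top]^2)]
          }
        } else {
          # cancel the running deviation with the best available mirror;
          # preferring words with more remaining uses leaves a leftover
          # pool of mostly distinct words, which keeps the dealt lists
          # easy to partition
          score <- pmax(abs(dev_d[cand] + acc_d),
                        abs(dev_f[cand] + acc_f)) + 0.06 * (4 - q[cand])
          cand[order(score, stats::runif(length(cand)))[1]]
        }
        chosen <- c(chosen, pick)
        acc_d <- acc_d + dev_d[pick]; acc_f <- acc_f + dev_f[pick]
        take(pick)
      }
      score <- 10 * clashes + max(abs(acc_d), abs(acc_f)) / L
      if (score < best_score && all(is.finite(score))) {
        best <- chosen; best_score <- score
      }
      untake(chosen)
      if (best_score <= 0.1) break
    }
    if (is.null(best)) stop_domain("word quota exhausted early")
    lists[[li]] <- best
    for (w in best) take(w)
  }
  # --- deal the 4-item lists jointly from the leftover multiset
  if (length(dealt)) {
    if (sum(q) != deal_units) stop_domain("quota bookkeeping error")
    n_lists <- length(dealt)
    slots_left <- lengths[dealt]
    dealt_lists <- replicate(n_lists, integer(0), simplify = FALSE)
    acc_d <- numeric(n_lists); acc_f <- numeric(n_lists)
    for (w in order(-q, stats::runif(length(q)))[seq_len(sum(q > 0))]) {
      if (q[w] == 0) next
      for (k in seq_len(q[w])) {
        open <- which(slots_left > 0 &
                        !vapply(dealt_lists, function(l) w %in% l,
                                logical(1)))
        if (!length(open)) stop_domain("word quota exhausted early")
        score <- vapply(open, function(j) {
          10 * n_clash(w, dealt_lists[[j]]) +
            max(abs(acc_d[j] + dev_d[w]), abs(acc_f[j] + dev_f[w])) -
            0.05 * slots_left[j]
        }, numeric(1))
        j <- open[order(score, stats::runif(length(open)))[1]]
        dealt_lists[[j]] <- c(dealt_lists[[j]], w)
        acc_d[j] <- acc_d[j] + dev_d[w]
        acc_f[j] <- acc_f[j] + dev_f[w]
        slots_left[j] <- slots_left[j] - 1L
      }
      q[w] <- 0L
    }
    # polish by unit exchanges between dealt lists: clear phoneme
    # clashes first, then tighten the spread of list means
    cl_of <- function(l) {
      3L * length(l) - length(unique(inventory$initial[l])) -
        length(unique(inventory$vowel[l])) -
        length(unique(inventory$final[l]))
    }
    cls <- vapply(dealt_lists, cl_of, numeric(1))
    # anneal the dealt lists on a combined objective (squared deviation
    # of list sums plus a clash penalty), then finish with strict
    # descent; the space is small, so this reliably approaches the best
    # clash-free balanced partition of the leftover multiset
    obj_try <- function(j1, p1, j2, p2) {
      w1 <- dealt_lists[[j1]][p1]; w2 <- dealt_lists[[j2]][p2]
      if (w1 == w2 || w2 %in% dealt_lists[[j1]] ||
          w1 %in% dealt_lists[[j2]]) return(NULL)
      dd <- dev_d[w2] - dev_d[w1]; df <- dev_f[w2] - dev_f[w1]
      l1 <- c(dealt_lists[[j1]][-p1], w2)
      l2 <- c(dealt_lists[[j2]][-p2], w1)
      d_obj <- (acc_d[j1] + dd)^2 + (acc_f[j1] + df)^2 +
        (acc_d[j2] - dd)^2 + (acc_f[j2] - df)^2 -
        (acc_d[j1]^2 + acc_f[j1]^2 + acc_d[j2]^2 + acc_f[j2]^2) +
        8 * (cl_of(l1) + cl_of(l2) - cls[j1] - cls[j2])
      list(d_obj = d_obj, l1 = l1, l2 = l2, dd = dd, df = df)
    }
    apply_move <- function(j1, j2, mv) {
      dealt_lists[[j1]] <<- mv$l1; dealt_lists[[j2]] <<- mv$l2
      cls[j1] <<- cl_of(mv$l1); cls[j2] <<- cl_of(mv$l2)
      acc_d[j1] <<- acc_d[j1] + mv$dd; acc_f[j1] <<- acc_f[j1] + mv$df
      acc_d[j2] <<- acc_d[j2] - mv$dd; acc_f[j2] <<- acc_f[j2] - mv$df
    }
    n_anneal <- 15000
    for (it in seq_len(n_anneal)) {
      temp <- 1.0 * (3e-4)^(it / n_anneal)
      j1 <- sample.int(n_lists, 1); j2 <- sample.int(n_lists, 1)
      if (j1 == j2) next
      mv <- obj_try(j1, sample.int(length(dealt_lists[[j1]]), 1),
                    j2, sample.int(length(dealt_lists[[j2]]), 1))
      if (is.null(mv)) next
      if (mv$d_obj < 0 || stats::runif(1) < exp(-mv$d_obj / temp)) {
        apply_move(j1, j2, mv)
      }
    }
    repeat {  # strict best-swap descent to a local optimum
      best <- NULL
      for (j1 in seq_len(n_lists - 1)) for (j2 in (j1 + 1):n_lists) {
        for (p1 in seq_along(dealt_lists[[j1]])) {
          for (p2 in seq_along(dealt_lists[[j2]])) {
            mv <- obj_try(j1, p1, j2, p2)
            if (!is.null(mv) && mv$d_obj < -1e-12 &&
                (is.null(best) || mv$d_obj < best$mv$d_obj)) {
              best <- list(j1 = j1, j2 = j2, mv = mv)
            }
          }
        }
      }
      if (is.null(best)) break
      apply_move(best$j1, best$j2, best$mv)
    }
    for (j in seq_len(n_lists)) lists[[dealt[j]]] <- dealt_lists[[j]]
  }
  lists
}

word_list_valid <- function(inventory, idx) {
  !anyDuplicated(inventory$initial[idx]) &&
    !anyDuplicated(inventory$vowel[idx]) &&
    !anyDuplicated(inventory$final[idx])
}

# Stochastic swap repair. Word exchanges between two lists of the same
# block (which preserve per-block usage quotas) are accepted under a
# lexicographic objective: first the total number of within-list phoneme
# clashes, then the summed squared excess of class spreads over the
# balance tolerance. The excess is zero exactly when every length class
# passes the criterion; updates are incremental so a large proposal budget
# stays cheap.
repair_lists <- function(blocks, lengths, inventory, tol, max_swaps) {
  dens <- inventory$neighborhood_density
  freq <- inventory$log_frequency
  attrs <- cbind(dens, freq)
  sds <- c(stats::sd(dens), stats::sd(freq))
  n_blocks <- length(blocks)
  n_per_block <- length(lengths)
  flat_block <- rep(seq_len(n_blocks), each = n_per_block)
  flat_li <- rep(seq_len(n_per_block), n_blocks)
  flat_len <- lengths[flat_li]
  n_flat <- length(flat_len)
  idx_of <- vector("list", n_flat)
  for (r in seq_len(n_flat)) idx_of[[r]] <- blocks[[flat_block[r]]][[flat_li[r]]]
  M <- cbind(vapply(idx_of, function(i) mean(dens[i]), numeric(1)),
             vapply(idx_of, function(i) mean(freq[i]), numeric(1)))
  ini <- inventory$initial; vow <- inventory$vowel; fin <- inventory$final
  clash_count <- function(idx) {
    (length(idx) - length(unique(ini[idx]))) +
      (length(idx) - length(unique(vow[idx]))) +
      (length(idx) - length(unique(fin[idx])))
  }
  cl <- vapply(idx_of, clash_count, numeric(1))
  class_rows <- split(seq_len(n_flat), flat_len)
  class_rows <- class_rows[vapply(class_rows, length, 0L) >= 2]
  cls_of <- match(as.character(flat_len), names(class_rows))
  class_excess <- function(ci) {
    rows <- class_rows[[ci]]
    sD <- diff(range(M[rows, 1])) / sds[1]
    sF <- diff(range(M[rows, 2])) / sds[2]
    max(sD - tol, 0)^2 + max(sF - tol, 0)^2
  }
  exc <- vapply(seq_along(class_rows), class_excess, numeric(1))
  total_cl <- sum(cl)
  total_exc <- sum(exc)
  # assess an exchange of word a (list r1) for word b (list r2); returns
  # NULL if impossible, else the clash and excess deltas plus state
  assess_swap <- function(r1, a, r2, b) {
    A <- idx_of[[r1]]; B <- idx_of[[r2]]
    if (a == b || b %in% A || a %in% B) return(NULL)
    A2 <- c(A[A != a], b); B2 <- c(B[B != b], a)
    d_cl <- clash_count(A2) + clash_count(B2) - cl[r1] - cl[r2]
    old1 <- M[r1, ]; old2 <- M[r2, ]
    M[r1, ] <<- M[r1, ] + (attrs[b, ] - attrs[a, ]) / length(A)
    M[r2, ] <<- M[r2, ] + (attrs[a, ] - attrs[b, ]) / length(B)
    cis <- unique(cls_of[c(r1, r2)])
    new_exc <- vapply(cis, class_excess, numeric(1))
    d_exc <- sum(new_exc) - sum(exc[cis])
    M[r1, ] <<- old1; M[r2, ] <<- old2
    list(r1 = r1, a = a, r2 = r2, b = b, d_cl = d_cl, d_exc = d_exc,
         A2 = A2, B2 = B2, cis = cis, new_exc = new_exc)
  }
  apply_swap <- function(s) {
    M[s$r1, ] <<- M[s$r1, ] +
      (attrs[s$b, ] - attrs[s$a, ]) / length(idx_of[[s$r1]])
    M[s$r2, ] <<- M[s$r2, ] +
      (attrs[s$a, ] - attrs[s$b, ]) / length(idx_of[[s$r2]])
    exc[s$cis] <<- s$new_exc
    cl[s$r1] <<- clash_count(s$A2); cl[s$r2] <<- clash_count(s$B2)
    total_cl <<- total_cl + s$d_cl
    total_exc <<- total_exc + s$d_exc
    idx_of[[s$r1]] <<- s$A2
    idx_of[[s$r2]] <<- s$B2
  }
  try_swap <- function(r1, a, r2, b, temp = 0) {
    s <- assess_swap(r1, a, r2, b)
    if (is.null(s) || s$d_cl > 0) return(FALSE)
    accept <- s$d_cl < 0 || s$d_exc < -1e-12 ||
      (temp > 0 && stats::runif(1) < exp(-s$d_exc / temp))
    if (accept) { apply_swap(s); TRUE } else FALSE
  }
  swaps <- 0L
  while ((total_cl > 0 || total_exc > 0) && swaps < max_swaps) {
    swaps <- swaps + 1L
    temp <- 0  # strict descent: construction already lands near the target
    if (total_cl > 0) {
      # fix distinctness first: among clash-reducing exchanges, apply the
      # one that damages the attribute balance least
      bad <- which(cl > 0)
      r1 <- bad[sample.int(length(bad), 1)]
      same_block <- setdiff(which(flat_block == flat_block[r1]), r1)
      best <- NULL
      for (k in seq_len(20)) {
        r2 <- same_block[sample.int(length(same_block), 1)]
        A <- idx_of[[r1]]; B <- idx_of[[r2]]
        s <- assess_swap(r1, A[sample.int(length(A), 1)], r2,
                         B[sample.int(length(B), 1)])
        if (!is.null(s) && s$d_cl < 0 &&
            (is.null(best) || s$d_exc < best$d_exc)) best <- s
      }
      if (!is.null(best)) apply_swap(best)
    } else if (stats::runif(1) < 0.7) {
      # guided: most deviant list of the worst class, aimed replacement
      ci <- which.max(exc)
      rows <- class_rows[[ci]]
      at <- if (diff(range(M[rows, 1])) / sds[1] >
                  diff(range(M[rows, 2])) / sds[2]) 1L else 2L
      ctr <- mean(M[rows, at])
      r1 <- rows[which.max(abs(M[rows, at] - ctr))]
      A <- idx_of[[r1]]
      dev <- M[r1, at] - ctr
      a <- A[order(-(attrs[A, at] - mean(attrs[A, at])) * sign(dev))][1]
      target <- attrs[a, at] - dev * length(A)
      cand <- order(abs(attrs[, at] - target))
      cand <- cand[!(cand %in% A)]
      cand <- cand[seq_len(min(8, length(cand)))]
      b <- cand[sample.int(length(cand), 1)]
      same_block <- which(flat_block == flat_block[r1])
      r2s <- same_block[vapply(same_block, function(r) {
        r != r1 && b %in% idx_of[[r]]
      }, logical(1))]
      if (!length(r2s)) next
      try_swap(r1, a, r2s[sample.int(length(r2s), 1)], b, temp = temp)
    } else {
      r1 <- sample.int(n_flat, 1)
      same_block <- which(flat_block == flat_block[r1])
      r2 <- same_block[sample.int(length(same_block), 1)]
      if (r1 == r2) next
      A <- idx_of[[r1]]; B <- idx_of[[r2]]
      try_swap(r1, A[sample.int(length(A), 1)], r2,
               B[sample.int(length(B), 1)], temp = temp)
    }
  }
  # final exhaustive pass: for the extreme lists of the worst class,
  # scan every in-block exchange and apply the best excess reducer; with
  # construction delivering all but one class inside the band, this trims
  # the few offending lists without disturbing the rest
  if (total_cl == 0 && total_exc > 0) {
    for (move in seq_len(300)) {
      if (total_exc <= 0) break
      sprd <- vapply(seq_along(class_rows), function(ci) {
        rows <- class_rows[[ci]]
        max(diff(range(M[rows, 1])) / sds[1],
            diff(range(M[rows, 2])) / sds[2])
      }, numeric(1))
      ci <- which.max(sprd)
      rows <- class_rows[[ci]]
      at <- if (diff(range(M[rows, 1])) / sds[1] >
                  diff(range(M[rows, 2])) / sds[2]) 1L else 2L
      ctr <- mean(range(M[rows, at]))
      t_order <- rows[order(-abs(M[rows, at] - ctr))]
      cvar <- function() {
        stats::var(M[rows, 1] / sds[1]) + stats::var(M[rows, 2] / sds[2])
      }
      applied <- FALSE
      for (r1 in t_order[seq_len(min(6, length(t_order)))]) {
        best <- NULL
        v0 <- cvar()
        partners <- which(flat_block == flat_block[r1] &
                            seq_len(n_flat) != r1)
        for (a in idx_of[[r1]]) {
          for (r2 in partners) {
            for (b in idx_of[[r2]]) {
              s <- assess_swap(r1, a, r2, b)
              if (is.null(s) || s$d_cl > 0 || s$d_exc > 1e-12) next
              # variance of the class means is smooth: it keeps
              # improving through tied-extreme plateaus where the range
              # cannot move in one step
              M1 <- M[c(r1, r2), , drop = FALSE]
              M[r1, ] <- M[r1, ] +
                (attrs[b, ] - attrs[a, ]) / length(idx_of[[r1]])
              M[r2, ] <- M[r2, ] +
                (attrs[a, ] - attrs[b, ]) / length(idx_of[[r2]])
              dv <- cvar() - v0
              M[c(r1, r2), ] <- M1
              if (dv < -1e-12 && (is.null(best) || dv < best$dv)) {
                best <- list(s = s, dv = dv)
              }
            }
          }
        }
        if (!is.null(best)) {
          apply_swap(best$s)
          applied <- TRUE
          break
        }
      }
      if (!applied) break
    }
  }
  if (total_cl > 0) {
    stop_domain("could not satisfy word-list distinctness constraints ",
                "within the swap budget")
  }
  if (total_exc > 0) {
    worst <- sqrt(max(exc)) + tol
    stop_domain(sprintf(
      paste0("word-list balance criterion not met: spread %.2f pooled SD ",
             "exceeds tolerance %.2f after %d proposals; relax balance_tol ",
             "or supply an inventory with more attribute-central words"),
      worst, tol, swaps))
  }
  for (r in seq_len(n_flat)) blocks[[flat_block[r]]][[flat_li[r]]] <- idx_of[[r]]
  blocks
}

#' Generate balanced word-span lists for all blocks
#'
#' Builds word lists for `n_blocks` blocks (one per spectral-resolution
#' condition) under the full constraint set: within a list all initial
#' consonants, vowels and final consonants are distinct; every word is
#' used 3 or 4 times per block and 10 or 11 times overall (with the
#' default 10-trials-per-length blocks, the slot count that makes that
#' usage constraint attainable for 60 words over three blocks); and lists
#' of equal length have similar mean neighborhood density and log
#' frequency. Lists are found by constrained, balance-aware random
#' assignment followed by pairwise swap repair; an explicit error is
#' raised if the constraints cannot be met within the search budget, never
#' a silent violation.
#'
#' @param inventory a `word_inventory` (e.g. [synthetic_word_inventory()]).
#' @param lengths_per_block list lengths presented in each block; default
#'   ten trials of each length 1-6.
#' @param n_blocks number of blocks (default 3).
#' @param balance_tol maximum allowed pairwise difference of list means
#'   within a length class, in units of the pooled (inventory) SD of the
#'   attribute (default 0.5).
#' @param max_swaps swap-repair proposal budget (default 3e4).
#' @param seed optional seed.
#' @return object of class `word_lists`: per-block lists of inventory row
#'   indices, with the inventory attached.
#' @export
#' @examples
#' inv <- synthetic_word_inventory(seed = 1)
#' wl <- generate_word_lists(inv, seed = 1)
#' word_usage(wl)[1:5, ]
generate_word_lists <- function(inventory,
                                lengths_per_block = rep(1:6, each = 10),
                                n_blocks = 3, balance_tol = 0.5,
                                max_swaps = 3e4, seed = NULL) {
  run <- function() {
    n <- nrow(inventory)
    lengths <- as.integer(lengths_per_block)
    if (any(lengths < 1 | lengths > 6)) {
      stop_domain("word list lengths must be between 1 and 6")
    }
    dens <- inventory$neighborhood_density
    freq <- inventory$log_frequency
    zd <- (dens - mean(dens)) / stats::sd(dens)
    zf <- (freq - mean(freq)) / stats::sd(freq)
    seed_w <- which.min(pmax(abs(zd), abs(zf)))
    # distance to one shared central seed word: singleton lists in every
    # block then come from the same tight attribute cluster
    centrality <- pmax(abs(zd - zd[seed_w]), abs(zf - zf[seed_w]))
    # couple usage quotas over antipodal word pairs: matching each word
    # with its attribute near-mirror and giving both members the same
    # per-block quota keeps compensating partners available together
    pairing <- rep(NA_integer_, n)
    if (n %% 2L == 0L) {
      left <- order(-pmax(abs(zd), abs(zf)))
      unit <- 0L
      while (length(left)) {
        w <- left[1]; left <- left[-1]
        u <- left[which.min(pmax(abs(zd[w] + zd[left]),
                                 abs(zf[w] + zf[left])))]
        left <- left[left != u]
        unit <- unit + 1L
        pairing[c(w, u)] <- unit
      }
    }
    last_err <- NULL
    for (attempt in 1:8) {
      res <- tryCatch({
        quota <- if (!anyNA(pairing)) {
          qu <- assign_quotas(n %/% 2L, sum(lengths) %/% 2L, n_blocks)
          qu[pairing, , drop = FALSE]
        } else {
          assign_quotas(n, sum(lengths), n_blocks)
        }
        blocks <- lapply(seq_len(n_blocks), function(b) {
          build_block_lists(inventory, lengths, quota[, b], centrality)
        })
        blocks <- repair_lists(blocks, lengths, inventory, balance_tol,
                               max_swaps)
        structure(list(blocks = blocks, lengths = lengths,
                       inventory = inventory),
                  class = "word_lists")
      }, error = function(e) e)
      if (!inherits(res, "error")) return(res)
      last_err <- res
    }
    stop(last_err)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Word usage counts of a generated list set
#'
#' @param x a `word_lists` object.
#' @return matrix (words x blocks) of usage counts, with a `total` column.
#' @export
word_usage <- function(x) {
  stopifnot(inherits(x, "word_lists"))
  n <- nrow(x$inventory)
  m <- sapply(x$blocks, function(bl) tabulate(unlist(bl), nbins = n))
  cbind(m, total = rowSums(m))
}

#' @export
as.data.frame.word_lists <- function(x, ...) {
  rows <- list()
  for (b in seq_along(x$blocks)) {
    for (li in seq_along(x$blocks[[b]])) {
      idx <- x$blocks[[b]][[li]]
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, trial = li, length = length(idx),
        items = paste(x$inventory$orthography[idx], collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract one word list as a `recall_list`
#'
#' @param x a `word_lists` object.
#' @param block,trial block and trial indices.
#' @param condition optional condition label.
#' @return a `recall_list` of kind `"word"`.
#' @export
word_list_at <- function(x, block, trial, condition = NA) {
  idx <- x$blocks[[block]][[trial]]
  recall_list("word", x$inventory[idx, , drop = FALSE], condition)
}

# ---- validation (independent re-implementation of the constraints) ------

#' Validate a recall list against the design constraints
#'
#' Re-checks every list-construction rule independently of the generators
#' and reports each violated rule by name. Digit rules: length 2-9, digits
#' from the alphabet, no adjacent pair differing by one or less. Word
#' rules: length 1-6, phonemes from the allowed sets, no repeated initial
#' consonant, vowel, or final consonant within the list.
#'
#' @param x a `recall_list`.
#' @param digits digit alphabet for digit lists.
#' @return list with elements `valid` (logical) and `violations`
#'   (character vector, empty when valid).
#' @export
#' @examples
#' validate_list(recall_list("digit", c(2, 3, 7)))
validate_list <- function(x, digits = 1:9) {
  stopifnot(inherits(x, "recall_list"))
  v <- character(0)
  if (x$kind == "digit") {
    d <- x$items
    if (length(d) < 2 || length(d) > 9) {
      v <- c(v, sprintf("length %d outside 2-9", length(d)))
    }
    if (!all(d %in% digits)) v <- c(v, "digit outside alphabet")
    if (length(d) >= 2) {
      for (i in seq_len(length(d) - 1)) {
        if (abs(d[i + 1] - d[i]) <= 1) {
          v <- c(v, sprintf("adjacent ±1 transition at positions %d-%d (%d,%d)",
                            i, i + 1, d[i], d[i + 1]))
        }
      }
    }
  } else {
    w <- x$items
    ph <- span_phonemes()
    if (nrow(w) < 1 || nrow(w) > 6) {
      v <- c(v, sprintf("length %d outside 1-6", nrow(w)))
    }
    if (!all(w$initial %in% ph$initial)) v <- c(v, "disallowed initial phoneme")
    if (!all(w$vowel %in% ph$vowel)) v <- c(v, "disallowed vowel phoneme")
    if (!all(w$final %in% ph$final)) v <- c(v, "disallowed final phoneme")
    for (col in c("initial", "vowel", "final")) {
      dup <- which(duplicated(w[[col]]))
      for (i in dup) {
        v <- c(v, sprintf("%s repeated in position %d (%s)",
                          if (col == "initial") "initial consonant"
                          else if (col == "vowel") "vowel"
                          else "final consonant", i, w[[col]][i]))
      }
    }
  }
  list(valid = length(v) == 0, violations = v)
}

# ---- presentation ordering ----------------------------------------------

#' Order lists into a presentation block
#'
#' Finds a presentation order in which no two consecutive lists share a
#' length and the first list is easy (at most six digits or four words).
#' Uses randomized backtracking over the length multiset; raises an
#' explicit error when no valid order exists.
#'
#' @param lengths integer vector of list lengths, one per trial.
#' @param kind `"digit"` or `"word"`; sets the first-trial cap (6 or 4).
#' @param first_max override the first-trial length cap.
#' @param seed optional seed.
#' @return integer permutation of `seq_along(lengths)`.
#' @export
#' @examples
#' order_block(c(2, 2, 3), kind = "digit", seed = 1)
order_block <- function(lengths, kind = c("digit", "word"),
                        first_max = NULL, seed = NULL) {
  kind <- match.arg(kind)
  cap <- first_max %||% if (kind == "digit") 6L else 4L
  run <- function() {
    vals <- sort(unique(lengths))
    counts <- as.integer(table(factor(lengths, levels = vals)))
    n <- length(lengths)
    seq_out <- integer(n)
    search <- function(step, counts, prev) {
      if (step > n) return(TRUE)
      remaining <- n - step + 1L
      cand <- if (is.na(prev)) which(counts > 0) else
        which(counts > 0 & vals != prev)
      if (step == 1L) cand <- cand[vals[cand] <= cap]
      if (!length(cand)) return(FALSE)
      for (ci in cand[sample.int(length(cand))]) {
        counts[ci] <- counts[ci] - 1L
        # necessary feasibility bound: most frequent remaining length must
        # fit into alternating slots
        if (max(counts) <= ceiling((remaining - 1L) / 2)) {
          seq_out[step] <<- ci
          if (search(step + 1L, counts, vals[ci])) return(TRUE)
        }
        counts[ci] <- counts[ci] + 1L
      }
      FALSE
    }
    if (!search(1L, counts, NA_integer_)) {
      stop_domain("no valid presentation order exists for these lengths")
    }
    ordered_vals <- vals[seq_out]
    # map the value sequence back to indices of the input
    pool <- split(seq_along(lengths), lengths)
    used <- integer(0)
    out <- integer(n)
    for (i in seq_len(n)) {
      key <- as.character(ordered_vals[i])
      out[i] <- pool[[key]][1]
      pool[[key]] <- pool[[key]][-1]
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
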