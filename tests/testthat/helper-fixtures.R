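# Shared fixtures, built once per test run and memoized. Word-list
# generation and cohort simulation are the expensive stages, so every
# test that needs them draws from this cache.

.fixtures <- new.env(parent = emptyenv())

fixture_inventory <- function() {
  if (is.null(.fixtures$inventory)) {
    .fixtures$inventory <- synthetic_word_inventory(seed = 1)
  }
  .fixtures$inventory
}

fixture_word_lists <- function() {
  if (is.null(.fixtures$word_lists)) {
    .fixtures$word_lists <- generate_word_lists(fixture_inventory(),
                                                seed = 999)
  }
  .fixtures$word_lists
}

fixture_session <- function() {
  if (is.null(.fixtures$session)) {
    .fixtures$session <- simulate_session(cohort_config(seed = 1))
  }
  .fixtures$session
}

fixture_analysis <- function() {
  if (is.null(.fixtures$analysis)) {
    .fixtures$analysis <- run_pipeline(fixture_session())
  }
  .fixtures$analysis
}

# stimulus lists shared by replicate cohorts (fixed study materials)
fixture_stimuli <- function() {
  fixture_session()$lists
}

rms <- function(x) sqrt(mean(x^2))
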