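---
title: "Methods: vocoded speech, serial recall, and the individual-differences pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocoded speech, serial recall, and the individual-differences pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vocospan)
```

## What the package models

Listeners with cochlear implants receive speech with drastically reduced
spectral resolution. A standard laboratory model of that situation is
noise-band channel vocoding: speech is divided into a small number of
frequency bands, the slow amplitude envelope of each band is extracted,
and the envelopes are re-imposed on band-limited noise carriers. With 16
channels sentence recognition is nearly easy; with 4 it is hard. The
scientific question the pipeline serves is *which aspects of cognition
predict a listener's ability to recognise such degraded sentences*, and
in particular whether verbal short-term memory, measured with auditory
serial recall of digits and words, carries that prediction across
spectral resolutions.

The package implements the full computational chain of such a study:
stimulus degradation (the vocoder), construction of constrained recall
lists, strict position-wise scoring, and the statistical stage (accuracy
composites by principal components, correlation families, standard major
axis fit lines, reaction-time trimming and ex-Gaussian modelling).
Because human data cannot ship with a package, a calibrated synthetic
cohort generator produces complete sessions with known latent structure,
so every stage is testable end to end and parameter recovery can be
verified.

## The vocoder

Analysis bands are *rectangular*: frequency-domain brick-wall masks
(FFT, zero all bins outside the band, inverse FFT). Rectangular masks
make channel boundaries exact, so the three presets (4, 8, 16 channels)
tile 100–10000 Hz with no gaps or overlaps and merging adjacent bands
adds their energies exactly — a property the tests exploit. The 17
master edge frequencies cover equal cochlear extent under the Greenwood
frequency–place map `F = A(10^(ax) − k)` with the standard human
constants `A = 165.4`, `a = 2.1`, `k = 0.88`; with these constants the
printed edges deviate from exact equal spacing by at most 3.7% of one
spacing step (with `k = 1` the deviation is 14.8%, so `k = 0.88` is the
map consistent with the edge table).

Band envelopes are the magnitude of the band-limited analytic signal
(Hilbert transform), low-pass filtered with a causal fourth-order
Butterworth at 300 Hz; small negative values after smoothing are clamped
to zero. The causal choice follows common vocoder practice; zero-phase
filtering is reserved for recording preprocessing, where phase
distortion of stored tokens matters. Carriers are unit-RMS Gaussian
noise, brick-wall band-limited, drawn per channel in channel order from
one generator seeded by the spec, so identical inputs give bit-identical
outputs. After summation the signal is confined to the full analysis
range with a final brick-wall mask: envelope sidebands of the edge
channels would otherwise place a small amount of energy below 100 Hz or
above 10 kHz, and the module contract bounds out-of-range energy at 1%.
Output level is RMS-matched to the input; calibration to a playback
sound level is a property of the playback chain, not of the file.

Default sample rate is 44.1 kHz; any rate whose Nyquist frequency
exceeds the top analysis edge is accepted, and nothing is resampled
silently.

## Recall lists

Digit lists (2–9 items over digits 1–9) exclude every adjacent pair
differing by one *or zero*: runs like 4‑5 chunk into single units, and
immediate repeats chunk at least as strongly, so both are removed. Lists
are rejection-sampled, which makes the distribution exactly uniform over
the valid sequences (for length 2 there are 56 of them, a closed-form
check in the tests).

Word lists use 60 consonant–vowel–consonant words over a restricted
phoneme inventory (10 initial consonants, 7 vowels, 10 final
consonants). The constraint set is heavy: within a list no phoneme may
repeat in the same word position; each word is used 3 or 4 times per
spectral-resolution block and 10 or 11 times in total; and lists of
equal length must have similar mean lexical neighborhood density and log
frequency (tolerance: at most 0.5 pooled SD between any two list means).
The usage bounds fix the trial counts: with 60 words over three blocks,
only ten trials of each length 1–6 per block (210 word slots) makes
"3 or 4 per block, 10 or 11 overall" attainable, so that is the default
word block; digit blocks default to two trials per length.

The generator works by balance-aware construction followed by swap
repair. Singleton lists take quota clustered around one shared central
word. Length-2 lists pair medium words with attribute-antipodal
partners. Length-3 lists close an anchored pair with a compensating
word. Six-item lists are built next, each anchored on an extreme word
and completed by near-mirror picks that cancel the running deviation, so
attribute outliers are consumed in pairs while the pool is rich. The 4-
and 5-item lists are dealt jointly from the leftover quota multiset (a
word with k remaining uses goes to k different lists), annealed on a
combined clash-plus-imbalance objective, and finished by best-swap
descent. A final repair pass exchanges words between lists of the same
block — which preserves all usage quotas — accepting moves that first
clear any remaining phoneme clashes and then shrink the spread of list
means; its last phase minimises the *variance* of the binding class's
list means, because range-based objectives stall when several lists tie
at the extremes. If the balance band cannot be met within the search
budget the generator raises an explicit error naming the spread
achieved; it never silently violates a constraint.

Two properties of the synthetic inventory make this search well-posed,
and both mirror how a real inventory is curated (the study's 60 words
were chosen from 79 candidates precisely so lists could be balanced):
attribute deviations come in antipodal pairs, so every word has a
near-mirror partner, and a core of attribute-typical words sits near the
centre. Usage quotas are assigned jointly over those antipodal pairs so
compensating partners remain available together.

Presentation orders never repeat a list length twice in a row, and each
block opens with an easy trial (at most six digits or four words); a
randomized backtracking search finds an order or proves none exists.

An independent validator re-implements every rule (it shares no code
with the generators) and reports violations by name; generator outputs
are tested against it at scale.

## Scoring

Serial recall is scored per position: slot *i* is correct exactly when
the response item at position *i* equals the target's. Missing positions
are wrong; surplus responses are ignored. Word trials are scored per
phoneme (3 slots per word), giving partial credit for partially correct
words. Sentences are scored by key words: order-free, one-to-one
matching of case-folded, punctuation-stripped tokens, with no
morphological credit — the strict convention is the reproducible one.
Condition summaries pool correct counts over slots
(`sum(correct)/sum(slots)`), so a nine-item list carries more weight
than a two-item list; an unweighted mean of trial proportions is
available behind a flag.

## Statistics

*Composites.* `pca_composite()` eigendecomposes the correlation matrix
of a participants × conditions accuracy table. Components with an
eigenvalue above 1 are retained by default; the serial-recall analysis
overrides this to keep components 1–2, because the second component
(sensitivity of word recall to vocoding) is retained on prior grounds
despite an eigenvalue below 1. Signs are fixed by forcing a positive
mean loading on every component. The linear mixed-effects comparison of
conditions is implemented as its balanced-design equivalent: with
complete data and a participant random intercept the fixed-effect
estimates equal condition means, so `condition_contrasts()` reports
condition means and paired t statistics against the 16-channel
reference; the original degrees of freedom of a mixed model are not
reproduced, and that is intentional.

*Correlations.* `correlate()` computes Pearson or Spearman coefficients
with two-sided p values from the t approximation. Bonferroni family
sizes are always caller-specified (6 for the matched-resolution
serial–sentence table, 8 for the component–sentence table, the number of
cells for the attention tables); the package never infers a family
silently. Spearman is the default for correlations against component
scores and the reasoning index; cross-resolution sentence accuracy
correlations are Pearson.

*SMA.* The standard major axis slope is `sign(r)·sd(y)/sd(x)` through
the means — the symmetric line for two error-carrying variables; it is
undefined at zero correlation and errors there.

*Reaction times.* Incorrect trials are discarded; outliers are trimmed
iteratively per participant and condition (remove everything above the
mean plus 4 sample SDs, recompute, repeat to a fixed point; only the
upper tail is touched). Condition costs are differences of geometric
mean RTs; each cost is tested across participants with the Wilcoxon
signed-rank Z (zero differences dropped, midranks with tie-corrected
variance, continuity correction of one half — without the correction the
normal approximation misses the exact small-sample p by up to 0.07,
more than the accepted tolerance). The ex-Gaussian (Gaussian μ, σ
convolved with exponential τ; mean μ+τ, variance σ²+τ²) is fitted by
bounded L-BFGS-B on the exact log density with moment-based starting
values (τ₀ from the third central moment, bounded below at 1 ms) and
bounds σ, τ ≥ 0.5 ms; non-convergence is flagged, not thrown. At least
50 trials per condition are required for a stable tail estimate; the
simulated tasks use 80 per condition.

## The synthetic cohort

Participant latents are multivariate normal: serial ability,
sentence-specific skill, reasoning, vocoder sensitivity and processing
speed, plus four independent sustained-attention percentiles. Defaults:
`corr(serial, reasoning) = 0.35`; speed correlates −0.45 with reasoning
and −0.35 with serial ability; the sentence-skill latent weighs serial
ability at 0.80, a value chosen so the *observed* Spearman correlation
between the serial composite and the sentence composite centres on 0.65
after measurement attenuation. Each scoring slot is a Bernoulli draw
with success probability `logistic(intercept − length penalty + loading
× ability − vocoding penalty × sensitivity + block noise)`; digit
conditions carry no vocoding penalty, which is what makes digit recall
flat across resolutions. Responses are materialised as item sequences
(errors draw a different item), so the generated tables flow through the
same scoring and IO paths as real data.

Intercepts were solved from the published group accuracies via the
logistic-normal attenuation approximation and verified once against
replicate medians: sentence conditions centre on 88/77/39% correct with
SDs near 5.6/6.4/7.2 points, digit recall on 81% in all conditions, word
recall on 86/82/65%. The per-condition sentence loadings (0.46, 0.29,
0.23) reproduce both the increasing SDs and the ~0.7 cross-resolution
correlations that give the sentence composite a first eigenvalue near
2.4; the recall noise SD of 0.30 logits keeps the serial-recall
six-variable composite's first eigenvalue near 4.4 rather than
saturating.

Reaction times are ex-Gaussian (baseline μ = 550 ms, σ = 60 ms,
τ = 150 ms) with a per-participant speed shift (60 ms per SD) and
multiplicative σ/τ scaling; the switch cost is 145 ms (SD 40 across
participants) and the Stroop incongruent condition sits 154 ms above
neutral with congruent 16 ms above neutral. One percent of trials are
replaced by slow contaminants (uniform between 5 and 10 SDs above the
mean) so the iterative trimmer always has work to do. The attention
tasks are completed by the full recruited sample of 38; six participants
drop out before the recall session, leaving 32 with complete data. That
split matters for one number: with all 38 participants showing a
positive switch cost, the signed-rank Z equals its one-sided maximum for
n = 38, which prints as 5.37 — at n = 32 the maximum would only be 4.94.

Two simplifications are documented limitations: scoring slots are
conditionally independent given the latents (real within-trial errors
are correlated, e.g. losing one's place corrupts several positions), and
phonetic confusions are uniform over alternatives (real confusions are
structured). Both mean that passing tests demonstrate the statistical
machinery, not the psycholinguistics of real listeners.

## Problem sizes and reproducibility

All randomness flows from one top-level seed through named substreams
(`substream_seed(seed, "lists")`, `"cohort"`, `"rt"`, …), so each stage
is independently reproducible and reruns are bit-identical. The test
suite exercises the vocoder at 44.1 kHz on one-second signals,
list generation at the full study size (180 word lists, 10,000 digit
lists for the validator sweep), ex-Gaussian recovery at n = 10,000, and
the end-to-end composite correlation on 100 replicate cohorts sharing
one set of stimulus materials. The acceptance script reports medians
over 21 replicate cohorts of 32 participants (38 for the reaction-time
tasks); replicate medians are reported because single-cohort correlation
estimates at n = 32 carry sampling SDs near 0.15. Word-list generation
is a constrained search that can fail for an unlucky substream; study
materials are therefore generated with a deterministic retry over
derived substreams (`study_stimuli()`), and an explicit error is raised
if the constraints cannot be met.
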