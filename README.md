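# vocospan

Tools for studying how verbal short-term memory predicts recognition of
spectrally degraded speech — the listening situation of cochlear-implant
users, modelled in normal-hearing listeners with noise-band channel
vocoding.

The package implements the full computational chain of such a study, for
researchers in auditory psychophysics and speech perception:

- **Vocoder** — speech is passed through rectangular (brick-wall)
  analysis filters whose edges cover equal cochlear extent under the
  Greenwood map `F = A(10^(ax) − k)` (A = 165.4, a = 2.1, k = 0.88);
  each band's Hilbert envelope is low-pass filtered at 300 Hz
  (fourth-order Butterworth) and multiplied onto a band-limited noise
  carrier; the products are summed. Presets of 16, 8 and 4 channels
  share one 17-edge table (100–10000 Hz), with adjacent bands merged for
  the lower resolutions.
- **Recall lists** — digit lists (2–9 items) with no adjacent ±1
  transitions, and word lists (1–6 CVC words) in which no phoneme
  repeats in the same word position, every word is used 3–4 times per
  block and 10–11 times overall, and lists of equal length are balanced
  on lexical neighborhood density and log frequency (≤ 0.5 pooled SD
  between list means). An independent validator re-checks every rule.
- **Scoring** — strict position-wise serial recall (per digit, per
  phoneme for words, giving partial credit) and order-free one-to-one
  key-word scoring for sentences; condition summaries pool correct
  counts over slots.
- **Statistics** — principal-component composites with the
  eigenvalue > 1 retention rule; correlation cells with explicit
  Bonferroni families; standard major axis fits
  (slope = sign(r)·sd(y)/sd(x)); iterative upper-tail reaction-time
  trimming (mean + 4 SD, to a fixed point); geometric-mean condition
  costs; tie-corrected Wilcoxon signed-rank Z; maximum-likelihood
  ex-Gaussian fits (μ, σ, τ) of reaction-time distributions.
- **Synthetic cohort** — a calibrated generator producing complete
  sessions (32 participants with full recall data, 38 with
  reaction-time data) whose group statistics match the study
  conditions, so the entire pipeline is testable end to end.

## Worked example

Simulate a study and run the full analysis:

```r
library(vocospan)
sess <- simulate_session(cohort_config(seed = 42))
an <- run_pipeline(sess)
print(an)
#> Vocoded sentence recognition / serial recall analysis
#>   sentence key words correct: ch16 88.4% (SD 5.4), ch8 78.4% (SD 6.7), ch4 39.8% (SD 6.3)
#>   digit recall: ch16 81%, ch8 81%, ch4 81%
#>   word recall (phonemes): ch16 87%, ch8 82%, ch4 65%
#>   sentence composite: first eigenvalue 2.43 (81% variance)
#>   serial recall: first eigenvalue 4.15 (69% variance)
#>   serial ability ~ sentence composite: rho = 0.59
#>   serial ability ~ reasoning: rho = 0.32 (p = 0.075)
#>   switch_cost: median 152 ms, Z = 5.37
#>   stroop_incongruent_neutral: median 141 ms, Z = 5.37
#>   stroop_incongruent_congruent: median 126 ms, Z = 5.35
#>   stroop_congruent_neutral: median 21 ms, Z = 3.86
```

Reading the output: sentence recognition collapses from ~88% to ~40% of
key words as spectral resolution drops from 16 to 4 channels, while
digit recall stays flat at ~81% — memory for clearly identifiable items
is insensitive to vocoding, whereas word recall (scored per phoneme)
declines because degraded words are harder to identify. One principal
component explains ~80% of the variance in sentence accuracy across
resolutions (individuals keep their rank), and the first serial-recall
component — overall recall ability — correlates with the sentence
composite at ρ ≈ 0.6. Attentional switch and Stroop costs are ~130–150
ms, positive in every participant, which puts the signed-rank Z at its
n = 38 maximum of 5.37.

Vocoding audio directly:

```r
x <- read_wav("sentence.wav")
y <- vocode(x, vocoder_spec(n_channels = 4, seed = 1))
write_wav(y, "sentence_4ch.wav")
```

A thin command-line wrapper with subcommands `vocode`, `make-lists`,
`score`, `analyze` and `simulate` is installed at
`inst/scripts/vocospan`.

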