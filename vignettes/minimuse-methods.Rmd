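---
title: "Methods: stimulus generation, tapping analysis and the model ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus generation, tapping analysis and the model ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimuse)
```

This vignette documents the models and design choices behind the
package: what the stimulus generators guarantee, how the tap-onset
detector and SEA score are defined, what the PCA composite and the
regression ladder compute, what the synthetic-data generators emulate,
and where the genuinely open decisions were settled.

## Symbolic melodies and mutation operators

A melody is a short sequence (3–5 notes) of MIDI pitches with durations
in beats, a major-key tonic, a nominal tempo and a meter. All pitches
are constrained to the melody's major scale, because every comparison
stimulus in the battery is required to stay in the key of its standard.

**Meter.** The battery fixes 4/4 with the quarter note as the beat. A
"downbeat" is a bar-initial beat (onset ≡ 0 mod 4 beats) and an
"upbeat" is any other position. The meter is not itself manipulated by
any task, and 4/4 is the unmarked Western default, so this is fixed
rather than configurable; it is what makes the downbeat/upbeat split of
the rhythm task well defined for 3- and 5-beat melodies (whose only
bar-initial onset is the first note).

**Contour.** The contour signature is the sign vector of successive
intervals, with three values (+, −, 0). Any change of the signature —
including a change from a rising or falling step to a repetition —
counts as contour-violating, since any alteration of the up/down
pattern is an audible contour change.

**Pitch mutations.** `mutate_pitch()` changes exactly one middle note
(the 2nd of 3, or the 2nd–4th of 5) by a fixed number of semitones,
keeping the result diatonic; contour-violating mutations use 8–12
semitones and contour-preserving ones 3–5. Feasibility is decided by
exhaustive enumeration of every legal substitution
(`pitch_mutation_candidates()`), which doubles as the test oracle. The
default battery's twelve melody-task deltas are the multisets
{8, 9, 9} / {9, 9, 12} (violating, 3- and 5-note) and {3, 4, 4} /
{3, 4, 5} (preserving), giving contour-type means of 56/6 ≈ 9.3 and
23/6 ≈ 3.8 semitones with ranges 8–12 and 3–5. No integer 12-trial set
split by contour type can *simultaneously* make the two per-length
means equal 6.5 and 6.2; the package therefore reproduces the
contour-type profile, which is the difficulty manipulation the tasks
actually rely on, and documents the per-length means as unattainable.

**Rhythm mutations.** `mutate_rhythm()` reassigns the durations of 2–3
adjacent notes from the grid {0.5, 1, 1.5, 2} beats, requiring every
affected note to change while conserving the note count and the total
duration — so standard and comparison render to the same length within
one sample. The first altered note's onset determines the
downbeat/upbeat class.

**Transposition.** The transposition offset is the smallest
non-negative shift mapping tonic to target, followed by whole-octave
centring that keeps the mean pitch within MIDI 55–84. The centring rule
keeps every key's stimuli inside a child-appropriate register; without
it, "transpose up to B major" would drift the register almost an octave
high.

**Composition.** Standards are composed feasibility-first: a random
walk over scale tones (steps ≤ 7 semitones, register ≈ F3–A5,
quarter-note durations, total length 1–3 s at the task tempo) is
retried until every required mutation has at least one candidate,
verified by enumeration, with a bound of 1000 attempts. The battery's
item bank is generated once under a fixed stimulus seed
(`battery_config()$stimulus_seed`), so every participant hears the same
stimuli; the per-participant seed controls only counterbalancing
assignment and trial order. Avoiding repeated adjacent pitches during
composition is a deliberate choice: it maximises the feasibility of
contour-preserving mutations, which are the tightest constraint.

## Audio rendering

Stimuli render at 44,100 Hz mono. Pure tones are sinusoids with linear
onset/offset ramps (the pitch-task standard: 1000 Hz, 400 ms, 25 ms
ramps). Melody notes use a pluggable timbre, by default a ramped
sinusoid with 5 ms ramps — the original instrument sound is unspecified,
and a sinusoid makes the spectral content of every task stimulus
analytically known. Note onsets fall at cumulative beat positions times
60/tempo, and the clip length equals the closed-form beat-sum
prediction within one sample. Metronome clicks are 10 ms damped 1 kHz
bursts: sharply onset, so they are themselves detectable by the onset
detector to sub-millisecond accuracy.

Files are RMS-normalized to −20 dBFS (and peak-limited) so relative
loudness is uniform across tasks. The absolute presentation level
(75 dB SPL in administration) is a playback calibration outside the
files themselves. WAV I/O is 16-bit PCM; round-trips are exact to one
quantisation step.

## Tap-onset detection and SEA

The detector squares the trial sample-wise and thresholds at
k·SD(squared trial), k = 4 by default. The first sample of each
supra-threshold run is a candidate; candidates are accepted left to
right and a 200 ms refractory window after each accepted onset
suppresses the rest of the same tap. Accepted onsets are therefore
always ≥ 200 ms apart, exactly. Because the threshold is relative to
the whole trial's energy distribution, a trial of pure light-tailed
background (e.g., low-level uniform noise) yields no onsets at all,
while heavy-tailed noise can produce spurious candidates — which is why
the workflow is semi-automatic: `inspect_detection()` returns the
candidate-level table (time, peak energy, accepted flag) that a human
reviews, re-running with adjusted `k` or refractory length per
participant when needed.

Taps are paired to clicks by the standard sensorimotor-synchronization
convention: nearest click within half the click inter-onset interval,
at most one tap per click, closest wins, unmatched taps and clicks
dropped. The trial score is the **standard error of asynchronies**,
read literally as SD/√n; `sea(type = "sd")` exposes the plain SD, which
differs only by the √n factor (constant at the fixed 20-tap trial
length). The child's outcome is the mean SEA over the 100 and 120 BPM
trials, since a single rate is unlikely to match any child's preferred
tempo. With 20 taps per trial the two conventions order children
identically; the package treats 20 clicks as the per-trial task length.

## Scoring and the phonological composite

Oddity tasks score as exact percent correct. Song production is the
mean of two independent 0–10 ratings, with `inter_rater()` reporting
the Pearson agreement. The phonological-awareness composite is a PCA on
the standardized subtests: components are retained by the Kaiser
criterion (eigenvalue > 1), loadings are eigenvector·√eigenvalue, and
factor scores use the regression method (for a PCA this reduces to
Z·V·Λ^(−1/2), mean 0 and SD 1 by construction). The extraction method
of the original scoring software is unknowable; the regression method
is the common default and is exposed as such. Diagnostics are KMO
(zero-order vs partial correlations from the inverse correlation
matrix) and Bartlett's sphericity χ² = −(n−1−(2p+5)/6)·ln det R with
p(p−1)/2 df — 6 df for the four subtests. Incomplete rows are deleted
listwise; the cohorts this battery serves routinely have per-task
missingness, and listwise deletion is the simplest defensible default
for a 4-variable PCA.

## The model ladder

`fit_lm()` is OLS on complete cases with coefficients reported
standardized (every variable z-scored); R², the overall F and the
Gaussian-ML AIC (constants included) come from the raw-scale fit.
`backward_eliminate()` repeats single-term deletions, each round
removing the term whose deletion most improves AIC, stopping when no
deletion improves it — the stopping rule a `drop1()`-style AIC workflow
implies; a p-value mode (drop the largest p > 0.05) is provided since
the elimination threshold in such workflows is often informal.
`compare_nested()` is the extra-sum-of-squares F test.

Interaction models are built from centred products (raw products
optional). By default the products enter *without* their constituent
main effects, mirroring the model structure this battery's analyses
tabulate; because that specification is non-standard — it confounds the
interaction with the mains — the function warns, and
`main_effects = TRUE` gives the conventional model.
`simple_slopes_points()` evaluates the unstandardized fit at the 2×2
grid of mean ± 1 SD of skill and moderator, holding covariates at
their means; these are the four points the moderation figures connect.

## Synthetic data: what it emulates, what it does not

`simulate_cohort()` draws a Gaussian copula at the requested
correlation structure, rescales to each variable's mean and SD, and
clamps to the legal score range. The default marginals
(`cohort_defaults()`) are the battery's reference-cohort values, e.g.
rhythm mean 8.60, SD 2.19 on a 1–12 scale. Clamping at a boundary
within ~1.5 SD of the mean (rhythm's ceiling) biases that variable's
realised mean by ≈ 0.03 SD and mildly attenuates its correlations —
visible in recovery tests as a small downward bias on large effects.
Simulated scores are continuous where real task scores are integer
counts; tests of the scoring arithmetic use integer responses instead.

`simulate_tapping_audio()` puts one tap per click at click time + mean
offset + N(0, σ) jitter over white noise. The tap transient is a
sharply-attacked damped 1 kHz sinusoid (instant attack, ~5 ms decay
constant), chosen so the squared-energy detector crosses threshold
within a fraction of a millisecond of the true onset — the generator is
a fixture for the detector's timing accuracy, not a physical model of a
drum. SNR is the tap-transient-to-noise power ratio in dB. Real
recordings differ in ways the generator does not emulate: tap-to-tap
amplitude variation, double bounces, room reverberation, and missed or
extra taps; passing recovery tests therefore demonstrate the
algorithm's correctness under its stated model, not field robustness —
that is what the semi-automatic review loop is for.

`simulate_oddity_responses()` uses P(correct) = 0.5 +
0.5·logistic(ability − difficulty): a guessing floor of 0.5 (two
alternatives), 0.75 at ability = difficulty, ceiling 1.

## Numerical choices and problem sizes

Onset times are sample-accurate (first supra-threshold sample, 0-based,
divided by the rate); refractory comparison is done in integer samples,
so the 200 ms spacing is exact. Rhythm-grid sums are compared at 1e−9
beats. PCA component signs are fixed so each component loads positively
on the subtest mean. Ties in tap-click pairing resolve to the earlier
tap. The test-suite problem sizes were chosen to make sampling error
negligible relative to each tolerance: 100 seeds for jitter-recovery
(σ estimated from 20 taps has ≈ 16% sampling SD, so the mean over 100
seeds is known to ≈ 1.6%), 2000 simulations for the nested-F type-I
rate (binomial SE ≈ 0.5 points at the 5% target), and 100 cohorts of
n = 300 for effect recovery and backward-elimination selection.

## Known limitations

Stimulus generation covers major keys and monophony only; no expressive
timing, harmony or alternative modes. The exact melodies of the
original battery are unrecoverable (only their construction constraints
are printed), so the item bank is a constraint-faithful regeneration,
not a replica. Inter-trial intervals are left to the administrator. The
package deliberately does not attempt to reproduce any cohort's
empirical regression coefficients: the synthetic cohorts demonstrate
that the pipeline recovers known structure, not that any particular
substantive finding replicates.
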