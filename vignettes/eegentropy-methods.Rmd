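---
title: "Methods: EEG complexity and directed phase-based connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG complexity and directed phase-based connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegentropy)
```

This vignette explains the estimators the package implements, the
assumptions behind them, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
decisions that were genuinely open.

## The analysis problem

Resting-state EEG studies of neurodevelopmental conditions commonly
summarize each subject's multichannel recording two ways: by the
*complexity* of each channel (how unpredictable the signal is, which tracks
the flexibility of the underlying cortical dynamics) and by the *directed
effective connectivity* between channels (which way information flows, and
how strongly). Group contrasts of these summaries — patients vs controls,
or pre- vs post-intervention — are then tested electrode by electrode or
edge by edge with multiplicity control. This package implements that whole
chain for the 8-channel frontal/temporal/central/occipital montage (F3, F4,
T3, C3, C4, T4, O1, O2, 1000 Hz) typical of paediatric clinical recordings,
while accepting arbitrary montages.

## Sample entropy and its multiscale extension

Sample entropy treats a series as a source of length-`m` templates and asks
how often templates that match within a tolerance `r` (Chebyshev distance,
self-matches excluded) continue to match at the next sample:
`SaEn = ln B − ln A`, with `B` and `A` the m- and (m+1)-point match counts.
It is the negative log of a conditional probability, so it is
non-negative, and because `r` is defined as a multiple of the series' SD it
is invariant to amplitude scaling — a gain change in an amplifier cannot
change the result. Defaults are the clinical-EEG convention `m = 2`,
`r = 0.15 × SD`. The whole recording is used (no epoching): the statistic's
bias does not depend strongly on length, and epoching would only discard
data.

Two degenerate outcomes need care. When every m-match extends (perfectly
regular signals) the value is 0. When *no* (m+1)-template pair matches, the
conditional probability is 0/positive and the statistic is undefined; the
package returns `NA` with a warning rather than a silent 0, because a zero
would drag group means toward "perfectly regular" for exactly the channels
where estimation failed.

The implementation sorts templates on their first coordinate so candidate
pairs are confined to a sliding window of width `2r`; it returns *exactly*
the brute-force counts (the test suite checks equality to 1e-12 against an
independent O(N²) counter across 20 seeds) at roughly 100× the speed on
60-second, 1000 Hz channels.

Multiscale entropy coarse-grains the series by non-overlapping means of `s`
consecutive samples (length `⌊N/s⌋`, trailing remainder dropped) and
re-evaluates SaEn at each scale `s = 1…20`. The tolerance stays fixed at
`0.15 × SD` of the *original* series across all scales. The alternative —
re-deriving `r` from each coarse-grained series — would renormalize away
the very variance reduction that coarse-graining produces and make white
noise look complex at every scale; with fixed `r` the package reproduces
the classic signatures (white-noise MSE decays with scale; 1/f noise stays
high, and exceeds white noise by scale 10), which the acceptance suite
verifies on 20 seeds. Scales where the statistic is undefined are reported
missing and excluded from the scale-averaged summary.

## Phase transfer entropy and dPTE

Transfer entropy measures how much the source's past reduces uncertainty
about the target's future beyond the target's own past. The phase variant
applies this to instantaneous phases of narrowband signals, which makes it
robust to linear mixing and volume conduction. The package extracts phases
by zero-phase band-pass (4th-order Butterworth, forward–backward) followed
by the Hilbert analytic signal, wrapping to [−π, π). Narrowbandness is a
precondition for the phase to be well defined, hence the band-pass is part
of the operation, with the four canonical bands δ/θ/α/β as defaults.

The estimator is the plug-in histogram form

`PTE = H(θy(t), θy(t′)) + H(θy(t′), θx(t′)) − H(θy(t′)) − H(θy(t), θy(t′), θx(t′))`

with `t′ = t − δ`, natural logarithms, and only overlapping samples
entering the histograms. Three numerical choices:

* **Bins.** Width follows the Scott-type rule `3.5σ/N^(1/3)` with σ the SD
  of the (pooled) wrapped phases and `N` the per-series sample count, and
  `n_bins = ⌈2π / width⌉` over the fixed circular support [−π, π). Phases
  enter wrapped (phase is circular; unwrapped phases would place each
  cycle in new bins and starve the histogram).
* **Delay.** One prediction delay per recording and band,
  `δ = round(N_s × N_ch / N_±)` clamped to ≥ 1, where `N_±` counts sign
  changes of the wrapped phase pooled over channels. Faster bands change
  sign more often and get shorter delays, roughly a quarter cycle of the
  band's centre frequency. Pooling over channels (rather than per-pair
  delays) follows the formula's `N_ch` term and keeps the whole matrix on
  one time base.
* **Bias.** The plug-in estimator can go slightly negative on finite data.
  Negative estimates are floored at 0 before the dPTE normalization
  `dPTE = PTE_xy / (PTE_xy + PTE_yx)`, which presumes non-negative weights;
  when both directions floor to 0 the balanced value 0.5 is returned. No
  bias correction is applied to the raw PTE values themselves — the
  directional index and the group contrasts both difference the bias away,
  and the suite validates the estimator at the level that matters:
  equality with a brute-force probability-table computation (1e-12),
  exact antisymmetry `dPTE_xy + dPTE_yx = 1`, balance on exchangeable
  inputs, null calibration (mean |dPTE − 0.5| < 0.05 on independent
  narrowband channels at N = 60000), and ≥ 95% direction recovery on
  strongly coupled pairs over 50 seeds.

Node in-/out-strengths are row/column sums of the directed PTE matrix with
the diagonal stored as missing — a channel contributes no self-flow.

## Preprocessing

The chain is notch (constrained biquad, Q = 30, default 50 Hz), band-pass
(0.5–45 Hz Butterworth), optional EEMD–ICA artifact suppression, amplitude
segment rejection, and common-average re-referencing. All filters run
forward–backward, and the implementation pads with odd reflection sized to
several time constants of the slowest corner so startup transients decay in
the padding, not in the data; a 4 s tone burst shows zero lag against its
filtered version in the tests. Common average was chosen as the offline
reference: recordings in this montage are referenced to Cz at acquisition,
and the average reference is the conventional, montage-agnostic offline
target; it forces per-sample channel sums to zero and is idempotent.

Artifact suppression decomposes each channel with ensemble EMD (defaults:
50 ensembles, noise SD 0.2 × SD(x), sifting stopped at SD criterion ≤ 0.2
or 10 sifts — a deliberately simple, documented EEMD variant), pools all
channels' IMFs, unmixes them with symmetric FastICA (tanh contrast), and
rejects components with excess kurtosis above 5 — the signature of sparse
transients such as blinks. A low-frequency power-fraction criterion is
available (`lowfreq_thresh`) but disabled by default: after the 0.5 Hz
high-pass, genuine slow EEG components also concentrate below 4 Hz, and on
synthetic blink-contaminated recordings an automatic sub-4 Hz cut measurably
*reduced* the cleaned signal's correlation with ground truth, while
kurtosis-only rejection improved it on 6–8 of 8 channels. Because most of
the EEG-derived IMF sources are near-Gaussian, the ICA rotation within
that subspace is not identifiable; the iteration therefore keeps the state
closest to a fixed point and treats a residual oscillation below 0.01 as
converged, restarting from fresh seeds a few times otherwise. True
non-convergence is reported with a warning and the recording passes through
unchanged — a no-op is safer than an unconverged unmixing. Visual segment
rejection is replaced by a deterministic rule (drop any 1 s window
exceeding 150 µV on any channel), with a manual-mask escape hatch.

Since EEMD is by far the most expensive stage (minutes per minute of 1000 Hz
data), it is off by default in the pipeline configuration and enabled with
`eeg_config(eemd_ica = TRUE)`; filtering, rejection and re-referencing
always run.

## Group statistics

Each feature (channel × metric, or band × edge/node) is tested separately:
Shapiro–Wilk on both groups (or on the paired differences); if normality is
not rejected at 0.05, a Student t-test — pooled variance, matching the df
convention of the sensitivity analysis; Welch is available behind a flag —
otherwise a Mann–Whitney/Wilcoxon fallback flagged by `normality_ok =
FALSE` as exploratory. Benjamini–Hochberg adjustment is applied within each
feature family (one metric across channels; one band across edges), not
globally: families are the units in which results are read and reported,
and global pooling would let a strong family mask weak ones. Under the
global null the suite verifies the empirical per-comparison false-positive
rate stays within [0.025, 0.075] at α = 0.05 over 1000 replicates of 20
features with 24 subjects per group.

The sensitivity analysis solves for the minimal detectable Cohen's d on the
exact noncentral-t distribution (independent: df = 2n − 2, ncp = d√(n/2);
paired: df = n − 1, ncp = d√n) by root-finding to |power error| < 1e-6; at
n = 24 per group, α = 0.05, power = 0.80 it returns d = 0.826. The
analogous paired-design number sometimes quoted for such designs (0.61) is
not consistent with any (n, power) combination in this design family under
the exact computation, so it is documented here but not produced as a
result.

## The synthetic cohort generator

Each channel is built as `complexity_scale × (1/f^γ background) +
oscillations + coupled components (+ blinks)`, standardized to 20 µV SD.
Choices and rationale:

* `γ = 1` background and an α-band oscillation at amplitude 0.8 of the
  unit-variance background: a generic awake resting spectrum. The study
  population's actual spectra are not characterized; these are calibration
  choices, not claims about any cohort.
* `complexity_scale` multiplies only the broadband component, so lowering
  it raises the predictable fraction of the signal and lowers SaEn at every
  channel — a controlled, sign-known complexity deficit. A per-subject
  log-normal jitter (SD 0.05) provides realistic between-subject spread
  while keeping a 10 vs 10 contrast of 0.7 vs 1.0 reliably detectable.
* Coupling edges add a band-limited source into the source channel and its
  `k`-scaled, `lag`-delayed copy into the target, creating a genuine phase
  lead detectable by PTE. Band-limited components are made with the same
  zero-phase Butterworth family the analysis uses, so estimator tests are
  not confounded by filter mismatch. Coupling is amplitude-additive rather
  than a phase-equation model: simpler, and sufficient to produce directed
  phase relationships.
* Blinks are 0.3–0.5 s raised-cosine bumps of 100–200 µV, frontally
  weighted — parameterized transients, not biophysical ocular models.
* Default duration is 60 s rather than a clinical ~5 min, to keep
  simulation-heavy validation fast; it is configurable upward.

What the generator does **not** emulate: volume conduction and a head
model (channels share no mixing matrix), non-stationarity over minutes,
realistic artifact morphology beyond blinks, and any particular clinical
population's spectra. Passing recovery tests on this generator therefore
demonstrates that the estimators detect what they claim to detect under
controlled conditions — not that any specific clinical effect would be
found in real data.

## Problem sizes used in validation

The suite validates at sizes chosen to make the statistical properties
sharp: oracle equivalence at N ≤ 500 (20 seeds); MSE class separation at
N = 20000 (20 seeds); coupling direction recovery and null balance at
N = 60000 (50 seeds each); cohort recovery on 10 vs 10 subjects × 60 s ×
1000 Hz with SaEn (scale 1) as the tested quantity; null calibration on
1000 replicated 20-feature tables. The full 20-scale MSE and 4-band
connectivity run appears in smaller worked examples.

## Known limitations

* The histogram PTE estimator's absolute values are bias-inflated at large
  bin counts; only differences and the dPTE index are interpretable, which
  is how the package (and the field) uses them.
* EEMD–ICA is effective against sparse high-kurtosis transients; slow
  drifts below the high-pass corner and continuous EMG are out of its
  default reach (the `lowfreq_thresh` and manual-mask options exist for
  those cases).
* The rank-test fallback changes the tested hypothesis (stochastic
  dominance rather than mean difference); such rows are flagged and should
  be read as exploratory.
* EDF output uses a single data record with 16-bit scaling per channel:
  round trips are exact only to the quantization step of each channel's
  physical range.
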