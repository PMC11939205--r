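# eegentropy

Complexity and directed phase-based effective connectivity analysis for
multichannel resting-state EEG, with the group statistics used to compare
clinical cohorts (e.g. autistic vs typically developing children, or pre- vs
post-intervention recordings) and a synthetic cohort generator that makes
every stage testable without clinical data.

## What it computes

**Signal complexity.** Sample entropy of a series of length *N* with
embedding dimension *m* and tolerance *r*:

    SaEn(m, r) = ln B^m(r) − ln A^m(r)

where *B* and *A* are the average counts of template pairs (self-matches
excluded, Chebyshev distance ≤ *r*) that match for *m* and *m + 1* points.
Defaults follow the common clinical-EEG convention *m* = 2,
*r* = 0.15 × SD of the original series. Multiscale entropy (MSE) evaluates
SaEn on coarse-grained series

    y_j^(s) = (1/s) Σ_{i=(j−1)s+1}^{js} x_i ,  j = 1 … ⌊N/s⌋

for scale factors *s* = 1…20, with *r* held fixed from the scale-1 series,
plus the scale-averaged MSE summary.

**Directed connectivity.** Instantaneous phases θ(t) are extracted per
frequency band (δ 0.5–4, θ 4–8, α 8–13, β 13–30 Hz; zero-phase Butterworth
+ Hilbert transform), and phase transfer entropy is estimated from
histograms of the binned phases:

    PTE_{X→Y} = H(θy(t), θy(t′)) + H(θy(t′), θx(t′))
              − H(θy(t′)) − H(θy(t), θy(t′), θx(t′))

with past states at t′ = t − δ. The prediction delay δ is
(N_s × N_ch) / N_± (N_± = phase sign changes pooled over channels), the bin
width follows the Scott-type rule 3.5σ/N^(1/3), and entropies use the
natural log. The directed index

    dPTE_{xy} = PTE_{xy} / (PTE_{xy} + PTE_{yx}) ∈ [0, 1]

is 0.5 for balanced flow and > 0.5 for net x → y information flow; node
in-/out-strengths sum the directed PTE weights entering/leaving each
electrode.

**Statistics.** Per feature: Shapiro–Wilk normality gate, then Student
t-tests (independent or paired) or a rank fallback, Benjamini–Hochberg FDR
within each feature family, plus exact noncentral-t sensitivity analysis
(minimal detectable Cohen's d) and Pearson correlation of behavioural
scores with connectivity features.

**Preprocessing.** 50 Hz notch and 0.5–45 Hz band-pass (both zero-phase),
optional EEMD–ICA artifact suppression (ensemble empirical mode
decomposition per channel, FastICA across the pooled IMFs, kurtosis-based
component rejection), amplitude-threshold segment rejection, common-average
re-reference.

**Synthetic cohorts.** 1/f background + band-limited oscillations +
directed, lagged band-specific coupling + blink-like frontal transients,
with a per-group *complexity scale* that controls the broadband/oscillation
mixture (lower ⇒ more regular signals ⇒ lower SaEn). Everything is
seed-deterministic.

## Worked example

```r
library(eegentropy)

dir <- tempfile()
specs <- list(asd = sim_spec(6, fs = 250, duration_s = 30, complexity_scale = 0.7),
              td  = sim_spec(6, fs = 250, duration_s = 30, complexity_scale = 1.0))
man <- gen_cohort(specs, dir, seed = 42)
cfg <- eeg_config(scales = 1:10, bands = c("alpha", "beta"), seed = 42)
res <- run_pipeline(man, cfg, quiet = TRUE)

res$tables$comparison_complexity |> dplyr::filter(family == "saen")
#> # A tibble: 8 × 10
#>   family feature test         statistic   p_raw   p_fdr normality_ok   n_a   n_b
#>   <chr>  <chr>   <chr>            <dbl>   <dbl>   <dbl> <lgl>        <int> <int>
#> 1 saen   C3      independent…     -5.92 1.48e-4 1.48e-4 TRUE             6     6
#> 2 saen   C4      independent…     -8.00 1.18e-5 2.37e-5 TRUE             6     6
#> 3 saen   F3      independent…    -10.7  8.80e-7 7.04e-6 TRUE             6     6
#> 4 saen   F4      independent…     -8.91 4.51e-6 1.20e-5 TRUE             6     6
#> 5 saen   O1      independent…     -9.62 2.27e-6 9.07e-6 TRUE             6     6
#> 6 saen   O2      independent…     -6.29 9.03e-5 1.20e-4 TRUE             6     6
#> 7 saen   T3      independent…     -6.96 3.91e-5 6.26e-5 TRUE             6     6
#> 8 saen   T4      independent…     -5.92 1.46e-4 1.48e-4 TRUE             6     6
```

The negative t statistics say the group generated with `complexity_scale
0.7` has lower sample entropy on every electrode, and all eight channels
stay significant after FDR adjustment — the injected complexity deficit is
recovered. `res$tables$edges` holds the per-band directed PTE/dPTE edge
lists, `res$tables$nodes` the in-/out-strengths, and
`write_results(res, out_dir)` writes everything as TSV plus a JSON run
summary. Each result type has `tidy()`/`glance()` methods and
`autoplot()`/`plot_mse_curves()` visualisations.

A thin command-line wrapper for shell use lives at
`inst/cli/eegentropy-cli.R` (subcommands `simulate`, `preprocess`,
`complexity`, `connectivity`, `stats`, `run`).

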