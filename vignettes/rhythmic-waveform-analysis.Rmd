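---
title: "Quantifying age-dependent rhythmic alteration of diurnal expression waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying age-dependent rhythmic alteration of diurnal expression waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmshift)
```

## The problem

Under a light/dark cycle, a large fraction of a plant transcriptome cycles
with a 24-h period. As leaves age, these rhythms do not merely lose
amplitude or shift phase: the *shape* of the daily waveform changes — the
duration for which a gene stays above half of its daily maximum can shorten
or lengthen, and the timing of its rise and fall can move. `rhythmshift`
quantifies this "rhythmic alteration" with four connected pieces:

1. **Rhythmicity detection** — which genes cycle at all (`detect_cycling()`).
2. **Waveform parameterization** — crest, ascending/descending sections, and
   full width at half maximum, FWHM (`fwhm()`, `sections()`).
3. **Replicate-permutation inference** — which genes have a well-defined
   single daily oscillation, and whose FWHM changes with age (`sog_test()`,
   `fwhm_change_test()`).
4. **Physiological time** — what time of day a whole transcriptome profile
   "looks like", via a circular ridge-regression estimator
   (`fit_time_model()`, `predict_time()`).

All stages are exercised on synthetic diurnal time courses with known
ground truth (`simulate_expression_matrix()`), so the estimators' recovery
properties are testable without external data.

## Rhythmicity: fixed-period cosinor

For gene expression $y$ measured at Zeitgeber times $t$ (hours after
lights-on), we fit by ordinary least squares

$$y(t) = M + \beta_c \cos\left(\tfrac{2\pi t}{24}\right)
            + \beta_s \sin\left(\tfrac{2\pi t}{24}\right) + \varepsilon,$$

giving mesor $M$, amplitude $A = \sqrt{\beta_c^2+\beta_s^2}$ and acrophase
$\phi = \tfrac{24}{2\pi}\,\mathrm{atan2}(\beta_s, \beta_c)$. The rhythmicity
p-value is the F-test of the two rhythm coefficients against the
intercept-only model. A gene is called cycling when $p < \alpha$ with
$\alpha = 5\times 10^{-4}$ by default; following the original procedure the
threshold is applied raw, with no multiple-testing correction (the
threshold is exposed as an argument). At least 4 distinct time points are
required; with the standard 6-point design the test has $2$ and $n-3$
degrees of freedom. Exact fits report the double-precision floor rather
than a p-value of zero, and zero-variance genes report $p = 1$ and
amplitude 0.

Whether the published 0.0005 cutoff was applied to this model-F p-value or
to another fit statistic is not recoverable from the methods text; we use
the model F-test, which is the conventional cosinor significance measure.

## Waveform parameterization

A single daily cycle is min-max normalized ("the minimum value becomes 0,
the maximum 1"; `normalize_minmax()`); amplitude-comparable displays use
division by the across-time mean instead (`normalize_by_mean()`). The
super-half-maximum set is $\{t : F(t) \ge 0.5\}$ evaluated at the samples;
its maximal contiguous runs are counted with circular wraparound across the
cycle boundary (a crest at ZT23 has one region spanning, say, ZT20 to ZT4).
When there is exactly one region, the ascending and descending crossings
are obtained by linear interpolation of the bracketing segment:

$$F^{-1}(0.5) = \frac{t_2\,(f_1 - 0.5) - t_1\,(f_2 - 0.5)}{f_1 - f_2},$$

and FWHM is the circular difference of the two crossings. Conventions,
each of them tested:

* a sample exactly at 0.5 counts as a crossing at that sample time (the
  interpolation formula returns the endpoint);
* crest and trough are the earliest maximal/minimal samples (ties flagged);
* multi-region curves report the region count and no FWHM — deciding
  whether a gene has "one" daily oscillation is delegated to the
  permutation test below rather than guessed from a single curve;
* `ascending + descending = cycle length` exactly, by construction.

Multi-day reporter traces are detrended with a centered, time-based running
mean (default window 24 h, shrinking at the edges) — the published analysis
says "detrended" without naming a method, and a one-period running mean is
the least structured choice that removes slow drift without touching the
24-h component. Free-running periods are estimated by a cosinor scan over
20–30 h in 0.05-h steps, taking the period with maximal $R^2$; a best fit
that is not significant at $10^{-3}$ is flagged non-rhythmic instead of
being assigned a period. The original luminescence period algorithm is
unnamed, so this scan is a documented stand-in and printed period values
are not treated as reproduction targets.

## Replicate-permutation inference

With $r$ replicates at each of $T$ time points, a *permutation curve* draws
one replicate value per time point uniformly at random ($r^T$ possible
curves, sampled with replacement). The ensemble (default $n = 10{,}000$)
drives two tests:

* **Single oscillation genes (SOGs).** `single_ratio` is the fraction of
  ensemble curves with exactly one super-half-maximum region; a gene with
  `single_ratio > 0.95` is a SOG. Degenerate (constant) curves count as
  non-single. Only SOGs have a well-defined FWHM, reported as the ensemble
  mean over single-region curves.
* **FWHM change.** For a gene that is a SOG at both ages,
  $\Delta\mathrm{FWHM}$ is the difference of ensemble-mean FWHMs (old −
  young). The published gates are $P < 0.05$ and $|\Delta| > 2$ h; the null
  construction behind the permutation p-value is not specified in the
  original methods, so we use the least-assuming scheme expressible with
  the machinery already defined: pool the two ensembles' FWHM values,
  resample group labels (default 1,000 times), and report the two-sided
  tail probability of the observed $|\Delta|$. Because ensemble means are
  precise, the p-value alone is permissive and the 2-h gate does the
  substantive work; the test's realized type-I error is simulated in the
  test suite and is far below 0.05.

Ensemble sizes are arguments everywhere (`n`, `n_null`); the test suite
runs at $n = 200{-}1{,}000$ for speed while defaults match the published
$10{,}000$.

## Physiological time

Two ridge-penalized linear predictors are trained on the reference-age
samples: one predicts $\cos(2\pi t/24)$, the other $\sin(2\pi t/24)$ of
the sampling time $t$. A profile's physiological time is the angle of the
two outputs, $\hat t = \tfrac{24}{2\pi}\,\mathrm{atan2}(o_2, o_1) \bmod
24$, and the error metric is the circular distance
$\min(|d|, 24 - |d|)$. Choices:

* features (typically the common-SOG set) are centered and scaled on the
  training samples; the intercept is unpenalized. The source analysis is
  silent on standardization; scaling makes the penalty comparable across
  genes of different expression magnitude.
* the penalty defaults to 1, the default of the common ridge
  implementations the original analysis invoked; it is exposed as
  `penalty`. The solver is the SVD closed form, exact for $p \gg n$.
* replicate predictions are aggregated by the circular (vector) mean —
  an arithmetic mean is wrong on the circle.
* validation is leave-one-*time-point*-out: all samples of one ZT are held
  out together, so the model never sees the time it is asked to predict.
* "noon" for distance summaries defaults to ZT8, mid-light under the
  LD 16:8 entrainment the data model assumes; it is configurable.

The subjective-time curve maps each query-age ZT to a reference-frame time;
spans between consecutive ZTs sum to 24 h around a full cycle (winding
number 1), a closure property the tests assert.

## The synthetic generator

Waveforms are powered half-cosine ramps: $s(t)$ rises 0→1 over `rise`
hours to the crest and falls 1→0 over `fall = period − rise` hours, and

$$w(t) = \mathrm{baseline} + \mathrm{amplitude}\cdot s(t)^{k}.$$

The family was chosen because its parameters independently control phase,
skew, and FWHM: at $k = 1$ the FWHM is exactly half the period; $k > 1$
sharpens (FWHM $\to 0$), $0 < k < 1$ broadens (FWHM $\to$ the full period).
Broad waveforms (FWHM beyond half the period, as real evening clock genes
show) therefore require $k < 1$. Ground-truth FWHM is computed on a dense
grid (0.001 h) with the same interpolation convention, and is cross-checked
in the tests against the family's closed-form crossings.

Default study conditions mirror the emulated designs: transcriptome mode
samples ZT 1, 5, 9, 13, 17, 21 with 3 replicates; qPCR mode samples every
30 min over 24 h; reporter mode generates multi-day traces at 20-min
intervals with an optional linear trend and a free period (e.g. 23.9 h for
an aged free-running rhythm). Replicate noise is multiplicative log-normal
with a given coefficient of variation (mean-preserving; all values stay
positive), defaulting to cv 0.1; an additive-Gaussian option exists for
analytic checks. The original publications do not report replicate
variance, so the noise levels are this package's calibration: cv 0.05
(clean qPCR-like), 0.1 (RNA-seq-like), 0.2 (stress case). Cycling-gene
parameters are drawn uniformly: peak phase over the full day, rise 6–18 h,
sharpness 1–4, amplitude 0.5–4 and baseline 0.5–2 expression units —
i.e. relative amplitudes from weak (0.25×) to strong (8×). Age effects
compose amplitude scaling, phase shift, and FWHM change (scaling $k$),
applied to a configurable fraction of cycling genes.

All randomness flows from one master seed through fixed per-gene
sub-streams, so the same gene index yields the same waveform and noise in
any configuration — subsetting a simulation is stable, and every run is
bit-reproducible.

### What the generator does and does not emulate

It reproduces the sampling designs, a realistic mix of cycling/flat genes,
age-dependent amplitude attenuation, phase shifts and waveform
broadening/sharpening. It does **not** model read-count discreteness,
normalization artifacts, correlated noise across genes, multi-peak genes
beyond additive bump mixtures, or trends within a day. Passing recovery
tests therefore demonstrates estimator correctness under the stated noise
model, not performance guarantees on any particular real dataset.

### Known limitations

* Half-max crossing precision is information-limited for weak rhythms: at
  replicate cv 0.05 on a 0.5-h grid, genes with amplitude below roughly
  1.5× their baseline have crossing standard errors approaching 0.25–0.5 h,
  so FWHM recovery to ±0.5 h is reliable only for moderately strong
  rhythms (the test suite quantifies this).
* Very broad waveforms (FWHM near the period) sit close to 0.5 for many
  consecutive samples; under fine (30-min) sampling, replicate noise then
  fragments the super-half-max region and such genes can fail the SOG
  gate even when genuinely unimodal. The coarser 6-point transcriptome
  grid is much less affected.
* With only 3 replicates, a single outlying replicate at a near-crossing
  time point propagates into a third of all permutation curves; SOG ratios
  for borderline genes are therefore noticeably seed-dependent.
* The cosinor p-value assumes Gaussian residuals; under the multiplicative
  noise model this holds only approximately at larger cv.

## Problem sizes used by the shipped tests

The test suite simulates at reduced but representative scales: detection
calibration at 20,000 null genes; permutation type-I at 200 null genes ×
1,000-curve ensembles; power at 10 seeds; physiological-time
cross-validation at 500 cycling features × 10 seeds; full-pipeline
integration at 40–60 genes with 300-curve ensembles. Defaults in the
package remain at the full published scales (10,000 permutations).

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  sim = sim_config(
    n_cycling = 40, n_flat = 20, noise_cv = 0.05, seed = 71,
    ages = list(
      young = age_effect(),
      old = age_effect(amplitude_scale = 0.5, phase_shift = 2,
                       fwhm_delta_mode = "broaden", applies_to = 0.5)
    )
  ),
  n_perm = 1000, seed = 71
)
bundle <- run_full_analysis(cfg)
bundle
```

The bundle holds per-stage tables (cycling calls, SOG calls, FWHM changes,
the subjective-time curve, correlation and PCA summaries); with `out_dir`
set, each is also written as TSV alongside a JSON report, and every printed
count is recomputable from those tables.
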