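---
title: "Methods: multi-assay FCGR3 copy-number determination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-assay FCGR3 copy-number determination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgr3cnv)
```

This vignette documents the statistical models behind each caller, the
assumptions of the synthetic cohort generator, and the design choices
made where the underlying methodology left the design open.

## The measurement problem

FCGR3A and FCGR3B are near-identical paralogs inside a copy-number
variable region. Each genotyping assay observes a *relative* signal —
a cycle-threshold difference, a peak-area ratio — whose expectation is
proportional to copy number, corrupted by multiplicative noise. The
caller's job is to map that continuous dosage estimate to a
non-negative integer, per gene where the assay resolves paralogs
(TaqMan, SYBR, REDVR) or for the locus total where it does not (PRT,
MSAT1/STR).

All callers share two conventions:

* **Rounding** is half-up (`round_half_up()`: 2.5 → 3). The boundary
  choice is not dictated by the assays; it is declared once and used
  everywhere, and is configurable in the sense that callers expose the
  continuous estimate so any other rule can be applied downstream.
* **Missingness is explicit.** A call that cannot be made (excessive
  replicate spread, unusable PRT reference peak) is flagged missing,
  never guessed, and evaluation denominators are pairwise-complete with
  the denominator printed beside every rate. This is also the assumed
  treatment wherever a real study's denominators are ambiguous.

## TaqMan duplex qPCR

The comparative model: with amplification efficiencies $E_t, E_r$ for
target and two-copy reference amplicon and mean cycle thresholds
averaged over replicate wells,

$$\widehat{CN} = CN_{cal}\; \frac{E_t^{\,\Delta Ct_t}}{E_r^{\,\Delta Ct_r}},
\qquad \Delta Ct = \overline{Ct}_{cal} - \overline{Ct}_{sample}.$$

Replicates are screened before averaging: any well more than
`outlier_cycles` (default 0.5) from the replicate median is discarded;
if the survivors still span more than `spread_max` (default 1.0)
cycles, the call is flagged missing. Defaults are in cycles; 0.5 is
roughly twice a well-behaved assay's replicate sd. Efficiencies default
to perfect doubling (2.0) and can be replaced by values fitted with
`fit_standard_curve()` ($E = 10^{-1/slope}$, slope in cycles per log10
dilution; fits below $R^2 = 0.98$ are refused for quantification).

**Diploid-mode anchoring.** The calibrator sample's own measurement
error enters every sample's estimate as a shared multiplicative
systematic (about 8% scale sd under the default noise), which a single
run cannot average away. `anchor_diploid_mode()` removes it the way
refined qPCR copy-number assays do in practice: the per-locus median
continuous estimate of the cohort is rescaled to 2 and integer calls
re-derived. This assumes the cohort's modal per-gene copy number is the
diploid 2 — true of the emulated population and of the reference
panels this locus is typed in — and needs a cohort-scale batch; it is
the default in `call_all_methods()` and off in the bare callers.

## SYBR Green qPCR (relative standard curve)

Target and reference quantities are interpolated on their own fitted
curves, and the sample's target/reference quantity ratio is normalized
to the calibrator's ratio and scaled by the calibrator copy number.
Samples interpolating more than one log outside the fitted dilution
range are flagged as extrapolated but still called.

## PRT + REDVR maximum likelihood

The paralog ratio test co-amplifies one product from both genes and a
reference product from chromosome 18; the raw area ratio is calibrated
against reference standards of known copy number
(`calibrate_prt()`): the calibration factor is the mean of
(raw ratio)/(true total / 2), and the error sigmas are empirical
standard deviations of the calibrated residuals — the ratio residual is
taken on the scale the likelihood uses (calibrated ratio minus
total/2). A degenerate calibrator set with zero residual variance
falls back to `sigma_floor` (0.05) with a warning; at least three
usable calibrators are required.

`ml_call()` scores every hypothesis $(a, b)$ with $a + b \le 8$:

$$\log L(a,b) = \log \pi(a,b)
 + \log \mathcal{N}\!\left(r;\; \tfrac{a+b}{2},\, \sigma_r\right)
 + \mathbb{1}[f_A \text{ observed},\, a+b>0]\,
   \log \mathcal{N}\!\left(f_A;\; \tfrac{a}{a+b},\, \sigma_f\right)$$

Design choices, in order of consequence:

* **Gaussian errors.** No distributional form is dictated by the assay;
  Gaussian on the calibrated ratio and digest fraction is the declared
  default, isolated behind `error_model()` so alternatives can be
  swapped.
* **Prior** uniform over all 45 hypothesis pairs with total ≤ 8 — no
  population prior, keeping calls data-driven.
* **The zero hypothesis** $(0,0)$ is scored with the fraction term
  omitted (a fraction is undefined without product), as is any
  hypothesis set when the digest fraction is missing.
* **Ties** (log-likelihoods within 1e-9) break toward the smaller
  total, then the smaller FCGR3A count — conservative for association
  use, where the risk allele is the deletion — and are always flagged.
  Margins below `margin_threshold` (1 nat) are flagged low-confidence;
  every input still yields a call.
* **The HNA1a/HNA1b (C147T) fraction** types neutrophil-antigen alleles
  within FCGR3B; how it should couple into the copy-number likelihood
  is not established, so it contributes a likelihood term only when a
  sub-allele split model is explicitly configured (`use_hna`), and is
  off by default.
* The reported FCGR3 call is always $a + b$ of the joint call, never an
  independently re-rounded total.

The caller is verified against an independently written brute-force
enumerator (plain nested loops, densities spelled out) on randomized
inputs; the two must agree exactly, since both are finite argmaxes.

## STR (MSAT1) with stutter correction

Polymerase slippage creates an artifact peak 2 bp below each true
allele with magnitude growing with allele length. The model is linear:
stutter area = $\alpha\,(L - L_0)$ × parent area, defaults
$\alpha = 0.002$/bp, $L_0 = 130$ bp, calibratable from single-allele
controls by least squares (`calibrate_stutter()`). The linear-in-length
form with a fitted offset is itself a declared choice — the phenomenon
is only known to grow with length.

`correct_slippage()` works from the largest peak down, subtracting each
peak's predicted stutter from the peak exactly 2 bp smaller, flooring
at zero, then dropping peaks below a noise floor (2% of the largest
corrected area). Working largest-first resolves cascades through runs
of 2 bp-spaced alleles in one pass. Correction is exactly idempotent
when no retained peak lies 2 bp below another; for 2 bp-spaced true
alleles a second application would re-subtract, so the correction is
applied exactly once in the pipeline.

Dosage then follows the normalizer-peak rules: with more than four
peaks the third-smallest-area peak is the per-copy unit, with three or
four the second-smallest, and — a declared extension, since the
published rules start at three peaks — with one or two peaks the
smallest, so a two-allele heterozygote defaults to one copy per
allele. Area ties break toward the smaller fragment. Each retained
peak's dosage is its area over the normalizer area, rounded half-up
with a floor of 1 (a surviving real allele cannot carry zero copies);
the call is the dosage sum. Both the rounded and unrounded sums are
reported.

## Consensus integration

`integrate_calls()` defaults to majority vote over non-missing integer
calls with ties settled by the TaqMan vote — TaqMan because it is the
most accurate single method both in the emulated conditions and in
published comparisons; the `integration_policy()` object makes the rule
explicit and swappable (precision weighting is available). Votes and
tie flags are carried as audit columns. Only integer votes are fused:
continuous estimates differ in scale and error structure across
methods, and the per-method tables a study would retain hold integer
calls.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws per-gene copy numbers independently with
mode 2 (defaults: 85% two copies, 5% one, 8% three, 1% zero and four),
spanning FCGR3 totals 2–7 like East Asian reference cohorts. The
defaults are stand-ins chosen for coverage of the observed classes, not
population estimates. Known limitations, deliberate:

* **No A/B linkage.** Real deletions at this locus remove contiguous
  regions so FCGR3A and FCGR3B losses are correlated; no joint
  distribution is established, so independence is the documented
  default.
* **Distinct STR alleles per copy.** Every copy receives its own
  dinucleotide-spaced MSAT1 length, so each peak carries one copy and
  the normalizer rules are exact. Real cohorts contain homozygous
  configurations (two copies sharing a length) for which *no*
  single-electropherogram dosage rule can recover the truth — a peak
  carrying two copies next to the normalizer is indistinguishable from
  one. Passing noise-free recovery tests therefore demonstrates the
  correctness of the correction/dosage arithmetic, not that STR typing
  of real homozygotes is error-free.
* **Replication protocol.** Every assay is emulated with the
  triplicate-wells, three-repeats design the callers assume: qPCR
  samples get 3×3 pooled wells, electrophoresis assays have their peak
  areas averaged over three repeats. Single-shot signals (set
  `assay_repeats = 1`) are substantially noisier and make the shared
  calibrator systematic dominate.
* **Noise forms.** Additive Gaussian on Ct and median-one
  multiplicative lognormal on areas — both consistent with measuring an
  exponential amplification on a log scale. Note the consequence: the
  *log* estimate is unbiased, so the mean continuous estimate exceeds
  the true copy number by $e^{\sigma^2_{\ln}/2}$ and, at low copy
  numbers, the integer-rounding boundaries are asymmetric on the log
  scale (the upper boundary $\ln 1.25$ is nearer than the lower
  $\ln 0.75$ at two copies). This is precisely the over-estimation
  tendency the evaluation layer is built to detect; Monte-Carlo tests
  assert means against the lognormal closed form, not against the copy
  number itself.
* The continuous array-style dosage reference is the true total with
  lognormal noise (CV 0.2, a typical array-level dispersion); it
  emulates relative-dosage behavior, not any particular platform.
* No sequence-level simulation and no raw fluorescence curves: Cts and
  peak tables are the inputs, as exported by instrument software.

## Evaluation conventions

Concordance is exact integer equality over pairwise-complete samples,
reported to two decimals (half-up) with the denominator; multiway
agreement requires all methods equal on a sample and so can only be
lower than the worst pairwise rate. Correlation against continuous
dosage uses continuous estimates when available (integer calls
otherwise) and records which was used. Error-direction profiles count
calls above/below/equal per true copy-number class; the partition
above + below + equal = class total is asserted property-style.

## Problem sizes and determinism

The test suite exercises noise-free recovery on a 500-sample cohort,
oracle equivalence on 1000 randomized maximum-likelihood inputs,
bias-direction and integration-gain properties on 1000-sample cohorts
(the latter pooled over ten seeds), sizes chosen so the full suite runs
in minutes while keeping binomial counting error well below the margins
under test. Every stochastic step flows from an explicit integer seed;
identical seeds give byte-identical outputs, which the command-line
round-trip test checks by file checksum.
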