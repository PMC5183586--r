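# fcgr3cnv

Multi-assay copy-number calling and concordance analysis for the
paralogous Fc gamma receptor genes **FCGR3A** and **FCGR3B** (1q23.3).

## The problem

Low FCGR3B genomic copy number is associated with several systemic
autoimmune diseases, but association results have been inconsistent —
largely because the PCR-based assays used to type this CNV disagree with
one another and tend to over-estimate copy number. Anyone planning a
case-control association study at this locus needs to know how the
candidate genotyping methods behave, how concordant they are, and
whether combining them helps.

`fcgr3cnv` implements the full analysis stack for that question:

* **Four signal-to-integer-copy-number callers**
  * *TaqMan duplex qPCR* — comparative quantification against a known
    calibrator: `CN = CN_cal · E_t^{ΔCt_t} / E_r^{ΔCt_r}`, with the
    coagulation factor V gene as the fixed two-copy internal reference;
  * *SYBR Green qPCR* — the relative standard-curve method
    (`E = 10^{-1/slope}`, quantities interpolated per amplicon);
  * *PRT + REDVR* — the paralog ratio test (combined FCGR3A+FCGR3B
    product vs a chromosome-18 reference product) resolved into
    `(CN_A, CN_B)` by maximum likelihood over all hypotheses with
    `CN_A + CN_B ≤ 8`, combining the calibrated dosage ratio with the
    C733 (Arg→Stop) digest fraction:
    `log L(a,b) = log π(a,b) + log N(r; (a+b)/2, σ_r) + log N(f_A; a/(a+b), σ_f)`;
  * *STR (MSAT1)* — microsatellite peak dosage after polymerase-slippage
    correction (stutter area `α·(length − offset)` of the parent peak,
    subtracted from the peak 2 bp below, largest first) and
    normalizer-peak rounding.
* **A consensus integrator** (majority vote with a configurable
  tiebreak method, or precision weighting).
* **An evaluation layer** — pairwise and multiway concordance rates
  over paired samples, Pearson correlation against continuous
  array-style dosage, and per-true-copy-number error-direction profiles
  (the red/green over-call vs under-call split).
* **A synthetic cohort generator** that emulates a diploid population
  (mode 2 copies per gene), triplicate qPCR wells with Gaussian Ct
  noise, lognormal peak-area noise, length-dependent stutter, and a
  triplicate-by-three-repeats assay protocol — so the whole pipeline is
  testable end to end without any laboratory data.

Everything is tidyverse-native: callers take and return tibbles, result
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(fcgr3cnv)

noise  <- noise_model(ct_sd = 0.25, area_cv = 0.15, slippage_alpha = 0.002)
cohort <- simulate_cohort(n = 90, noise = noise, seed = 7)
calls  <- call_all_methods(cohort, integrate = TRUE)

concordance_with_reference(calls, cohort$truth, locus = "FCGR3")
#> <cn_concordance>
#>   FCGR3   integrated vs reference: 98.89% (89/90)
#>   FCGR3   prt_redvr vs reference: 91.11% (82/90)
#>   FCGR3   str vs reference: 100.00% (90/90)
#>   FCGR3   taqman vs reference: 95.56% (86/90)

concordance_pairwise(calls, c("taqman", "prt_redvr"))
#> <cn_concordance>
#>   FCGR3A  taqman vs prt_redvr: 92.22% (83/90)
#>   FCGR3B  taqman vs prt_redvr: 88.89% (80/90)
#>   FCGR3   taqman vs prt_redvr: 87.78% (79/90)

correlate_with_dosage(calls, cohort$dosage, method = "taqman", locus = "FCGR3")
#> <cn_correlation> taqman / FCGR3: r = 0.549 (n = 90, p = 2.16e-08, continuous estimates)

glance(error_direction_profile(calls, cohort$truth, locus = "FCGR3"))
#> # A tibble: 4 × 8
#>   method     locus     n n_above n_below n_equal pct_above pct_below
#> 1 integrated FCGR3    90       1       0      89      1.11      0
#> 2 prt_redvr  FCGR3    90       8       0      82      8.89      0
#> 3 str        FCGR3    90       0       0      90      0         0
#> 4 taqman     FCGR3    90       3       1      86      3.33      1.11
```

Reading the output: each concordance line reports the share of paired
samples whose integer calls agree exactly, always beside its
denominator (missing calls are excluded pairwise). Here the 8 samples
the PRT+REDVR caller gets wrong on this noisy cohort are all called
*above* the truth — the over-estimation tendency that motivates
integrating several methods, and indeed the majority consensus (98.89%)
beats every single qPCR/PRT method.

A shell entry point wrapping the same functions ships at
`inst/cli/fcgr3cnv.R` with subcommands `simulate`, `call-taqman`,
`call-sybr`, `call-prt-redvr`, `call-str`, `integrate` and `evaluate`;
see `?fcgr_cli`.

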