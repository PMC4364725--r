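---
title: "Paired delta-beta analysis of methylation array cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired delta-beta analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltabeta)
```

## The analysis problem

Short courses of recombinant human growth hormone (rhGH) reliably raise
circulating IGF1 — the IGF1 generation test — but whether they leave a
DNA-methylation signature in blood cells is a different question. The
statistical difficulty is that in paired baseline/stimulated designs the
inter-individual variance of methylation dwarfs any consistent treatment
effect: unsupervised analyses group samples by person, not by treatment, and
groupwise tests that survive multiple-testing correction come up empty. What
*can* be detected are individual-level responses: probes where particular
individuals shift methylation substantially between their two samples, in
directions that differ from person to person.

`deltabeta` implements that evaluation strategy as a reusable pipeline for
Illumina 450K-style beta-value matrices:

1. **QC**: per-sample call rate (fraction of probes with detection p < 0.01;
   samples must exceed 98%) and per-probe detection filtering (a probe must
   pass in every retained sample).
2. **Groupwise statistics**: relative-variance filtering
   ($\sigma_i/\sigma_{max} > \tau$), mean-centered PCA, pooled two-sample
   and paired t-tests per probe, Benjamini–Hochberg (BH) q-values.
3. **Individualized evaluation**: per-pair
   $\Delta\beta = \beta_{stim} - \beta_{base}$, trinary coding
   ($+1$ if $\Delta\beta > 0.1$, $-1$ if $\Delta\beta < -0.1$, else 0),
   recurrence filtering (a probe is a *recurrent target* when at least 3 of
   the pairs exceed the threshold), gene aggregation (genes hit by at least
   3 recurrent probes) and hierarchical cluster ordering of delta or code
   matrices.
4. **Cross-platform concordance**: Pearson correlation of per-pair deltas and
   Bland–Altman bias with limits of agreement at exactly ±2 sample SDs,
   on the percent scale.
5. **Cross-sectional arm**: treated-vs-untreated pooled t-test, per-probe OLS
   of beta on months of treatment, and targeted re-testing of candidate
   probes with BH adjustment inside the candidate universe.
6. **Clinical response**: the IGF1 generation test summary over the cohort
   table (paired t-test, strict-increase count, age distribution).

## Conventions and parameter choices

**Delta-beta sign.** $\Delta\beta$ is stimulated minus baseline, so a $+1$
code means methylation *gained* under treatment. (Descriptions of this
quantity sometimes invert the subtraction order while keeping the "gained"
label for positive values; we fix the convention that makes the labels
coherent.)

**Strictness.** All threshold comparisons on p-values, call rates, variance
ratios and delta-beta codes are strict inequalities. A call rate of exactly
0.98 fails ("above 98%"); a delta of exactly ±0.1 codes 0; p = 0.0001
exactly is not significant at `raw_p_max = 1e-4`. The call-rate boundary is
configurable (`call_rate_boundary = "inclusive"`).

**Probe retention rule.** "Detection p < 0.01 per CpG" does not by itself
say across how many samples; we adopt the strictest reproducible reading —
the probe must pass in **all** retained samples — and apply the sample
filter first, so a bad sample cannot eliminate probes. `apply_qc` is
idempotent and its report counts reconcile exactly.

**FDR.** `adjust_bh` is the Benjamini–Hochberg step-up procedure (via
`stats::p.adjust`), applied over the non-missing p-values only; missing
p-values pass through as missing. Other q-value estimators would give
slightly different boundaries; BH was chosen as the standard, fully
reproducible procedure.

**Unpaired test.** Pooled-variance Student t by default (`var_equal =
FALSE` gives Welch); two-sided throughout. Tests operate on beta values
directly, not M-values — the method is defined on the beta scale and an
M-transform is deliberately out of scope.

**PCA.** Probes are mean-centered only. Beta values share a common \[0,1\]
scale, so unit-variance scaling would up-weight near-constant probes.

**Clustering.** Euclidean distance, complete linkage, on rows and columns.
Missing codes impute to 0 (unchanged), missing deltas to the probe's mean
delta. An all-equal matrix returns the input order with a warning.

**Bland–Altman.** Limits of agreement are bias ± exactly 2 sample SDs
(n−1 denominator), not 1.96; inputs are expected in percent so array and
pyrosequencing measurements share a range. Pearson r is scale-invariant, so
it does not matter whether deltas are correlated as fractions or percent.

**Duration regression scope.** Untreated children carry duration 0; pooling
them with treated samples would make the slope partly re-encode group
membership. The default `scope = "treated_only"` avoids that; `"all"` is
available for sensitivity analysis. "No duration effect" is operationalized
as zero probes at q < 0.05.

**Even-n median.** The age median is the mean of the two central order
statistics (`stats::median`), which is what reproduces 9.17 years from the
24 printed ages.

## The cohort simulator

`simulate_paired_cohort` draws, per probe $g$, a population mean $\mu_g \sim
N(0, 2)$ on the logit scale; per individual $i$ a probe-specific offset
$a_{gi} \sim N(0, 1)$ shared by both timepoints; and measurement noise
$N(0, 0.02)$ added on the beta scale after the inverse-logit, truncated to
\[0,1\]. Planted response loci add $\pm 0.2$ (sign drawn per individual,
flipped when the draw would leave \[0,1\]) to the stimulated beta of 5 of
the 24 individuals. Detection p-values are Uniform(0, 0.001) for passing
calls and 0.5 for calls failed at rate 0.001. The logit-normal individual
effect is the simplest mechanism that yields bounded values whose
inter-individual variance dominates everything else — the structure the
paired design exploits — and the random response sign reflects the observed
heterogeneity of direction in real individualized responses.

A homogeneous treatment signature is **absent by default**
(`treatment_effect_sd = 0`): the planted heterogeneous responses are the
only treatment signal, matching the study conditions the pipeline was built
for. Setting `treatment_effect_sd` to a fraction of `individual_effect_sd`
(e.g. 0.2 vs 1.0) lets one verify that even a consistent shift five times
weaker than the individual effect leaves PCA grouping by individual intact.

`simulate_longterm_cohort` generates one sample per child, 36 treated and
18 untreated, with log-normal treatment durations (meanlog = log 33,
sdlog = 1.03, giving median 33 months and quartiles near 15.5 and 62.25);
group shifts or duration-linear slopes can be planted for power studies but
default to null. `simulate_validation_measurements` emulates targeted
pyrosequencing: the pyro value is the array beta in percent plus Gaussian
assay noise, so at zero noise the platforms agree exactly — the identity
used to validate the concordance statistics.

What the simulator does **not** model: Infinium I/II chemistry differences,
batch and chip effects, cell-type composition shifts, the bimodal-with-
intermediate shape of real beta distributions beyond what a logit-normal
gives, or spatial correlation among neighbouring CpGs. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the assumed variance structure, not that real cohorts satisfy those
assumptions.

## Numerical choices

* Per-probe t statistics and OLS slopes are computed with vectorized
  closed forms (per-row masked sums), verified against `t.test` and `lm`
  in the test suite.
* Zero-variance detection uses a near-zero threshold ($10^{-24}$) on the
  centered sum of squares: exactly-constant rows leave rounding residue of
  order $10^{-33}$, while any genuine beta-scale variance exceeds
  $10^{-16}$.
* Tables are written with shortest-round-trip decimal rendering (15
  significant digits, 17 where needed), so `load(write(x))` reproduces
  doubles bit-for-bit.
* `recurrent_targets(min_fraction = f)` converts a fraction to the count
  `floor(f * n_pairs) + 1` ("strictly more than"), which maps 10% of 24
  pairs to the 3-pair rule.

## Problem sizes in the validation suite

The packaged checks run at the study's own design sizes (24 pairs;
36 vs 18), with probe counts chosen per check: null calibration uses the
full 20,000-probe default (10 seeds), planted-recovery and PCA checks use
2,000 probes (20 and 3 seeds), and the cross-sectional null uses 10,000
probes (20 seeds). Under a global null the BH procedure rejects at least
one probe in about 5% of cohorts, so the "zero discoveries in ≥95% of
seeds" check sits exactly at its expectation and will occasionally fail by
chance for a particular seed set.

## A worked example

```{r example}
sim <- simulate_paired_cohort(sim_config(seed = 7, n_probes = 2000))
dr <- classify_trinary(compute_delta_beta(sim$bm, sim$design), threshold = 0.1)
rec <- recurrent_targets(dr, min_pairs = 3)
length(rec)                                   # ~100 planted loci recovered
mean(sim$truth$planted_probes %in% rec)       # sensitivity

s <- summarize_igfgt(load_clinical_table())
s
```

## Known limitations

* The pipeline analyzes exported beta matrices; raw intensity processing and
  normalization happen upstream.
* Recurrence counts treat pairs as exchangeable; no per-individual response
  covariates are modelled.
* Gene aggregation counts probes per annotated symbol; a probe annotated to
  several genes counts toward each, and annotation completeness directly
  limits the gene-level results.
* No batch correction or cell-type deconvolution: if such structure is
  present, it will inflate the individual-effect component.
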