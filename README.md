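# deltabeta

Paired delta-beta analysis of DNA-methylation array cohorts.

## The problem

Short-term stimulation with recombinant human growth hormone (rhGH) produces
a clear clinical response — circulating IGF1 rises within days — but its
effect on blood-cell DNA methylation is subtle and heterogeneous. In paired
baseline/stimulated 450K-array designs, inter-individual methylation variance
dominates any consistent treatment effect: unsupervised analyses cluster
samples by person, groupwise tests do not survive false-discovery-rate
correction, and the detectable signal consists of *individual* responses —
probes where particular people shift methylation substantially between their
two samples, in person-specific directions.

`deltabeta` packages that evaluation strategy for analysts working with
beta-value matrices (probes × samples, values in [0,1], with per-call
detection p-values):

* **QC**: per-sample call rate (probes with detection p < 0.01; samples must
  be above 98%) and per-probe detection filtering; autosomal/non-SNP probe
  subsetting for cross-sectional cohorts.
* **Groupwise statistics**: relative-variance filter (σᵢ/σ_max > τ),
  mean-centered PCA, per-probe pooled and paired t-tests, Benjamini–Hochberg
  q-values.
* **Individualized evaluation** (the core): per-pair
  Δβ = β_stim − β_base, trinary coding (+1 if Δβ > 0.1, −1 if Δβ < −0.1,
  else 0), recurrence filtering (≥ 3 pairs exceeding the threshold),
  gene-level aggregation (≥ 3 recurrent CpGs per gene), gene-list overlap,
  and hierarchical cluster ordering of delta/code matrices.
* **Cross-platform concordance**: Pearson r of per-pair deltas and
  Bland–Altman bias with limits of agreement at ±2 SD (percent scale).
* **Cross-sectional arm**: treated-vs-untreated t-test, per-probe OLS of
  beta on months of treatment, targeted re-testing of candidate probes.
* **Clinical response**: the IGF1 generation test summary over the packaged
  24-child cohort table.
* **Simulator**: logit-normal cohorts with individual-dominant variance,
  planted heterogeneous responses and a detection-failure model, with ground
  truth, so every stage is testable without external data.

## Worked example

```r
library(deltabeta)

# a simulated 24-pair cohort with 100 planted response loci
sim <- simulate_paired_cohort(sim_config(seed = 7, n_probes = 2000))
dr  <- classify_trinary(compute_delta_beta(sim$bm, sim$design), threshold = 0.1)
rec <- recurrent_targets(dr, min_pairs = 3)
length(rec)
#> [1] 100
mean(sim$truth$planted_probes %in% rec)   # sensitivity
#> [1] 1

# IGF1 generation test on the packaged clinical table
summarize_igfgt(load_clinical_table())
#> IGF1 generation test summary (n = 24)
#>   IGF1 increase in 22/24 patients (strict)
#>   paired t-test stimulated vs baseline: t = 6.312, p = 1.93e-06
#>   median age 9.17 years (range 5.17-15.42)
```

All 100 planted loci (|Δβ| = 0.2 in 5 of 24 pairs, noise SD 0.02) are
recovered by the 0.1/3-pair recurrence rule with no false positives, while
the same rule finds essentially nothing on fully null cohorts. The clinical
summary shows the expected strong short-term response: IGF1 rises in 22 of
24 children, paired t-test p ≈ 1.9 × 10⁻⁶.

End-to-end drivers `run_short_term()` and `run_long_term()` wire the stages
together and write all result tables plus a config echo as TSV; a thin
command-line wrapper lives at `inst/scripts/deltabeta-cli.R`.

## Documentation

The methods vignette (`vignettes/delta-beta-methods.Rmd`) describes the
model and conventions (delta-beta sign, strict thresholds, the all-samples
probe rule, BH over tested probes), the simulator's assumptions and what
they do and do not establish about real data, and the numerical choices.
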