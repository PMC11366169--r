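# imprintDMR

Methylation analysis of imprinted differentially methylated regions (DMRs)
in tumour cohorts, built around neuroblastoma. Imprinted DMRs are methylated
on exactly one parental allele, so bulk Illumina 450K-style beta-values sit
near 0.5 in normal biparental tissue. Tumours deviate from that
hemi-methylated state through true epimutations (gain or loss of methylation
on the methylated allele) or through allele-specific copy-number alterations
(CNAs) that change the ratio of methylated to unmethylated copies. This
package is for epigenomics researchers who want to classify those
deviations, decide which are copy-number artefacts, and ask whether they
predict outcome.

## What it computes

**Imprinting-status classification.** For sample *s* and probe *p* with
beta-value *β*, with a control reference (mean *μ*, SD *σ* over normal
samples):

- GOM if *β* > 0.8; LOM if *β* < 0.2 (strict, strong calls take precedence)
- Intermediate LOM if *β* < *μ* − 2*σ*; Intermediate GOM if *β* > *μ* + 2*σ*
- otherwise No change

A region call is the category backed by > 60% of the region's probes
(strict; no winner → No change, flagged ambiguous). A DMR is "most altered"
when > 30% of samples show strong GOM or strong LOM — in both cohorts when
a discovery and a validation set are supplied.

**CNA-predicted methylation.** From ASCAT-style allele-specific segments
(nMajor, nMinor), the minor methylation value is nMinor / (nMajor + nMinor).
If the majority of a region's probe betas are ≤ 0.5 the minor allele is
taken as the methylated one and the prediction equals the minor methylation
value; otherwise it is 1 − that value. Per region, observed methylation is
regressed on the prediction (OLS); the adjusted R² = 1 − (1 − R²)(n−1)/(n−2)
says how much of the methylation variance CNAs explain. Negative adjusted R²
means CNAs explain nothing — the signature of a true epimutation region.

**Cohort statistics and survival.** Pearson chi-squared association between
region status and clinical factors with Benjamini–Hochberg correction;
pairwise Wilcoxon comparisons of per-sample altered-DMR burden;
Kaplan–Meier/log-rank stratification by imprinting status (including within
the MYCN-non-amplified "low-risk" stratum split by 11q status); Cox
proportional-hazards contrasts (focal status vs No change, Efron ties) with
adjustment for age ≥ 1.5 years, MYCN amplification and 11q deletion; and a
Kaplan-scan optimal expression cutoff with Bonferroni correction over the
cutoffs tested.

**Synthetic cohorts.** `sim_config()` / `generate_cohort()` build complete
seeded cohorts — betas, controls, probe manifest, allele-specific segments,
clinical table, survival times — with recorded ground truth, plus
uniparental-diploidy reference samples (`generate_upd_references()`), so the
whole pipeline is testable without patient data.

A packaged catalog of 49 imprinted DMRs (GRCh37, 1-based inclusive
coordinates, methylated parental allele, overlapping genes) ships in
`inst/extdata/imprinted_dmr_catalog.tsv` and loads via `load_dmr_catalog()`.

## Worked example

A 300-tumour synthetic cohort in which one region (NNAT:TSS-DMR) gains
methylation in ~45% of tumours with a survival penalty (true HR 3), and one
(NDN:TSS-DMR) loses methylation in ~45%:

```r
library(imprintDMR)
catalog <- load_dmr_catalog()
cfg <- sim_config(
  seed = 7, n_tumours = 300,
  prevalence_overrides = data.frame(
    dmr_name = c("NNAT:TSS-DMR", "NDN:TSS-DMR"),
    GOM = c(0.45, 0), LOM = c(0, 0.45),
    INT_GOM = c(0.05, 0), INT_LOM = c(0, 0.10)),
  survival = list(baseline_hazard = 0.08, censor_time = 15,
                  effects = data.frame(dmr_name = "NNAT:TSS-DMR",
                                       status = "GOM", log_hr = log(3))))
cohort <- generate_cohort(cfg)

ctrl        <- build_control_reference(cohort$beta, cohort$control_ids)
mapped      <- map_probes_to_dmrs(cohort$probes[, 1:3], catalog)
tumours     <- setdiff(colnames(cohort$beta), cohort$control_ids)
probe_calls <- classify_probes(cohort$beta[, tumours], ctrl, mapped$probes)
region_calls <- call_regions(probe_calls)
head(summarize_cohort(region_calls)[, c("dmr_name", "n_called", "p_gom",
                                        "p_lom", "most_altered",
                                        "dominant_event")], 4)
#>             dmr_name n_called  p_gom p_lom most_altered dominant_event
#> 29      NNAT:TSS-DMR      300 0.4700 0.000         TRUE            GOM
#> 28       NDN:TSS-DMR      300 0.0000 0.417         TRUE            LOM
#> 39 SNU13:alt-TSS-DMR      300 0.0567 0.193        FALSE           <NA>
#> 7   GNAS-AS1:TSS-DMR      300 0.0500 0.183        FALSE           <NA>
```

Both planted regions clear the strict 30% most-altered rule; the recovered
proportions (0.470, 0.417) sit within sampling noise of the configured
prevalences. Survival stratification at the GOM region:

```r
nnat <- region_calls[region_calls$dmr_name == "NNAT:TSS-DMR", ]
surv <- cohort$clinical[match(nnat$sample_id, cohort$clinical$sample_id), ]
km_logrank(nnat$call, surv$os_time_years, surv$os_event)
#> Log-rank test: chi2 = 72.64 df = 2 p = <2e-16
#> Groups: GOM=141, INT_GOM=15, NO_CHANGE=144

cox_fit(nnat$call, surv$os_time_years, surv$os_event, focal = "GOM",
        adjusters = data.frame(
          mycn = as.integer(surv$mycn == "amplified"),
          age  = as.integer(surv$age_group == ">=1.5")))
#>               term   hr ci_low ci_high        p   n n_event
#> 1 GOM_vs_NO_CHANGE 2.96  2.265    3.86 1.44e-15 285     239
#> 2             mycn 1.17  0.852    1.61 3.31e-01 285     239
#> 3              age 0.93  0.713    1.21 5.92e-01 285     239
```

The adjusted hazard ratio for GOM vs No change (2.96, 95% CI 2.27–3.86)
recovers the simulated HR of 3; the clinical covariates, generated
independently of survival here, stay null.

## Vignette

`vignettes/imprintDMR-methods.Rmd` documents the model, thresholds, the
noise model and defaults of the synthetic generator, numerical choices and
known limitations.
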