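---
title: "Models and methods behind imprintDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imprintDMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintDMR)
```

## The biological model

An imprinted differentially methylated region (DMR) carries DNA methylation
on exactly one parental allele. On a bisulfite array, the beta-value at such
a locus — methylated intensity over total intensity — therefore averages
about 0.5 in normal biparental tissue. Two distinct mechanisms move a
tumour's beta away from 0.5:

1. **Epimutation**: methylation is gained on the unmethylated allele (beta
   drifts toward 1) or lost on the methylated allele (toward 0), with no
   change in DNA copy number.
2. **Allele-specific copy-number alteration (CNA)**: the ratio of methylated
   to unmethylated copies changes. A cell that loses the unmethylated allele
   shows beta near 1; a copy-neutral loss of heterozygosity shows 0 or 1; a
   3+1 aneuploid state shows 0.25 or 0.75.

Array data alone cannot distinguish the two, but their biology differs: an
epimutation changes gene expression, while losing the methylated (already
silent) allele does not. The package's pipeline first classifies deviations,
then uses allele-specific copy-number profiles to decide which regions carry
true epimutations.

## Classification thresholds

Probe calls use five ordered categories. With control reference mean $\mu_p$
and SD $\sigma_p$ per probe:

| Call | Rule |
|---|---|
| GOM | $\beta > 0.8$ |
| LOM | $\beta < 0.2$ |
| Intermediate GOM | $\beta > \mu_p + k\sigma_p$ (default $k = 2$) |
| Intermediate LOM | $\beta < \mu_p - k\sigma_p$ |
| No change | otherwise |

All inequalities are strict, and the strong calls are evaluated first, so a
beta of exactly 0.8 is not GOM (it is Intermediate GOM when outside the
control band), and a beta of 0.85 is GOM even when it also exceeds
$\mu + 2\sigma$. Strictness at every boundary makes the partition total and
monotone in beta, which the test suite asserts as a property.

The region call is the category supported by **strictly more than 60%** of
the region's usable probes. When no category clears 60% the original
majority rule is silent; we assign No change and set `ambiguous = TRUE`
rather than invent a tie-break, and the flag is preserved in outputs so
downstream users can exclude ambiguous calls. Probes with missing betas
leave the denominator; a region call is still made from what remains, and a
(sample, region) pair with no usable probe is excluded from all cohort
denominators.

"Most altered" regions are those with strong GOM or strong LOM in **strictly
more than 30%** of called samples — in both cohorts when a validation set is
given. Intermediate calls do not count toward this criterion, nor toward the
per-sample altered-DMR burden; the published phrasing reports intermediates
separately from the loss/gain percentages, and we follow that reading.

Control references require at least two control samples (otherwise the SD is
undefined). A control SD of exactly zero is allowed: the intermediate bands
collapse to the mean and any deviation becomes an intermediate call.

## CNA-predicted methylation and concordance

For a (sample, region) pair with allele counts `nMajor >= nMinor`, the minor
methylation value is $m = n_{minor} / (n_{major} + n_{minor})$. The
methylated haplotype is assumed to be the minor one when the fraction of the
region's probe betas at or below 0.5 is at least one half — equality folds
into the minor branch because the rule's wording places "equal to 0.5" in
the first case. The prediction is $m$ on the minor side and $1 - m$ on the
major side; a 1+1 diploid predicts 0.5 either way, and homozygous deletions
(total 0) are excluded with a warning.

When several segments overlap a region, the one covering the largest
fraction of the region wins and its coverage is recorded; allele counts are
never length-averaged across segments, which would produce non-integer
counts. Pairs with no overlapping segment are simply absent (in the source
data this happened for one region, which lacked CNA information entirely).

Per region, observed methylation — by default the **median** probe beta per
(sample, region); the outcome scalar is not pinned down by the published
method, and the median is robust to a single aberrant probe (the mean is
available via an argument) — is regressed on the prediction by ordinary
least squares. The adjusted coefficient of determination for this
single-predictor model is

$$\bar R^2 = 1 - (1 - R^2)\frac{n-1}{n-2},$$

which is negative when the predictor fits worse than the mean-only model.
That sign is informative: copy-number-driven regions show $\bar R^2$ near 1,
epimutation-driven regions near or below 0.

One subtlety the simulation exposes: because the side-selection rule reads
the observed betas, predictions are not fully independent of observations
even at an epimutation-driven region. Whenever such a region sits on a
chromosome with a *high* CNA rate, samples carrying both an epimutation and
a loss get concordant (observed ≈ 0, predicted = 0) pairs and the adjusted
R² can reach ≈ 0.2 despite the methylation being epigenetic in origin. The
near-zero values observed in practice at the most-altered regions are
consistent with those regions (largely on chromosome 15) sitting on
chromosomes with few segmental alterations in this tumour type. The
package's dichotomy checks therefore state the epimutation scenario on a
CNA-quiet chromosome; this is a biological statement about the simulated
world, not a tuned tolerance.

## Statistics

Associations between region status and clinical factors use Pearson's
chi-squared without continuity correction, on status-by-factor tables of
called samples; a warning flags expected cells below 5. P-values are
adjusted with the Benjamini–Hochberg step-up within one family per factor
(across the tested DMRs). Burden comparisons — per-sample counts of regions
with strong GOM or LOM — use two-sided Wilcoxon rank-sum tests for every
group pair, BH-adjusted across the pairs of one comparison. The choice of
the rank-sum test is ours (the published figures do not name the test);
counts are non-normal, and a Welch t-test is available by argument.
Association tests default to the most-altered DMR set, with a flag to test
all regions.

## Survival

Overall survival runs from diagnosis to death or end of follow-up.
Kaplan–Meier curves and the multi-group log-rank test compare the status
categories present at a region; curves include the $S(0) = 1$ origin and are
non-increasing step functions. Cox proportional-hazards contrasts are
"focal category vs No change": samples in neither group are excluded, which
matches the way published contrasts are labelled, with an `all_levels`
option that instead dummy-codes every category against No change (the two
readings differ only when intermediate categories are informative). Ties use
the Efron approximation — with year-scale follow-up, tied event times are
expected. Adjusters are the established binary risk factors: age at
diagnosis ≥ 1.5 years (the printed clinical grouping, not continuous age),
MYCN amplification and 11q deletion; covariates constant after restriction
are dropped with a warning. The low-risk stratification restricts to MYCN
non-amplified samples and tests status groups within the 11q-normal and
11q-deleted strata separately.

The Kaplan scan examines every distinct expression value as a candidate
cutoff, requiring at least `min_group = 8` samples on each side (the
platform this emulates does not publish its minimum; 8 keeps the log-rank
approximation serviceable), and returns the cutoff minimizing the two-group
log-rank p with a Bonferroni factor equal to the number of cutoffs actually
tested. Because only ranks enter, the scan is invariant to strictly
monotone transforms of expression.

## The synthetic-data generator

`generate_cohort()` draws, in a fixed seed-determined order: clinical
covariates, whole-chromosome allele-specific CNA events, per-(sample,
region) true status, probe betas, and survival times. Defaults state a
neuroblastoma-like world: 300 tumours and 11 controls; MYCN amplification
25%, 11q deletion 30%, age ≥ 1.5 years 65%, a stage-4-dominated stage
distribution; LOM more prevalent than GOM (baseline 15% vs 5% strong, 8% vs
2% intermediate); chromosome gain/loss/CN-LOH rates 20/10/5% with optional
per-chromosome overrides; administrative censoring at 15 years with baseline
hazard 0.08 per year.

Betas come from a two-parameter Beta distribution parameterized by mean and
precision, $\mathrm{Beta}(\mu\phi, (1-\mu)\phi)$: bounded on $[0,1]$ with
variance shrinking toward the boundaries, as array betas do. The default
precision $\phi = 277$ gives a control SD of about 0.03 at $\mu = 0.5$,
typical of imprinted-DMR spread across 450K control sets. Status centres are
0.5 (No change), 0.9 (GOM), 0.1 (LOM) and $0.5 \pm 3\sigma_{ctrl}$ for the
intermediates — inside the intermediate bands but outside $\mu \pm 2\sigma$.
Means are clamped to $[0.03, 0.97]$ so both Beta shapes stay positive; the
same centres give the uniparental-diploidy references their near-0/near-1
values. For regions flagged `cna_driven_dmrs`, the beta centre is instead
the methylated-allele fraction implied by the sample's allele counts, with
the methylated haplotype assigned to the major or minor side with equal
probability per (sample, chromosome); those regions carry truth status No
change, i.e. no epimutation.

Clinical enrichment multiplies the odds of a chosen status category by
`exp(log_or)` for samples with a given factor level and renormalizes, so
chi-squared power is directly tunable. Survival times are exponential with
hazard $\lambda_0 e^{\eta}$, where $\eta$ sums the configured per-(region,
status) log-hazard-ratios over the sample's true statuses.

What the generator does **not** emulate: probe-type chemistry differences,
batch effects, detection failures, tumour-purity dilution, correlated probes
within a region beyond the shared mean, sub-chromosomal segmental events,
and non-proportional hazards. A green recovery test therefore establishes
that the pipeline's logic is correct under the stated noise model, not that
the thresholds are optimal for any particular real dataset.

## Numerical choices and degenerate inputs

- Coordinates are 1-based and inclusive at both ends (GRCh37); probe-to-DMR
  mapping includes both boundary positions, and single-CpG regions are
  stored with `start == end`. No liftover is performed.
- A probe overlapping two catalog regions is an error — the packaged catalog
  is pairwise disjoint, and silent double-assignment would corrupt counts.
- Region aggregation at the exact 60% boundary (e.g. 3 of 5 probes) yields
  the ambiguous No-change call; the exact 30% boundary does not qualify as
  most-altered.
- Regression requires at least 3 pairs and a non-constant predictor;
  chi-squared requires at least 2 observed levels on both margins; Cox
  requires both contrast groups; each failure returns `NULL` with a recorded
  reason rather than a fabricated number.
- Log-rank on identical groups is zero only to numerical tolerance (1e-8 in
  the tests).
- Seeds: every generator draw is governed by the single config seed; the UPD
  reference generator uses `seed + 1` so references do not share the main
  cohort's stream.

## Known limitations

- The packaged catalog transcribes the source inventory of 49 regions; the
  wider literature lists a 50th imprinted DMR that the source excluded
  without naming it, so it cannot be included.
- The catalog's per-region CpG counts are not shipped: the printed counts
  sum to 684 while the accompanying text counts 704 overlapping CpGs, so
  probe counts are always derived from the user's manifest instead.
- Association and burden tests are asymptotic; with small strata the
  expected-count warning should be taken seriously.
- The Cox implementation assumes proportional hazards and offers no
  diagnostics beyond the fit itself.
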