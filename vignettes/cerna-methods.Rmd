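---
title: "Methods: ceRNA network discovery and prognostic screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network discovery and prognostic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological model

The competing-endogenous-RNA (ceRNA) hypothesis holds that transcripts
sharing miRNA binding sites compete for a limited miRNA pool. A circRNA
that sponges a miRNA lowers the effective dose of that miRNA and thereby
de-represses its mRNA targets. In a tumor-versus-normal comparison this
predicts a characteristic signature for a genuine sponge triplet
(circRNA, miRNA, mRNA): the mRNA moves in the **same** direction as the
circRNA and in the **opposite** direction to the miRNA. `ceRNAscreen`
operationalizes ceRNA discovery as a chain of well-defined statistical
stages around this sign constraint, each exposed as a plain R function and
orchestrated by `run_pipeline()`.

## Stages, statistics and parameters

### Differential expression

Expression enters on the log2 scale (`log2_transform()` with a default
pseudo-count of 1 for count-like data, so zero maps to zero). For each
feature, `differential_expression()` computes

* `log2fc` = mean(log2 tumor) − mean(log2 normal),
* a t-test p-value: a paired t-test when complete tumor/normal pairing is
  available, Welch's t otherwise (`de_method = "auto"`; Student's pooled t
  is available for reference computations). A moderated/empirical-Bayes
  variance model is deliberately out of scope: with the small paired
  designs this pipeline targets, the plain t-test is the transparent
  reference implementation and its operating characteristics are validated
  directly against planted truth.

A feature is called differential when `p < 0.05` **and** `|log2fc| > 1`
(strict inequalities, so boundary values never pass; both thresholds are
`threshold_config()` parameters, with `p_threshold` on raw p by default —
BH-adjusted p-values are always reported and can be used for calling via
`use_adjusted_p`). Two data-hygiene rules matter in practice:

* features missing in more than 20% of samples are dropped before testing
  (`max_missing_frac`);
* features with zero variance in both groups cannot be t-tested; they get
  p = 0 when the group means differ and p = 1 when equal, with a warning.
  This keeps constant spike-ins and saturated probes from silently
  vanishing.

Duplicate probes mapping to one identifier are collapsed by keeping the
probe with the highest mean expression (`"max_mean"`, the common microarray
convention); averaging (`"mean"`) is available where summation semantics
are preferred.

### Overlap of DE lists across cohorts

Two independent circRNA cohorts rarely share platforms, so the replicable
signal is the overlap of their DE lists. `overlap_significance()` performs
the one-sided Fisher exact test: with universe size `N` (by default the
features measured in **both** cohorts), list sizes `|A|` and `|B|` and
overlap `k`, the p-value is the hypergeometric upper tail `P(X ≥ k)`. The
odds ratio is the cross-product ratio of the 2×2 table, with 0.5 added to
every cell when any cell is zero. The pipeline carries forward the
overlapping circRNAs whose direction agrees in both cohorts.

### Network assembly

`build_cerna_network()` joins miRNA–circRNA and miRNA–mRNA interaction
pairs (ENCORI-style two-column tables; stringency of the upstream database
is the caller's concern — pairs are inputs, not predictions) over the
differential features, then applies the sign rule. The default mode is
`sign_rule` because the typical design measures circRNAs in one cohort
(arrays) and miRNA/mRNA in another (sequencing): sample-level correlation
across cohorts does not exist, and direction concordance is the faithful
realization of the positive/negative-correlation requirement. When all
partners are measured on the same samples, `mode = "correlation"` applies
`correlation_filter()` (Spearman, sign plus `|rho|` threshold, default 0.3)
to the pair tables before the join. Triplets are emitted in canonical
lexicographic order so outputs are diffable and golden-file stable.

### Over-representation analysis

`hypergeometric_enrichment()` tests network gene lists against GMT
collections with the hypergeometric upper tail. Two policy choices:

* the universe defaults to the genes actually measured in the mRNA matrix,
  not the genome — an unmeasured gene can never enter the query, and
  including it would inflate significance;
* this is one-sided over-representation of an unranked DE-derived list, not
  a ranked GSEA statistic: the network gene list carries no meaningful
  ranking, so over-representation is the only computation its input
  supports. BH correction is applied within each collection (GO and KEGG
  are tested as separate GMT files).

`top_terms()` returns the first `k` results strictly below the p cutoff;
ties in p are broken by set name, making selection deterministic.

### Survival screening

`median_split()` dichotomizes at the median with ties assigned to **low**,
so "high" always means strictly above the cohort median; which side median
ties belong to is an arbitrary convention, and fixing it (plus erroring on
degenerate constant profiles) keeps the screen reproducible.
`km_estimate()` and `logrank_test()` wrap the `survival` package's
product-limit estimator and two-group log-rank test (standard
hypergeometric variance, no stratification or weighting); the test suite
pins them to hand-computed risk tables. `prognostic_screen()` runs
median-split + log-rank per gene and never drops a gene silently — genes
absent from the matrix, with too few usable samples, or with degenerate
splits carry explicit skip reasons. Times are days internally; no Cox
adjustment is attempted, matching the univariate design of the screen.

### Drug–gene associations

`spearman_cor()` uses average-rank ties and a two-sided p-value: the exact
permutation distribution for n ≤ 10 without ties, the
`t = ρ√((n−2)/(1−ρ²))` approximation otherwise. `drug_gene_screen()` tests
every gene × drug pair pairwise-complete over missing IC50 entries (pairs
falling below 3 complete observations are skipped with a reason, as are
constant profiles, and neither enters the BH adjustment). FDR control is
applied over the whole screen jointly by default — the conservative choice
when the true grouping convention of the upstream resource is unknown —
with `fdr_grouping = "per_gene"` available. ρ < 0 (higher expression, lower
IC50) is reported as *sensitizing*, ρ > 0 as *resistant*.

## The synthetic-data generator

`generate_synthetic_study()` is first-class, tested code: it is the
acceptance oracle for every other module. It emulates

* two small paired circRNA cohorts (4 and 5 tumor/normal pairs), a small
  paired mRNA cohort, and large unpaired miRNA/mRNA cohorts (45 normal /
  450 tumor), mirroring the cohort shapes of typical ceRNA discovery
  studies;
* log2-scale Gaussian expression: per-feature baseline uniform on 4–12,
  within-group sd 0.5, a shared per-patient baseline shift (sd 0.25) in
  paired cohorts, and planted tumor shifts of ±2 log2 units in 10% of
  features (half up, half down). An effect of 2 with sd 0.5 gives paired
  designs of 4–5 pairs high but not saturating power, which is what makes
  the sensitivity/false-positive checks informative;
* interaction tables wiring each planted triplet, plus decoys that each
  violate exactly one network condition (non-DE circRNA, miRNA or gene, or
  one of the two sign breaches) on a dedicated miRNA so each decoy can be
  audited individually, plus inert background pairs among non-DE features;
* exponential survival with hazard `h0·exp(log(HR)·z)` where `z` indicates
  above-median expression of a planted gene (default HR 3, baseline hazard
  1/1000 per day ≈ two-year median survival), and uniform censoring whose
  upper bound is solved numerically to hit the target censoring fraction
  (default 0.6, i.e. ~40% events);
* an ln-IC50 drug matrix in which planted gene–drug pairs follow
  `IC50 = b·z(expr) + noise` with |b|/sd(noise) = 1 and configurable sign,
  plus a missingness mask (default 10%);
* a GMT collection of random sets plus one set containing the planted
  network genes.

Randomness is a single seed fanned out into named substreams (expression,
interactions, gene sets, clinical, drugs), so adding draws to one generator
never perturbs another, and a fixed seed reproduces every file bit for bit.

What the generator does **not** emulate: probe-level microarray chemistry,
sequencing-depth/count noise (simulation is Gaussian directly on the log2
scale, matching the scale on which the statistics operate), batch effects,
correlated co-expression structure, and informative censoring. Passing
tests therefore demonstrate that the statistical machinery is correct and
well calibrated under its stated model — not that real cohorts satisfy that
model.

## Numerical choices and degenerate inputs

* Strict inequalities at every threshold; boundary values never pass.
* Expression TSVs are serialized with 17 significant digits so write/read
  round trips are exact.
* `log2_transform(already_log = TRUE)` is a bit-identical no-op; a
  transform producing non-finite values (zero offset on zero counts) is a
  hard error rather than silent `-Inf`.
* Empty interaction tables, empty networks and absent circRNAs yield empty
  (not missing) results; absent genes in screens yield rows with explicit
  skip reasons.
* The log-rank test with no events in either group returns p = 1 with a
  warning; a constant expression profile is a "degenerate split" error.
* Odds ratios use the 0.5 continuity substitute only when a 2×2 cell is 0.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to be decisive yet quick:
exhaustive hypergeometric enumeration for all configurations with universe
≤ 60; Spearman permutation enumeration at n ≤ 7; DE operating
characteristics over 20 seeds of 200-feature, 5-pair cohorts (observed
sensitivity ≥ 0.9, false-positive rate ≤ 0.1); survival screening over 20
seeds of a 400-tumor cohort with one HR-3 gene among 20 nulls, plus 1000
null log-rank simulations (type-I error within [0.03, 0.07]); drug
screening over 50 null seeds of a 50 × 20 screen at n = 30 cell lines.
`scripts/acceptance.R` recomputes the same quantities from scratch for any
seed.

## Known limitations

* Direction concordance is a necessary, weak surrogate for sample-level
  ceRNA correlation; `mode = "correlation"` is stronger but needs
  same-cohort measurements.
* The t-test path assumes approximate normality on the log2 scale; heavy
  count noise at low expression is not modelled (no voom-style weighting).
* The survival screen is univariate median-split log-rank; it ignores
  covariates and continuous dose-response in expression.
* Interaction tables are trusted as given; no target prediction or binding
  evidence weighting is performed.
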