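# ceRNAscreen

Competing endogenous RNA (ceRNA) network discovery and prognostic screening
for tumor transcriptomics.

circRNAs can act as miRNA sponges: by sequestering a miRNA they de-repress
that miRNA's target mRNAs. `ceRNAscreen` implements the complete screening
pipeline that turns tumor/normal expression cohorts, miRNA interaction
tables, gene-set collections, clinical follow-up and drug-response data into
a sign-consistent circRNA–miRNA–mRNA network with functional, prognostic and
pharmacological annotation. It is aimed at computational biologists running
ceRNA discovery on microarray/RNA-seq cohorts, and ships a seeded
synthetic-data generator with planted ground truth so every stage of the
pipeline can be validated end to end.

## The method

1. **Differential expression.** For each feature on the log2 scale,
   log2FC = mean(log2 tumor) − mean(log2 normal), with a paired, Welch or
   Student t-test p-value. A feature is differential when *p* < 0.05 and
   |log2FC| > 1 (strict inequalities; both thresholds configurable).
   Benjamini–Hochberg adjusted p-values are always reported.
2. **Cross-cohort overlap.** The overlap of two circRNA DE lists from
   independent cohorts is tested with a one-sided Fisher exact test
   (hypergeometric upper tail P(X ≥ k)); circRNAs differential in both
   cohorts with concordant direction are carried forward.
3. **ceRNA network assembly.** Candidate triplets (circRNA, miRNA, mRNA) are
   formed from miRNA–circRNA and miRNA–mRNA interaction pairs restricted to
   differential features, and kept only under the sponge sign rule:
   the mRNA moves **with** the circRNA and **against** the miRNA.
4. **Over-representation.** Network gene sets are tested against GMT
   collections by the hypergeometric upper tail with BH correction, against
   a measured-gene universe.
5. **Survival screening.** Each network gene splits the cohort at its median
   expression ("high" = strictly above the median); the two groups are
   compared with the Kaplan–Meier / log-rank machinery
   (χ² = (O − E)²/Var on the pooled risk table, 1 df).
6. **Drug associations.** Spearman rank correlation between gene expression
   and drug IC50 across cell lines, pairwise-complete, with BH FDR control
   over the whole screen; ρ < 0 is a sensitizing association.

## Worked example

Simulate a complete study (five cohorts, planted triplets, decoys,
a prognostic gene and a drug association) and run the pipeline over it:

```r
library(ceRNAscreen)
cfg_path <- simulate_study_dir(seed = 7, dir = "study7")
report <- run_pipeline(cfg_path)
```

`study7/results/report.txt` from this exact run:

```
ceRNAscreen 0.1.0 pipeline report
thresholds: p < 0.05, |log2FC| > 1, method auto
network mode: sign_rule

DE [circ_a]: 200 features, 10 up / 10 down
DE [circ_b]: 200 features, 10 up / 10 down
DE [mirna]: 150 features, 8 up / 7 down
DE [mrna]: 400 features, 20 up / 20 down
circRNA overlap: 20 shared (universe 200), Fisher p = 6.2e-28, 20 concordant carried forward
ceRNA network: 6 triplets
enrichment (top circRNA circ_s0030): 11 sets tested, 2 significant
survival screen: 6 genes, 1 prognostic
drug screen: 10 pairs tested, 1 flagged
```

Reading it: both circRNA cohorts call their 20 planted features (10 up, 10
down), the two DE lists overlap far beyond chance (Fisher p ≈ 6×10⁻²⁸), the
six planted triplets are recovered exactly (no decoy passes the sign rule),
the planted prognostic gene is the one log-rank hit among the six network
genes, and the planted gene–drug IC50 association is the one flagged pair.
Stage tables (`cerna_network.tsv`, `survival_screen.tsv`, `drug_screen.tsv`,
…) and a machine-readable `report.json` sit next to the text report, and
`study7/manifest.json` holds the planted truth for comparison.

A command-line wrapper with `simulate`, `de`, `overlap`, `run-all` and
per-stage subcommands is installed at
`system.file("scripts", "cerna-pipeline.R", package = "ceRNAscreen")`.

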