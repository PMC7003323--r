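# coxfilter

Subtype-specific prognostic gene screening with interaction Cox models.

Cancer cohorts often mix two histological subtypes — esophageal squamous
cell carcinoma vs adenocarcinoma, laryngeal vs hypopharyngeal squamous
carcinoma — whose prognostic biomarkers need not coincide. A survival
screen run on the pooled cohort averages subtype-specific effects away.
`coxfilter` screens features (genes, lncRNAs) one at a time with a Cox
proportional-hazards model that lets each subtype carry its own
expression effect, and labels every feature as prognostic for one subtype,
the other, both, or neither.

## The model

For feature *g*, sample *i* of subtype *j* ∈ {c1, c2} with expression
X<sub>ig</sub> on the log2(FPKM+1) scale:

```
λ_ig(t) = λ0g(t) · exp( β1g·I(j = c2) + β2g·X_ig + β3g·I(j = c2)·X_ig )
```

The per-unit log-hazard of expression is β2g in subtype c1 and β2g + β3g
in subtype c2, so

* **β2g ≠ 0** → the feature is prognostic for subtype **c1**,
* **β2g + β3g ≠ 0** → prognostic for subtype **c2**.

Each gene is fit by Newton–Raphson on the partial likelihood (Efron ties
by default); the two hypotheses get two-sided Wald tests; each test family
is adjusted across the genome by Benjamini–Hochberg; adjusted p-values
below α (default 0.05) define the c1 and c2 prognostic sets and their
Venn partition (`c1_specific` / `c2_specific` / `shared` / `none`).

The package also ships FPKM preprocessing (row-sum < 4 filter,
log2(FPKM+1) transform, clinical alignment with completeness rules), a
synthetic two-subtype cohort generator with planted per-gene effect
classes, downstream signature evaluation (multivariate Cox risk score,
median split, Kaplan–Meier, log-rank, Wilcoxon), and a one-call pipeline
with recovery scoring against the planted truth.

## Worked example

Simulate a 500-gene cohort (81 + 83 samples, 70% null genes, planted
effects of |β| = 2), screen it, and score the recovery:

```r
library(coxfilter)

cfg    <- sim_config(n_genes = 500, beta2_effect = 2, beta3_effect = 2,
                     seed = 42)
cohort <- generate_cohort(cfg)
screen <- screen_genes(cohort, alpha = 0.05)
screen
#> screen_result: 500 genes, alpha = 0.05 (separate BH)
#>   prognostic for c1: 101 | for c2: 104 | overlap: 50 | unfit: 0
#>
#> c1_specific c2_specific        none      shared
#>          51          54         345          50
```

101 genes land in the c1-prognostic set and 104 in the c2 set, 50 genes in
both — close to the planted 10% + 10% + 10% class structure. A
c1-specific gene shows a strong β2 whose interaction β3 cancels it in
subtype c2:

```r
head(subset(screen$table, label == "c1_specific",
            select = c(gene_id, beta2, beta3, padj_c1, padj_c2)), 3)
#>    gene_id    beta2     beta3      padj_c1   padj_c2
#> 14  G00014 1.719950 -1.403835 2.342913e-12 0.4474562
#> 20  G00020 2.258669 -2.502127 7.000836e-15 0.5199872
#> 21  G00021 1.835462 -1.897999 1.976136e-12 0.9417891

score_recovery(screen, cohort$truth)$sets
#>      set  TP FP FN  TN n_rejected        fdr sensitivity
#> 1 set_c1 100  1  0 399        101 0.00990099           1
#> 2 set_c2 100  4  0 396        104 0.03846154           1
```

Both sets recover every planted gene (sensitivity 1) with empirical FDR
about 1% and 4% — inside the nominal 5% Benjamini–Hochberg level.

The whole flow, including preprocessing of raw-FPKM input and signature
evaluation, is one call:

```r
run_pipeline(list(mode = "synthetic",
                  simulation = list(n_genes = 200, sim_mode = "cohort",
                                    n_drivers = 5)),
             out_dir = "run1", seed = 1)
```

or, from a shell, via the thin wrapper `inst/cli/coxfilter.R`
(`run`, `simulate`, `preprocess`, `screen` subcommands).

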