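---
title: "Screening for subtype-specific prognostic genes with interaction Cox models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for subtype-specific prognostic genes with interaction Cox models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxfilter)
```

## The problem

Many cancers comprise histological subtypes with distinct molecular
profiles — esophageal cancer splits into squamous cell carcinoma and
adenocarcinoma, head-and-neck squamous carcinoma into laryngeal and
hypopharyngeal disease — yet prognostic gene signatures are usually derived
for the disease as a whole. A gene whose expression predicts survival in
one subtype may carry no information in the other, and a pooled analysis
averages the two away. `coxfilter` screens each feature (a gene or lncRNA)
for *subtype-specific* prognostic value in a two-subtype cohort.

## The model

For feature $g$, sample $i$ with subtype $j \in \{c_1, c_2\}$ and
expression $X_{ig}$ (log2(FPKM+1) scale), the hazard is modelled as

$$
\lambda_{ig}(t) \;=\; \lambda_{0g}(t)\,
  \exp\!\big(\beta_{1g}\, I_i(j=c_2) + \beta_{2g}\, X_{ig}
       + \beta_{3g}\, I_i(j=c_2)\, X_{ig}\big).
$$

The log-hazard per expression unit is $\beta_{2g}$ within subtype $c_1$ and
$\beta_{2g} + \beta_{3g}$ within $c_2$. Hence:

* $\beta_{2g} \ne 0$ — the feature is prognostic for subtype $c_1$;
* $\beta_{2g} + \beta_{3g} \ne 0$ — prognostic for subtype $c_2$.

Each feature is fit one at a time by maximizing the Cox partial likelihood
(Newton–Raphson with step-halving, Efron tie handling by default). The two
hypotheses are tested with two-sided Wald statistics on the linear
combinations $w = (0,1,0)$ and $w = (0,1,1)$:
$z = w^\top\hat\beta \big/ \sqrt{w^\top \widehat{\mathrm{Cov}}\, w}$.
Benjamini–Hochberg adjustment at a cutoff (default $\alpha = 0.05$) then
partitions the features into `c1_specific`, `c2_specific`, `shared` and
`none` — the Venn regions of a subtype-specificity diagram. $\beta_{1g}$ is
estimated but never tested; it only absorbs the subtype's baseline risk
difference.

Design choices worth stating explicitly:

* **Covariates.** The per-gene model contains *only* subtype, expression
  and their interaction. Clinical covariates (age, gender, stage) are used
  as completeness requirements during alignment but are not entered into
  the model; the screen is intentionally the minimal interaction model.
* **Adjustment scope.** Each test family ($\beta_2$ across genes;
  $\beta_2+\beta_3$ across genes) is its own genome-wide screen and is
  adjusted separately — each family asks one question per gene, and mixing
  the two would make each family's FDR depend on the other's signal
  density. A pooled variant is exposed via
  `screen_genes(adjust_scope = "pooled")` for sensitivity analysis.
* **Test type.** Wald tests on the coefficient combinations are the direct
  reading of "significance of the coefficients"; they need one fit per
  gene and give the confidence intervals reported downstream. A
  likelihood-ratio alternative would require refits under each null and is
  not implemented.
* **Ties.** Efron's approximation is the default (standard modern
  practice); Breslow is available and the two coincide exactly on tie-free
  data — a property the test-suite checks to 1e-10.

## Numerical behaviour of the fitter

The engine (`cox_partial_loglik`, used by both `fit_cox_gene` and
`fit_multivariate_cox`) evaluates the log partial likelihood in its
probability form (so the maximized value is always $\le 0$), with analytic
gradient and observed information; the linear predictor is centred before
exponentiation so large coefficients cannot overflow. Newton–Raphson starts
from $\beta = 0$ with up to 50 iterations, up to 30 step-halvings per
iteration (guaranteeing monotone likelihood ascent), and declares
convergence when the log-likelihood improves by less than a relative
`tol = 1e-8`.

Three degenerate regimes are handled as *data* outcomes, never exceptions:

* expression constant within both subtype strata — no information on
  $\beta_{2g}$ or $\beta_{3g}$: reported as unfit
  (`"degenerate covariate"`);
* no observed events: unfit (`"no events"`);
* monotone likelihood (perfect concordance, common in tiny strata): any
  $|\hat\beta_k| > 10$ flags `"monotone likelihood suspected"` with
  `converged = FALSE`.

Unfit genes are labelled `unfit` and excluded from both BH families, so
they neither gain nor grant multiplicity.

## What the synthetic cohorts emulate

The generator (`sim_config()` + `generate_cohort()`) exists because the
screen's operating characteristics — calibration, power, coverage,
imbalance behaviour — can only be measured against known truth. Its
defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_c1 : n_c2` | 81 : 83 | a balanced two-subtype design; the 89 : 6 variant probes extreme imbalance |
| class fractions | 0.70 / 0.10 / 0.10 / 0.10 | mostly-null genome with planted subtype-specific and shared effects |
| `beta2_effect` | 1 | log-hazard per log2-expression unit; a moderate, detectable effect |
| `baseline_rate` | log(2)/800 per day | exponential baseline with median overall survival near 800 days, the scale typical of the motivating cohorts |
| `censor_rate` | 1.3e-3 per day | independent exponential censoring giving roughly 40% observed events |
| `expr_mean`, `expr_sd` | 2, 1 | log2(FPKM+1)-like values |

Generative coefficients per class: `null` $(0,0)$; `c1_only`
$(\beta, -\beta)$ so the $c_2$ contrast cancels; `c2_only` $(0, \beta)$;
`shared` $(\beta, 0)$ — the same effect in both subtypes. Event times come
from inverse-CDF sampling of the proportional-hazards model with an
exponential baseline (`weibull_shape` generalizes it), and censoring is an
independent exponential, optionally truncated administratively. The hazard
uses mean-centred expression: a covariate shift only rescales
$\lambda_{0}$ (Cox estimates are invariant to it), and centring keeps the
event fraction at its configured value regardless of `expr_mean`.

**Per-gene versus cohort simulation.** A single shared survival outcome
cannot be driven by hundreds of planted genes at once without the combined
linear predictor swamping every marginal effect, while a single-gene fit is
only exactly calibrated when that gene is the sole driver of its outcome.
The generator therefore has two modes:

* `sim_mode = "per_gene"` (default): every gene receives its own
  independent survival replicate driven by that gene alone, stored as
  per-gene time/event matrices that `screen_genes()` consumes
  automatically. Each gene's fitted model is then *exactly* its generative
  model — the mode used for calibration, recovery and classification
  studies.
* `sim_mode = "cohort"`: one shared outcome driven jointly by the planted
  signal genes (optionally capped with `n_drivers`; demoted genes become
  true nulls so the recorded truth stays consistent). Per-gene fits are
  approximations here. This mode feeds the pipeline demonstrations and the
  signature evaluation, which need a single clinical table.

What the generator deliberately does **not** emulate: RNA-seq library-size
and overdispersion structure, gene–gene correlation, subtype-dependent
expression shifts (expression is independent of subtype by construction),
and competing risks. Passing simulation suites therefore demonstrate the
statistical machinery under the stated model, not robustness to every
feature of real transcriptomic cohorts.

## Preprocessing rules

On raw FPKM input the pipeline (i) deletes features whose FPKM sum across
*all* samples, subtypes combined, is strictly below 4 — a sum of exactly 4
is retained; (ii) transforms to $\log_2(\text{FPKM}+1)$; (iii) keeps the
samples shared by matrix and clinical table with complete values in every
required field (`NA`, `NaN`, empty strings and `"[Not Available]"` count
as missing). The same FPKM threshold is applied to any cohort and is
exposed as a parameter. A subtype with fewer than 10 aligned samples
triggers a warning, not an error — six-sample minority subtypes are a
realistic regime this method is expected to face, and the screen still
estimates the minority contrast by borrowing the dominant subtype's
information through the shared model.

## Downstream evaluation

`evaluate_signature()` reproduces the conventional signature workflow: a
multivariate Cox fit over the selected genes (same Newton engine, $k$
covariates), the linear predictor as a per-sample risk score, a split at
the *median* training score (ties at the median go to the low-risk group —
deterministic and documented), Kaplan–Meier curves per group, and a
log-rank comparison. By default the model is trained and evaluated
in-sample, matching common practice; this is optimistic, and a
`split = "holdout"` mode trains on a random half and evaluates on the
other. The Wilcoxon helper switches from exact enumeration to the
tie-corrected normal approximation (with continuity correction) at a
combined sample size of 20.

Under the simulation conditions these pieces compose into a dissociation
property: when planted effects are prognostic but expression is independent
of subtype, the risk-score split separates survival (log-rank $p < 0.05$ in
nearly every replicate) while the same score classifies subtype at chance
(AUC $\approx$ 0.5). Prognostic value and subtype-discriminative value are
different questions, and the screen targets only the first.

## Problem sizes used in the validation studies

The shipped simulation studies use 1000-gene all-null cohorts (20
replicates) for calibration, 1000 single-driver genes for recovery and
coverage, 400 genes per design for the 81:83-versus-89:6 imbalance
comparison, 50 replicates of 200-gene cohorts for classification recovery,
and 30 replicates for the dissociation property. These sizes give Monte
Carlo standard errors well inside the asserted bands while keeping a full
run on one CPU in the minutes range.

Known limitations, restated: coverage of the minority-subtype contrast
degrades and monotone-likelihood failures appear as the minority shrinks
toward a handful of samples (the 89:6 studies report both); the
per-gene screen makes no claim about joint effects; in-sample signature
evaluation overstates separation; and the BH guarantee is an FDR statement
across genes, not a per-gene error rate.
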