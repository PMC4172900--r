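---
title: "Methods: relative quantification and RECPAM-style survival trees for gemcitabine-pathway expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative quantification and RECPAM-style survival trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Gemcitabine is the standard adjuvant chemotherapy after resection of
pancreatic ductal adenocarcinoma (PDAC), and its effect depends on a small
set of pathway genes: the nucleoside transporter *hENT1* that carries the
drug across the plasma membrane, the kinase *DCK* that activates it, the
efflux/resistance protein *MRP1*, and the stress-induced transcription
factor *CHOP*, a repressor of *hENT1*. Tumor-vs-normal expression of these
genes, measured by qRT-PCR in matched tissue pairs, may therefore stratify
patients into subgroups with different mortality and progression risk.

`gemtree` implements that analysis end to end: comparative relative
quantification from cycle-threshold (Ct) data, expression-level statistics,
person-years incidence rates, a Cox proportional-hazards fitter, and a
RECPAM-style survival tree (RECursive Partitioning and AMalgamation) that
searches for threshold-defined prognostic classes. Because the motivating
cohort's patient-level data were never published, the package also ships a
synthetic cohort generator that emulates the cohort's statistical
structure, so every stage is testable and the engine's operating
characteristics can be measured by simulation.

## Relative quantification and expression statistics

Fold change is the comparative (2^-ddCt) quantity:

$$\Delta\Delta C_t = (C_t^{\text{target,tumor}} - C_t^{\text{ref,tumor}})
 - (C_t^{\text{target,normal}} - C_t^{\text{ref,normal}}),
 \qquad \text{FC} = 2^{-\Delta\Delta C_t},$$

with the housekeeping gene as the reference. Adding any constant to all
four Ct values leaves FC unchanged; this invariance is tested.

Differential expression per gene is a two-sided one-sample t-test of the
mean log fold change against zero. The t statistic and p-value are
invariant to the logarithm base, so the natural log is used internally,
while medians and quartiles are reported on the original fold-change
scale. Quartiles use linear interpolation between order statistics (R's
default type-7 convention; no convention was imposed by the study design).
Inter-gene association is Pearson's r on log values with the two-sided p
from the t transform; gene-vs-phenotype comparisons use the classical
pooled-variance two-sample t-test (2 groups) or one-way ANOVA (more
groups). These statistics are written out as explicit closed forms so the
test suite can verify them against R's reference implementations
(`t.test`, `cor.test`, `aov`) to 1e-8 — a genuine dual-route check rather
than a wrapper around the thing being checked. Zero-variance inputs yield
flagged degenerate results (p = NA) instead of aborting a multi-gene
pipeline or silently reporting p = 0 or 1. P-values are raw; no
multiple-testing adjustment is applied, and adjustment is left to the
caller.

## Time-to-event primitives

Endpoints are built from dates as years = days / 365.25, from surgery
(baseline) to the event or, for event-free subjects, to the last clinical
follow-up. Incidence rates are events divided by summed person-years,
times 100. The integer *display* value truncates toward zero — that is the
convention under which 17 events over 29 person-years prints as 58
(17/29 x 100 = 58.62) — while the exact rate is always retained alongside.

`fit_cox()` maximizes the Cox partial likelihood with the Breslow
approximation for ties, by Newton-Raphson with step-halving, convergence
when the log partial likelihood moves by less than 1e-9 (at most 100
iterations), and Wald 95% intervals exp(beta ± 1.96 SE). Covariates are
centered internally for numerical stability (the coefficient is
translation-invariant). Monotone likelihood — risk perfectly separated, the
coefficient diverging — is detected when |beta| exceeds 15 and reported as
a flagged non-convergence rather than a silently huge hazard ratio.
Per-class survivor curves come from the Breslow baseline cumulative
hazard: $S_k(t) = S_0(t)^{\mathrm{HR}_k}$ with
$\hat H_0(t) = \sum_{t_j \le t} d_j / \sum_{i \in R(t_j)} e^{\eta_i}$.

## The tree engine

At each node, every candidate covariate is scanned over its admissible
binary splits: midpoints between consecutive distinct values for
continuous covariates, all two-set partitions of the observed levels for
categorical covariates (at most 4 levels). A split is admissible when both
children have at least 3 subjects and at least 1 event (the stopping
floor, applied during search so no emitted leaf can violate it). Each
split is scored by the likelihood-ratio chi-square of the single-indicator
Cox model, $2\{\ell(\hat\beta) - \ell(0)\}$; the LR statistic was chosen
over the Wald form for stability at small n, where Wald statistics degrade
under near-monotone likelihoods. The indicator's HR and Wald CI are kept
for reporting on the branches.

### Permutation selection and the node gate

For covariate $j$, $T_j$ is the maximum LR statistic over its admissible
splits, and its permutation p-value compares $T_j$ with the null
distribution obtained by shuffling that covariate's values among the
node's members with outcomes fixed (B = 199 draws, add-one estimator
$(1 + \#\{T^{(b)}_j \ge T_j\})/(1+B)$). The covariate with the smallest
permutation p is selected, ties broken by larger $T_j$, then by name.

Splitting is *gated* at the node level: the best observed statistic
$\max_j T_j$ is compared with the permutation distribution of
$\max_j T^{(b)}_j$, and the node splits only when this max-statistic p is
at or below alpha (default 0.05). A gate on the selected covariate's own
p-value would test each of the (here four) covariates at level alpha and
spuriously split about $1-(1-\alpha)^4 \approx 18\%$ of pure-noise nodes;
the max-statistic form keeps the node-level type-I error at the nominal
level no matter how many covariates compete, which is what the package's
calibration experiment verifies (root-split rate at most alpha + 0.03
under a global null). Covariates are permuted independently within their
complete cases; when covariates are positively correlated this makes the
gate conservative, never anti-conservative. Per-node RNG substreams are
derived from (seed, node id), so trees are reproducible regardless of
traversal order. With alpha = 0 the gate is closed and the tree is the
root leaf.

Missing covariate values are excluded from that covariate's scan but the
patients are never dropped from the node; if the chosen split covariate is
missing for a patient, the patient follows the child with more
complete-case members (majority rule — the least informative default).

### Stopping, amalgamation, risk classes

A node becomes a leaf when the depth bound (default 5; the planted and
expected trees have depth 2) is reached, no admissible split exists, or
the gate does not pass. Leaves are then amalgamated into risk classes:
iteratively, the pair of current classes with the *largest* two-class Cox
Wald p-value merges as long as that p exceeds the amalgamation threshold.
The threshold defaults to 1, i.e. merging off and leaves = classes,
because the analysis this package implements reports terminal nodes
directly as classes; the merging rule itself is this package's documented
choice (the historical method's merging criterion is not publicly
specified). The reference class is the one with the lowest crude event
rate (events per person-year); one Cox fit on class indicators against it
yields the class HRs and 95% CIs, and classes are numbered in decreasing
HR order. Class tables carry event counts, exact and truncated incidence
rates per 100 person-years, and median follow-up in months. Clinical
profiles across classes use Kruskal-Wallis for continuous covariates and
Fisher's exact test for categorical ones (all class tables here have
n <= 26, so exact enumeration is cheap).

One caveat the analyst should know: in the motivating study the abstract
and the results section disagree on which gene pair drives the
progression endpoint (*hENT1*+*CHOP* vs *hENT1*+*DCK*); this package's
planted defaults and documentation follow the results/figures.

## The synthetic cohort generator

The generator's defaults are the study conditions, fixed once:

* **Expression.** Log-normal marginals with a Gaussian copula on the log
  scale — chosen because the analysis log-transforms expression and the
  reported medians with asymmetric quartiles are the signature of skewed
  positive data. Medians 0.53 (*hENT1*), 1.02 (*CHOP*), 0.58 (*MRP1*),
  1.15 (*DCK*); log-sds derived from the reported interquartile ranges via
  sigma = ln(Q3/Q1)/(2 x 0.6745) (1.04, 1.88, 1.26, 1.58); correlations
  *MRP1*–*hENT1* 0.53 and *MRP1*–*CHOP* 0.42, other pairs 0. The
  correlation matrix must be positive semi-definite (eigenvalues >=
  -1e-10); offending configurations are rejected with the offending
  eigenvalue reported.
* **Survival.** A planted tree of threshold rules partitions patients into
  leaves (defaults: *DCK* <= 0.27 reference; *DCK* > 0.27 & *CHOP* <= 0.25
  high risk; remainder intermediate), each leaf with a constant hazard in
  events per person-year (0.23 / 0.63 / 0.35, the per-class crude
  mortality rates). Exponential event times keep planted hazard ratios
  exact under the proportional-hazards model and analytically checkable.
  Administrative censoring is uniform on (0, 5] years, picked to give a
  median follow-up of roughly 1.4 years at the default hazards.
* **Endpoints.** Progression and death are nested: progression is
  exponential at 58/35 times the leaf mortality hazard (the ratio of the
  cohort-level progression and mortality rates), death follows progression
  after an exponential residual at the leaf mortality hazard, and both
  share one censoring time — so `pfs_time <= os_time` holds by
  construction, matching the clinical semantics. The single-endpoint
  simulator `simulate_survival()` draws the event time directly at the
  leaf hazard; that is the analytically checkable contract used by the
  recovery experiments.
* **Clinical covariates.** Independent Bernoulli flags at the cohort's
  prevalences (jaundice 0.58, diabetes 0.35, family history 0.19, previous
  neoplasia 0.08, R1 margins 0.31, stage IIB 0.88, mucinous histotype
  0.15, vascular invasion 0.12, perineural invasion 0.54, fewer than six
  gemcitabine cycles 0.39) plus continuous covariates with fixed
  cohort-calibrated distributions (age, lymph-node ratio bounded in
  [0, 1], pre-operative CEA and CA19-9, gemcitabine cycles). Covariates
  are independent of the genes: the motivating analysis reports marginal
  associations but no joint model, and inventing one would bake untested
  structure into every downstream test.
* **Reproducibility.** All randomness flows from one base seed through
  named substreams (expression 11, clinical 12, survival 13, and per-node
  permutation streams keyed by node id), so a cohort is a pure function of
  its configuration.

What the generator does *not* emulate: Ct-level chemistry (amplification
efficiency drift, plate effects), gene–clinical dependence, non-constant
hazards, and informative censoring. Passing tests therefore demonstrate
that the engine recovers structure *of the kind the model assumes*; they
cannot certify behavior under real-data violations such as time-varying
effects or dependent censoring.

## Validation experiments and problem sizes

The package fixes three simulation experiments (run by
`analysis/05_method_validation.R`, the test suite, and
`scripts/acceptance.R`):

* **Cox oracle.** 50 random single-covariate datasets with n <= 12; the
  fitted coefficient must sit within 1e-3 of the argmax of an
  independently coded brute-force Breslow partial likelihood evaluated on
  a grid over [-5, 5] with step 1e-4. Datasets whose maximum approaches
  the grid boundary are regenerated, since an unbounded (monotone)
  likelihood has no interior maximum to compare against.
* **Gate calibration.** 500 replicates of a 26-patient cohort with four
  independent log-normal noise covariates, exponential survival (hazard
  0.35/year) and uniform censoring on (0, 5]; the root may split in at
  most alpha + 0.03 of replicates at alpha = 0.05, B = 199.
* **Planted-tree recovery.** 100 cohorts of n = 400 from the depth-2 tree
  above with leaf hazards 0.23/0.69/2.07 (ratios 1/3/9) and censoring
  effectively off, so the experiment isolates split localization from
  censoring noise. A replicate counts as recovered when the root splits on
  the first planted gene within ±0.05 of 0.27 and the high-expression
  child splits on the second within ±0.05 of 0.25 — i.e. the planted
  splits are found at the right places; with a 5% gate an occasional extra
  (spurious) split below the planted structure is the expected behavior of
  the procedure, not a recovery failure, and is tracked separately via the
  leaf count. Mean class HRs over recovered three-leaf replicates must
  fall within 30% of the planted 3 and 9.

These sizes keep each experiment in the minutes range on one CPU while
leaving Monte-Carlo error well inside the tested margins.

## Numerical choices

* Breslow tie handling everywhere (fitter, split scan, baseline hazard):
  the simplest well-defined choice, and the one a brute-force oracle can
  mirror exactly. No Efron or exact-tie methods.
* Newton-Raphson with step-halving; convergence at |delta logPL| < 1e-9 or
  100 iterations (60 in the compiled scan); |beta| > 15 flags monotone
  likelihood. The threshold scan warm-starts each Newton iteration from
  the neighbouring threshold's solution and stops when the
  quadratic-predicted gain falls below tolerance — initialization
  shortcuts that do not move the maximum.
* The compiled scan accumulates the sum of log-denominators as chunked
  products (one `log` per eight risk sets), a rewrite of the same quantity
  that is several-fold faster and accurate to ~1e-13.
* Tie-breaks are total and documented: covariates by (permutation p,
  -T_max, name); thresholds by smaller value when statistics tie within
  1e-12. Together with the per-node substreams this makes tree, classes
  and serialized report byte-reproducible.
* Degenerate inputs: zero-variance statistics are flagged, non-PSD
  correlation matrices rejected, rows not covered by planted rules named,
  cohort validation reports all violations at once.

## Interfaces

The package functions are the interface, driven by the numbered scripts
under `analysis/` (simulate, expression statistics, incidence rates,
trees, validation); `run_pipeline()` sequences the stages with a manifest
of seeds, input checksums and per-output MD5 sums, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.
Cohorts travel as plain CSV (one row per patient, `<gene>_fc` columns,
clinical columns, `os_time`/`os_event`/`pfs_time`/`pfs_event`) written
with round-trip precision; trees serialize to JSON (nodes keyed by id,
with member ids, event/non-event counts, split condition, HR and CI, gate
p-value) plus an indented text report.

## Known limitations

No surrogate splits, no cost-complexity pruning or cross-validation, no
competing risks, no time-varying covariates or stratified/frailty Cox. The
study's exact cutoffs (0.27, 0.25, 0.11, 1.43) and hazard ratios are not
reproducible from first principles because the underlying patient-level
data were never published; the planted-tree defaults reuse those published
cutoffs as simulation truth, which is a statement about the engine, not a
re-estimation of the study. The amalgamation criterion is this package's
choice, off by default. The permutation gate doubles as pre-pruning; both
"rank only" (alpha = 1) and "gate" (alpha < 1) behaviors are reachable.
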