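# gemtree

Survival-tree analysis of gemcitabine-pathway gene expression in resected
pancreatic ductal adenocarcinoma (PDAC).

Gemcitabine is the standard adjuvant chemotherapy after PDAC resection, and
its efficacy runs through a small pathway: the nucleoside transporter
*hENT1* imports the drug, the kinase *DCK* activates it, *MRP1* effluxes
it, and the stress factor *CHOP* represses *hENT1*. Tumor-vs-normal mRNA
levels of these genes, measured by qRT-PCR, may define subgroups of
patients at different mortality and disease-progression risk. `gemtree`
implements that analysis for biostatisticians and translational
researchers:

* **Relative quantification** by the comparative method,
  FC = 2^−ΔΔCt with ΔΔCt = (Ct_target,tumor − Ct_ref,tumor) −
  (Ct_target,normal − Ct_ref,normal), plus one-sample t-tests on log fold
  changes, inter-gene Pearson correlations, and gene-vs-phenotype t/ANOVA
  tests.
* **Time-to-event primitives**: endpoints from dates (years =
  days/365.25), person-years incidence rates (events/person-years × 100,
  with the truncating integer display convention), and a Cox
  proportional-hazards fitter (Breslow ties, Newton–Raphson, Wald 95% CI,
  monotone-likelihood detection) with Breslow-baseline survivor curves
  S_k(t) = S_0(t)^HRk per risk class.
* **A RECPAM-style survival tree** (RECursive Partitioning and
  AMalgamation): binary splits scored by the Cox likelihood-ratio
  chi-square 2{ℓ(β̂) − ℓ(0)} of the split indicator, splitting variables
  chosen by permutation p-values, a max-statistic permutation gate that
  holds the node-level type-I error at α regardless of how many covariates
  compete, stopping rules of ≥1 event and ≥3 subjects per leaf, optional
  amalgamation of leaves, and risk classes ranked by hazard ratio against
  the lowest-risk reference class.
* **A synthetic cohort generator** (log-normal fold changes with a
  Gaussian copula, planted threshold-defined hazard subgroups, nested
  progression/death times, clinical covariates at the cohort's
  prevalences) so the whole pipeline is testable without patient-level
  data, which the motivating study never published.

The hot loop (single-indicator Cox threshold scans and their permutation
nulls) is compiled C++ (Rcpp), as in other survival-tree packages.

## Worked example

Simulate a 400-patient cohort from a planted depth-2 tree (DCK cut at
0.27, then CHOP at 0.25 among DCK-high patients; leaf hazards 0.23 / 0.69
/ 2.07 events per person-year, i.e. hazard ratios 1 / 3 / 9) and ask the
engine to find the structure:

```r
library(gemtree)
cfg <- sim_config(n_patients = 400,
                  leaf_hazards = c(low = 0.23, mid = 0.69, high = 2.07),
                  censor_time_max = 1e6, seed = 11)
expr <- simulate_expression(cfg, seed = 11)
sv   <- simulate_survival(expr, cfg$planted_tree, cfg$leaf_hazards,
                          cfg$censor_time_max, seed = 11, genes = cfg$genes)
cohort <- cbind(data.frame(patient_id = sprintf("P%03d", 1:400)), expr,
                os_time = sv$time, os_event = sv$event)
tree <- grow_tree(cohort, "os", c("hENT1", "CHOP", "MRP1", "DCK"),
                  n_permutations = 199, alpha = 0.05, seed = 11)
print(tree)
print(amalgamate(tree))
```

```
RECPAM survival tree (OS): n = 400, events = 400, 3 leaves
node 1 [400 events / 0 non-events] split: DCK <= 0.2937 (LR = 75.89, gate p = 0.0050)
  node 2 [79 events / 0 non-events] (leaf)
  node 3 [321 events / 0 non-events] split: CHOP <= 0.2979 (LR = 53.92, gate p = 0.0050)
    node 6 [64 events / 0 non-events] (leaf)
    node 7 [257 events / 0 non-events] (leaf)
Risk classes (reference = class 3 )
  class_id leaves   n n_events       hr ci95_low ci95_high rate_per_100py
1        1      6  64       64 9.593537 6.549264 14.052868      238.02882
2        2      7 257      257 2.736507 2.079978  3.600263       73.20701
3        3      2  79       79 1.000000 1.000000  1.000000       28.17157
```

The engine recovers both planted cuts (0.294 vs 0.27; 0.298 vs 0.25) and
the planted hazard ratios (9.59 vs 9; 2.74 vs 3). Class 3, the patients
with low *DCK*, is the reference (lowest crude event rate, HR = 1 by
construction); class 1 — high *DCK*, low *CHOP* — carries the highest
mortality. Node labels show events (top) and non-events (bottom), the
split condition sits on the branch, and the gate p-value is the
max-statistic permutation p at that node.

The rate arithmetic follows the person-years convention with truncated
integer display:

```r
incidence_rate(events = 16, person_years = 45)$rate_display  # 35
incidence_rate(events = 17, person_years = 29)$rate_display  # 58
```

## The analysis workflow

The numbered drivers under `analysis/` run the study-scale analysis
(26-patient simulated cohort) end to end and write tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | generate and validate the synthetic cohort (CSV) |
| `02_expression_stats.R` | per-gene fold-change tests, inter-gene correlations, phenotype associations |
| `03_survival_rates.R` | person-years incidence rates per endpoint |
| `04_recpam_trees.R` | full pipeline: trees, risk classes, survivor curves, class profiles, run manifest |
| `05_method_validation.R` | Cox-vs-grid-search oracle, gate calibration, planted-tree recovery |

At the 26-patient scale the permutation gate frequently (and correctly)
declines to split — a calibrated gate pays for its type-I control with
power at small n; the engine's operating characteristics are therefore
demonstrated at n = 400 (script 05 and the vignette).

## Documentation

The methods vignette (`vignettes/gemtree-methods.Rmd`) documents the
models and their assumptions, the permutation gate design, the synthetic
generator's defaults and what they do and do not emulate, numerical
choices, and known limitations.
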