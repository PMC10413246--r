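# tripath

Mining ordered disease triplet pathways from longitudinal claims data.

`tripath` is for epidemiologists and health-services researchers who work
with claims databases (dated outpatient/inpatient diagnosis records) and
want to ask: *which ordered sequences of diseases precede an outcome such
as incident dementia, and how predictive are they?* It implements a
hypothesis-led machine-learning pipeline over matched case-control cohorts,
plus a seeded synthetic-cohort generator so the whole pipeline can be
developed and validated without access to restricted claims data.

## The method

For each person, incident diagnoses are validated (a disease category
counts iff it has ≥ 3 outpatient claims within 365 days or ≥ 1 inpatient
claim) and sorted by first-diagnosis date into a strictly dated disease
sequence, using only events before the index date (first dementia diagnosis
for cases; the matched anchor for controls). The pipeline then:

1. **Enumerates** every ordered disease triplet A → B → C occurring as a
   dated subsequence (a sequence of *n* strictly dated diseases yields
   *n(n−1)(n−2)/6* triples), and keeps triples supported by ≥ 10 cases.
2. **Screens** each triple by univariable logistic regression of case
   status on exposure. For a binary exposure the MLE odds ratio is the 2×2
   cross-product ratio OR = *ad/bc* with Wald SE(log OR) =
   √(1/a + 1/b + 1/c + 1/d); triples with OR > 1 and two-sided *p* < .05
   are retained.
3. **Encodes** each retained triplet as 15 binary features in 7 groups —
   4 ordinal (`A->B->C`; `A->B`, `B->C`; `1_A->B`, `2_B->C`; `1_A`, `2_B`,
   `3_C`) and 3 nonordinal (`A`, `B`, `C`; `A&B`, `A&C`, `B&C`; `A&B&C`) —
   and builds the persons × features sparse binary design matrix.
4. **Selects and classifies**: L1-penalized logistic regression (one model
   over all features, or one per feature group with the union of nonzero
   coefficients), then a linear SVM or random forest tuned by 3-fold
   cross-validation; the four resulting models are compared on the held-out
   third of pairs and the best **test sensitivity** wins.
5. **Visualizes**: final-model pathways are consolidated into disease trees
   (parents = first diseases, children merged on shared ordered prefixes;
   each node carries a dementia probability = covered cases / covered
   persons), parents are ordered by cumulative covered dementia population
   fraction, the top-5 children per parent are kept, and the retained
   pathways are projected onto a directed temporal disease network whose
   edges keep ≥ 50 covering cases.

## Worked example

Simulate a matched cohort of 200 case-control pairs over 15 disease
categories with one planted pathway (`C01 -> C02 -> C03`, present in order
in 45% of cases vs 10% of controls) and run the whole pipeline:

```r
library(tripath)
cfg <- pipeline_config(
  sim = sim_config(
    n_cases = 200, n_categories = 15, seed = 42,
    planted_pathways = list(
      list(triplet = c("C01", "C02", "C03"), p_case = 0.45, p_control = 0.1))),
  min_case_support = 10, min_edge_cases = 10, seed = 42)
res <- run_pipeline(cfg, "run42")
```

The run logs the funnel as it narrows:

```
[tripath] validate     4966 incident diagnoses (0 categories failed validation)
[tripath] triplets     1825 supported triplet clusters (>=10 cases) from 2486 enumerated
[tripath] screen       526 of 1825 pathways positively associated (OR>1, p<0.05)
[tripath] featurize    1388 corresponding features from 526 pathways
[tripath] model        final model: one_model + random_forest (sensitivity 0.597, AUC 0.678, 18 features)
[tripath] visualize    13 parent nodes, 7 chosen by coverage, 81 network edges
```

`res$models$comparison` holds the four-model table (metrics on the held-out
test pairs):

```
   feature_selection    classifier n_features accuracy sensitivity specificity   ppv   npv   auc
1:         one_model           svm         18    0.664       0.537       0.791 0.720 0.631 0.683
2:         one_model random_forest         18    0.657       0.597       0.716 0.678 0.640 0.678
3:          by_group           svm        182    0.642       0.567       0.716 0.667 0.623 0.681
4:          by_group random_forest        182    0.604       0.582       0.627 0.609 0.600 0.627
```

The final model is the maximum-sensitivity row (here the one-model random
forest at 0.597 — on a cohort this small the four models sit within noise
of one another; at 500 pairs with three planted pathways the by-group SVM
reaches test AUC near 0.8, as the acceptance suite checks). `res$coverage$curve` shows the greedy parent ordering — the
first parent already covers 60% of test cases, six parents reach 91% — and
`res$network$edges` lists the retained directed disease pairs with their
covering-case weights, with the planted edges `C01->C02` (116 cases) and
`C02->C03` (123) among the heaviest. All stage artifacts (support,
screening, vocabulary, MTX matrices, model reports, trees as JSON, network
as GraphML/DOT, manifest with content hashes) are written under `run42/`.

A thin command-line wrapper with `simulate` / `preprocess` / `screen` /
`run` subcommands lives at `inst/cli/tripath.R`.

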