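---
title: "Mining ordered disease triplet pathways from claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ordered disease triplet pathways from claims cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripath)
library(data.table)
```

## The problem

Incident dementia is rarely the first event in an older adult's medical
history: cardiometabolic disease, cerebrovascular events, mobility disorders,
infections and mood disorders accumulate over years, and their *order* may
carry information that unordered comorbidity lists do not. Longitudinal
claims databases record exactly this: dated outpatient and inpatient
diagnosis claims, per person, over a decade or more. `tripath` implements a
hypothesis-led machine-learning pipeline that mines **ordered disease
triplet pathways** (A&nbsp;→&nbsp;B&nbsp;→&nbsp;C over strictly increasing
incident dates) from such histories in a matched case-control design,
screens them for positive association with case status, encodes them as
binary features, fits penalized and kernel classifiers, and condenses the
final model into disease trees and a directed temporal disease network.

The pipeline operates on two tables: a long-format claims event table
(`person_id`, `date`, `code`, `setting` ∈ outpatient/inpatient) and a person
registry (`person_id`, `birth_year`, `sex`, `is_case`, `index_date`,
`match_id`). The index date is the case's first dementia diagnosis; its
matched control inherits the same index year. All analysis uses only events
strictly before the person's index date, which enforces temporal precedence
of every predictor.

## Stage by stage

### Incident diagnoses and sequences

A diagnosis category counts as *incident and valid* for a person iff it is
documented at least 3 times in outpatient claims within a 365-day window, or
appears on at least one inpatient claim (`validate_diagnoses()`, parameters
`min_outpatient` and `window_days`). This claims-validation rule guards
against rule-out codes that appear once and vanish. The incident date is the
earliest claim of the category in *any* setting once validity is
established; the rule does not restrict the date to the qualifying window.
Codes can first be collapsed to ~253 clinically coherent categories with a
CCS-style longest-prefix crosswalk (`map_to_ccs()`); a toy mapping ships
under `inst/extdata/`.

Each person's valid incident diagnoses, sorted by incident date, form their
disease sequence (`build_timelines()`). Two choices matter here:

* **Tied dates.** Categories sharing an incident date get no order relation
  between themselves (they may still pair with strictly earlier or later
  diseases). Sequential occurrence requires strict precedence, and any
  tie-breaking rule would manufacture order that the data do not contain.
* **Outcome exclusion.** The `exclude` argument removes categories from
  every sequence; passing the dementia-defining categories there keeps the
  outcome out of its own predictors. The default is to exclude nothing,
  because the synthetic generator never emits outcome codes as predictors.

`enumerate_triplets()` then emits every ordered 3-subsequence with strictly
increasing incident dates. A strictly dated sequence of *n* diseases yields
exactly *n(n−1)(n−2)/6* triples; the test suite holds the implementation to
that closed form and to a brute-force enumerator.

### Screening

`count_support()` keeps triples carried by at least `min_case_support = 10`
*case* persons (the support threshold is a property of the case series;
controls enter only through the exposure counts). For each supported triple
the 2×2 table of exposure against case status is screened by univariable
logistic regression (`screen_triplets()`). For a single binary covariate
the logistic MLE of the odds ratio is the cross-product ratio
*(ad)/(bc)* and the Wald standard error of its log is
*√(1/a + 1/b + 1/c + 1/d)*, so both are computed in closed form; the test
suite verifies agreement with an iterative `glm()` fit to 10⁻⁶ on the
log odds ratio. Pathways with OR &gt; 1 and two-sided *p* &lt; 0.05 are
retained. No multiplicity adjustment is applied at this stage — the screen
is a filter feeding a penalized model, not a hypothesis test whose level is
reported — and tables with a zero cell are flagged non-estimable and
dropped rather than continuity-corrected.

### Corresponding features

Every selected triplet (A, B, C) expands into 15 binary feature keys in 7
groups (`encode_triplet()`): the full ordered pathway `A->B->C` (group 1),
the consecutive ordered doublets `A->B`, `B->C` (group 2), the
position-anchored doublets `1_A->B`, `2_B->C` (group 3), the
position-anchored singles `1_A`, `2_B`, `3_C` (group 4), the unordered
singles (group 5), the unordered pairs `A&B`, `A&C`, `B&C` (group 6) and the
unordered triple `A&B&C` (group 7). Groups 1–4 are ordinal (their tokens
change when the triplet is reversed), groups 5–7 are nonordinal and
canonicalized by lexicographic sorting. Group 2 deliberately contains only
the *consecutive* doublets, not `A->C`.

A person's feature is 1 iff some triplet in the intersection of their
enumerated triplets with the selected set generates the key
(`build_feature_matrix()`). An alternative rule — match the token pattern
anywhere in the raw sequence regardless of selection — was considered and
rejected as the default: features are defined *from* the selected clusters,
and mediating assignment through the selected set keeps the feature matrix
a deterministic function of the screening output. Assignment is monotone in
the selected set: enlarging it never clears a 1.

### Feature selection and classification

`lasso_select()` fits L1-penalized logistic regression with `glmnet`, either
over all columns at once (`one_model`) or per feature group with the union
of nonzero-coefficient features taken afterwards (`by_group`). The penalty
is chosen by 3-fold cross-validated binomial deviance at the minimum (not
the 1-SE rule) over a 50-point log-spaced path; the minimum-deviance rule is
the least-surprising default where no rule is prescribed. Coefficients with
|β| &gt; 10⁻⁸ count as selected. Folds are stratified by case status and
seeded.

`train_classifier()` fits a linear-kernel SVM (`e1071`; costs 0.01–10) or a
random forest (`randomForest`; 300 trees, `mtry` at 0.5×, 1× and 2× √p),
choosing hyperparameters by 3-fold cross-validated accuracy and refitting on
the full training split. The linear kernel is the default because the
feature space is high-dimensional sparse binary, where linear margins are
the standard first choice; an RBF kernel is available via `svm_kernel`.
Class weights are unnecessary: the cohort is 1:1 matched by design.

`evaluate_classifier()` reports accuracy, sensitivity, specificity, PPV,
NPV at the classifier's native operating point (decision score 0 for the
SVM, vote majority for the forest — no threshold tuning) and AUC by the
rank statistic with midrank tie correction, which the tests pin to
trapezoidal ROC integration at 10⁻⁹. Metrics with empty denominators are
`NA`, never 0. `select_final()` picks the report with the best test
sensitivity, breaking ties by higher AUC and then fewer features;
sensitivity is the deliberate criterion because the intended use is flagging
at-risk patients, where misses are costlier than false alarms.

### Disease trees and the temporal network

`pathways_from_final_model()` maps the final model's features back to the
screened triplets that generate them. `build_trees()` merges triplets
sharing ordered prefixes: one parent node per first disease, children
merging on (d1, d2), leaves at depth 3. A person covers a node iff the
root-to-node ordered path occurs (strict dates) in their sequence; each
node's *dementia probability* is covered cases / covered persons.
`rank_children()` keeps the top-5 children per parent by dementia
probability, ties broken by covered case count then category name. The
count-based ranking can be had by reordering on `n_cases` directly from the
`nodes` table.

`cumulative_coverage()` orders parents greedily by incremental newly-covered
cases and reports the cumulative covered case fraction after each parent.
The "optimal" parent count is operationalized as the first parent whose
marginal gain falls below `epsilon` (default 0.1%) of the case series — a
plateau criterion. This is an artifact decision: the underlying idea
(stop adding parents when coverage stops improving) admits many
formalizations, so the full curve is always returned and the cut is
configurable. `build_temporal_network()` projects retained root-to-leaf
pathways onto directed edges d1→d2, d2→d3 weighted by the number of distinct
case persons covering the full pathway, aggregates weights over pathways
sharing an edge *before* applying the 50-case edge threshold, and exports
GraphML/DOT via `igraph`.

## The synthetic cohort generator

Claims data of the kind this pipeline targets are access-restricted, so
`sim_config()` / `generate_cohort()` emulate the cohort structure end to
end: per-person dated diagnosis streams over a 2003–2013 window, roughly 30
outpatient visits per person-year (repeat claims of already-diagnosed
conditions), incident index dates with at least 3 years of observable
history, uniform ages 55–90 at index, and 1:1 controls matched exactly on
sex, year of age and index year (control index dates are redrawn uniformly
within the case's index year, since matching is on index *year*).

Background incident diagnoses arrive as a Poisson process (default 3 per
person-year) uniformly over the category vocabulary — the simplest
exchangeable null. Planted pathways are the signal: with probability
`p_case` (cases) or `p_control` (controls) the full ordered triple is
embedded with inter-diagnosis gaps uniform on [30, 365] days, every claim
dated so the validation rule passes and precedes the index date. Planted
categories are withheld from the background vocabulary, so triple exposure
is exactly Bernoulli and the planted odds ratio is
(p_case/(1−p_case))/(p_ctrl/(1−p_ctrl)) in closed form — the generator's
calibration tests rest on this identity. One global seed drives per-stage
substreams, making cohorts byte-identical under replay.

What the generator does **not** emulate — and what passing tests therefore
do not show about real claims data: correlated comorbidity structure beyond
the planted triples, code-level ICD microstructure (categories are opaque
labels), mortality and enrollment censoring, secular trends in coding
practice, and misclassified or missing diagnoses. Results on synthetic
cohorts validate the machinery, not the epidemiology.

## Problem sizes and numerical choices

The package's own validation runs at desk scale: calibration suites use
200–500 matched pairs over 10–20 categories, 10–20 seeded replicates, and
planting probabilities 0.4–0.6 vs 0.1–0.15 — large enough that the planted
odds ratio (6–9) is detected with high power, small enough that the whole
suite runs in minutes. Degenerate inputs are handled explicitly: empty
timelines enumerate to empty triple sets, zero-cell screening tables are
non-estimable rather than corrected, all-constant feature columns are
dropped with a message, an empty selection is an error directing the user
to relax the penalty, and a screening stage that retains nothing stops the
pipeline cleanly after writing partial outputs.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(
    n_cases = 200, n_categories = 15, seed = 42,
    planted_pathways = list(
      list(triplet = c("C01", "C02", "C03"), p_case = 0.45, p_control = 0.1))),
  min_case_support = 10, min_edge_cases = 10, seed = 42)
res <- run_pipeline(cfg, "run42")
res$models$comparison   # the four-model table
res$coverage$curve      # cumulative covered case fraction per parent
res$network$edges       # the retained temporal-network edges
```

## Known limitations

* Triplets only: longer pathways appear only as consolidated trees, and
  inter-diagnosis time gaps are deliberately not featurized.
* The screening stage's raw *p* &lt; 0.05 filter is anticonservative as a
  multiple-testing procedure; it is a funnel stage, and the LASSO behind it
  is what controls model complexity.
* `by_group` selection unions seven separately tuned fits, so its feature
  count is not comparable to `one_model`'s at equal penalty.
* Matching is greedy without replacement; in thin strata it can leave cases
  unmatched that an optimal assignment would match (unmatched cases are
  reported, never dropped silently).
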