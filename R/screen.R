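#' Univariable odds-ratio screening of triplet clusters
#'
#' For each triplet the 2x2 table of exposure against case status is
#' summarised by the odds ratio and a two-sided Wald p-value. In a
#' single-covariate logistic model of case status on a binary exposure the
#' maximum-likelihood odds ratio equals the cross-product ratio
#' (a d)/(b c), and the Wald standard error of its log is
#' sqrt(1/a + 1/b + 1/c + 1/d); both are computed in closed form. Tables
#' with any zero cell are flagged non-estimable (no continuity correction)
#' and never selected.
#'
#' @param support `TripletCluster` table from [count_support()].
#' @param alpha significance level for the selection flag (raw, no
#'   multiplicity adjustment: this is a screening stage).
#' @return `ScreenRecord` table: the triple, the four counts `a` (case
#'   exposed), `b` (case unexposed), `c` (control exposed), `d` (control
#'   unexposed), `odds_ratio`, `p_value`, `estimable`, `selected`.
#' @export
screen_triplets <- function(support, alpha = 0.05) {
  sup <- as.data.table(support)
  need <- c("n_case_exposed", "n_case_unexposed", "n_ctrl_exposed", "n_ctrl_unexposed")
  assert_that(all(need %in% names(sup)), "support must carry the four 2x2 counts")
  rec <- sup[, .(d1, d2, d3,
                 a = as.numeric(n_case_exposed), b = as.numeric(n_case_unexposed),
                 c = as.numeric(n_ctrl_exposed), d = as.numeric(n_ctrl_unexposed))]
  rec[, estimable := a > 0 & b > 0 & c > 0 & d > 0]
  rec[, odds_ratio := ifelse(estimable, (a * d) / (b * c), NA_real_)]
  rec[, p_value := ifelse(
    estimable,
    2 * pnorm(-abs(log(odds_ratio) / sqrt(1 / a + 1 / b + 1 / c + 1 / d))),
    NA_real_)]
  rec[, selected := estimable & odds_ratio > 1 & p_value < alpha]
  rec[]
}

#' Retain positively associated pathways
#'
#' Applies the screening rule: keep triplets with odds ratio > 1 and
#' p-value < `alpha`; non-estimable records are excluded.
#'
#' @param records output of [screen_triplets()].
#' @param alpha significance level.
#' @return the selected subset, with `selected` recomputed at `alpha`.
#' @export
select_pathways <- function(records, alpha = 0.05) {
  rec <- as.data.table(records)
  rec[estimable & odds_ratio > 1 & p_value < alpha][, selected := TRUE][]
}
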