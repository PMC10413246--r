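library(data.table)

## --- independent oracles -----------------------------------------------

## brute-force ordered-triple enumerator: plain nested loops over all index
## triples with a strict date comparison (independent of the package path)
oracle_triplets <- function(categories, dates) {
  n <- length(categories)
  out <- list()
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trip <- c(i, j, k)
    trip <- trip[order(dates[trip], categories[trip])]
    if (dates[trip[1]] < dates[trip[2]] && dates[trip[2]] < dates[trip[3]])
      out[[length(out) + 1L]] <- categories[trip]
  }
  if (length(out) == 0L)
    return(data.table(d1 = character(0), d2 = character(0), d3 = character(0)))
  unique(rbindlist(lapply(out, function(x)
    data.table(d1 = x[1], d2 = x[2], d3 = x[3]))))
}

## logistic-regression oracle for a 2x2 table: MLE odds ratio and Wald p
oracle_or_glm <- function(a, b, c, d) {
  df <- data.frame(y = rep(c(1, 1, 0, 0), c(a, b, c, d)),
                   x = rep(c(1, 0, 1, 0), c(a, b, c, d)))
  fit <- glm(y ~ x, family = binomial(), data = df,
             control = glm.control(epsilon = 1e-12))
  s <- summary(fit)$coefficients
  list(or = exp(unname(coef(fit)["x"])), p = unname(s["x", "Pr(>|z|)"]))
}

## trapezoidal ROC integration oracle for the AUC
oracle_auc_trapezoid <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## --- fixture builders --------------------------------------------------

## timelines table from a named list of character sequences; the i-th
## disease of a person gets onset day 10 * i unless explicit days given
toy_timelines <- function(seqs, is_case = NULL, days = NULL,
                          index_day = 10000) {
  origin <- as.Date("2003-01-01")
  if (is.null(is_case)) is_case <- rep(TRUE, length(seqs))
  rbindlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    d <- if (is.null(days)) 10 * seq_along(s) else days[[i]]
    data.table(person_id = names(seqs)[i] %||% paste0("p", i),
               is_case = is_case[i], index_date = origin + index_day,
               category = s, onset = origin + d,
               tied = duplicated(d) | duplicated(d, fromLast = TRUE))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## claims rows for one person at given day offsets
toy_events <- function(person_id, days, code, setting = "outpatient",
                       origin = as.Date("2003-01-01")) {
  data.table(person_id = person_id, date = origin + days, code = code,
             setting = setting)
}

## classifier stub whose decision score is its single feature, for testing
## the evaluation arithmetic in isolation
score_stub_classifier <- function(feature = "s") {
  structure(list(kind = "svm", features = feature,
                 model = structure(list(), class = "score_stub")),
            class = "tripath_classifier")
}

predict.score_stub <- function(object, newdata, decision.values = TRUE, ...) {
  s <- newdata[, 1]
  structure(s, decision.values = matrix(s, ncol = 1,
                                        dimnames = list(NULL, "1/0")))
}
registerS3method("predict", "score_stub", predict.score_stub,
                 envir = asNamespace("stats"))

## synthetic model_report with chosen metrics (for selection-rule tests)
fake_report <- function(sensitivity, auc = 0.6, n_features = 10,
                        feature_selection = "by_group", classifier = "svm") {
  structure(list(feature_selection = feature_selection, classifier = classifier,
                 n_features = n_features, tp = NA, fn = NA, tn = NA, fp = NA,
                 accuracy = NA_real_, sensitivity = sensitivity,
                 specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                 auc = auc, scores = numeric(0)),
            class = "model_report")
}

## run the preprocessing chain of the package on a generated cohort
cohort_support <- function(cohort, min_case_support = 10L) {
  inc <- validate_diagnoses(cohort$events)
  tl <- build_timelines(inc, cohort$registry)
  tr <- enumerate_triplets(tl)
  count_support(tr, cohort$registry, min_case_support = min_case_support)
}
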