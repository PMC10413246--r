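## stratified k-fold assignment, seeded
make_folds <- function(y, k, seed) {
  set.seed(stage_seed(seed, "folds"))
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample_vec(which(y == cls))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

drop_constant_cols <- function(X) {
  cs <- Matrix::colSums(X)
  keep <- cs > 0 & cs < nrow(X)
  if (!all(keep))
    message(sprintf("dropping %d all-constant feature column(s)", sum(!keep)))
  X[, keep, drop = FALSE]
}

## cv.glmnet over one column block; returns tokens with |coef| > tol at
## lambda.min. glmnet needs >= 2 columns, so a 1-column block is mirrored
## (L1 keeps the duplicate's selection status identical in aggregate).
cv_lasso_block <- function(X, y, foldid, nlambda, tol = 1e-8, lambda = NULL) {
  single <- ncol(X) == 1L
  if (single) X <- cbind(X, X)
  if (is.null(lambda)) {
    fit <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                             nlambda = nlambda, standardize = FALSE)
    s <- fit$lambda.min
    grid <- fit$lambda
  } else {
    fit <- glmnet::glmnet(X, y, family = "binomial", standardize = FALSE)
    ## at the top of the path every coefficient is zero already, so any
    ## larger penalty (incl. Inf) is equivalent to the path maximum
    s <- min(lambda, max(fit$lambda))
    grid <- fit$lambda
  }
  co <- as.matrix(coef(fit, s = s))[-1L, , drop = FALSE]
  if (single) {
    tok <- colnames(X)[1L]
    sel <- if (sum(abs(co)) > tol) tok else character(0)
  } else {
    sel <- rownames(co)[abs(co[, 1L]) > tol]
  }
  list(selected = sel, lambda = s, lambda_grid = grid)
}

#' LASSO feature selection: one-model or by-group
#'
#' L1-penalized logistic regression of case status on the binary feature
#' matrix. `one_model` fits a single model over all columns; `by_group`
#' fits seven independent models, one per corresponding-feature group, and
#' returns the union of features with nonzero coefficients. The penalty is
#' chosen per fit by `cv_folds`-fold cross-validated binomial deviance over
#' a log-spaced lambda path (minimum-deviance rule); coefficients with
#' absolute value above 1e-8 count as selected. All-constant columns are
#' dropped up front.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param y binary case labels (0/1 or logical), aligned to `fm$X` rows.
#' @param mode `"one_model"` or `"by_group"`.
#' @param cv_folds folds for the internal cross-validation (default 3).
#' @param nlambda points on the lambda path.
#' @param seed integer seed (fold assignment).
#' @param lambda optional fixed penalty; skips the cross-validated choice
#'   (`Inf` shrinks every coefficient to zero, yielding an empty selection).
#' @return list of class `lasso_selection`: `method`, `selected` (tokens),
#'   `per_group` (by_group only: token list per group), `lambda` (chosen
#'   penalty per fit), `lambda_grid`.
#' @export
lasso_select <- function(fm, y, mode = c("one_model", "by_group"),
                         cv_folds = 3L, nlambda = 50L, seed = 1L,
                         lambda = NULL) {
  mode <- match.arg(mode)
  assert_that(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  y <- as.numeric(y)
  assert_that(length(y) == nrow(fm$X), "y must align with the feature matrix rows")
  assert_that(ncol(fm$X) > 0L && nrow(fm$X) > 0L, "empty feature matrix")
  X <- drop_constant_cols(fm$X)
  assert_that(ncol(X) > 0L, "all feature columns are constant")
  foldid <- make_folds(y, cv_folds, seed)
  if (mode == "one_model") {
    blk <- cv_lasso_block(X, y, foldid, nlambda, lambda = lambda)
    res <- list(method = "one_model", selected = sort(blk$selected),
                per_group = NULL, lambda = blk$lambda, lambda_grid = blk$lambda_grid)
  } else {
    groups <- fm$groups[colnames(X)]
    per_group <- list(); lambda <- c()
    for (g in sort(unique(groups))) {
      Xg <- X[, names(groups)[groups == g], drop = FALSE]
      blk <- cv_lasso_block(Xg, y, foldid, nlambda, lambda = lambda)
      per_group[[as.character(g)]] <- sort(blk$selected)
      lambda[as.character(g)] <- blk$lambda
    }
    res <- list(method = "by_group",
                selected = sort(unique(unlist(per_group, use.names = FALSE))),
                per_group = per_group, lambda = lambda, lambda_grid = NULL)
  }
  structure(res, class = "lasso_selection")
}

## orient SVM decision values so that larger means "case"
svm_scores <- function(model, X) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1L]
  ## e1071 orients toward the first level named in the column label
  if (startsWith(colnames(dv)[1L], "1/")) s else -s
}

fit_one_classifier <- function(X, y, kind, par) {
  yf <- factor(y, levels = c(0, 1))
  if (kind == "svm") {
    e1071::svm(X, yf, kernel = par$kernel %||% "linear", cost = par$cost,
               scale = FALSE)
  } else {
    randomForest::randomForest(X, yf, ntree = par$ntree, mtry = par$mtry)
  }
}

score_classifier <- function(model, kind, X) {
  if (kind == "svm") svm_scores(model, X)
  else predict(model, X, type = "prob")[, "1"]
}

## native operating point: SVM decision boundary at score 0, RF vote majority
classify_scores <- function(kind, scores) {
  thr <- if (kind == "svm") 0 else 0.5
  as.integer(scores > thr)
}

#' Train an SVM or random-forest classifier with 3-fold cross-validation
#'
#' Hyperparameters are chosen by stratified `cv_folds`-fold cross-validated
#' accuracy over a small grid (SVM: linear kernel, cost in
#' `c(0.01, 0.1, 1, 10)`; random forest: `ntree = 300`, `mtry` at 0.5x, 1x
#' and 2x sqrt(p)), then the model is refit on the full training split.
#' Fold assignment and tuning are fully determined by `seed`.
#'
#' @param fm a `feature_matrix` (training split).
#' @param y binary case labels aligned to `fm$X` rows.
#' @param features tokens to use (e.g. `selection$selected`); must be
#'   nonempty.
#' @param kind `"svm"` or `"random_forest"`.
#' @param cv_folds cross-validation folds (default 3).
#' @param seed integer seed.
#' @param svm_kernel SVM kernel (`"linear"` default; `"radial"` available).
#' @return list of class `tripath_classifier`: the fitted `model`, `kind`,
#'   `features`, chosen hyperparameters `par`, and the CV grid summary
#'   `cv_summary`.
#' @export
train_classifier <- function(fm, y, features, kind = c("svm", "random_forest"),
                             cv_folds = 3L, seed = 1L, svm_kernel = "linear") {
  kind <- match.arg(kind)
  assert_that(length(features) >= 1L,
              "zero selected features: relax the LASSO penalty before training")
  assert_that(all(features %in% colnames(fm$X)),
              "some requested features are absent from the matrix")
  X <- as.matrix(fm$X[, features, drop = FALSE])
  y <- as.numeric(y)
  p <- ncol(X)
  grid <- if (kind == "svm") {
    lapply(c(0.01, 0.1, 1, 10), function(cc) list(cost = cc, kernel = svm_kernel))
  } else {
    mtrys <- unique(pmax(1L, pmin(p, round(sqrt(p) * c(0.5, 1, 2)))))
    lapply(mtrys, function(m) list(ntree = 300L, mtry = m))
  }
  foldid <- make_folds(y, cv_folds, seed)
  cv_acc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    ok <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      set.seed(stage_seed(seed, paste0("fit", kind, gi, f)))
      m <- fit_one_classifier(X[tr, , drop = FALSE], y[tr], kind, grid[[gi]])
      sc <- score_classifier(m, kind, X[!tr, , drop = FALSE])
      ok <- ok + sum(classify_scores(kind, sc) == y[!tr])
    }
    cv_acc[gi] <- ok / length(y)
  }
  best <- which.max(cv_acc)  # first max wins: ties go to the smaller setting
  set.seed(stage_seed(seed, paste0("refit", kind)))
  model <- fit_one_classifier(X, y, kind, grid[[best]])
  structure(list(model = model, kind = kind, features = features,
                 par = grid[[best]],
                 cv_summary = data.table(
                   param = vapply(grid, function(g)
                     paste(names(g), unlist(g), sep = "=", collapse = ","),
                     character(1)),
                   cv_accuracy = cv_acc)),
            class = "tripath_classifier")
}

#' @export
predict.tripath_classifier <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_matrix"))
    as.matrix(newdata$X[, object$features, drop = FALSE])
  else as.matrix(newdata[, object$features, drop = FALSE])
  s <- score_classifier(object$model, object$kind, X)
  if (type == "score") s else classify_scores(object$kind, s)
}

## AUC by the rank (Mann-Whitney) statistic with midrank tie correction
auc_rank <- function(scores, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on a held-out split
#'
#' Computes the confusion matrix at the classifier's native operating point
#' and the six standard metrics: accuracy, sensitivity, specificity,
#' positive and negative predictive value, and AUC by the rank statistic
#' over the decision scores (midrank tie correction). Metrics whose
#' denominator is zero (degenerate test labels) are reported as `NA`, never
#' as 0.
#'
#' @param classifier a `tripath_classifier`.
#' @param fm_test `feature_matrix` of the test split.
#' @param y_test binary labels aligned to `fm_test$X` rows.
#' @param feature_selection label recorded in the report (e.g.
#'   `"by_group"`).
#' @return list of class `model_report`: `feature_selection`, `classifier`,
#'   `n_features`, confusion counts `tp fn tn fp`, the six metrics, and the
#'   score vector.
#' @export
evaluate_classifier <- function(classifier, fm_test, y_test,
                                feature_selection = NA_character_) {
  y <- as.numeric(y_test)
  scores <- predict(classifier, fm_test, type = "score")
  pred <- classify_scores(classifier$kind, scores)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    feature_selection = feature_selection,
    classifier = classifier$kind,
    n_features = length(classifier$features),
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = div(tp + tn, length(y)),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    auc = auc_rank(scores, y),
    scores = scores), class = "model_report")
}

#' Choose the final model by test-set sensitivity
#'
#' Returns the report with the highest sensitivity; ties are broken by
#' higher AUC, then by fewer features.
#'
#' @param reports list of `model_report`s.
#' @return the winning `model_report`.
#' @export
select_final <- function(reports) {
  assert_that(length(reports) >= 1L, "need at least one model report")
  key <- vapply(reports, function(r)
    c(r$sensitivity %||% NA_real_, r$auc %||% NA_real_, -r$n_features),
    numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ], decreasing = TRUE)
  reports[[ord[1L]]]
}

#' Run the four-model comparison (2 selections x 2 classifiers)
#'
#' Convenience wrapper: for each feature-selection mode runs
#' [lasso_select()], trains both classifier kinds on the selected features,
#' and evaluates them on the test split.
#'
#' @param fm_train,fm_test training / test `feature_matrix` (same columns).
#' @param y_train,y_test binary labels.
#' @param modes feature-selection modes to run.
#' @param classifiers classifier kinds to run.
#' @param cv_folds folds for both LASSO and classifier tuning.
#' @param seed integer seed.
#' @return list with `reports` (list of `model_report`), `selections`
#'   (per-mode `lasso_selection`), `final` (the winning report), and
#'   `comparison` (a table of the six metrics per model).
#' @export
run_model_comparison <- function(fm_train, y_train, fm_test, y_test,
                                 modes = c("one_model", "by_group"),
                                 classifiers = c("svm", "random_forest"),
                                 cv_folds = 3L, seed = 1L) {
  reports <- list(); selections <- list()
  for (mode in modes) {
    sel <- lasso_select(fm_train, y_train, mode = mode, cv_folds = cv_folds,
                        seed = seed)
    selections[[mode]] <- sel
    for (kind in classifiers) {
      clf <- train_classifier(fm_train, y_train, sel$selected, kind = kind,
                              cv_folds = cv_folds, seed = seed)
      reports[[paste(mode, kind, sep = "_")]] <-
        evaluate_classifier(clf, fm_test, y_test, feature_selection = mode)
    }
  }
  comparison <- rbindlist(lapply(reports, function(r)
    data.table(feature_selection = r$feature_selection, classifier = r$classifier,
               n_features = r$n_features, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               ppv = r$ppv, npv = r$npv, auc = r$auc)))
  list(reports = reports, selections = selections,
       final = select_final(reports), comparison = comparison)
}
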