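#' Pipeline configuration
#'
#' Flat configuration for the end-to-end runner. Defaults mirror the
#' study-design thresholds the pipeline is built around: incident
#' diagnoses validated by 3 outpatient claims within 365 days (or one
#' admission), triplet support of at least 10 cases, raw screening at
#' alpha = 0.05 with odds ratio > 1, 2/3-1/3 pair-level train/test split,
#' 3-fold cross-validation, top-5 children per parent node, and a 50-case
#' temporal-network edge threshold.
#'
#' @param sim a [sim_config()] to simulate the cohort, or `NULL` to read
#'   `events_path` / `registry_path`.
#' @param events_path,registry_path input CSVs (ignored when `sim` given).
#' @param ccs_path optional code-prefix mapping applied to the event codes.
#' @param exclude_categories categories removed from every sequence (e.g.
#'   outcome-defining codes).
#' @param window_days,min_outpatient claims validation rule.
#' @param min_case_support triplet support threshold (cases).
#' @param alpha screening significance level.
#' @param train_fraction fraction of pairs in the training split.
#' @param cv_folds folds for LASSO and classifier tuning.
#' @param nlambda lambda-path length.
#' @param selection_modes,classifiers model grid to run.
#' @param top_children children kept per parent node.
#' @param min_edge_cases temporal-network edge threshold.
#' @param coverage_epsilon marginal-gain cut for the parent-count choice.
#' @param seed global seed; all stages derive substreams from it.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(sim = NULL, events_path = NULL, registry_path = NULL,
                            ccs_path = NULL, exclude_categories = character(0),
                            window_days = 365L, min_outpatient = 3L,
                            min_case_support = 10L, alpha = 0.05,
                            train_fraction = 2 / 3, cv_folds = 3L, nlambda = 50L,
                            selection_modes = c("one_model", "by_group"),
                            classifiers = c("svm", "random_forest"),
                            top_children = 5L, min_edge_cases = 50L,
                            coverage_epsilon = 0.001, seed = 1L) {
  cfg <- as.list(environment())
  assert_that(alpha >= 0 && alpha <= 1, "alpha must be in [0,1]")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0,1)")
  assert_that(min_case_support >= 1L, "min_case_support must be >= 1")
  assert_that(!is.null(sim) || (!is.null(events_path) && !is.null(registry_path)),
              "either a sim config or events/registry paths are required")
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[tripath] %-12s %s", stage, sprintf(...)))
}

write_stage <- function(obj, path, manifest) {
  if (is.data.frame(obj)) fwrite(obj, path) else
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$files[[basename(path)]] <- list(
    md5 = unname(tools::md5sum(path)),
    rows = if (is.data.frame(obj)) nrow(obj) else NA_integer_)
  manifest
}

#' Run the full pipeline end to end
#'
#' Executes the four-step study algorithm -- preprocessing, pathway
#' selection, model construction/optimization, and visualization -- and
#' writes every stage artifact plus a manifest (input hashes, seeds,
#' per-stage counts) into `out_dir`. Re-running with an identical config
#' and inputs reproduces identical outputs.
#'
#' If screening retains zero pathways the run stops cleanly after the
#' screening stage with status `"no_pathways_selected"`; partial outputs
#' are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisible list with every stage object, the manifest, and
#'   `status` (`"ok"` or `"no_pathways_selected"`).
#' @export
run_pipeline <- function(config, out_dir) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("tripath")),
                   counts = list(), files = list())

  ## stage 1: inputs
  if (!is.null(config$sim)) {
    pipeline_log("simulate", "generating cohort (n_cases=%d, seed=%d)",
                 config$sim$n_cases, config$sim$seed)
    cohort <- generate_cohort(config$sim)
    events <- cohort$events; registry <- cohort$registry
  } else {
    events <- read_events(config$events_path)
    registry <- read_registry(config$registry_path)
    manifest$input_md5 <- list(events = unname(tools::md5sum(config$events_path)),
                               registry = unname(tools::md5sum(config$registry_path)))
  }
  if (!is.null(config$ccs_path)) {
    events <- map_to_ccs(events, read_ccs_mapping(config$ccs_path))
    pipeline_log("map", "%d claims left unmapped", attr(events, "n_unmapped"))
  }
  write_events(events, file.path(out_dir, "events.csv"))
  write_registry(registry, file.path(out_dir, "registry.csv"))
  for (f in c("events.csv", "registry.csv"))
    manifest$files[[f]] <- list(md5 = unname(tools::md5sum(file.path(out_dir, f))),
                                rows = if (f == "events.csv") nrow(events) else nrow(registry))
  manifest$counts$events <- nrow(events)
  manifest$counts$persons <- nrow(registry)

  ## stage 2: preprocessing
  incidents <- validate_diagnoses(events, window_days = config$window_days,
                                  min_outpatient = config$min_outpatient)
  pipeline_log("validate", "%d incident diagnoses (%d categories failed validation)",
               nrow(incidents), attr(incidents, "n_invalid"))
  timelines <- build_timelines(incidents, registry,
                               exclude = config$exclude_categories)
  split <- split_train_test(registry, train_fraction = config$train_fraction,
                            seed = config$seed)
  tl_train <- timelines[person_id %in% split$train]
  tl_test <- timelines[person_id %in% split$test]
  trip_train <- enumerate_triplets(tl_train)
  trip_test <- enumerate_triplets(tl_test)
  support <- count_support(trip_train, as.data.table(registry)[person_id %in% split$train],
                           min_case_support = config$min_case_support)
  pipeline_log("triplets", "%d supported triplet clusters (>=%d cases) from %d enumerated",
               nrow(support), config$min_case_support,
               uniqueN(trip_train, by = c("d1", "d2", "d3")))
  manifest$counts$supported_triplets <- nrow(support)
  manifest <- write_stage(support, file.path(out_dir, "support.csv"), manifest)

  ## stage 3: screening
  screened <- screen_triplets(support, alpha = config$alpha)
  selected <- select_pathways(screened, alpha = config$alpha)
  manifest$counts$selected_pathways <- nrow(selected)
  manifest <- write_stage(screened, file.path(out_dir, "screening.csv"), manifest)
  pipeline_log("screen", "%d of %d pathways positively associated (OR>1, p<%.3g)",
               nrow(selected), nrow(screened), config$alpha)
  if (nrow(selected) == 0L) {
    pipeline_log("screen", "no pathways selected: stopping after screening")
    manifest$status <- "no_pathways_selected"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(list(status = "no_pathways_selected", manifest = manifest,
                          screened = screened)))
  }

  ## stage 4: features + models
  vocab <- build_vocabulary(selected)
  manifest$counts$features <- nrow(vocab$vocabulary)
  pipeline_log("featurize", "%d corresponding features from %d pathways",
               nrow(vocab$vocabulary), nrow(selected))
  reg <- as.data.table(registry)
  fm_train <- build_feature_matrix(trip_train, vocab, split$train)
  fm_test <- build_feature_matrix(trip_test, vocab, split$test)
  y_train <- as.numeric(reg[match(split$train, person_id), is_case])
  y_test <- as.numeric(reg[match(split$test, person_id), is_case])
  manifest <- write_stage(vocab$provenance, file.path(out_dir, "vocabulary.csv"),
                          manifest)
  write_feature_matrix(fm_train, file.path(out_dir, "matrix_train"))
  write_feature_matrix(fm_test, file.path(out_dir, "matrix_test"))

  cmp <- run_model_comparison(fm_train, y_train, fm_test, y_test,
                              modes = config$selection_modes,
                              classifiers = config$classifiers,
                              cv_folds = config$cv_folds, seed = config$seed)
  manifest <- write_stage(cmp$comparison, file.path(out_dir, "model_comparison.csv"),
                          manifest)
  final_sel <- cmp$selections[[cmp$final$feature_selection]]
  report_out <- lapply(cmp$reports, function(r) r[setdiff(names(r), "scores")])
  manifest <- write_stage(report_out, file.path(out_dir, "model_reports.json"),
                          manifest)
  manifest$counts$final_model_features <- cmp$final$n_features
  pipeline_log("model", "final model: %s + %s (sensitivity %.3f, AUC %.3f, %d features)",
               cmp$final$feature_selection, cmp$final$classifier,
               cmp$final$sensitivity, cmp$final$auc, cmp$final$n_features)

  ## stage 5: trees + network
  final_triplets <- pathways_from_final_model(final_sel, vocab)
  forest <- build_trees(final_triplets, tl_test)
  forest <- rank_children(forest, k = config$top_children)
  coverage <- cumulative_coverage(forest, case_ids = reg[person_id %in% split$test &
                                                           is_case == TRUE, person_id],
                                  epsilon = config$coverage_epsilon)
  network <- build_temporal_network(forest, min_cases = config$min_edge_cases)
  export_graph(forest, "json", file.path(out_dir, "trees.json"))
  export_graph(coverage, "csv", file.path(out_dir, "coverage.csv"))
  export_graph(network, "graphml", file.path(out_dir, "network.graphml"))
  export_graph(network, "dot", file.path(out_dir, "network.dot"))
  for (f in c("trees.json", "coverage.csv", "network.graphml", "network.dot"))
    manifest$files[[f]] <- list(md5 = unname(tools::md5sum(file.path(out_dir, f))),
                                rows = NA_integer_)
  manifest$counts$final_pathways <- nrow(final_triplets)
  manifest$counts$parent_nodes <- forest$nodes[level == 1L, .N]
  manifest$counts$chosen_parents <- coverage$chosen
  manifest$counts$network_edges <- nrow(network$edges)
  pipeline_log("visualize", "%d parent nodes, %d chosen by coverage, %d network edges",
               manifest$counts$parent_nodes, coverage$chosen, nrow(network$edges))

  manifest$status <- "ok"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(status = "ok", manifest = manifest, registry = registry,
                 timelines = timelines, split = split, support = support,
                 screened = screened, selected = selected, vocabulary = vocab,
                 fm_train = fm_train, fm_test = fm_test,
                 models = cmp, forest = forest, coverage = coverage,
                 network = network))
}
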