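#' Map final-model features back to pathways
#'
#' Returns the screened triplets whose generated feature keys intersect the
#' final model's selected key set, using the vocabulary provenance.
#'
#' @param selection a `lasso_selection` (or character vector of tokens).
#' @param vocabulary the `triplet_vocabulary` the features came from.
#' @return `data.table` of triplets (`d1`, `d2`, `d3`); empty (with a
#'   warning) if no key intersects.
#' @export
pathways_from_final_model <- function(selection, vocabulary) {
  tokens <- if (inherits(selection, "lasso_selection")) selection$selected else selection
  prov <- vocabulary$provenance
  out <- unique(prov[token %in% tokens, .(d1, d2, d3)])
  if (nrow(out) == 0L)
    warning("no pathway generates any selected feature: empty forest")
  setorder(out, d1, d2, d3)
  out[]
}

## wide person x category onset table (numeric days, NA = absent)
onset_matrix <- function(timelines, categories) {
  tl <- as.data.table(timelines)[category %in% categories]
  persons <- unique(as.data.table(timelines)[, .(person_id, is_case)])
  W <- matrix(NA_real_, nrow = nrow(persons), ncol = length(categories),
              dimnames = list(persons$person_id, categories))
  if (nrow(tl)) {
    W[cbind(match(tl$person_id, persons$person_id),
            match(tl$category, categories))] <- as.numeric(tl$onset)
  }
  list(W = W, persons = persons)
}

## case/total coverage of one ordered path over the onset matrix: a person
## covers a path iff all its categories are present with strictly
## increasing onsets (each category has one incident date per person)
path_cover <- function(W, path) {
  ok <- !is.na(W[, path[1L]])
  if (length(path) > 1L) for (k in 2:length(path)) {
    ok <- ok & !is.na(W[, path[k]]) & W[, path[k - 1L]] < W[, path[k]]
  }
  ok
}

#' Consolidate pathways into disease trees with coverage counts
#'
#' Triplets sharing the first disease merge under one parent (root) node;
#' shared (d1, d2) prefixes merge at level 2; level-3 nodes are leaves. A
#' person covers a node iff the root-to-node ordered path occurs as a
#' strictly dated subsequence of their disease sequence. Each node records
#' the number of covered cases, covered persons overall, and the dementia
#' probability (covered cases / covered persons).
#'
#' @param triplets table of pathways (`d1`, `d2`, `d3`).
#' @param timelines the timelines the coverage is counted against (usually
#'   the test split, optionally the full cohort).
#' @return object of class `disease_forest`: `nodes` (one row per node:
#'   `path` like `"A|B"`, `parent_path`, `level`, `category`, `n_cases`,
#'   `n_total`, `probability`, list-column `case_ids`) and `triplets`.
#' @export
build_trees <- function(triplets, timelines) {
  tr <- unique(as.data.table(triplets)[, .(d1, d2, d3)])
  assert_that(nrow(tr) > 0L, "empty triplet set")
  cats <- unique(c(tr$d1, tr$d2, tr$d3))
  om <- onset_matrix(timelines, cats)
  is_case <- om$persons$is_case
  paths <- unique(rbind(
    tr[, .(path = d1, parent_path = NA_character_, level = 1L, category = d1)],
    tr[, .(path = paste(d1, d2, sep = "|"), parent_path = d1, level = 2L,
           category = d2)],
    tr[, .(path = paste(d1, d2, d3, sep = "|"),
           parent_path = paste(d1, d2, sep = "|"), level = 3L, category = d3)]))
  cover <- lapply(strsplit(paths$path, "|", fixed = TRUE), path_cover, W = om$W)
  nodes <- copy(paths)
  nodes[, n_cases := vapply(cover, function(ok) sum(ok & is_case), integer(1))]
  nodes[, n_total := vapply(cover, sum, integer(1))]
  nodes[, probability := ifelse(n_total > 0, n_cases / n_total, NA_real_)]
  nodes[, case_ids := lapply(cover, function(ok) om$persons$person_id[ok & is_case])]
  setorder(nodes, path)
  structure(list(nodes = nodes, triplets = tr), class = "disease_forest")
}

#' Keep the top-k children of every parent node
#'
#' For each parent (level-1 and level-2) node, retains the `k` children
#' with the highest dementia probability; ties are broken by higher covered
#' case count, then lexicographic category. Descendants of pruned nodes are
#' dropped too.
#'
#' @param forest a `disease_forest`.
#' @param k children kept per parent (default 5).
#' @return the pruned `disease_forest`.
#' @export
rank_children <- function(forest, k = 5L) {
  nodes <- copy(forest$nodes)
  keep <- nodes[level == 1L, path]
  for (lev in 2:3) {
    kids <- nodes[level == lev & parent_path %in% keep]
    if (nrow(kids) == 0L) break
    setorder(kids, parent_path, -probability, -n_cases, category)
    kept <- kids[, head(.SD, k), by = parent_path]$path
    keep <- c(keep, kept)
  }
  nodes <- nodes[path %in% keep]
  leaf <- nodes[level == 3L, tstrsplit(path, "|", fixed = TRUE)]
  triplets <- if (nrow(leaf)) setnames(leaf, c("d1", "d2", "d3"))
  else forest$triplets[0]
  structure(list(nodes = nodes, triplets = triplets), class = "disease_forest")
}

#' Cumulative covered dementia population fraction over parent nodes
#'
#' Parent nodes are ordered greedily by incremental newly-covered cases; a
#' parent's covered set is the union of the covering case sets of its
#' root-to-leaf pathways. Point j of the curve is the fraction of all cases
#' covered by the union of the first j parents. The suggested parent count
#' is the last parent before the marginal gain first drops below
#' `epsilon` x (number of cases); the full curve is returned so any other
#' cut can be applied.
#'
#' @param forest a `disease_forest` (typically after [rank_children()]).
#' @param case_ids ids of all cases the fraction is taken over.
#' @param epsilon marginal-gain threshold as a fraction of cases.
#' @return list: `curve` (`j`, `root`, `n_new`, `cum_fraction`), `chosen`
#'   (suggested number of parents), `order` (roots in greedy order).
#' @export
cumulative_coverage <- function(forest, case_ids, epsilon = 0.001) {
  nodes <- forest$nodes
  roots <- nodes[level == 1L, path]
  if (length(roots) == 0L)
    return(list(curve = data.table(j = integer(0), root = character(0),
                                   n_new = integer(0), cum_fraction = numeric(0)),
                chosen = 0L, order = character(0)))
  leaf_sets <- nodes[level == 3L,
                     .(ids = list(unique(unlist(case_ids)))),
                     by = .(root = tstrsplit(path, "|", fixed = TRUE)[[1L]])]
  root_sets <- setNames(leaf_sets$ids, leaf_sets$root)
  for (r in setdiff(roots, names(root_sets))) root_sets[[r]] <- character(0)
  root_sets <- lapply(root_sets, intersect, y = case_ids)
  n_cases <- length(case_ids)
  covered <- character(0); left <- roots
  curve <- vector("list", length(roots))
  for (j in seq_along(roots)) {
    gains <- vapply(root_sets[left], function(s) length(setdiff(s, covered)),
                    integer(1))
    pick <- left[order(-gains, left)][1L]
    covered <- union(covered, root_sets[[pick]])
    curve[[j]] <- data.table(j = j, root = pick,
                             n_new = as.integer(max(gains)),
                             cum_fraction = length(covered) / n_cases)
    left <- setdiff(left, pick)
  }
  curve <- rbindlist(curve)
  below <- which(curve$n_new < epsilon * n_cases)
  chosen <- if (length(below)) below[1L] else nrow(curve)
  list(curve = curve, chosen = max(chosen, 1L), order = curve$root)
}

#' Build the directed temporal disease network
#'
#' Each retained root-to-leaf pathway (d1, d2, d3) contributes the directed
#' edges d1 -> d2 and d2 -> d3, weighted by the number of distinct case
#' persons covering that full pathway. Weights are aggregated over all
#' pathways sharing an edge, and only then are edges below `min_cases`
#' dropped.
#'
#' @param forest a `disease_forest` with coverage counts.
#' @param min_cases minimum aggregated case count per edge (default 50).
#' @return object of class `temporal_network`: `edges` (`from`, `to`,
#'   `weight`) and `graph` (directed `igraph`).
#' @export
build_temporal_network <- function(forest, min_cases = 50L) {
  leaves <- forest$nodes[level == 3L]
  if (nrow(leaves) == 0L) {
    edges <- data.table(from = character(0), to = character(0), weight = integer(0))
  } else {
    parts <- leaves[, tstrsplit(path, "|", fixed = TRUE)]
    setnames(parts, c("d1", "d2", "d3"))
    parts[, n_cases := leaves$n_cases]
    edges <- rbind(parts[, .(from = d1, to = d2, weight = n_cases)],
                   parts[, .(from = d2, to = d3, weight = n_cases)])
    edges <- edges[, .(weight = sum(weight)), by = .(from, to)]
    edges <- edges[weight >= min_cases]
    setorder(edges, from, to)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  structure(list(edges = edges[], graph = g, min_cases = min_cases),
            class = "temporal_network")
}

#' Export trees, networks and coverage curves to standard formats
#'
#' Supported: `temporal_network` to `"graphml"` or `"dot"`; `disease_forest`
#' to `"json"` (nested node structure); a coverage result to `"csv"`.
#'
#' @param x a `temporal_network`, `disease_forest`, or the list returned by
#'   [cumulative_coverage()].
#' @param format output format (see above).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(x, format, path) {
  if (inherits(x, "temporal_network")) {
    if (!format %in% c("graphml", "dot"))
      stop("unsupported network format '", format, "'; use graphml or dot",
           call. = FALSE)
    igraph::write_graph(x$graph, path, format = format)
  } else if (inherits(x, "disease_forest")) {
    if (format != "json")
      stop("unsupported forest format '", format, "'; use json", call. = FALSE)
    jsonlite::write_json(forest_to_list(x), path, auto_unbox = TRUE, digits = NA)
  } else if (is.list(x) && !is.null(x$curve)) {
    if (format != "csv")
      stop("unsupported coverage format '", format, "'; use csv", call. = FALSE)
    fwrite(x$curve, path)
  } else {
    stop("don't know how to export this object; supported: temporal_network (graphml, dot), disease_forest (json), coverage (csv)",
         call. = FALSE)
  }
  invisible(path)
}

## nested representation of a forest for JSON export
forest_to_list <- function(forest) {
  nodes <- forest$nodes
  as_node <- function(row_path) {
    r <- nodes[path == row_path]
    kids <- nodes[!is.na(parent_path) & parent_path == row_path, path]
    out <- list(category = r$category, level = r$level, n_cases = r$n_cases,
                n_total = r$n_total, probability = r$probability)
    if (length(kids)) out$children <- lapply(sort(kids), as_node)
    out
  }
  lapply(sort(nodes[level == 1L, path]), as_node)
}
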