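trip <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.table(d1 = m[, 1], d2 = m[, 2], d3 = m[, 3])
}

## hand-written cohort: 8 timelines over categories A..F
tree_cohort <- function() {
  toy_timelines(
    list(p1 = c("A", "B", "C"), p2 = c("A", "B", "D"), p3 = c("A", "E", "F"),
         p4 = c("B", "A", "C"), p5 = c("A", "B", "C", "D"),
         p6 = c("A", "B"), p7 = c("E", "F", "A"), p8 = c("A", "C", "B")),
    is_case = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
}

test_that("final-model features map back to their generating pathways", {
  ## all 15 keys of the only triplet -> that triplet alone
  v1 <- build_vocabulary(trip("A", "B", "C"))
  sel1 <- encode_triplet(c("A", "B", "C"))$token
  expect_equal(pathways_from_final_model(sel1, v1), trip("A", "B", "C"))
  ## a shared nonordinal key maps back to both generators
  vocab <- build_vocabulary(trip("A", "B", "C", "C", "A", "B"))
  expect_equal(nrow(pathways_from_final_model("A&B", vocab)), 2L)
  expect_warning(out <- pathways_from_final_model("Z", vocab), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("triplets merge into trees by shared ordered prefixes", {
  fo <- build_trees(trip("A", "B", "C", "A", "B", "D", "A", "E", "F"),
                    tree_cohort())
  expect_equal(fo$nodes[level == 1, path], "A")
  expect_setequal(fo$nodes[level == 2, path], c("A|B", "A|E"))
  expect_setequal(fo$nodes[level == 3, path], c("A|B|C", "A|B|D", "A|E|F"))
  ## disjoint roots give one tree per root
  fo2 <- build_trees(trip("A", "B", "C", "D", "E", "F"), tree_cohort())
  expect_equal(fo2$nodes[level == 1, .N], 2L)
})

test_that("node coverage equals brute-force subsequence recounts", {
  tl <- tree_cohort()
  fo <- build_trees(trip("A", "B", "C", "A", "B", "D", "A", "E", "F"), tl)
  ## independent recount: walk each person's sequence for each ordered path
  covers <- function(seq_cats, path) {
    pos <- match(path, seq_cats)
    !anyNA(pos) && all(diff(pos) > 0)
  }
  seqs <- split(tl$category, tl$person_id)
  cases <- unique(tl[is_case == TRUE, person_id])
  for (i in seq_len(nrow(fo$nodes))) {
    p <- strsplit(fo$nodes$path[i], "|", fixed = TRUE)[[1]]
    hit <- names(seqs)[vapply(seqs, covers, logical(1), path = p)]
    expect_equal(fo$nodes$n_total[i], length(hit))
    expect_equal(fo$nodes$n_cases[i], length(intersect(hit, cases)))
    expect_equal(fo$nodes$probability[i],
                 length(intersect(hit, cases)) / length(hit))
    expect_setequal(fo$nodes$case_ids[[i]], intersect(hit, cases))
  }
})

test_that("rank_children keeps the top-k children with stated tie-breaks", {
  nodes <- data.table(
    path = c("R", paste0("R|", LETTERS[2:7])),
    parent_path = c(NA, rep("R", 6)), level = c(1L, rep(2L, 6)),
    category = c("R", LETTERS[2:7]),
    n_cases = c(100L, 10L, 20L, 30L, 40L, 40L, 60L),
    n_total = c(200L, 100L, 100L, 100L, 100L, 50L, 100L))
  nodes[, probability := n_cases / n_total]
  nodes[, case_ids := list(list(character(0)))]
  fo <- structure(list(nodes = nodes, triplets = trip("R", "B", "C")[0]),
                  class = "disease_forest")
  ## probabilities: B .1, C .2, D .3, E .4, F .8, G .6 -> drop the lowest (B)
  pruned <- rank_children(fo, k = 5)
  expect_setequal(pruned$nodes[level == 2, category], c("C", "D", "E", "F", "G"))
  ## with k = 2 a probability tie (E .4 vs a hypothetical) uses case counts:
  nodes2 <- copy(nodes)[path %in% c("R", "R|E", "R|F", "R|G")]
  nodes2[category == "F", `:=`(n_cases = 40L, n_total = 100L, probability = 0.4)]
  fo2 <- structure(list(nodes = nodes2, triplets = trip("R", "B", "C")[0]),
                   class = "disease_forest")
  keep2 <- rank_children(fo2, k = 2)$nodes[level == 2, category]
  ## G (.6) first, then E vs F tied at .4 with equal counts -> lexicographic E
  expect_setequal(keep2, c("G", "E"))
  ## a parent with fewer children than k keeps them all
  expect_equal(nrow(rank_children(fo, k = 10)$nodes), nrow(nodes))
})

test_that("tie on probability falls back to the higher case count", {
  nodes <- data.table(
    path = c("R", "R|X", "R|Y", "R|Z"), parent_path = c(NA, "R", "R", "R"),
    level = c(1L, 2L, 2L, 2L), category = c("R", "X", "Y", "Z"),
    n_cases = c(100L, 80L, 40L, 60L), n_total = c(200L, 100L, 50L, 75L))
  nodes[, probability := n_cases / n_total]  # X,Y,Z all 0.8
  nodes[, case_ids := list(list(character(0)))]
  fo <- structure(list(nodes = nodes, triplets = trip("R", "X", "Y")[0]),
                  class = "disease_forest")
  keep <- rank_children(fo, k = 2)$nodes[level == 2, category]
  expect_setequal(keep, c("X", "Z"))  # 80 and 60 covered cases beat 40
})

## a synthetic forest whose three parents cover prescribed case sets
coverage_fixture <- function(sets, all_cases) {
  roots <- paste0("R", seq_along(sets))
  nodes <- rbindlist(list(
    data.table(path = roots, parent_path = NA_character_, level = 1L,
               category = roots, n_cases = lengths(sets),
               n_total = lengths(sets)),
    data.table(path = paste0(roots, "|X|Y"), parent_path = paste0(roots, "|X"),
               level = 3L, category = "Y", n_cases = lengths(sets),
               n_total = lengths(sets))))
  nodes[, probability := 1]
  nodes[, case_ids := c(sets, sets)]
  structure(list(nodes = nodes, triplets = NULL), class = "disease_forest")
}

test_that("cumulative coverage is greedy, monotone and correctly fractioned", {
  cases <- as.character(1:50)
  sets <- list(as.character(1:30), as.character(20:40), as.character(35:45))
  fo <- coverage_fixture(sets, cases)
  cov <- cumulative_coverage(fo, cases, epsilon = 0.001)
  ## greedy by incremental gain: R1 (+30), then R3 (+11 > R2's +10), then R2
  expect_equal(cov$curve$cum_fraction, c(0.60, 0.82, 0.90))
  expect_equal(cov$curve$root, c("R1", "R3", "R2"))
  expect_equal(cov$curve$n_new, c(30L, 11L, 4L))
  ## monotone nondecreasing, bounded by 1, nonincreasing marginal gains
  expect_true(all(diff(cov$curve$cum_fraction) >= 0))
  expect_true(all(cov$curve$cum_fraction <= 1))
  expect_true(all(diff(cov$curve$n_new) <= 0))
  ## single parent covering everything
  cov1 <- cumulative_coverage(coverage_fixture(list(cases), cases), cases)
  expect_equal(cov1$curve$cum_fraction, 1.0)
  expect_equal(cov1$chosen, 1L)
  ## empty forest
  fo0 <- structure(list(nodes = fo$nodes[0], triplets = NULL),
                   class = "disease_forest")
  expect_equal(nrow(cumulative_coverage(fo0, cases)$curve), 0L)
})

test_that("network edges aggregate over pathways before thresholding", {
  ## two pathways sharing edge A->B with 30 + 30 cases: aggregated to 60
  tl <- tree_cohort()
  nodes <- data.table(
    path = c("A", "A|B", "A|B|C", "A|B|D", "E", "E|F", "E|F|G"),
    parent_path = c(NA, "A", "A|B", "A|B", NA, "E", "E|F"),
    level = c(1L, 2L, 3L, 3L, 1L, 2L, 3L),
    category = c("A", "B", "C", "D", "E", "F", "G"),
    n_cases = c(70L, 65L, 30L, 30L, 40L, 40L, 40L),
    n_total = c(80L, 70L, 35L, 33L, 45L, 44L, 42L))
  nodes[, probability := n_cases / n_total]
  nodes[, case_ids := list(list(character(0)))]
  fo <- structure(list(nodes = nodes, triplets = NULL), class = "disease_forest")
  nw <- build_temporal_network(fo, min_cases = 50)
  expect_equal(nw$edges[from == "A" & to == "B", weight], 60L)
  ## the 40-case pathway E->F->G falls below the threshold entirely
  expect_equal(nrow(nw$edges[from == "E"]), 0L)
  expect_true(all(nw$edges$weight >= 50))
  ## re-applying the threshold is idempotent
  nw2 <- build_temporal_network(fo, min_cases = 50)
  expect_identical(nw$edges, nw2$edges)
  ## no self-loops can arise from distinct-category triplets
  expect_true(all(nw$edges$from != nw$edges$to))
})

test_that("exports round-trip through graphml, dot and json", {
  tl <- tree_cohort()
  fo <- build_trees(trip("A", "B", "C", "A", "B", "D", "A", "E", "F"), tl)
  nw <- build_temporal_network(fo, min_cases = 1)
  tmp <- withr::local_tempdir()
  gml <- file.path(tmp, "net.graphml")
  export_graph(nw, "graphml", gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), nrow(nw$edges))
  ee <- igraph::as_data_frame(g2)
  setorder(setDT(ee), from, to)
  expect_equal(ee$weight, as.numeric(nw$edges$weight))

  dot <- file.path(tmp, "net.dot")
  export_graph(nw, "dot", dot)
  expect_equal(length(grep("->", readLines(dot))), nrow(nw$edges))

  js <- file.path(tmp, "forest.json")
  export_graph(fo, "json", js)
  back <- jsonlite::read_json(js)
  expect_length(back, 1)                       # one root
  expect_equal(back[[1]]$category, "A")
  expect_length(back[[1]]$children, 2)         # B and E
  n_nodes <- function(x) 1 + sum(vapply(x$children %||% list(), n_nodes, numeric(1)))
  expect_equal(n_nodes(back[[1]]), nrow(fo$nodes))

  expect_error(export_graph(nw, "gexf", file.path(tmp, "x")), "unsupported")
  expect_error(export_graph(fo, "dot", file.path(tmp, "x")), "unsupported")
})
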