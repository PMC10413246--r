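## Feature tokens: "->" marks sequence, "&" marks unordered co-occurrence,
## "1_"/"2_"/"3_" mark position inside the triplet. Category labels must not
## contain these reserved substrings.

triplet_id <- function(d1, d2, d3) paste(d1, d2, d3, sep = "|")

#' Expand ordered triplets into the seven corresponding-feature groups
#'
#' Each ordered triplet (A, B, C) generates 15 binary feature keys in 7
#' groups -- 4 ordinal (order-sensitive) and 3 nonordinal:
#' \describe{
#'   \item{group 1 (ordinal)}{the full ordered pathway `A->B->C`}
#'   \item{group 2 (ordinal)}{the consecutive ordered doublets `A->B`, `B->C`}
#'   \item{group 3 (ordinal)}{position-anchored doublets `1_A->B`, `2_B->C`}
#'   \item{group 4 (ordinal)}{position-anchored singles `1_A`, `2_B`, `3_C`}
#'   \item{group 5 (nonordinal)}{singles `A`, `B`, `C`}
#'   \item{group 6 (nonordinal)}{unordered pairs `A&B`, `A&C`, `B&C`}
#'   \item{group 7 (nonordinal)}{the unordered triple `A&B&C`}
#' }
#' Nonordinal tokens are canonicalized by sorting categories
#' lexicographically, so (A,B,C) and (C,B,A) share all group 5-7 keys.
#' Group sizes are (1, 2, 2, 3, 3, 3, 1).
#'
#' @param triplets either a length-3 character vector (one triplet) or a
#'   table with columns `d1`, `d2`, `d3`.
#' @return `data.table` with `triplet_id`, `d1`, `d2`, `d3`, `group`
#'   (integer 1-7), `token`; 15 rows per triplet.
#' @examples
#' encode_triplet(c("A", "B", "C"))
#' @export
encode_triplet <- function(triplets) {
  if (is.character(triplets) && length(triplets) == 3L)
    triplets <- data.table(d1 = triplets[1], d2 = triplets[2], d3 = triplets[3])
  tr <- as.data.table(triplets)[, .(d1, d2, d3)]
  assert_that(nrow(tr) > 0L, "no triplets to encode")
  if (any(tr$d1 == tr$d2 | tr$d1 == tr$d3 | tr$d2 == tr$d3))
    stop("triplet categories must be pairwise distinct", call. = FALSE)
  A <- tr$d1; B <- tr$d2; C <- tr$d3
  id <- triplet_id(A, B, C)
  amp <- function(...) {
    m <- apply(cbind(...), 1L, function(x) paste(sort(x), collapse = "&"))
    as.character(m)
  }
  piece <- function(group, token) data.table(triplet_id = id, d1 = A, d2 = B,
                                             d3 = C, group = group, token = token)
  out <- rbind(
    piece(1L, paste0(A, "->", B, "->", C)),
    piece(2L, paste0(A, "->", B)), piece(2L, paste0(B, "->", C)),
    piece(3L, paste0("1_", A, "->", B)), piece(3L, paste0("2_", B, "->", C)),
    piece(4L, paste0("1_", A)), piece(4L, paste0("2_", B)), piece(4L, paste0("3_", C)),
    piece(5L, A), piece(5L, B), piece(5L, C),
    piece(6L, amp(A, B)), piece(6L, amp(A, C)), piece(6L, amp(B, C)),
    piece(7L, amp(A, B, C))
  )
  setorder(out, triplet_id, group, token)
  out[]
}

#' Build the deduplicated feature vocabulary with provenance
#'
#' Union of [encode_triplet()] keys over all selected triplets. Each key
#' remembers which triplets generate it so that final-model features can be
#' mapped back to pathways.
#'
#' @param selected_triplets table with `d1`, `d2`, `d3` (e.g. the output of
#'   [select_pathways()]).
#' @return list of class `triplet_vocabulary`: `vocabulary` (`token`,
#'   `group`, one row per distinct key) and `provenance` (`token`, `group`,
#'   `triplet_id`, `d1`, `d2`, `d3`).
#' @export
build_vocabulary <- function(selected_triplets) {
  tr <- unique(as.data.table(selected_triplets)[, .(d1, d2, d3)])
  assert_that(nrow(tr) > 0L, "no selected triplets: vocabulary would be empty")
  prov <- encode_triplet(tr)
  vocab <- unique(prov[, .(token, group)])
  if (anyDuplicated(vocab$token))
    stop("feature token collision across groups; category labels must not contain '->', '&' or positional prefixes",
         call. = FALSE)
  setorder(vocab, group, token)
  structure(list(vocabulary = vocab,
                 provenance = prov[, .(token, group, triplet_id, d1, d2, d3)]),
            class = "triplet_vocabulary")
}

#' Build the persons x features binary design matrix
#'
#' A person's feature key is 1 iff some triplet in the intersection of the
#' person's enumerated triplets with the selected set generates that key;
#' all other keys are 0. Persons absent from the triplet table (or carrying
#' no selected triplet) get all-zero rows. Enlarging the selected set can
#' only turn 0s into 1s, never the reverse.
#'
#' @param person_triplets output of [enumerate_triplets()].
#' @param vocabulary a `triplet_vocabulary` built from the selected triplets.
#' @param persons character vector of person ids defining the row set and
#'   order (e.g. the training-split registry).
#' @return list of class `feature_matrix`: `X` (sparse 0/1 `dgCMatrix`,
#'   persons x tokens), `groups` (integer group per column, named by token).
#' @export
build_feature_matrix <- function(person_triplets, vocabulary, persons) {
  assert_that(inherits(vocabulary, "triplet_vocabulary"),
              "vocabulary must come from build_vocabulary()")
  tr <- as.data.table(person_triplets)
  vocab <- vocabulary$vocabulary
  prov <- vocabulary$provenance[, .(triplet_id, token)]
  tr <- tr[person_id %in% persons]
  tr[, triplet_id := triplet_id(d1, d2, d3)]
  hits <- unique(tr[prov, on = "triplet_id", nomatch = 0,
                    allow.cartesian = TRUE][, .(person_id, token)])
  X <- Matrix::sparseMatrix(
    i = match(hits$person_id, persons),
    j = match(hits$token, vocab$token),
    x = 1,
    dims = c(length(persons), nrow(vocab)),
    dimnames = list(persons, vocab$token))
  structure(list(X = X, groups = setNames(vocab$group, vocab$token)),
            class = "feature_matrix")
}
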