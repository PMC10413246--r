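#' Validate diagnoses and derive incident dates from claims
#'
#' A disease category is valid for a person iff it is documented at least
#' `min_outpatient` times in outpatient claims within any `window_days`-day
#' window, or appears on at least one inpatient claim. The incident date of
#' a valid category is the earliest claim of that category in any setting.
#' Categories failing the rule are excluded; their count is attached as
#' attribute `n_invalid`.
#'
#' @param events claims table: `person_id`, `date`, `code` (category),
#'   `setting` in `outpatient` / `inpatient`.
#' @param window_days length of the qualifying outpatient window (days);
#'   claims on days d and d + window_days - 1 are the widest pair counted
#'   as inside one window.
#' @param min_outpatient outpatient claims required inside one window.
#' @return `data.table` with `person_id`, `category`, `onset` (incident
#'   date), one row per valid (person, category).
#' @examples
#' ev <- data.table::data.table(
#'   person_id = "p1",
#'   date = as.Date("2005-01-01") + c(0, 100, 300),
#'   code = "C01", setting = "outpatient")
#' validate_diagnoses(ev)
#' @export
validate_diagnoses <- function(events, window_days = 365L, min_outpatient = 3L) {
  ev <- as.data.table(events)
  assert_that(all(c("person_id", "date", "code", "setting") %in% names(ev)),
              "events must have person_id, date, code, setting")
  ev <- ev[, .(person_id, date = as_date(date), code, setting)]
  assert_that(all(ev$setting %in% c("outpatient", "inpatient")),
              "setting must be 'outpatient' or 'inpatient'")

  ## inpatient disjunct: one admission suffices
  inp <- unique(ev[setting == "inpatient", .(person_id, code)])

  ## outpatient disjunct: some window of window_days holds >= min_outpatient
  ## claims; with sorted dates d, that is d[i + m - 1] - d[i] < window_days
  outp <- ev[setting == "outpatient"]
  setorder(outp, person_id, code, date)
  outp[, prev2 := shift(date, min_outpatient - 1L), by = .(person_id, code)]
  outw <- unique(outp[!is.na(prev2) & as.integer(date - prev2) < window_days,
                      .(person_id, code)])

  valid <- unique(rbind(inp, outw))
  n_all <- uniqueN(ev, by = c("person_id", "code"))
  res <- if (nrow(valid) == 0L) {
    data.table(person_id = character(0), category = character(0),
               onset = as.Date(character(0)))
  } else {
    ev[valid, on = c("person_id", "code")][
      , .(onset = min(date)), by = .(person_id, category = code)]
  }
  setorder(res, person_id, onset, category)
  setattr(res, "n_invalid", n_all - nrow(res))
  res[]
}

#' Read a code-prefix to category mapping table
#'
#' Two-column delimited text (with header): diagnosis-code prefix and
#' category label, in the style of the Clinical Classifications Software
#' (CCS) crosswalk that collapses ICD-9 codes into ~253 categories.
#'
#' @param path file path.
#' @return `data.table` with columns `prefix`, `category`.
#' @export
read_ccs_mapping <- function(path) {
  m <- fread(path, colClasses = "character")
  assert_that(ncol(m) >= 2L, "mapping must have two columns: prefix, category")
  setnames(m, 1:2, c("prefix", "category"))
  m[, .(prefix, category)]
}

#' Map diagnosis codes to disease categories by longest prefix
#'
#' Each code is assigned the category of the longest mapping prefix it
#' starts with. Codes matching no prefix are routed to the sentinel
#' category `"UNMAPPED"` (counted in attribute `n_unmapped`), or raise an
#' error in strict mode when the mapping is empty.
#'
#' @param events claims table with a `code` column.
#' @param mapping `data.table` with `prefix`, `category` columns
#'   (see [read_ccs_mapping()]).
#' @param strict error on an empty mapping instead of mapping everything to
#'   the sentinel.
#' @param unmapped_label sentinel category for unmapped codes.
#' @return events with `code` replaced by the mapped category.
#' @export
map_to_ccs <- function(events, mapping, strict = FALSE, unmapped_label = "UNMAPPED") {
  ev <- as.data.table(events)
  mapping <- as.data.table(mapping)
  if (nrow(mapping) == 0L && strict)
    stop("empty code mapping in strict mode", call. = FALSE)
  codes <- unique(ev$code)
  lut <- setNames(mapping$category, mapping$prefix)
  resolve <- function(code) {
    for (L in seq(nchar(code), 1L)) {
      hit <- lut[substr(code, 1L, L)]
      if (!is.na(hit)) return(unname(hit))
    }
    unmapped_label
  }
  mapped <- vapply(codes, resolve, character(1))
  out <- copy(ev)[, code := mapped[match(code, codes)]]
  setattr(out, "n_unmapped", sum(out$code == unmapped_label))
  out[]
}

#' Build strictly dated per-person disease sequences
#'
#' Joins validated incident diagnoses to the person registry, drops
#' incidents on or after the person's index date (count in attribute
#' `n_dropped_post_index`) and any excluded categories (e.g. the
#' outcome-defining codes, to keep the outcome out of the predictors), and
#' sorts each person's sequence by incident date. Categories sharing an
#' incident date are flagged `tied`; tied pairs carry no order relation
#' downstream.
#'
#' @param incidents output of [validate_diagnoses()].
#' @param registry person registry with `person_id`, `is_case`, `index_date`.
#' @param exclude categories to drop from every sequence.
#' @return `timelines` table: `person_id`, `is_case`, `index_date`,
#'   `category`, `onset`, `tied`, sorted by person and onset.
#' @export
build_timelines <- function(incidents, registry, exclude = character(0)) {
  inc <- as.data.table(incidents)
  reg <- as.data.table(registry)
  assert_that(all(c("person_id", "is_case", "index_date") %in% names(reg)),
              "registry must have person_id, is_case, index_date")
  tl <- inc[reg[, .(person_id, is_case, index_date = as_date(index_date))],
            on = "person_id", nomatch = 0]
  n0 <- nrow(tl)
  tl <- tl[onset < index_date]
  n_dropped <- n0 - nrow(tl)
  if (length(exclude)) tl <- tl[!category %in% exclude]
  setorder(tl, person_id, onset, category)
  tl[, tied := duplicated(onset) | duplicated(onset, fromLast = TRUE),
     by = person_id]
  setcolorder(tl, c("person_id", "is_case", "index_date", "category", "onset", "tied"))
  setattr(tl, "n_dropped_post_index", n_dropped)
  tl[]
}

#' Enumerate every ordered disease triplet in each person's sequence
#'
#' Emits every ordered 3-subsequence (A, B, C) of a person's incident
#' diseases whose incident dates are strictly increasing. Diseases sharing
#' an incident date contribute no order relation between themselves but may
#' still pair with strictly earlier or later diseases. For a sequence of n
#' strictly dated diseases this yields n(n-1)(n-2)/6 triples.
#'
#' @param timelines output of [build_timelines()].
#' @return `data.table` with `person_id`, `d1`, `d2`, `d3`.
#' @export
enumerate_triplets <- function(timelines) {
  tl <- as.data.table(timelines)
  assert_that(all(c("person_id", "category", "onset") %in% names(tl)),
              "timelines must have person_id, category, onset")
  one <- function(cat, ons) {
    n <- length(cat)
    if (n < 3L) return(NULL)
    o <- order(ons, cat)
    cat <- cat[o]; r <- frank(as.numeric(ons)[o], ties.method = "dense")
    idx <- tri_indices(n)
    keep <- r[idx[1L, ]] < r[idx[2L, ]] & r[idx[2L, ]] < r[idx[3L, ]]
    if (!any(keep)) return(NULL)
    list(d1 = cat[idx[1L, keep]], d2 = cat[idx[2L, keep]], d3 = cat[idx[3L, keep]])
  }
  out <- tl[, one(category, onset), by = person_id]
  if (nrow(out) == 0L)
    out <- data.table(person_id = character(0), d1 = character(0),
                      d2 = character(0), d3 = character(0))
  out[]
}

#' Count case/control support for every observed triplet
#'
#' One row per ordered triple observed in at least `min_case_support` case
#' timelines; a person is exposed iff the triple occurs in their enumerated
#' set. Exposure complements are taken against the full case / control
#' group sizes in the supplied registry, so exposed + unexposed always
#' equals the group size.
#'
#' @param triplets output of [enumerate_triplets()].
#' @param registry registry restricted to the persons under study (e.g. the
#'   training split), with `person_id`, `is_case`.
#' @param min_case_support minimum number of case persons carrying the
#'   triple (the support threshold is counted over cases only).
#' @return `TripletCluster` table: `d1 d2 d3 n_case_exposed n_case_unexposed
#'   n_ctrl_exposed n_ctrl_unexposed`.
#' @export
count_support <- function(triplets, registry, min_case_support = 10L) {
  tr <- as.data.table(triplets)
  reg <- as.data.table(registry)[, .(person_id, is_case)]
  n_case <- reg[is_case == TRUE, .N]
  n_ctrl <- reg[is_case == FALSE, .N]
  if (nrow(tr) == 0L)
    return(data.table(d1 = character(0), d2 = character(0), d3 = character(0),
                      n_case_exposed = integer(0), n_case_unexposed = integer(0),
                      n_ctrl_exposed = integer(0), n_ctrl_unexposed = integer(0)))
  tj <- tr[reg, on = "person_id", nomatch = 0]
  sup <- tj[, .(n_case_exposed = sum(is_case), n_ctrl_exposed = sum(!is_case)),
            by = .(d1, d2, d3)]
  sup <- sup[n_case_exposed >= min_case_support]
  sup[, `:=`(n_case_unexposed = n_case - n_case_exposed,
             n_ctrl_unexposed = n_ctrl - n_ctrl_exposed)]
  setcolorder(sup, c("d1", "d2", "d3", "n_case_exposed", "n_case_unexposed",
                     "n_ctrl_exposed", "n_ctrl_unexposed"))
  setorder(sup, d1, d2, d3)
  sup[]
}
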