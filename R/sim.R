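#' Configuration for the synthetic matched claims cohort generator
#'
#' Defines a synthetic longitudinal claims cohort: dated diagnosis streams
#' per person over a multi-year study window, 1:1 (or 1:k) case-control
#' matching on age, sex and index year, and ordered triplet pathways planted
#' with elevated probability in cases. The defaults emulate a claims cohort
#' of older adults: roughly 30 outpatient visits per person-year, a study
#' window of 2003--2013, and incident dementia-like index dates drawn after
#' at least `min_history_days` of observable history.
#'
#' @param n_cases number of cases to simulate.
#' @param control_ratio matched controls per case (default 1).
#' @param n_categories size of the disease-category vocabulary (>= 3);
#'   categories are labelled `"C01"`, `"C02"`, ...
#' @param study_start,study_end calendar bounds of the study window.
#' @param background_rate expected background incident diagnoses per
#'   person-year (each incident category is emitted so that it passes the
#'   claims validation rule: three outpatient claims within a year, or one
#'   inpatient claim).
#' @param planted_pathways list of planted ordered pathways, each a list
#'   with elements `triplet` (character vector of 3 distinct categories),
#'   `p_case` and `p_control` (probability that the full ordered triple is
#'   planted in a case / control history). Planted categories are reserved:
#'   they never occur as background noise, so the planting probabilities
#'   fully determine triple exposure.
#' @param visit_rate outpatient visits per person-year; visits beyond the
#'   validation claims are emitted as repeat claims of already-diagnosed
#'   categories.
#' @param admission_prob probability that an incident diagnosis is
#'   documented by a single inpatient claim rather than three outpatient
#'   claims.
#' @param age_range integer range of age at index date.
#' @param sex_ratio proportion of female persons.
#' @param min_history_days minimum days of observable history before any
#'   index date (>= 1095 guarantees room for a planted triple at the widest
#'   inter-diagnosis gaps).
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_cases = 200L,
                       control_ratio = 1L,
                       n_categories = 20L,
                       study_start = "2003-01-01",
                       study_end = "2013-12-31",
                       background_rate = 3,
                       planted_pathways = list(),
                       visit_rate = 30,
                       admission_prob = 0.1,
                       age_range = c(55L, 90L),
                       sex_ratio = 0.5,
                       min_history_days = 1095L,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), control_ratio = as.integer(control_ratio),
    n_categories = as.integer(n_categories),
    study_start = as_date(study_start), study_end = as_date(study_end),
    background_rate = background_rate, planted_pathways = planted_pathways,
    visit_rate = visit_rate, admission_prob = admission_prob,
    age_range = as.integer(age_range), sex_ratio = sex_ratio,
    min_history_days = as.integer(min_history_days), seed = as.integer(seed)
  )
  assert_that(cfg$n_cases >= 1L, "n_cases must be >= 1")
  assert_that(cfg$control_ratio >= 1L, "control_ratio must be >= 1")
  assert_that(cfg$n_categories >= 3L, "n_categories must be >= 3")
  assert_that(cfg$study_start < cfg$study_end, "study_start must precede study_end")
  assert_that(cfg$background_rate >= 0, "background_rate must be nonnegative")
  assert_that(cfg$admission_prob >= 0 && cfg$admission_prob <= 1,
              "admission_prob must be in [0,1]")
  assert_that(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1, "sex_ratio must be in [0,1]")
  cats <- category_labels(cfg$n_categories)
  span <- as.integer(cfg$study_end - cfg$study_start)
  assert_that(span > cfg$min_history_days,
              "study window shorter than min_history_days: no feasible index dates")
  for (pw in cfg$planted_pathways) {
    assert_that(is.list(pw) && all(c("triplet", "p_case", "p_control") %in% names(pw)),
                "each planted pathway needs fields triplet, p_case, p_control")
    assert_that(length(pw$triplet) == 3L && !anyDuplicated(pw$triplet),
                "planted triplet must hold 3 distinct categories")
    assert_that(all(pw$triplet %in% cats),
                sprintf("planted triplet [%s] uses categories outside the vocabulary",
                        paste(pw$triplet, collapse = ", ")))
    assert_that(pw$p_case >= 0 && pw$p_case <= 1 && pw$p_control >= 0 && pw$p_control <= 1,
                "planting probabilities must be in [0,1]")
    assert_that(pw$p_case >= pw$p_control,
                sprintf("pathway [%s]: p_case must be >= p_control",
                        paste(pw$triplet, collapse = ", ")))
    if (cfg$min_history_days < 90L)
      stop(sprintf(
        "observation window too short to place planted pathway [%s] in order: need >= 90 days of history",
        paste(pw$triplet, collapse = " -> ")), call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

category_labels <- function(n) {
  sprintf(paste0("C%0", max(2L, nchar(n)), "d"), seq_len(n))
}

## claims emitted for one incident (category, onset): either one inpatient
## claim or >= 3 outpatient claims inside a 365-day window, all before index
emit_validation_claims <- function(category, onset, index_date, admission_prob) {
  if (runif(1) < admission_prob) {
    return(list(date = onset, code = category, setting = "inpatient"))
  }
  room <- min(364L, as.integer(index_date - onset) - 1L)
  extra <- if (room >= 1L) sort(sample.int(room, 2L, replace = TRUE)) else c(0L, 0L)
  list(date = onset + c(0L, extra), code = rep(category, 3L),
       setting = rep("outpatient", 3L))
}

## place an ordered triple strictly before the index date: inter-diagnosis
## gaps uniform in [30, 365] days, last disease at least 30 days pre-index
plant_triplet_dates <- function(index_date, study_start) {
  avail <- as.integer(index_date - study_start)
  maxgap <- min(365L, avail %/% 3L)
  gaps <- 29L + sample.int(maxgap - 29L, 3L, replace = TRUE)
  index_date - cumsum(gaps)[3:1]
}

simulate_person_events <- function(person_id, index_date, cfg, p_field, bg_vocab) {
  dates <- list(); codes <- list(); settings <- list()
  push <- function(cl) {
    dates[[length(dates) + 1L]] <<- cl$date
    codes[[length(codes) + 1L]] <<- cl$code
    settings[[length(settings) + 1L]] <<- cl$setting
  }
  onsets <- character(0); onset_dates <- as.Date(character(0))

  for (pw in cfg$planted_pathways) {
    if (runif(1) < pw[[p_field]]) {
      tdates <- plant_triplet_dates(index_date, cfg$study_start)
      for (k in 1:3) {
        push(emit_validation_claims(pw$triplet[k], tdates[k], index_date,
                                    cfg$admission_prob))
        onsets <- c(onsets, pw$triplet[k]); onset_dates <- c(onset_dates, tdates[k])
      }
    }
  }

  years <- as.numeric(index_date - cfg$study_start) / 365.25
  n_bg <- min(rpois(1, cfg$background_rate * years), length(bg_vocab))
  if (n_bg > 0L) {
    bg_cats <- sample_vec(bg_vocab, n_bg)
    bg_days <- sort(sample.int(as.integer(index_date - cfg$study_start) - 1L,
                               n_bg, replace = TRUE))
    for (k in seq_len(n_bg)) {
      d <- cfg$study_start + bg_days[k]
      push(emit_validation_claims(bg_cats[k], d, index_date, cfg$admission_prob))
      onsets <- c(onsets, bg_cats[k]); onset_dates <- c(onset_dates, d)
    }
  }

  ## repeat visits: chronic conditions are re-coded at later outpatient visits
  if (length(onsets) > 0L && cfg$visit_rate > 0) {
    n_extra <- rpois(1, max(0, cfg$visit_rate * years - 3 * length(onsets)))
    if (n_extra > 0L) {
      pick <- sample.int(length(onsets), n_extra, replace = TRUE)
      rooms <- pmax(as.integer(index_date - onset_dates[pick]) - 1L, 1L)
      rdates <- onset_dates[pick] + (runif(n_extra) * rooms + 0.5)
      push(list(date = as.Date(pmin(as.numeric(rdates), as.numeric(index_date) - 1),
                               origin = "1970-01-01"),
                code = onsets[pick], setting = rep("outpatient", n_extra)))
    }
  }

  if (length(dates) == 0L) return(NULL)
  data.table(person_id = person_id,
             date = as.Date(unlist(dates), origin = "1970-01-01"),
             code = unlist(codes), setting = unlist(settings))
}

#' Generate a matched case-control claims cohort with planted pathways
#'
#' Simulates per-person dated diagnosis claim streams and a person registry.
#' Cases carry each planted pathway's three diseases in the stated order
#' with probability `p_case` (controls: `p_control`); every emitted incident
#' diagnosis passes the claims validation rule by construction, and no claim
#' is dated on or after its person's index date. Controls are generated
#' matched 1:`control_ratio` to their case on sex and exact year of age,
#' with index dates drawn uniformly within the case's index year (claims
#' cohorts typically match on index year, not exact date).
#'
#' @param config a [sim_config()].
#' @return list with `events` (person_id, date, code, setting) and
#'   `registry` (person_id, birth_year, sex, is_case, index_date, match_id),
#'   both `data.table`s sorted for byte-stable output.
#' @examples
#' cfg <- sim_config(n_cases = 20, n_categories = 8, seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(cohort$registry)
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(stage_seed(config$seed, "cohort"))
  cats <- category_labels(config$n_categories)
  planted_cats <- unique(unlist(lapply(config$planted_pathways, `[[`, "triplet")))
  bg_vocab <- setdiff(cats, planted_cats)

  span <- as.integer(config$study_end - config$study_start)
  first_index_offset <- config$min_history_days

  reg <- vector("list", config$n_cases * (1L + config$control_ratio))
  ev <- vector("list", length(reg))
  pid <- 0L
  for (i in seq_len(config$n_cases)) {
    pid <- pid + 1L
    case_id <- sprintf("P%06d", pid)
    index_date <- config$study_start + first_index_offset +
      sample.int(span - first_index_offset + 1L, 1L) - 1L
    age <- config$age_range[1] + sample.int(diff(config$age_range) + 1L, 1L) - 1L
    sex <- if (runif(1) < config$sex_ratio) "F" else "M"
    birth_year <- as.integer(format(index_date, "%Y")) - age
    reg[[pid]] <- data.table(person_id = case_id, birth_year = birth_year,
                             sex = sex, is_case = TRUE, index_date = index_date,
                             match_id = case_id)
    ev[[pid]] <- simulate_person_events(case_id, index_date, config, "p_case", bg_vocab)

    index_year <- as.integer(format(index_date, "%Y"))
    year_start <- as.Date(sprintf("%d-01-01", index_year))
    year_end <- as.Date(sprintf("%d-12-31", index_year))
    lo <- max(year_start, config$study_start + first_index_offset)
    hi <- min(year_end, config$study_end)
    for (j in seq_len(config$control_ratio)) {
      pid <- pid + 1L
      ctrl_id <- sprintf("P%06d", pid)
      ctrl_index <- lo + sample.int(as.integer(hi - lo) + 1L, 1L) - 1L
      reg[[pid]] <- data.table(person_id = ctrl_id, birth_year = birth_year,
                               sex = sex, is_case = FALSE, index_date = ctrl_index,
                               match_id = case_id)
      ev[[pid]] <- simulate_person_events(ctrl_id, ctrl_index, config,
                                          "p_control", bg_vocab)
    }
  }
  events <- rbindlist(ev)
  registry <- rbindlist(reg)
  setorder(events, person_id, date, code, setting)
  setorder(registry, person_id)
  list(events = events, registry = registry)
}

#' Match controls to cases on sex, index year and age
#'
#' Greedy seeded 1:1 matching without replacement: cases are visited in
#' random order and each draws one control from the pool with the same sex,
#' the same index year, and birth year within `age_band` years (default 0 =
#' exact year of age). Cases whose stratum is exhausted are reported
#' unmatched, never silently dropped.
#'
#' @param cases registry rows of cases (person_id, birth_year, sex, index_date).
#' @param pool registry rows of candidate controls, same columns.
#' @param age_band maximum |birth-year difference| allowed (years).
#' @param seed integer seed for the visiting order and within-stratum draws.
#' @return list with `matched` (registry of cases and their controls, both
#'   carrying `match_id` = case person_id) and `unmatched` (case ids that
#'   found no control).
#' @export
match_controls <- function(cases, pool, age_band = 0L, seed = 1L) {
  cases <- as.data.table(cases); pool <- as.data.table(pool)
  assert_that(all(c("person_id", "birth_year", "sex", "index_date") %in% names(cases)),
              "cases must have person_id, birth_year, sex, index_date")
  set.seed(stage_seed(seed, "match"))
  cases <- copy(cases)[, index_year := as.integer(format(as_date(index_date), "%Y"))]
  pool <- copy(pool)[, index_year := as.integer(format(as_date(index_date), "%Y"))]
  used <- rep(FALSE, nrow(pool))
  order_cases <- sample.int(nrow(cases))
  match_of <- rep(NA_integer_, nrow(cases))
  for (ci in order_cases) {
    elig <- which(!used &
                    pool$sex == cases$sex[ci] &
                    pool$index_year == cases$index_year[ci] &
                    abs(pool$birth_year - cases$birth_year[ci]) <= age_band)
    if (length(elig) == 0L) next
    pick <- elig[sample.int(length(elig), 1L)]
    used[pick] <- TRUE
    match_of[ci] <- pick
  }
  matched_idx <- which(!is.na(match_of))
  unmatched <- cases$person_id[is.na(match_of)]
  if (length(matched_idx) == 0L) {
    return(list(matched = cases[0][, match_id := character(0)], unmatched = unmatched))
  }
  mc <- cases[matched_idx][, `:=`(is_case = TRUE, match_id = person_id)]
  ctl <- pool[match_of[matched_idx]][, `:=`(is_case = FALSE,
                                            match_id = cases$person_id[matched_idx])]
  matched <- rbind(mc, ctl, fill = TRUE)[, index_year := NULL]
  setorder(matched, match_id, -is_case)
  list(matched = matched[], unmatched = unmatched)
}

#' Split matched pairs into training and testing sets
#'
#' The case-control pair is the unit of assignment: both members of a pair
#' land in the same split. The number of training pairs is the target
#' fraction rounded to the nearest integer, ties toward training.
#'
#' @param registry registry with `person_id`, `match_id` columns.
#' @param train_fraction fraction of pairs assigned to training (default 2/3).
#' @param seed integer seed.
#' @return list with `train` / `test` person-id vectors and
#'   `train_pairs` / `test_pairs` match-id vectors.
#' @export
split_train_test <- function(registry, train_fraction = 2 / 3, seed = 1L) {
  registry <- as.data.table(registry)
  assert_that("match_id" %in% names(registry), "registry must carry match_id")
  pairs <- sort(unique(registry$match_id))
  assert_that(length(pairs) > 0L, "no matched pairs to split")
  set.seed(stage_seed(seed, "split"))
  n_train <- as.integer(floor(length(pairs) * train_fraction + 0.5))
  train_pairs <- sort(sample_vec(pairs, n_train))
  test_pairs <- setdiff(pairs, train_pairs)
  list(train = registry[match_id %in% train_pairs, person_id],
       test = registry[match_id %in% test_pairs, person_id],
       train_pairs = train_pairs, test_pairs = test_pairs)
}
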