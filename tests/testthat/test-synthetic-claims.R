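pw <- function(triplet, p_case, p_control)
  list(triplet = triplet, p_case = p_case, p_control = p_control)

test_that("config validation rejects impossible cohorts", {
  expect_error(sim_config(n_categories = 2), "n_categories")
  expect_error(sim_config(study_start = "2010-01-01", study_end = "2005-01-01"),
               "study_start")
  expect_error(sim_config(planted_pathways = list(pw(c("C01", "C02", "C03"), 0.1, 0.5))),
               "p_case")
  expect_error(sim_config(planted_pathways = list(pw(c("C01", "C01", "C02"), 0.5, 0.1))),
               "distinct")
  ## a window too short to hold an ordered triple names the pathway
  expect_error(
    sim_config(min_history_days = 60,
               planted_pathways = list(pw(c("C01", "C02", "C03"), 0.5, 0.1))),
    "C01 -> C02 -> C03")
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_cases = 30, n_categories = 10, seed = 11,
                    planted_pathways = list(pw(c("C01", "C02", "C03"), 0.5, 0.1)))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$registry, b$registry)
  c2 <- generate_cohort(sim_config(n_cases = 30, n_categories = 10, seed = 12))
  expect_false(identical(a$events, c2$events))
})

test_that("no event postdates its person's index date", {
  co <- generate_cohort(sim_config(n_cases = 40, n_categories = 10, seed = 2,
                                   planted_pathways = list(pw(c("C01", "C02", "C03"), 0.5, 0.1))))
  idx <- co$registry[match(co$events$person_id, person_id), index_date]
  expect_true(all(co$events$date < idx))
})

test_that("generated pairs are matched exactly on sex, age and index year", {
  co <- generate_cohort(sim_config(n_cases = 50, n_categories = 8, seed = 3))
  reg <- co$registry
  cases <- reg[is_case == TRUE]
  ctrls <- reg[is_case == FALSE]
  m <- cases[ctrls, on = "match_id"]
  expect_equal(nrow(m), 50L)
  expect_true(all(m$sex == m$i.sex))
  expect_true(all(m$birth_year == m$i.birth_year))
  expect_true(all(format(m$index_date, "%Y") == format(m$i.index_date, "%Y")))
})

test_that("every generated diagnosis passes the claims validation rule", {
  co <- generate_cohort(sim_config(n_cases = 25, n_categories = 10, seed = 4,
                                   planted_pathways = list(pw(c("C01", "C02", "C03"), 0.6, 0.2))))
  inc <- validate_diagnoses(co$events)
  ## every (person, category) ever claimed must be a valid incident
  claimed <- unique(co$events[, .(person_id, category = code)])
  expect_equal(nrow(inc), nrow(claimed))
})

test_that("planted ordered pathway reproduces the closed-form odds ratio", {
  ## planting model: exposure ~ Bernoulli(p_case) in cases, Bernoulli(p_ctrl)
  ## in controls, so OR = (.5/.5)/(.1/.9) = 9.0 exactly. Per replicate the
  ## log-OR sampling SE at 500 pairs is ~0.17, so a single replicate sits
  ## inside +/-30% of 9.0 with probability ~0.91; the replicate-rate bound is
  ## therefore set at 80% (false-alarm probability < 0.005) and the pooled
  ## estimate, whose SE shrinks by sqrt(20), is held to the +/-30% band.
  ors <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cases = 500, n_categories = 10, seed = s,
                      planted_pathways = list(pw(c("C01", "C02", "C03"), 0.5, 0.1)))
    sup <- cohort_support(generate_cohort(cfg), min_case_support = 1L)
    row <- sup[d1 == "C01" & d2 == "C02" & d3 == "C03"]
    row[, n_case_exposed * n_ctrl_unexposed / (n_case_unexposed * n_ctrl_exposed)]
  }, numeric(1))
  pooled <- exp(mean(log(ors)))
  expect_gt(pooled, 9 * 0.7)
  expect_lt(pooled, 9 * 1.3)
  expect_gte(mean(ors >= 9 * 0.7 & ors <= 9 * 1.3), 0.80)
})

test_that("with no planted signal, case and control exposure rates agree in expectation", {
  cfg <- sim_config(n_cases = 300, n_categories = 8, seed = 9)
  sup <- cohort_support(generate_cohort(cfg), min_case_support = 10L)
  expect_gt(nrow(sup), 10)
  ## exposure proportions should track each other closely triple by triple
  diffs <- sup[, n_case_exposed / (n_case_exposed + n_case_unexposed) -
                 n_ctrl_exposed / (n_ctrl_exposed + n_ctrl_unexposed)]
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("match_controls matches exactly and reports exhausted strata", {
  cases <- data.table(person_id = c("a", "b"), birth_year = c(1940L, 1950L),
                      sex = c("F", "M"),
                      index_date = as.Date(c("2008-05-01", "2009-06-01")))
  ## exact duplicates in the pool: everyone matches
  pool <- copy(cases)[, person_id := c("x", "y")]
  res <- match_controls(cases, pool, seed = 1)
  expect_length(res$unmatched, 0)
  expect_equal(sort(res$matched[is_case == FALSE, person_id]), c("x", "y"))
  expect_true(all(res$matched[, uniqueN(sex), by = match_id]$V1 == 1))

  ## empty pool: all cases flagged unmatched, nothing silently dropped
  res0 <- match_controls(cases, pool[0], seed = 1)
  expect_equal(sort(res0$unmatched), c("a", "b"))
  expect_equal(nrow(res0$matched), 0L)

  ## one eligible control, two cases in the stratum: exactly one matched,
  ## and which one is seed-determined
  cases2 <- data.table(person_id = c("a", "b"), birth_year = 1940L, sex = "F",
                       index_date = as.Date("2008-05-01"))
  pool2 <- data.table(person_id = "x", birth_year = 1940L, sex = "F",
                      index_date = as.Date("2008-11-30"))
  r1 <- match_controls(cases2, pool2, seed = 7)
  expect_length(r1$unmatched, 1)
  expect_equal(nrow(r1$matched), 2L)
  r2 <- match_controls(cases2, pool2, seed = 7)
  expect_identical(r1$matched$person_id, r2$matched$person_id)
})

test_that("train/test split keeps pairs together and rounds toward training", {
  reg <- function(n) data.table(person_id = c(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n)),
                                match_id = rep(sprintf("c%02d", 1:n), 2))
  s9 <- split_train_test(reg(9), seed = 1)
  expect_length(s9$train_pairs, 6)
  expect_length(s9$test_pairs, 3)
  s10 <- split_train_test(reg(10), seed = 1)
  expect_length(s10$train_pairs, 7)
  expect_length(s10$test_pairs, 3)
  ## both members of a pair land on the same side
  r <- reg(10)
  expect_setequal(r[match_id %in% s10$train_pairs, person_id], s10$train)
  ## seeded determinism
  expect_identical(split_train_test(reg(10), seed = 4)$train_pairs,
                   split_train_test(reg(10), seed = 4)$train_pairs)
})
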