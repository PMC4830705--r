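study_world <- function(seed, n = 300) {
  spec <- generator_spec(seed = seed, n_patients = n)
  terms <- generate_terminologies(spec)
  closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
  gen <- generate_cohort(spec, terms)
  list(spec = spec, terms = terms, closure = closure, cohort = gen$cohort,
       truth = gen$truth, schemes = unname(terms$schemes))
}

two_event_patient <- function(gap_days) {
  cohort(
    tibble::tibble(patient_id = "p1", birth_year = 1950L,
                   gender = "male", country = "A"),
    tibble::tibble(
      patient_id = "p1",
      kind = c("medication", "condition"),
      scheme = c("ATCA", "MEDC"), code = c("A2_1", "R4_1"),
      start = as.Date("2005-01-01") + c(0, gap_days))
  )
}

test_that("temporal windows are inclusive at both bounds", {
  q <- qry_temporal(qry_leaf("medication", c("ATCA", "A2_1")),
                    qry_leaf("condition", c("MEDC", "R4_1")),
                    "after", 120)
  expect_equal(evaluate_query(q, two_event_patient(0)), "p1")    # day 0 counts
  expect_equal(evaluate_query(q, two_event_patient(120)), "p1")  # boundary in
  expect_equal(evaluate_query(q, two_event_patient(121)), character())
  expect_equal(evaluate_query(q, two_event_patient(-1)), character())
  before <- qry_temporal(qry_leaf("medication", c("ATCA", "A2_1")),
                         qry_leaf("condition", c("MEDC", "R4_1")),
                         "before", 120)
  expect_equal(evaluate_query(before, two_event_patient(-120)), "p1")
  expect_equal(evaluate_query(before, two_event_patient(-121)), character())
  either <- qry_temporal(qry_leaf("medication", c("ATCA", "A2_1")),
                         qry_leaf("condition", c("MEDC", "R4_1")),
                         "either", 120)
  expect_equal(evaluate_query(either, two_event_patient(-120)), "p1")
  expect_equal(evaluate_query(either, two_event_patient(120)), "p1")
})

test_that("undated statements never satisfy temporal constraints", {
  co <- two_event_patient(60)
  co$statements$start[2] <- NA
  q <- qry_temporal(qry_leaf("medication", c("ATCA", "A2_1")),
                    qry_leaf("condition", c("MEDC", "R4_1")), "after", 120)
  expect_equal(evaluate_query(q, co), character())
  # but the plain leaf still matches
  expect_equal(evaluate_query(qry_leaf("condition", c("MEDC", "R4_1")), co), "p1")
})

test_that("boolean nodes combine patient sets; negation complements", {
  co <- toy_cohort()
  med <- qry_leaf("medication", c("ATCA", "A2_1"))
  conf <- qry_leaf("condition", c("MEDC", "R4_2"))
  expect_setequal(evaluate_query(qry_or(med, conf), co), c("p1", "p2", "p3"))
  expect_equal(evaluate_query(qry_and(med, conf), co), character())
  expect_setequal(evaluate_query(qry_leaf("condition", c("MEDC", "R4_2"),
                                          negated = TRUE), co), c("p1", "p2"))
})

test_that("evaluation matches the exhaustive per-pair scan oracle", {
  study <- demo_study()
  for (seed in c(3, 12)) {
    w <- study_world(seed, n = 300)
    for (q in list(study$foreground, study$background)) {
      expect_equal(evaluate_query(q, w$cohort), brute_force_eligible(q, w$cohort),
                   info = paste("seed", seed))
    }
  }
})

test_that("localization expands leaves with provenance and flags unmapped codes", {
  w <- study_world(5, n = 50)
  study <- demo_study()
  ss <- list(condition = "ICD9A", medication = "ATCA", lab_result = "LABA")
  loc <- localize_query(study$foreground, ss, w$closure, w$schemes, "S1")
  leafcodes <- loc$query$children[[2]]$related$codes
  expect_true(all(leafcodes$scheme == "ICD9A"))
  expect_gt(nrow(leafcodes), 0L)
  expect_true(all(c("orig_code", "code") %in% names(loc$provenance)))
  # unmapped code -> unsatisfiable leaf + warning
  lonely <- qry_leaf("condition", c("MEDC", w$terms$meta$reaction_pt))
  expect_warning(
    localize_query(lonely, list(condition = "LABA"), w$closure, w$schemes),
    "unsatisfiable")
  suppressWarnings({
    no_map <- localize_query(lonely, list(condition = "LABA"), w$closure, w$schemes)
  })
  expect_equal(nrow(no_map$query$codes), 0L)
  expect_equal(evaluate_query(no_map, w$cohort), character())
  expect_error(localize_query(lonely, list(medication = "ATCA"), w$closure, w$schemes),
               class = "casechar_config_error")
})

test_that("localized evaluation on source-coded data equals direct evaluation", {
  study <- demo_study()
  for (seed in c(1, 2, 9)) {
    w <- study_world(seed, n = 300)
    for (care in c("ICD9A", "ICD10A")) {
      recoded <- casechar:::recode_to_care(w$cohort, w$terms, care)
      loc <- localize_query(study$foreground, infer_source_schemes(recoded),
                            w$closure, w$schemes)
      expect_equal(evaluate_query(loc, recoded),
                   evaluate_query(study$foreground, w$cohort),
                   info = paste(seed, care))
    }
  }
})

test_that("foreground is contained in the background it extends", {
  study <- demo_study()
  for (seed in 1:6) {
    w <- study_world(seed, n = 200)
    pops <- select_populations(study, w$cohort)
    fg <- pops$patient_id[pops$label == "foreground"]
    bg <- pops$patient_id[pops$label == "background"]
    expect_true(all(fg %in% bg), info = paste("seed", seed))
  }
  # fg query == bg query -> identical sets
  same <- study_definition("same", study$background, study$background,
                           study$grouping, "gender")
  w <- study_world(7, n = 100)
  pops <- select_populations(same, w$cohort)
  expect_setequal(pops$patient_id[pops$label == "foreground"],
                  pops$patient_id[pops$label == "background"])
})

test_that("zero reaction events give an empty foreground, nonempty background", {
  spec <- generator_spec(seed = 3, n_patients = 200, p_w = 0, p_bg = 0)
  terms <- generate_terminologies(spec)
  gen <- generate_cohort(spec, terms)
  study <- demo_study()
  expect_equal(evaluate_query(study$foreground, gen$cohort), character())
  expect_gt(length(evaluate_query(study$background, gen$cohort)), 0L)
})

test_that("widening or dropping the temporal constraint never shrinks eligibility", {
  study <- demo_study()
  no_temporal <- qry_and(study$foreground$children[[1]],
                         qry_leaf("condition", c("MEDC", "R4_1")))
  for (seed in 1:6) {
    w <- study_world(seed, n = 300)
    base <- evaluate_query(study$foreground, w$cohort)
    wide <- study$foreground
    wide$children[[2]]$window_days <- 365L
    expect_true(all(base %in% evaluate_query(wide, w$cohort)))
    expect_true(all(evaluate_query(wide, w$cohort) %in%
                      evaluate_query(no_temporal, w$cohort)))
  }
})

test_that("derived-condition rules fire on converging evidence, idempotently", {
  rules <- read_derived_rules(system.file("extdata", "derived_rules.yaml",
                                          package = "casechar"))
  p <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                      birth_year = c(1950L, 1950L, 1995L),
                      gender = "female", country = "A")
  s <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    kind = c("medication", "lab_result", "medication", "medication", "lab_result"),
    scheme = c("ATCA", "LABA", "ATCA", "ATCA", "LABA"),
    code = c("A2_2", "A1C", "A2_2", "A2_2", "A1C"),
    start = as.Date(c("2004-01-01", "2005-06-01", "2004-01-01",
                      "2004-01-01", "2005-06-01")),
    value_num = c(NA, 7.2, NA, NA, 7.2)
  )
  co <- cohort(p, s)
  out <- apply_derived_condition_rules(co, rules)
  derived <- out$statements[out$statements$derived, ]
  # p1: med + high lab + age ok; p2 lacks the lab; p3 too young
  expect_equal(derived$patient_id, "p1")
  expect_equal(derived$code, "R4_2")
  expect_equal(derived$start, as.Date("2004-01-01"))  # earliest evidence
  # idempotence
  again <- apply_derived_condition_rules(out, rules)
  expect_equal(as.data.frame(again$statements), as.data.frame(out$statements))
})

test_that("aggregation namespaces ids and conserves counts", {
  w <- study_world(10, n = 100)
  study <- demo_study()
  half <- w$cohort$patients$patient_id[1:50]
  split_cohort <- function(ids) {
    cohort(dplyr::filter(w$cohort$patients, patient_id %in% ids),
           dplyr::filter(w$cohort$statements, patient_id %in% ids))
  }
  c1 <- split_cohort(half)
  c2 <- split_cohort(setdiff(w$cohort$patients$patient_id, half))
  srcs <- list(
    list(source_id = "S1", cohort = c1,
         populations = select_populations(study, c1, "S1")),
    list(source_id = "S2", cohort = c2,
         populations = select_populations(study, c2, "S2"))
  )
  agg <- aggregate_sources(srcs)
  expect_equal(nrow(agg$cohort$patients), 100L)
  expect_true(all(grepl("^S[12]:", agg$cohort$patients$patient_id)))
  n_fg <- sum(agg$populations$label == "foreground")
  expect_equal(n_fg,
               sum(srcs[[1]]$populations$label == "foreground") +
                 sum(srcs[[2]]$populations$label == "foreground"))
  expect_error(aggregate_sources(list(srcs[[1]], srcs[[1]])),
               class = "casechar_config_error")
  # single source is an identity modulo namespacing
  one <- aggregate_sources(srcs[1])
  expect_equal(nrow(one$cohort$patients), 50L)
})
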