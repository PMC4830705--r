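report_world <- function(seed, n = 300) {
  spec <- generator_spec(seed = seed, n_patients = n)
  terms <- generate_terminologies(spec)
  closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
  gen <- generate_cohort(spec, terms)
  study <- demo_study()
  res <- run_study(study, list(list(source_id = "S1", cohort = gen$cohort)),
                   unname(terms$schemes), closure)
  list(spec = spec, terms = terms, closure = closure, gen = gen, study = study,
       res = res)
}

test_that("foreground share reproduces the printed worked-example values", {
  expect_identical(proportion(108, 34773), 0.31)
  expect_identical(proportion(423, 34773), 1.22)
  expect_identical(proportion(0, 1000), 0)
  expect_true(is.na(proportion(5, 0)))
})

test_that("group enrichment equals a direct per-code lookup oracle", {
  w <- report_world(6, n = 200)
  enriched <- w$res$cohort
  gl <- materialize_group_links(w$closure, unname(w$terms$schemes), "MEDC", "hlgt")
  s <- enriched$statements
  ann <- enriched$annotations
  cond_ids <- s$stmt_id[s$kind == "condition"]
  expect_setequal(ann$stmt_id[ann$kind == "condition"], cond_ids)
  for (i in sample(cond_ids, 25)) {
    row <- s[s$stmt_id == i, ]
    expected <- gl$code_b[gl$scheme_a == row$scheme & gl$code_a == row$code]
    if (!length(expected)) expected <- "UNMAPPED"
    got <- ann$group_code[ann$stmt_id == i]
    expect_setequal(got, expected)
  }
  # original codes untouched by enrichment
  raw <- canonicalize_cohort(w$gen$cohort)$statements
  expect_equal(sort(s$code[s$kind == "condition"]),
               sort(raw$code[raw$kind == "condition"]))
})

test_that("multiaxial group codes are annotated once per axis", {
  mx <- multiaxial_scheme("MEDC")
  gl <- materialize_group_links(empty_links <- tibble::tibble(
    kind = character(), scheme_a = character(), code_a = character(),
    scheme_b = character(), code_b = character()), list(mx), "MEDC", "grp")
  co <- cohort(
    tibble::tibble(patient_id = "p1", birth_year = 1950L, gender = "f",
                   country = "A"),
    tibble::tibble(patient_id = "p1", kind = "condition", scheme = "MEDC",
                   code = "P1", start = as.Date("2005-01-01"))
  )
  en <- enrich_codes(co, list(condition = list(scheme = "MEDC", level = "grp")),
                     gl, list(mx))
  expect_setequal(en$annotations$group_code, c("G1", "G2"))
})

test_that("demographics boxes tally rates with UNKNOWN handling", {
  co <- toy_cohort()
  b <- demographics_box(co, fg = c("p1", "p2"), bg = c("p1", "p2", "p3"), "gender")
  expect_equal(b$rows$fg_rate[b$rows$item_code == "male"], 50)
  expect_equal(b$rows$bg_rate[b$rows$item_code == "female"], 66.67)
  # absent birth years -> single UNKNOWN row at 100%
  co2 <- co
  co2$patients$birth_year <- NA_integer_
  b2 <- demographics_box(co2, fg = "p3", bg = co2$patients$patient_id, "age")
  expect_equal(b2$rows$item_code, "UNKNOWN")
  expect_equal(b2$rows$fg_rate, 100)
})

test_that("generator-known demographics are recovered exactly", {
  spec <- generator_spec(seed = 4, n_patients = 1000,
                         gender_split = c(male = 0.6, female = 0.4))
  terms <- generate_terminologies(spec)
  gen <- generate_cohort(spec, terms)
  ids <- gen$cohort$patients$patient_id
  b <- demographics_box(gen$cohort, ids, ids, "gender")
  # exact recovery of the realized split (same tally the generator drew)
  realized <- table(gen$cohort$patients$gender)
  expect_equal(b$rows$fg_count[b$rows$item_code == "male"],
               unname(realized[["male"]]))
  expect_equal(sum(b$rows$fg_count), 1000L)
})

test_that("common-items boxes count patients, not events, and respect the index", {
  p <- tibble::tibble(patient_id = c("p1", "p2"), birth_year = 1950L,
                      gender = "f", country = "A")
  s <- tibble::tibble(
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    kind = c("condition", "condition", "medication", "condition", "medication"),
    scheme = "MEDC",
    code = c("R4_1", "R4_1", "A2_1", "R4_1", "A2_1"),
    start = as.Date(c("2005-03-01", "2006-04-01", "2005-01-01",
                      "2005-01-01", "2005-01-01"))
  )
  s$scheme[s$kind == "medication"] <- "ATCA"
  co <- cohort(p, s)
  terms <- generate_terminologies(generator_spec(seed = 1))
  closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
  gl <- dplyr::bind_rows(
    materialize_group_links(closure, unname(terms$schemes), "MEDC", "hlgt"),
    materialize_group_links(closure, unname(terms$schemes), "ATCA", "class"))
  grouping <- list(condition = list(scheme = "MEDC", level = "hlgt"),
                   medication = list(scheme = "ATCA", level = "class"))
  en <- enrich_codes(co, grouping, gl, unname(terms$schemes))
  both <- c("p1", "p2")
  overall <- common_items_box(en, both, both, "condition", "overall")
  # p1 has two statements in the same group: patient-level count is 1 each
  expect_equal(overall$rows$fg_count, 2L)
  expect_equal(overall$rows$fg_events, 3L)  # event tally kept alongside
  # index-day events fall in neither before nor after
  idx <- qry_leaf("medication", c("ATCA", "A2_1"))
  before <- common_items_box(en, both, both, "condition", "before_index", idx)
  after <- common_items_box(en, both, both, "condition", "after_index", idx)
  expect_equal(sum(before$rows$fg_count), 0L)       # p2's condition is ON index
  expect_equal(after$rows$fg_count, 1L)             # p1's post-index conditions
  expect_equal(after$rows$fg_events, 2L)
})

test_that("risk factors hit source-coded data through expansion", {
  w <- report_world(5, n = 200)
  care <- casechar:::recode_to_care(w$gen$cohort, w$terms, "ICD9A")
  ids <- care$patients$patient_id
  rf <- tibble::tibble(scheme = "MEDC", code = w$terms$meta$confounder_pt,
                       label = "confounder")
  b <- risk_factor_box(care, ids, ids, rf, w$closure, unname(w$terms$schemes))
  # oracle: patients carrying the confounder in the research-coded cohort
  oracle <- unique(w$gen$cohort$statements$patient_id[
    w$gen$cohort$statements$code == w$terms$meta$confounder_pt])
  expect_equal(b$rows$fg_count, length(oracle))
  # risk code matching nothing -> zero row, still present
  rf0 <- tibble::tibble(scheme = "MEDC", code = "R4_54", label = "nothing")
  b0 <- risk_factor_box(care, ids, ids, rf0, w$closure, unname(w$terms$schemes))
  expect_equal(b0$rows$fg_count, 0L)
})

test_that("injected confounder prevalence is recovered within binomial tolerance", {
  spec <- generator_spec(seed = 5, n_patients = 400)
  terms <- generate_terminologies(spec)
  closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
  gen <- generate_cohort(spec, terms)
  reactors <- gen$truth$patient_id[gen$truth$reacted]
  nonreactors <- setdiff(gen$truth$patient_id, reactors)
  rf <- tibble::tibble(scheme = "MEDC", code = terms$meta$confounder_pt,
                       label = "confounder")
  b <- risk_factor_box(gen$cohort, reactors, nonreactors, rf, closure,
                       unname(terms$schemes))
  p_r <- spec$confounder_prev[["reactors"]]
  tol_r <- 3 * sqrt(p_r * (1 - p_r) / max(length(reactors), 1)) * 100
  expect_lt(abs(b$rows$fg_rate - 100 * p_r), max(tol_r, 1e-9) + 1e-9)
  p_n <- spec$confounder_prev[["nonreactors"]]
  tol_n <- 3 * sqrt(p_n * (1 - p_n) / length(nonreactors)) * 100
  expect_lt(abs(b$rows$bg_rate - 100 * p_n), tol_n)
})

test_that("reports are internally consistent and deterministic", {
  w <- report_world(2, n = 250)
  rep <- w$res$report
  td <- tidy(rep)
  expect_true(all(td$fg_rate >= 0 & td$fg_rate <= 100))
  expect_true(all(td$bg_rate >= 0 & td$bg_rate <= 100))
  expect_true(all(td$fg_count <= td$fg_n))
  expect_true(all(td$bg_count <= td$bg_n))
  g <- glance(rep)
  expect_equal(g$fg_share_pct, proportion(g$fg_size, g$bg_size))
  # byte-identical JSON on re-run with identical inputs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep, d1)
  rep2 <- report_world(2, n = 250)$res$report
  write_report(rep2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  # plot method returns a ggplot without error
  expect_s3_class(ggplot2::autoplot(rep, box = "gender"), "ggplot")
})

test_that("an empty foreground yields an all-zero foreground column", {
  spec <- generator_spec(seed = 8, n_patients = 150, p_w = 0, p_bg = 0)
  terms <- generate_terminologies(spec)
  closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
  gen <- generate_cohort(spec, terms)
  res <- run_study(demo_study(), list(list(source_id = "S1", cohort = gen$cohort)),
                   unname(terms$schemes), closure)
  expect_equal(res$report$fg_size, 0L)
  td <- tidy(res$report)
  expect_true(all(td$fg_count == 0L))
  expect_gt(res$report$bg_size, 0L)
})
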