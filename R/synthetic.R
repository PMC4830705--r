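# Synthetic terminologies, mappings and cohorts with known ground
# truth: structurally analogous stand-ins for licensed vocabularies
# (a multi-level research scheme, a flat bridge scheme and two care
# schemes linked by three curated mapping sets) and cohorts with an
# exposed background population, windowed drug reactions and injected
# confounders. Everything is deterministic under a fixed seed, with
# one RNG stream per concern so changing one spec field does not
# perturb unrelated draws.

#' Synthetic study generator specification
#'
#' Defines the conditions a generated study emulates: terminology
#' shapes, mapping consistency, drug exposure, the windowed reaction
#' model (a background-rate reaction plus an elevated within-window
#' reaction probability for exposed patients), confounder prevalences
#' and demographics. Defaults give a 2,000-patient cohort observed
#' over ten years with exposure probability 0.3, window reaction
#' probability `p_w = 0.05` inside a 120-day window and baseline
#' reaction probability `p_bg = 0.005`.
#'
#' @param seed Master seed; all streams derive from it.
#' @param n_patients Cohort size.
#' @param mapping_consistency Fraction of care-scheme leaves given a
#'   correct research-scheme match; below 1 injects unmapped codes.
#' @param exposure_prob Probability a patient is exposed to the study
#'   drug (one dated prescription per exposed patient).
#' @param p_w,window_days,p_bg Reaction model: window reaction
#'   probability, window length in days, baseline reaction probability.
#' @param confounder_prev Length-2 numeric: confounder prevalence in
#'   reactors and non-reactors.
#' @param gender_split Named probabilities for `gender` sampling.
#' @param birth_year_range Inclusive birth-year bounds.
#' @param countries Named probabilities for `country` sampling.
#' @param noise_conditions_mean,noise_medications_mean Poisson means
#'   for unrelated background conditions/medications per patient.
#' @param lab_prob,lab_mean,lab_sd Probability and distribution of a
#'   glycaemia-analogue lab result per patient.
#' @param span_start,span_days Observation window (10-year default).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1, n_patients = 2000,
                           mapping_consistency = 1.0,
                           exposure_prob = 0.3,
                           p_w = 0.05, window_days = 120, p_bg = 0.005,
                           confounder_prev = c(reactors = 0.25, nonreactors = 0.10),
                           gender_split = c(male = 0.52, female = 0.48),
                           birth_year_range = c(1920, 1990),
                           countries = c(A = 0.7, B = 0.3),
                           noise_conditions_mean = 1.5,
                           noise_medications_mean = 0.8,
                           lab_prob = 0.3, lab_mean = 6.0, lab_sd = 1.0,
                           span_start = as.Date("2000-01-01"), span_days = 3653) {
  stopifnot(mapping_consistency >= 0, mapping_consistency <= 1,
            p_w >= 0, p_w <= 1, p_bg >= 0, p_bg <= 1, window_days >= 0,
            exposure_prob >= 0, exposure_prob <= 1)
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         mapping_consistency = mapping_consistency, exposure_prob = exposure_prob,
         p_w = p_w, window_days = as.integer(window_days), p_bg = p_bg,
         confounder_prev = confounder_prev, gender_split = gender_split,
         birth_year_range = birth_year_range, countries = countries,
         noise_conditions_mean = noise_conditions_mean,
         noise_medications_mean = noise_medications_mean,
         lab_prob = lab_prob, lab_mean = lab_mean, lab_sd = lab_sd,
         span_start = as.Date(span_start), span_days = as.integer(span_days)),
    class = "generator_spec"
  )
}

# Build a tree-shaped scheme: level i holds prod(branching[1:i]) concepts.
build_tree_scheme <- function(scheme_id, levels, branching, prefix) {
  stopifnot(length(levels) == length(branching), all(branching >= 1))
  concepts <- list()
  for (i in seq_along(levels)) {
    n_i <- prod(branching[seq_len(i)])
    codes <- paste0(prefix, i, "_", seq_len(n_i))
    broader <- if (i == 1L) {
      rep(list(character()), n_i)
    } else {
      lapply(seq_len(n_i), function(j) {
        paste0(prefix, i - 1L, "_", ceiling(j / branching[i]))
      })
    }
    concepts[[i]] <- tibble(code = codes,
                            label = paste(scheme_id, levels[i], seq_len(n_i)),
                            level = levels[i], broader = broader)
  }
  concept_scheme(scheme_id, levels, bind_rows(concepts))
}

scheme_leaves <- function(scheme) {
  last <- scheme$level_names[length(scheme$level_names)]
  scheme$concepts$code[scheme$concepts$level == last]
}

#' Generate synthetic terminologies and mappings
#'
#' Produces a four-level research scheme (SOC > HLGT > HLT > PT
#' analogue), a flat bridge scheme (SNOMED-analogue pivot), two
#' three-level care schemes (ICD analogues) and a two-level drug
#' scheme plus a flat lab scheme. Mapping assertions come in three
#' relation tags mirroring how curated crosswalks chain in practice:
#' care-1 leaf -> bridge (`omop_like`), bridge -> research PT
#' (`protect_like`), bridge -> care-2 leaf (`crossmap_like`), so close
#' matches between care codes and research PTs only arise through
#' transitive closure. The first care leaf of each care scheme always
#' maps to the designated reaction PT and the second to the confounder
#' PT; the remaining leaves are mapped with probability
#' `mapping_consistency`. The ground-truth table records every care
#' leaf's true research PT and research group (HLGT-level ancestor),
#' `NA` when deliberately unmapped.
#'
#' @param spec A [generator_spec()].
#' @return List with `schemes` (named list of [concept_scheme()]),
#'   `mappings` (assertion tibble), `truth` (ground-truth tibble) and
#'   `meta` (designated codes: reaction PT, confounder PT, exposure
#'   drug, comparator drug, lab code, group level).
#' @export
generate_terminologies <- function(spec) {
  research <- build_tree_scheme("MEDC", c("soc", "hlgt", "hlt", "pt"),
                                c(2, 3, 3, 3), "R")
  care1 <- build_tree_scheme("ICD9A", c("chapter", "block", "code"),
                             c(3, 4, 4), "C")
  care2 <- build_tree_scheme("ICD10A", c("chapter", "block", "code"),
                             c(3, 4, 4), "D")
  drug <- build_tree_scheme("ATCA", c("class", "substance"), c(4, 5), "A")
  lab <- concept_scheme("LABA", "analyte",
                        tibble(code = c("A1C", "GLU"),
                               label = c("glycated haemoglobin analogue",
                                         "glucose analogue"),
                               level = "analyte", broader = list(character(),
                                                                 character())))
  bridge_concepts <- tibble(code = character(), label = character(),
                            level = character(), broader = list())
  pts <- scheme_leaves(research)
  reaction_pt <- pts[1]
  confounder_pt <- pts[2]
  mappings <- list()
  truth <- list()
  withr::with_seed(stream_seed(spec$seed, "terminology"), {
    for (care in list(care1, care2)) {
      leaves <- scheme_leaves(care)
      mapped <- stats::runif(length(leaves)) < spec$mapping_consistency
      mapped[1:2] <- TRUE
      pt_of <- sample(pts, length(leaves), replace = TRUE)
      pt_of[1] <- reaction_pt
      pt_of[2] <- confounder_pt
      for (i in seq_along(leaves)) {
        if (!mapped[i]) {
          truth[[length(truth) + 1L]] <- tibble(
            care_scheme = care$scheme_id, care_code = leaves[i],
            research_pt = NA_character_, research_group = NA_character_)
          next
        }
        pt <- pt_of[i]
        bcode <- paste0("B_", pt)
        if (!bcode %in% bridge_concepts$code) {
          bridge_concepts <- bind_rows(bridge_concepts, tibble(
            code = bcode, label = paste("bridge", pt), level = "finding",
            broader = list(character())))
          mappings[[length(mappings) + 1L]] <- tibble(
            source_scheme = "SCTA", source_code = bcode,
            target_scheme = "MEDC", target_code = pt, relation = "protect_like")
        }
        rel <- if (care$scheme_id == "ICD9A") "omop_like" else "crossmap_like"
        mappings[[length(mappings) + 1L]] <- if (care$scheme_id == "ICD9A") {
          tibble(source_scheme = care$scheme_id, source_code = leaves[i],
                 target_scheme = "SCTA", target_code = bcode, relation = rel)
        } else {
          tibble(source_scheme = "SCTA", source_code = bcode,
                 target_scheme = care$scheme_id, target_code = leaves[i],
                 relation = rel)
        }
        grp <- ancestors_at_level(research, pt, "hlgt")
        truth[[length(truth) + 1L]] <- tibble(
          care_scheme = care$scheme_id, care_code = leaves[i],
          research_pt = pt, research_group = grp[1])
      }
    }
  })
  bridge <- concept_scheme("SCTA", "finding", bridge_concepts)
  list(
    schemes = list(MEDC = research, SCTA = bridge, ICD9A = care1,
                   ICD10A = care2, ATCA = drug, LABA = lab),
    mappings = bind_rows(mappings),
    truth = bind_rows(truth),
    meta = list(reaction_pt = reaction_pt, confounder_pt = confounder_pt,
                exposure_drug = scheme_leaves(drug)[1],
                comparator_drug = scheme_leaves(drug)[2],
                lab_code = "A1C", group_level = "hlgt")
  )
}

# PTs usable as background-noise conditions: mapped in BOTH care
# schemes (so any source dialect can express them), minus designated.
covered_noise_pts <- function(terms) {
  cov <- terms$truth |>
    filter(!is.na(.data$research_pt)) |>
    distinct(.data$care_scheme, .data$research_pt) |>
    count(.data$research_pt) |>
    filter(.data$n == 2L) |>
    pull("research_pt")
  setdiff(cov, c(terms$meta$reaction_pt, terms$meta$confounder_pt))
}

#' Generate a synthetic cohort with ground truth
#'
#' Samples demographics, exposes patients to the study drug with one
#' dated prescription, draws a within-window reaction with probability
#' `p_w` for exposed patients and a baseline reaction with probability
#' `p_bg` for everyone, injects confounder conditions at different
#' prevalences in reactors and non-reactors, and adds unrelated noise
#' conditions/medications and lab results. Condition codes are in the
#' research scheme; [emit_source_dialects()] re-expresses them in a
#' care scheme. The ground-truth table records each patient's true
#' exposure and foreground membership (a reaction dated within the
#' window after the prescription — deterministic given the events, so
#' engine-selected populations can be compared for exact equality).
#'
#' @param spec A [generator_spec()].
#' @param terms Output of [generate_terminologies()].
#' @return List with `cohort` (a [cohort()]) and `truth` (tibble:
#'   `patient_id`, `exposed`, `fg_true`, `reacted`).
#' @export
generate_cohort <- function(spec, terms) {
  n <- spec$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  research_labels <- stats::setNames(terms$schemes$MEDC$concepts$label,
                                     terms$schemes$MEDC$concepts$code)
  drug_labels <- stats::setNames(terms$schemes$ATCA$concepts$label,
                                 terms$schemes$ATCA$concepts$code)
  rand_day <- function(k) sample.int(spec$span_days, k, replace = TRUE) - 1L
  date_of <- function(day) spec$span_start + day

  withr::with_seed(stream_seed(spec$seed, "demographics"), {
    patients <- tibble(
      patient_id = ids,
      birth_year = as.integer(sample(seq(spec$birth_year_range[1],
                                         spec$birth_year_range[2]), n, TRUE)),
      gender = sample(names(spec$gender_split), n, TRUE, prob = spec$gender_split),
      country = sample(names(spec$countries), n, TRUE, prob = spec$countries)
    )
  })

  withr::with_seed(stream_seed(spec$seed, "exposures"), {
    exposed <- stats::runif(n) < spec$exposure_prob
    presc_day <- ifelse(exposed, rand_day(n), NA_integer_)
    comparator <- stats::runif(n) < 0.15
    comparator_day <- ifelse(comparator, rand_day(n), NA_integer_)
    n_noise_med <- stats::rpois(n, spec$noise_medications_mean)
  })

  withr::with_seed(stream_seed(spec$seed, "reactions"), {
    win_react <- exposed & stats::runif(n) < spec$p_w
    win_day <- presc_day + sample.int(spec$window_days + 1L, n, TRUE) - 1L
    base_react <- stats::runif(n) < spec$p_bg
    base_day <- rand_day(n)
  })

  reacted <- win_react | base_react
  withr::with_seed(stream_seed(spec$seed, "confounders"), {
    prev <- ifelse(reacted, spec$confounder_prev[["reactors"]],
                   spec$confounder_prev[["nonreactors"]])
    has_conf <- stats::runif(n) < prev
    conf_day <- rand_day(n)
  })

  noise_pool <- covered_noise_pts(terms)
  other_drugs <- setdiff(scheme_leaves(terms$schemes$ATCA),
                         c(terms$meta$exposure_drug, terms$meta$comparator_drug))
  withr::with_seed(stream_seed(spec$seed, "noise"), {
    n_noise_cond <- stats::rpois(n, spec$noise_conditions_mean)
    noise_cond <- lapply(seq_len(n), function(i) {
      k <- n_noise_cond[i]
      if (k == 0L || !length(noise_pool)) return(NULL)
      tibble(patient_id = ids[i], kind = "condition", scheme = "MEDC",
             code = sample(noise_pool, k, replace = TRUE),
             start = date_of(rand_day(k)))
    })
    noise_med <- lapply(seq_len(n), function(i) {
      k <- n_noise_med[i]
      if (k == 0L || !length(other_drugs)) return(NULL)
      tibble(patient_id = ids[i], kind = "medication", scheme = "ATCA",
             code = sample(other_drugs, k, replace = TRUE),
             start = date_of(rand_day(k)))
    })
  })

  withr::with_seed(stream_seed(spec$seed, "labs"), {
    has_lab <- stats::runif(n) < spec$lab_prob
    lab_val <- round(stats::rnorm(n, spec$lab_mean, spec$lab_sd), 4)
    lab_day <- rand_day(n)
  })

  stmts <- bind_rows(
    tibble(patient_id = ids[exposed], kind = "medication", scheme = "ATCA",
           code = terms$meta$exposure_drug, start = date_of(presc_day[exposed])),
    tibble(patient_id = ids[comparator], kind = "medication", scheme = "ATCA",
           code = terms$meta$comparator_drug,
           start = date_of(comparator_day[comparator])),
    tibble(patient_id = ids[win_react], kind = "condition", scheme = "MEDC",
           code = terms$meta$reaction_pt, start = date_of(win_day[win_react])),
    tibble(patient_id = ids[base_react], kind = "condition", scheme = "MEDC",
           code = terms$meta$reaction_pt, start = date_of(base_day[base_react])),
    tibble(patient_id = ids[has_conf], kind = "condition", scheme = "MEDC",
           code = terms$meta$confounder_pt, start = date_of(conf_day[has_conf])),
    bind_rows(noise_cond),
    bind_rows(noise_med),
    tibble(patient_id = ids[has_lab], kind = "lab_result", scheme = "LABA",
           code = terms$meta$lab_code, start = date_of(lab_day[has_lab]),
           value_num = lab_val[has_lab], value_unit = "%")
  )
  stmts$label <- dplyr::case_when(
    stmts$scheme == "MEDC" ~ unname(research_labels[stmts$code]),
    stmts$scheme == "ATCA" ~ unname(drug_labels[stmts$code]),
    stmts$scheme == "LABA" ~ "glycated haemoglobin analogue",
    TRUE ~ NA_character_
  )

  # true foreground membership from the realized events
  react_days <- dplyr::case_when(win_react ~ win_day, TRUE ~ NA_integer_)
  fg_true <- exposed & (
    (win_react & win_day - presc_day >= 0 & win_day - presc_day <= spec$window_days) |
      (base_react & base_day - presc_day >= 0 &
         base_day - presc_day <= spec$window_days)
  )
  fg_true[is.na(fg_true)] <- FALSE
  truth <- tibble(patient_id = ids, exposed = exposed,
                  reacted = reacted, fg_true = fg_true)
  list(cohort = canonicalize_cohort(cohort(patients, stmts)), truth = truth)
}

# Research-coded conditions -> care-coded: for each research PT pick
# the lexicographically first care leaf whose ground truth is that PT.
recode_to_care <- function(x, terms, care_scheme) {
  map <- terms$truth |>
    filter(.data$care_scheme == .env$care_scheme, !is.na(.data$research_pt)) |>
    group_by(.data$research_pt) |>
    summarise(care_code = min(.data$care_code), .groups = "drop")
  care_sch <- terms$schemes[[care_scheme]]
  care_labels <- stats::setNames(care_sch$concepts$label, care_sch$concepts$code)
  s <- x$statements
  is_cond <- s$kind == "condition" & s$scheme == "MEDC"
  m <- match(s$code[is_cond], map$research_pt)
  if (anyNA(m)) {
    abort(paste0("condition code(s) with no counterpart in scheme '", care_scheme,
                 "': ", paste(unique(s$code[is_cond][is.na(m)]), collapse = ", ")),
          class = "casechar_integrity_error")
  }
  s$code[is_cond] <- map$care_code[m]
  s$scheme[is_cond] <- care_scheme
  s$label[is_cond] <- unname(care_labels[s$code[is_cond]])
  x$statements <- s
  canonicalize_cohort(x)
}

date_compact <- function(d) ifelse(is.na(d), NA_character_, format(d, "%Y%m%d"))

#' Emit a cohort in a source dialect
#'
#' Re-expresses condition codes in the designated care scheme (reverse
#' ground-truth mapping; medications and labs keep their shared
#' schemes) and writes either the XML patient-summary dialect (one
#' document, with the matching `code_systems.tsv` lookup alongside) or
#' the relational CSV dialect (a directory of tables). Both dialects
#' round-trip through the mediation module back to the care-coded
#' records.
#'
#' @param x A [cohort()] with research-coded conditions.
#' @param dialect `"xml"` or `"relational"`.
#' @param path Output file (xml) or directory (relational).
#' @param terms Output of [generate_terminologies()].
#' @param care_scheme Care scheme id to code conditions in.
#' @return Invisibly, a list with `path` and the care-coded `cohort`.
#' @export
emit_source_dialects <- function(x, dialect = c("xml", "relational"), path,
                                 terms, care_scheme = "ICD9A") {
  dialect <- match.arg(dialect)
  xr <- recode_to_care(x, terms, care_scheme)
  if (dialect == "xml") {
    emit_xml_dialect(xr, path)
    lookup <- tibble(system_id = vapply(names(terms$schemes), scheme_oid, ""),
                     scheme_id = names(terms$schemes))
    readr::write_tsv(lookup, file.path(dirname(path), "code_systems.tsv"),
                     progress = FALSE)
  } else {
    emit_relational_dialect(xr, path)
  }
  invisible(list(path = path, cohort = xr))
}

emit_xml_dialect <- function(x, path) {
  doc <- xml2::xml_new_root("patientSummarySet")
  by_pat <- split(x$statements, factor(x$statements$patient_id,
                                       levels = x$patients$patient_id))
  section_of <- c(condition = "problems", medication = "medications",
                  lab_result = "results", procedure = "procedures",
                  allergy = "allergies")
  for (i in seq_len(nrow(x$patients))) {
    p <- x$patients[i, ]
    ps <- xml2::xml_add_child(doc, "patientSummary", id = p$patient_id)
    demo <- xml2::xml_add_child(ps, "patient")
    if (!is.na(p$birth_year)) {
      xml2::xml_add_child(demo, "birthYear", value = as.character(p$birth_year))
    }
    if (!is.na(p$gender)) xml2::xml_add_child(demo, "gender", code = p$gender)
    if (!is.na(p$country)) xml2::xml_add_child(demo, "country", code = p$country)
    stmts <- by_pat[[p$patient_id]]
    for (sec_kind in names(section_of)) {
      sk <- stmts[stmts$kind == sec_kind, ]
      if (nrow(sk) == 0L) next
      sec <- xml2::xml_add_child(ps, "section", type = section_of[[sec_kind]])
      for (j in seq_len(nrow(sk))) {
        st <- sk[j, ]
        obs <- xml2::xml_add_child(sec, "observation")
        code_el <- xml2::xml_add_child(obs, "code", code = st$code,
                                       codeSystem = scheme_oid(st$scheme))
        if (!is.na(st$label)) xml2::xml_set_attr(code_el, "displayName", st$label)
        if (!is.na(st$start)) {
          xml2::xml_add_child(obs, "effectiveTime", value = date_compact(st$start))
        }
        if (!is.na(st$end)) {
          xml2::xml_add_child(obs, "effectiveTimeEnd", value = date_compact(st$end))
        }
        if (!is.na(st$value_num)) {
          v <- xml2::xml_add_child(obs, "value",
                                   value = sprintf("%.4f", st$value_num))
          if (!is.na(st$value_unit)) xml2::xml_set_attr(v, "unit", st$value_unit)
        }
      }
    }
  }
  xml2::write_xml(xml2::xml_root(doc), path)
  invisible(path)
}

emit_relational_dialect <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(d) ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))
  readr::write_csv(x$patients, file.path(dir, "patients.csv"), progress = FALSE,
                   na = "")
  tab <- function(kind) {
    x$statements |>
      filter(.data$kind == .env$kind) |>
      mutate(start_date = iso(.data$start), end_date = iso(.data$end)) |>
      select("patient_id", "scheme", "code", "label", "start_date", "end_date")
  }
  readr::write_csv(tab("condition"), file.path(dir, "conditions.csv"),
                   progress = FALSE, na = "")
  readr::write_csv(tab("medication"), file.path(dir, "medications.csv"),
                   progress = FALSE, na = "")
  labs <- x$statements |>
    filter(.data$kind == "lab_result") |>
    mutate(start_date = iso(.data$start),
           value = ifelse(is.na(.data$value_num), NA_character_,
                          sprintf("%.4f", .data$value_num))) |>
    select("patient_id", "scheme", "code", "label", "start_date", "value",
           unit = "value_unit")
  readr::write_csv(labs, file.path(dir, "labs.csv"), progress = FALSE, na = "")
  invisible(dir)
}

#' Analytic expectation of the foreground share
#'
#' Closed-form expectation of the fraction of exposed (background)
#' patients that end up foreground-eligible under the generator's
#' reaction model: `p_w + (1 - p_w) * p_bg * q`, where `q` is the
#' probability that an independently, uniformly dated baseline
#' reaction lands within the post-prescription window when the
#' prescription day is itself uniform on the observation span:
#' `q = ((W+1) * D - W * (W+1) / 2) / D^2` for window `W` and span `D`
#' days (discrete-day counting, both bounds inclusive).
#'
#' @param spec A [generator_spec()].
#' @return Expected foreground share of the background population, as
#'   a percentage.
#' @export
expected_fg_share <- function(spec) {
  D <- spec$span_days
  W <- spec$window_days
  q <- ((W + 1) * D - W * (W + 1) / 2) / D^2
  100 * (spec$p_w + (1 - spec$p_w) * spec$p_bg * q)
}
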