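#' Localize an eligibility query to a source's terminologies
#'
#' Rewrites every leaf of the criteria tree into the terminology the
#' source actually uses for that statement kind, via
#' [expand_query_codes()] (close matches plus their narrower
#' descendants). Expansion provenance (original code to expanded set)
#' is retained on the returned object, and leaves whose expansion is
#' empty are kept (they match no patient) and reported.
#'
#' @param query A `criteria_node`.
#' @param source_schemes Named character vector/list: statement kind to
#'   the scheme id the source codes that kind in.
#' @param closure Materialized close-match links.
#' @param schemes List of [concept_scheme()] objects.
#' @param source_id Identifier of the source (for provenance).
#' @return A `localized_query`: list with `source_id`, `query`,
#'   `provenance` (tibble) and `unsatisfiable` (tibble of empty leaves).
#' @export
localize_query <- function(query, source_schemes, closure, schemes,
                           source_id = "source") {
  prov <- list()
  unsat <- list()
  walk <- function(node) {
    if (node$type == "leaf") {
      tgt <- source_schemes[[node$kind]]
      if (is.null(tgt)) {
        abort(paste0("source declares no scheme for kind '", node$kind, "'"),
              class = "casechar_config_error")
      }
      tgt <- unlist(tgt)  # a source may code one kind in several schemes
      expanded <- purrr::map_dfr(seq_len(nrow(node$codes)), function(i) {
        ex <- purrr::map_dfr(tgt, function(tg) {
          codes <- expand_query_codes(c(node$codes$scheme[i], node$codes$code[i]),
                                      tg, closure, schemes)
          if (!length(codes)) return(NULL)
          tibble(scheme = tg, code = codes)
        })
        if (nrow(ex) == 0L) {
          unsat[[length(unsat) + 1L]] <<- tibble(
            kind = node$kind, scheme = node$codes$scheme[i], code = node$codes$code[i])
          return(NULL)
        }
        prov[[length(prov) + 1L]] <<- tibble(
          kind = node$kind, orig_scheme = node$codes$scheme[i],
          orig_code = node$codes$code[i], scheme = ex$scheme, code = ex$code)
        ex
      })
      node$codes <- if (nrow(expanded)) distinct(expanded) else
        tibble(scheme = character(), code = character())
      return(node)
    }
    if (node$type == "bool") {
      node$children <- lapply(node$children, walk)
      return(node)
    }
    node$anchor <- walk(node$anchor)
    node$related <- walk(node$related)
    node
  }
  localized <- walk(query)
  unsat <- if (length(unsat)) distinct(bind_rows(unsat)) else
    tibble(kind = character(), scheme = character(), code = character())
  if (nrow(unsat)) {
    warn(paste0("localization for source '", source_id, "' left ", nrow(unsat),
                " criterion code(s) unsatisfiable (no mapping into source scheme)"))
  }
  structure(list(source_id = source_id, query = localized,
                 provenance = if (length(prov)) bind_rows(prov) else NULL,
                 unsatisfiable = unsat),
            class = "localized_query")
}

match_leaf_statements <- function(node, statements) {
  if (nrow(node$codes) == 0L) {
    return(statements[0, ])
  }
  statements |>
    filter(.data$kind == node$kind) |>
    semi_join(node$codes, by = c("scheme", "code"))
}

#' Evaluate an eligibility query over a cohort
#'
#' Returns the set of eligible patient ids. A leaf matches a patient
#' iff some statement of the leaf's kind carries one of the leaf's
#' (scheme, code) pairs — no descendant closure is applied here, query
#' localization has already expanded codes. Boolean nodes intersect /
#' union their children's patient sets. A temporal node matches iff
#' some anchor statement and some related statement of the patient
#' have start dates within the window (inclusive at both ends; day 0
#' counts); undated statements never satisfy temporal constraints.
#'
#' @param query A `criteria_node` or `localized_query`.
#' @param x A [cohort()].
#' @return Character vector of eligible patient ids (sorted).
#' @export
evaluate_query <- function(query, x) {
  if (inherits(query, "localized_query")) {
    query <- query$query
  }
  all_ids <- x$patients$patient_id
  s <- x$statements
  eval_node <- function(node) {
    switch(node$type,
      leaf = {
        hit <- unique(match_leaf_statements(node, s)$patient_id)
        if (node$negated) setdiff(all_ids, hit) else intersect(all_ids, hit)
      },
      bool = {
        sets <- lapply(node$children, eval_node)
        if (node$op == "and") Reduce(intersect, sets) else Reduce(union, sets)
      },
      temporal = {
        a <- match_leaf_statements(node$anchor, s) |>
          filter(!is.na(.data$start)) |>
          select("patient_id", a_start = "start")
        r <- match_leaf_statements(node$related, s) |>
          filter(!is.na(.data$start)) |>
          select("patient_id", r_start = "start")
        if (nrow(a) == 0L || nrow(r) == 0L) return(character())
        pairs <- inner_join(a, r, by = "patient_id",
                            relationship = "many-to-many")
        d <- as.integer(pairs$r_start - pairs$a_start)
        w <- node$window_days
        ok <- switch(node$direction,
                     after = d >= 0L & d <= w,
                     before = d <= 0L & d >= -w,
                     either = abs(d) <= w)
        sort(unique(pairs$patient_id[ok]))
      }
    )
  }
  sort(intersect(all_ids, eval_node(query)))
}

#' Select foreground and background populations
#'
#' Evaluates the study's two eligibility queries. When the foreground
#' query is structurally the background query plus extra criteria (the
#' usual drug+reaction vs drug pattern), foreground containment in the
#' background is asserted.
#'
#' @param study A `study_definition`.
#' @param x A [cohort()].
#' @param source_id Source identifier recorded on the populations.
#' @return Tibble with columns `source_id`, `patient_id`, `label`
#'   (`foreground` / `background`).
#' @export
select_populations <- function(study, x, source_id = "source") {
  fg <- evaluate_query(study$foreground, x)
  bg <- evaluate_query(study$background, x)
  fgq <- qry_normalize(study$foreground)
  if (fgq$type == "bool" && fgq$op == "and") {
    bgq <- qry_normalize(study$background)
    extends_bg <- any(vapply(fgq$children, identical, TRUE, y = bgq)) ||
      (bgq$type == "bool" && bgq$op == "and" &&
         all(vapply(bgq$children, function(c) {
           any(vapply(fgq$children, identical, TRUE, y = c))
         }, TRUE)))
    if (extends_bg) {
      stopifnot(all(fg %in% bg))
    }
  }
  bind_rows(
    tibble(source_id = source_id, patient_id = fg, label = "foreground"),
    tibble(source_id = source_id, patient_id = bg, label = "background")
  )
}

#' Add derived conditions by rule
#'
#' A derived-condition rule infers a condition that is not explicitly
#' recorded from converging indirect evidence: a minimum age, the
#' presence of specific medications, and a lab result above a
#' threshold (e.g. inferring diabetes from age, metformin-class
#' prescriptions and elevated glycosylated haemoglobin). Each rule is a
#' list with optional `min_age`, optional `medications` (tibble
#' `scheme`, `code`), optional `lab` (`list(scheme, code, threshold)`),
#' and a mandatory `condition` (`list(scheme, code, label)`). The
#' inferred statement is flagged `derived`, dated at the earliest
#' supporting evidence, and never added when the patient already
#' carries the condition code — re-application is a no-op.
#'
#' @param x A [cohort()].
#' @param rules List of derived-condition rule specs.
#' @param reference_date Date used to compute age from birth year.
#' @return The cohort with inferred condition statements appended.
#' @export
apply_derived_condition_rules <- function(x, rules,
                                          reference_date = as.Date("2010-01-01")) {
  s <- x$statements
  p <- x$patients
  new_stmts <- list()
  for (r in rules) {
    if (is.null(r$condition$scheme) || is.null(r$condition$code)) {
      abort("derived-condition rule lacks a target condition",
            class = "casechar_config_error")
    }
    candidates <- p$patient_id
    evidence <- s[0, ]
    if (!is.null(r$medications)) {
      med <- s |>
        filter(.data$kind == "medication") |>
        semi_join(as_tibble(r$medications), by = c("scheme", "code"))
      candidates <- intersect(candidates, unique(med$patient_id))
      evidence <- bind_rows(evidence, med)
    }
    if (!is.null(r$lab)) {
      lab <- s |>
        filter(.data$kind == "lab_result", .data$scheme == r$lab$scheme,
               .data$code == r$lab$code, !is.na(.data$value_num),
               .data$value_num >= r$lab$threshold)
      candidates <- intersect(candidates, unique(lab$patient_id))
      evidence <- bind_rows(evidence, lab)
    }
    if (!is.null(r$min_age)) {
      ref_year <- as.integer(format(reference_date, "%Y"))
      old_enough <- p$patient_id[!is.na(p$birth_year) &
                                   (ref_year - p$birth_year) >= r$min_age]
      candidates <- intersect(candidates, old_enough)
    }
    already <- s |>
      filter(.data$kind == "condition", .data$scheme == r$condition$scheme,
             .data$code == r$condition$code) |>
      pull("patient_id") |>
      unique()
    candidates <- setdiff(candidates, already)
    if (!length(candidates)) next
    ev_dates <- evidence |>
      filter(.data$patient_id %in% candidates, !is.na(.data$start)) |>
      group_by(.data$patient_id) |>
      summarise(start = min(.data$start), .groups = "drop")
    add <- tibble(patient_id = candidates) |>
      left_join(ev_dates, by = "patient_id") |>
      mutate(kind = "condition", scheme = r$condition$scheme,
             code = r$condition$code,
             label = r$condition$label %||% r$condition$code,
             derived = TRUE)
    new_stmts[[length(new_stmts) + 1L]] <- add
  }
  if (length(new_stmts)) {
    x$statements <- bind_rows(s, cohort(statements = bind_rows(new_stmts))$statements)
  }
  canonicalize_cohort(x)
}

#' Aggregate per-source populations and records
#'
#' Merges cohorts and selected populations from multiple sources into
#' one analysis set. Patient ids are namespaced as
#' `source_id:patient_id` so identically named patients at different
#' sites never collide; per-source provenance is retained and counts
#' add exactly.
#'
#' @param sources List of `list(source_id, cohort, populations)` where
#'   `populations` is the tibble from [select_populations()].
#' @return List with `cohort` (merged) and `populations` (merged,
#'   namespaced ids).
#' @export
aggregate_sources <- function(sources) {
  ids <- vapply(sources, `[[`, "", "source_id")
  if (anyDuplicated(ids)) {
    abort("duplicate source_id in aggregation", class = "casechar_config_error")
  }
  namespaced <- lapply(sources, function(src) {
    ns <- function(pid) paste0(src$source_id, ":", pid)
    co <- src$cohort
    co$patients$patient_id <- ns(co$patients$patient_id)
    co$statements$patient_id <- ns(co$statements$patient_id)
    pop <- src$populations
    pop$patient_id <- ns(pop$patient_id)
    pop$source_id <- src$source_id
    list(cohort = co, populations = pop)
  })
  merged <- cohort(
    patients = bind_rows(lapply(namespaced, function(z) z$cohort$patients)),
    statements = bind_rows(lapply(namespaced, function(z) z$cohort$statements))
  )
  list(cohort = canonicalize_cohort(merged),
       populations = bind_rows(lapply(namespaced, `[[`, "populations")))
}
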