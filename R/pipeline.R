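#' Infer which scheme a source codes each statement kind in
#'
#' @param x A [cohort()].
#' @return Named list: statement kind -> character vector of scheme ids
#'   occurring in the source's statements of that kind.
#' @export
infer_source_schemes <- function(x) {
  s <- filter(x$statements, !is.na(.data$scheme))
  sp <- distinct(s, .data$kind, .data$scheme)
  split(sp$scheme, sp$kind)
}

#' Read derived-condition rules from YAML
#'
#' @param path YAML file; see the shipped `derived_rules.yaml`.
#' @return List of rule specs for [apply_derived_condition_rules()].
#' @export
read_derived_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  lapply(rules, function(r) {
    if (!is.null(r$medications)) {
      r$medications <- purrr::map_dfr(r$medications, as_tibble)
    }
    r
  })
}

#' Run a comparative characterization study end-to-end
#'
#' The full pipeline for one study over one or more mediated sources:
#' localize the eligibility queries into each source's terminologies,
#' evaluate them, aggregate populations and records across sources
#' (namespacing patient ids), materialize grouping links for the
#' study's grouping configs, enrich the aggregated statements, and
#' build the comparative report. When `out_dir` is given, the report
#' (JSON + per-box CSV) and a localized-query audit dump (expansion
#' provenance) are written there.
#'
#' @param study A `study_definition`.
#' @param sources List of `list(source_id, cohort, source_schemes)`;
#'   `source_schemes` defaults to [infer_source_schemes()] per source.
#' @param schemes List of [concept_scheme()] objects.
#' @param closure Materialized close-match links
#'   ([materialize_close_match()]).
#' @param derived_rules Optional derived-condition rules applied to
#'   every source cohort before evaluation.
#' @param out_dir Optional output directory.
#' @return List with `report` (a `comparative_report`), `populations`,
#'   `cohort` (aggregated, enriched) and `localized` (per-source audit).
#' @export
run_study <- function(study, sources, schemes, closure, derived_rules = NULL,
                      out_dir = NULL) {
  localized_audit <- list()
  per_source <- lapply(sources, function(src) {
    co <- src$cohort
    if (!is.null(derived_rules)) {
      co <- apply_derived_condition_rules(co, derived_rules)
    }
    ss <- src$source_schemes %||% infer_source_schemes(co)
    fg_loc <- localize_query(study$foreground, ss, closure, schemes, src$source_id)
    bg_loc <- localize_query(study$background, ss, closure, schemes, src$source_id)
    localized_audit[[src$source_id]] <<- list(
      foreground = fg_loc$provenance, background = bg_loc$provenance,
      unsatisfiable = bind_rows(fg_loc$unsatisfiable, bg_loc$unsatisfiable)
    )
    fg <- evaluate_query(fg_loc, co)
    bg <- evaluate_query(bg_loc, co)
    pops <- bind_rows(
      tibble(source_id = src$source_id, patient_id = fg, label = "foreground"),
      tibble(source_id = src$source_id, patient_id = bg, label = "background")
    )
    idx_leaf <- NULL
    if (!is.null(study$index_anchor)) {
      idx_loc <- localize_query(study$index_anchor, ss, closure, schemes,
                                src$source_id)
      idx_leaf <- idx_loc$query$codes
    }
    list(source_id = src$source_id, cohort = co, populations = pops,
         index_codes = idx_leaf)
  })
  agg <- aggregate_sources(per_source)
  # index anchor valid across all sources: union of localized code sets
  study_local <- study
  if (!is.null(study$index_anchor)) {
    all_codes <- distinct(bind_rows(lapply(per_source, `[[`, "index_codes")))
    study_local$index_anchor <- qry_leaf(study$index_anchor$kind, all_codes)
  }
  group_links <- empty_closure()
  for (kind in names(study$grouping)) {
    cfg <- study$grouping[[kind]]
    group_links <- bind_rows(group_links, materialize_group_links(
      closure, schemes, cfg$scheme, cfg$level))
  }
  group_links <- distinct(group_links)
  enriched <- enrich_codes(agg$cohort, study$grouping, group_links, schemes)
  report <- build_report(study_local, enriched, agg$populations, closure, schemes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, out_dir)
    jsonlite::write_json(
      lapply(localized_audit, function(a) {
        list(foreground = a$foreground, background = a$background,
             unsatisfiable = a$unsatisfiable)
      }),
      file.path(out_dir, "localized_queries.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  list(report = report, populations = agg$populations, cohort = enriched,
       localized = localized_audit)
}

#' Run manifest
#'
#' Every pipeline run records what produced its artifacts: the tool
#' version, content hashes of the inputs, the configuration snapshot,
#' timestamps and per-stage record counts. Hashes recompute
#' identically for identical inputs.
#'
#' @param inputs Character vector of input file paths (hashed).
#' @param config List: configuration snapshot.
#' @param counts List: per-stage record counts.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(inputs = character(), config = list(), counts = list()) {
  existing <- inputs[file.exists(inputs)]
  hashes <- if (length(existing)) {
    as.list(stats::setNames(unname(tools::md5sum(existing)), basename(existing)))
  } else {
    list()
  }
  structure(
    list(tool = "casechar",
         version = as.character(utils::packageVersion("casechar")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         input_hashes = hashes, config = config, counts = counts),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
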