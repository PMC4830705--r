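UNMAPPED <- "UNMAPPED"

#' Annotate coded statements with analyst-scheme group codes
#'
#' Adds the terminology-reasoning annotation the comparative report is
#' built on: every coded statement of a kind with a grouping config is
#' linked to its (possibly several, in multiaxial hierarchies) group
#' codes at the analyst's preferred scheme and level, via the
#' materialized group links. Statements with no group link are
#' annotated `UNMAPPED` rather than dropped — silent loss of unmapped
#' codes would bias a safety characterization. Original codes are
#' never touched.
#'
#' @param x A [cohort()].
#' @param grouping Named list (by statement kind) of
#'   `list(scheme, level)` grouping configs.
#' @param group_links Tibble of `group_link` rows materialized for each
#'   configured (scheme, level) ([materialize_group_links()] output,
#'   possibly concatenated).
#' @param schemes Optional list of [concept_scheme()] objects used to
#'   attach group labels.
#' @return The cohort with an `annotations` element: a tibble
#'   (`stmt_id`, `patient_id`, `kind`, `group_scheme`, `group_code`,
#'   `group_label`), one row per (statement, group) pair.
#' @export
enrich_codes <- function(x, grouping, group_links, schemes = NULL) {
  s <- mutate(x$statements, stmt_id = dplyr::row_number())
  ann <- list()
  for (kind in names(grouping)) {
    cfg <- grouping[[kind]]
    sk <- filter(s, .data$kind == !!kind, !is.na(.data$code))
    if (nrow(sk) == 0L) next
    links <- group_links |>
      filter(.data$kind == "group_link", .data$scheme_b == cfg$scheme) |>
      select(scheme = "scheme_a", code = "code_a", group_code = "code_b")
    hit <- sk |>
      select("stmt_id", "patient_id", "kind", "scheme", "code") |>
      left_join(links, by = c("scheme", "code"),
                relationship = "many-to-many") |>
      mutate(group_scheme = cfg$scheme,
             group_code = as.character(ifelse(is.na(.data$group_code), UNMAPPED,
                                              .data$group_code)))
    ann[[length(ann) + 1L]] <- distinct(
      select(hit, "stmt_id", "patient_id", "kind", "group_scheme", "group_code"))
  }
  annotations <- if (length(ann)) bind_rows(ann) else
    tibble(stmt_id = integer(), patient_id = character(), kind = character(),
           group_scheme = character(), group_code = character())
  annotations$group_label <- annotations$group_code
  if (!is.null(schemes)) {
    names(schemes) <- vapply(schemes, `[[`, "", "scheme_id")
    for (sid in unique(annotations$group_scheme)) {
      sch <- schemes[[sid]]
      if (is.null(sch)) next
      idx <- annotations$group_scheme == sid
      m <- match(annotations$group_code[idx], sch$concepts$code)
      lab <- sch$concepts$label[m]
      annotations$group_label[idx] <- ifelse(is.na(lab),
                                             annotations$group_code[idx], lab)
    }
  }
  x$statements <- s
  x$annotations <- arrange(annotations, .data$stmt_id, .data$group_code)
  x
}

box_row_sort <- function(rows) {
  arrange(rows, desc(.data$fg_rate), .data$item_code)
}

stat_box <- function(box, rows, fg_n, bg_n, grouping = NULL) {
  rows <- box_row_sort(rows)
  structure(list(box = box, rows = rows, fg_n = fg_n, bg_n = bg_n,
                 grouping = grouping),
            class = "stat_box")
}

#' @export
print.stat_box <- function(x, ...) {
  cat("<stat_box> ", x$box, " (fg n=", x$fg_n, ", bg n=", x$bg_n, ")\n", sep = "")
  print(x$rows, ...)
  invisible(x)
}

rate_rows <- function(items_fg, items_bg, fg_n, bg_n) {
  # items_*: tibble(item_code, item_label, patient_id) of distinct pairs
  tally <- function(items, n, prefix) {
    items |>
      distinct(.data$item_code, .data$item_label, .data$patient_id) |>
      count(.data$item_code, .data$item_label, name = paste0(prefix, "_count")) |>
      mutate("{prefix}_rate" := round_half_up(
        100 * .data[[paste0(prefix, "_count")]] / max(n, 1L), 2))
  }
  out <- full_join(tally(items_fg, fg_n, "fg"), tally(items_bg, bg_n, "bg"),
                   by = c("item_code", "item_label"))
  out |>
    mutate(across(c("fg_count", "bg_count"), ~ tidyr::replace_na(.x, 0L)),
           across(c("fg_rate", "bg_rate"), ~ tidyr::replace_na(.x, 0))) |>
    select("item_code", "item_label", "fg_count", "fg_rate", "bg_count", "bg_rate")
}

age_band <- function(age) {
  ifelse(is.na(age), "UNKNOWN",
         ifelse(age >= 90, "90+", paste0(10 * (age %/% 10), "-", 10 * (age %/% 10) + 9)))
}

#' Comparative demographics box
#'
#' Tallies a demographic item over the foreground and background
#' populations. Ages are computed as reference year minus birth year
#' and banded into decades; missing values fall into an `UNKNOWN` row.
#' Rates are percentages of the population size, rounded half-up to
#' two decimals; rows sort by foreground rate descending, ties by code.
#'
#' @param x A [cohort()].
#' @param fg,bg Character vectors of foreground / background patient ids.
#' @param kind `"age"`, `"gender"` or `"country"`.
#' @param reference_date Date anchoring the age computation.
#' @return A `stat_box`.
#' @export
demographics_box <- function(x, fg, bg, kind = c("age", "gender", "country"),
                             reference_date = as.Date("2010-01-01")) {
  kind <- match.arg(kind)
  p <- x$patients
  item_of <- function(ids) {
    pp <- p[p$patient_id %in% ids, ]
    item <- switch(kind,
      age = age_band(as.integer(format(reference_date, "%Y")) - pp$birth_year),
      gender = ifelse(is.na(pp$gender), "UNKNOWN", pp$gender),
      country = ifelse(is.na(pp$country), "UNKNOWN", pp$country)
    )
    item <- as.character(item)  # ifelse() degrades to logical(0) when empty
    tibble(item_code = item, item_label = item, patient_id = pp$patient_id)
  }
  rows <- rate_rows(item_of(fg), item_of(bg), length(fg), length(bg))
  stat_box(kind, rows, length(fg), length(bg))
}

patient_index_dates <- function(x, index_anchor) {
  match_leaf_statements(index_anchor, x$statements) |>
    filter(!is.na(.data$start)) |>
    group_by(.data$patient_id) |>
    summarise(index_date = min(.data$start), .groups = "drop")
}

#' Comparative common-items box
#'
#' For one statement kind, counts per analyst-level group the number
#' of patients carrying at least one statement annotated with that
#' group — patient counts, not event counts, so rates are
#' population-comparable (event counts are carried alongside in
#' `fg_events` / `bg_events`). With `scope = "before_index"` /
#' `"after_index"` only statements strictly before / strictly after
#' the patient's index date count (index-day events appear only in the
#' overall box), optionally within `window_days` of the index;
#' patients without an index date are excluded from the denominator.
#'
#' @inheritParams demographics_box
#' @param kind Statement kind to tabulate (e.g. `"condition"`).
#' @param scope `"overall"`, `"before_index"` or `"after_index"`.
#' @param index_anchor Leaf criterion whose earliest match dates the
#'   index per patient (required for before/after scopes).
#' @param window_days Optional window bound relative to the index.
#' @return A `stat_box`; `fg_n`/`bg_n` are the denominators actually
#'   used (population size, or patients with an index date).
#' @export
common_items_box <- function(x, fg, bg, kind,
                             scope = c("overall", "before_index", "after_index"),
                             index_anchor = NULL, window_days = NULL) {
  scope <- match.arg(scope)
  if (is.null(x$annotations)) {
    abort("cohort has no annotations; run enrich_codes() first",
          class = "casechar_config_error")
  }
  ann <- filter(x$annotations, .data$kind == !!kind)
  stmts <- select(x$statements, "stmt_id", "start")
  ann <- left_join(ann, stmts, by = "stmt_id")
  fg_ids <- fg; bg_ids <- bg
  if (scope != "overall") {
    if (is.null(index_anchor)) {
      abort("before/after scope needs an index_anchor", class = "casechar_config_error")
    }
    idx <- patient_index_dates(x, index_anchor)
    ann <- ann |>
      inner_join(idx, by = "patient_id") |>
      filter(!is.na(.data$start))
    d <- as.integer(ann$start - ann$index_date)
    keep <- if (scope == "before_index") d < 0L else d > 0L
    if (!is.null(window_days)) {
      keep <- keep & abs(d) <= window_days
    }
    ann <- ann[keep, ]
    fg_ids <- intersect(fg, idx$patient_id)
    bg_ids <- intersect(bg, idx$patient_id)
  }
  items <- ann |>
    select("patient_id", "stmt_id", item_code = "group_code",
           item_label = "group_label")
  ev <- function(ids, prefix) {
    items |>
      filter(.data$patient_id %in% ids) |>
      distinct(.data$item_code, .data$stmt_id) |>
      count(.data$item_code, name = paste0(prefix, "_events"))
  }
  rows <- rate_rows(filter(items, .data$patient_id %in% fg_ids),
                    filter(items, .data$patient_id %in% bg_ids),
                    length(fg_ids), length(bg_ids)) |>
    left_join(ev(fg_ids, "fg"), by = "item_code") |>
    left_join(ev(bg_ids, "bg"), by = "item_code") |>
    mutate(across(c("fg_events", "bg_events"), ~ tidyr::replace_na(.x, 0L)))
  box_name <- if (scope == "overall") paste0("common_", kind, "s") else
    paste0(kind, "s_", sub("_index", "", scope), "_index")
  stat_box(box_name, rows, length(fg_ids), length(bg_ids))
}

#' Comparative risk-factor box
#'
#' Patient-level prevalence of each analyst-defined risk factor
#' (confounder) code in both populations. Matching expands each risk
#' code into every scheme occurring in the statements, so an
#' analyst-scheme risk code hits source-coded data; derived statements
#' count like any other statement.
#'
#' @inheritParams demographics_box
#' @param risk_factors Tibble `scheme`, `code`, `label`.
#' @param closure Materialized close-match links.
#' @param schemes List of [concept_scheme()] objects.
#' @return A `stat_box`.
#' @export
risk_factor_box <- function(x, fg, bg, risk_factors, closure, schemes) {
  s <- x$statements
  data_schemes <- unique(stats::na.omit(s$scheme))
  items <- purrr::map_dfr(seq_len(nrow(risk_factors)), function(i) {
    rf <- risk_factors[i, ]
    targets <- purrr::map_dfr(data_schemes, function(ds) {
      codes <- expand_query_codes(c(rf$scheme, rf$code), ds, closure, schemes)
      if (!length(codes)) return(NULL)
      tibble(scheme = ds, code = codes)
    })
    hit <- if (nrow(targets)) {
      semi_join(s, targets, by = c("scheme", "code"))
    } else {
      s[0, ]
    }
    tibble(item_code = rf$code, item_label = rf$label,
           patient_id = unique(hit$patient_id))
  })
  rows <- rate_rows(filter(items, .data$patient_id %in% fg),
                    filter(items, .data$patient_id %in% bg),
                    length(fg), length(bg))
  # keep zero-prevalence risk factors visible
  missing <- anti_join(select(risk_factors, item_code = "code", item_label = "label"),
                       rows, by = "item_code")
  if (nrow(missing)) {
    rows <- bind_rows(rows, mutate(missing, fg_count = 0L, fg_rate = 0,
                                   bg_count = 0L, bg_rate = 0))
  }
  stat_box("risk_factor", box_row_sort(rows), length(fg), length(bg))
}

#' Build the comparative case-series report
#'
#' Assembles every statistics box the study requests, plus the
#' headline foreground share of the background population. The report
#' is deterministic given its inputs: identical inputs serialize to
#' byte-identical JSON.
#'
#' @param study A `study_definition`.
#' @param x An enriched [cohort()] ([enrich_codes()] applied).
#' @param populations Tibble from [select_populations()] (or the
#'   aggregated equivalent).
#' @param closure,schemes Needed when risk factors are requested.
#' @return A `comparative_report`.
#' @export
build_report <- function(study, x, populations, closure = NULL, schemes = NULL) {
  fg <- sort(unique(populations$patient_id[populations$label == "foreground"]))
  bg <- sort(unique(populations$patient_id[populations$label == "background"]))
  ref <- study$reference_date
  if (is.na(ref)) ref <- as.Date("2010-01-01")
  boxes <- list()
  for (stat in study$statistics) {
    boxes[[stat]] <- switch(stat,
      age = demographics_box(x, fg, bg, "age", ref),
      gender = demographics_box(x, fg, bg, "gender", ref),
      country = demographics_box(x, fg, bg, "country", ref),
      common_conditions = common_items_box(x, fg, bg, "condition", "overall"),
      common_medications = common_items_box(x, fg, bg, "medication", "overall"),
      conditions_before_index = common_items_box(x, fg, bg, "condition",
                                                 "before_index", study$index_anchor),
      conditions_after_index = common_items_box(x, fg, bg, "condition",
                                                "after_index", study$index_anchor),
      medications_before_index = common_items_box(x, fg, bg, "medication",
                                                  "before_index", study$index_anchor),
      medications_after_index = common_items_box(x, fg, bg, "medication",
                                                 "after_index", study$index_anchor),
      risk_factor = risk_factor_box(x, fg, bg, study$risk_factors, closure, schemes),
      abort(paste0("unknown statistic '", stat, "'"), class = "casechar_config_error")
    )
  }
  if (nrow(study$risk_factors) && !"risk_factor" %in% names(boxes) &&
      !is.null(closure)) {
    boxes$risk_factor <- risk_factor_box(x, fg, bg, study$risk_factors,
                                         closure, schemes)
  }
  structure(
    list(study_id = study$study_id, fg_size = length(fg), bg_size = length(bg),
         fg_share_pct = proportion(length(fg), length(bg)),
         grouping = study$grouping, boxes = boxes),
    class = "comparative_report"
  )
}

#' @export
print.comparative_report <- function(x, ...) {
  cat("<comparative_report> ", x$study_id, "\n", sep = "")
  cat("  foreground: ", x$fg_size, " patients; background: ", x$bg_size,
      " patients (", ifelse(is.na(x$fg_share_pct), "NA", x$fg_share_pct),
      "% of background)\n", sep = "")
  cat("  boxes: ", paste(names(x$boxes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a comparative report into one long tibble
#'
#' @param x A `comparative_report`.
#' @param ... Unused.
#' @return Tibble with one row per (box, item): counts and rates for
#'   both populations.
#' @exportS3Method generics::tidy
tidy.comparative_report <- function(x, ...) {
  purrr::map_dfr(x$boxes, function(b) {
    mutate(b$rows, box = b$box, fg_n = b$fg_n, bg_n = b$bg_n, .before = 1)
  })
}

#' One-row summary of a comparative report
#'
#' @inheritParams tidy.comparative_report
#' @return Tibble with foreground/background sizes and the foreground
#'   share percentage.
#' @exportS3Method generics::glance
glance.comparative_report <- function(x, ...) {
  tibble(study_id = x$study_id, fg_size = x$fg_size, bg_size = x$bg_size,
         fg_share_pct = x$fg_share_pct, n_boxes = length(x$boxes))
}

#' Plot a comparative report box
#'
#' Side-by-side foreground/background rates for one statistics box.
#'
#' @param object A `comparative_report`.
#' @param box Name of the box to plot (default: the first).
#' @param top_n Keep the `top_n` highest-foreground-rate rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.comparative_report <- function(object, box = NULL, top_n = 10, ...) {
  box <- box %||% names(object$boxes)[1]
  b <- object$boxes[[box]]
  df <- utils::head(b$rows, top_n) |>
    select("item_label", foreground = "fg_rate", background = "bg_rate") |>
    tidyr::pivot_longer(c("foreground", "background"),
                        names_to = "population", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$item_label, .data$rate),
    y = .data$rate, fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "patients (%)",
                  title = paste0(object$study_id, ": ", b$box)) +
    ggplot2::theme_minimal()
}

#' Serialize a comparative report
#'
#' Writes the machine-readable JSON (full report, deterministic byte
#' layout for identical inputs) and one CSV per box for analysts.
#'
#' @param report A `comparative_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    study_id = report$study_id,
    fg_size = report$fg_size, bg_size = report$bg_size,
    fg_share_pct = report$fg_share_pct,
    grouping = report$grouping,
    boxes = lapply(report$boxes, function(b) {
      list(box = b$box, fg_n = b$fg_n, bg_n = b$bg_n, rows = b$rows)
    })
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  for (nm in names(report$boxes)) {
    readr::write_csv(report$boxes[[nm]]$rows,
                     file.path(dir, paste0("box_", nm, ".csv")), progress = FALSE)
  }
  invisible(dir)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
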