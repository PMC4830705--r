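statement_cols <- function() {
  tibble(
    patient_id = character(), kind = character(), scheme = character(),
    code = character(), label = character(),
    start = as.Date(character()), end = as.Date(character()),
    value_num = double(), value_unit = character(),
    value_scheme = character(), value_code = character(),
    derived = logical()
  )
}

patient_cols <- function() {
  tibble(patient_id = character(), birth_year = integer(),
         gender = character(), country = character())
}

statement_kinds <- c("condition", "medication", "lab_result", "procedure", "allergy")

#' Construct a common-model cohort
#'
#' The common information model subset: a demographics table (one row
#' per patient) plus a dated, coded clinical-statement table (long,
#' one row per statement). Statement kinds are condition, medication,
#' lab_result, procedure and allergy; only lab results carry a value
#' (numeric quantity + unit, or a coded value). Dates are at day
#' granularity throughout.
#'
#' @param patients Tibble with columns `patient_id`, `birth_year`,
#'   `gender`, `country`.
#' @param statements Tibble with (a subset of) the statement columns;
#'   missing columns are filled with NA.
#' @return An object of class `cohort`.
#' @export
cohort <- function(patients = patient_cols(), statements = statement_cols()) {
  patients <- as_tibble(patients)
  statements <- as_tibble(statements)
  tmpl <- statement_cols()
  for (col in setdiff(names(tmpl), names(statements))) {
    statements[[col]] <- tmpl[[col]][rep(NA_integer_, nrow(statements))]
  }
  statements <- statements[names(tmpl)]
  ptmpl <- patient_cols()
  for (col in setdiff(names(ptmpl), names(patients))) {
    patients[[col]] <- ptmpl[[col]][rep(NA_integer_, nrow(patients))]
  }
  patients <- patients[names(ptmpl)]
  patients$birth_year <- as.integer(patients$birth_year)
  statements$start <- as.Date(statements$start)
  statements$end <- as.Date(statements$end)
  statements$derived <- ifelse(is.na(statements$derived), FALSE, statements$derived)
  structure(list(patients = patients, statements = statements), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$patients), " patients, ", nrow(x$statements),
      " statements\n", sep = "")
  invisible(x)
}

#' Canonical ordering of a cohort
#'
#' Sorts patients by id and statements by patient, kind, scheme, code
#' and date, so that cohorts produced along different mediation paths
#' compare exactly.
#'
#' @param x A [cohort()].
#' @return The cohort with both tables sorted.
#' @export
canonicalize_cohort <- function(x) {
  x$patients <- arrange(x$patients, .data$patient_id)
  x$statements <- arrange(x$statements, .data$patient_id, .data$kind, .data$scheme,
                          .data$code, .data$start, .data$end)
  x
}

finding <- function(severity, path, message) {
  tibble(severity = severity, path = path, message = message)
}

#' Validate a cohort against the common-model invariants
#'
#' Returns findings rather than raising: each finding carries a
#' severity (`error` or `warning`), the record path it concerns and a
#' message. An empty tibble means the cohort is fully valid. When
#' terminologies are supplied, coded values are resolved against them;
#' a code from an unloaded scheme is a warning, an unknown code within
#' a loaded scheme an error.
#'
#' @param x A [cohort()].
#' @param terminologies Optional list of [concept_scheme()] objects.
#' @return Tibble of findings (severity, path, message).
#' @export
validate_records <- function(x, terminologies = NULL) {
  out <- list()
  p <- x$patients
  bad_id <- which(is.na(p$patient_id) | !nzchar(p$patient_id))
  for (i in bad_id) {
    out[[length(out) + 1L]] <- finding("error", paste0("patients[", i, "]"),
                                       "empty patient_id")
  }
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  bad_by <- which(!is.na(p$birth_year) & (p$birth_year < 1900 | p$birth_year > this_year))
  for (i in bad_by) {
    out[[length(out) + 1L]] <- finding("error", paste0("patients[", i, "].birth_year"),
                                       paste0("implausible birth_year ", p$birth_year[i]))
  }
  s <- x$statements
  orphan <- which(!s$patient_id %in% p$patient_id)
  for (i in orphan) {
    out[[length(out) + 1L]] <- finding("error", paste0("statements[", i, "]"),
                                       "statement for unknown patient")
  }
  bad_kind <- which(!s$kind %in% statement_kinds)
  for (i in bad_kind) {
    out[[length(out) + 1L]] <- finding("error", paste0("statements[", i, "].kind"),
                                       paste0("unknown kind '", s$kind[i], "'"))
  }
  bad_interval <- which(!is.na(s$start) & !is.na(s$end) & s$end < s$start)
  for (i in bad_interval) {
    out[[length(out) + 1L]] <- finding("error", paste0("statements[", i, "]"),
                                       "effective_end before effective_start")
  }
  has_value <- !is.na(s$value_num) | !is.na(s$value_code)
  lab_noval <- which(s$kind == "lab_result" & !has_value)
  for (i in lab_noval) {
    out[[length(out) + 1L]] <- finding("error", paste0("statements[", i, "]"),
                                       "lab_result without a value")
  }
  val_nonlab <- which(s$kind != "lab_result" & has_value)
  for (i in val_nonlab) {
    out[[length(out) + 1L]] <- finding("error", paste0("statements[", i, "]"),
                                       "value on a non-lab_result statement")
  }
  if (!is.null(terminologies)) {
    names(terminologies) <- vapply(terminologies, `[[`, "", "scheme_id")
    for (i in seq_len(nrow(s))) {
      sid <- s$scheme[i]
      if (is.na(sid)) next
      sch <- terminologies[[sid]]
      if (is.null(sch)) {
        out[[length(out) + 1L]] <- finding("warning", paste0("statements[", i, "].scheme"),
                                           paste0("scheme '", sid, "' not loaded"))
      } else if (!s$code[i] %in% sch$concepts$code) {
        out[[length(out) + 1L]] <- finding("error", paste0("statements[", i, "].code"),
                                           paste0("code '", s$code[i],
                                                  "' unknown in scheme '", sid, "'"))
      }
    }
  }
  if (!length(out)) {
    return(finding(character(), character(), character())[0, ])
  }
  bind_rows(out)
}

# ---- NDJSON record format ---------------------------------------------------

date_chr <- function(d) ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))

record_to_list <- function(pat, stmts) {
  sl <- lapply(seq_len(nrow(stmts)), function(i) {
    s <- stmts[i, ]
    x <- list(kind = s$kind, scheme = s$scheme, code = s$code)
    if (!is.na(s$label)) x$label <- s$label
    if (!is.na(s$start)) x$start <- date_chr(s$start)
    if (!is.na(s$end)) x$end <- date_chr(s$end)
    if (!is.na(s$value_num)) {
      x$value <- list(num = s$value_num)
      if (!is.na(s$value_unit)) x$value$unit <- s$value_unit
    } else if (!is.na(s$value_code)) {
      x$value <- list(scheme = s$value_scheme, code = s$value_code)
    }
    if (isTRUE(s$derived)) x$derived <- TRUE
    x
  })
  x <- list(patient_id = pat$patient_id)
  if (!is.na(pat$birth_year)) x$birth_year <- pat$birth_year
  if (!is.na(pat$gender)) x$gender <- pat$gender
  if (!is.na(pat$country)) x$country <- pat$country
  x$statements <- sl
  x
}

parse_date_strict <- function(x, where) {
  if (is.null(x)) return(as.Date(NA))
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d) || format(d, "%Y-%m-%d") != x) {
    abort(paste0("invalid date '", x, "' at ", where), class = "casechar_parse_error")
  }
  d
}

list_to_record <- function(x, where) {
  if (is.null(x$patient_id) || !nzchar(x$patient_id)) {
    abort(paste0("missing patient_id at ", where), class = "casechar_parse_error")
  }
  pat <- tibble(patient_id = x$patient_id,
                birth_year = as.integer(x$birth_year %||% NA_integer_),
                gender = x$gender %||% NA_character_,
                country = x$country %||% NA_character_)
  stmts <- purrr::map_dfr(x$statements, function(s) {
    if (is.null(s$kind) || !s$kind %in% statement_kinds) {
      abort(paste0("bad statement kind at ", where), class = "casechar_parse_error")
    }
    tibble(
      patient_id = x$patient_id, kind = s$kind,
      scheme = s$scheme %||% NA_character_, code = s$code %||% NA_character_,
      label = s$label %||% NA_character_,
      start = parse_date_strict(s$start, where),
      end = parse_date_strict(s$end, where),
      value_num = as.double(s$value$num %||% NA_real_),
      value_unit = s$value$unit %||% NA_character_,
      value_scheme = s$value$scheme %||% NA_character_,
      value_code = s$value$code %||% NA_character_,
      derived = isTRUE(s$derived)
    )
  })
  list(patient = pat, statements = stmts)
}

#' Read / write cohort records as newline-delimited JSON
#'
#' One patient record per line: demographics plus a `statements` array.
#' Write then read is an identity on canonicalized cohorts. Schema
#' violations (bad dates, unknown kinds, missing ids) raise a parse
#' error naming the offending line.
#'
#' @param path NDJSON file path.
#' @return [read_records()]: a [cohort()]. [write_records()]: `path`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "casechar_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(cohort())
  }
  recs <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) {
                    abort(paste0("invalid JSON at line ", i, " of ", path),
                          class = "casechar_parse_error")
                  })
    list_to_record(x, paste0("line ", i, " of ", path))
  })
  cohort(
    patients = purrr::map_dfr(recs, "patient"),
    statements = purrr::map_dfr(recs, "statements")
  )
}

#' @rdname read_records
#' @param x A [cohort()].
#' @export
write_records <- function(x, path) {
  x <- canonicalize_cohort(x)
  by_pat <- split(x$statements, factor(x$statements$patient_id,
                                       levels = x$patients$patient_id))
  lines <- vapply(seq_len(nrow(x$patients)), function(i) {
    pat <- x$patients[i, ]
    stmts <- by_pat[[pat$patient_id]] %||% statement_cols()
    jsonlite::toJSON(record_to_list(pat, stmts), auto_unbox = TRUE, digits = NA,
                     null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
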