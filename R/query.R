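#' Eligibility criteria constructors
#'
#' Criteria form an AST. A leaf matches patients having at least one
#' statement of the given kind whose (scheme, code) pair is in the
#' leaf's code set; `qry_and()` / `qry_or()` combine children by set
#' intersection / union; `qry_temporal()` matches patients having an
#' anchor-matching statement and a related-matching statement whose
#' start dates fall within the configured window. Windows are inclusive
#' at both ends: `direction = "after"` means the related statement
#' starts 0 to `window_days` days after the anchor (day 0 counts),
#' `"before"` mirrors this, `"either"` is their union. Temporal anchor
#' and related criteria must be leaves — statement-level matching is
#' only defined for a single coded criterion.
#'
#' @param kind Statement kind (`condition`, `medication`, ...).
#' @param codes Tibble with columns `scheme`, `code` (a single
#'   `c(scheme, code)` pair is also accepted).
#' @param negated If `TRUE` the leaf matches patients with no such
#'   statement.
#' @return A `criteria_node` object.
#' @export
qry_leaf <- function(kind, codes, negated = FALSE) {
  stopifnot(kind %in% statement_kinds)
  if (is.character(codes) && length(codes) == 2L) {
    codes <- tibble(scheme = codes[1], code = codes[2])
  }
  codes <- as_tibble(codes)[c("scheme", "code")]
  structure(list(type = "leaf", kind = kind, codes = distinct(codes),
                 negated = isTRUE(negated)),
            class = "criteria_node")
}

qry_bool <- function(op, children) {
  children <- lapply(children, function(x) {
    stopifnot(inherits(x, "criteria_node"))
    x
  })
  if (length(children) < 2L) {
    abort("boolean criteria need at least 2 children", class = "casechar_config_error")
  }
  structure(list(type = "bool", op = op, children = children), class = "criteria_node")
}

#' @rdname qry_leaf
#' @param ... Child `criteria_node` objects (at least two).
#' @export
qry_and <- function(...) qry_bool("and", list(...))

#' @rdname qry_leaf
#' @export
qry_or <- function(...) qry_bool("or", list(...))

#' @rdname qry_leaf
#' @param anchor,related Leaf criteria defining the anchor and related
#'   statements of a temporal constraint.
#' @param direction `"after"`, `"before"` or `"either"` (related
#'   relative to anchor).
#' @param window_days Non-negative integer window width in days.
#' @export
qry_temporal <- function(anchor, related, direction = c("after", "before", "either"),
                         window_days) {
  direction <- match.arg(direction)
  stopifnot(inherits(anchor, "criteria_node"), inherits(related, "criteria_node"))
  if (anchor$type != "leaf" || related$type != "leaf") {
    abort("temporal anchor/related must be leaf criteria",
          class = "casechar_config_error")
  }
  if (!is.numeric(window_days) || window_days < 0) {
    abort("window_days must be >= 0", class = "casechar_config_error")
  }
  structure(list(type = "temporal", anchor = anchor, related = related,
                 direction = direction, window_days = as.integer(window_days)),
            class = "criteria_node")
}

#' @export
print.criteria_node <- function(x, ...) {
  cat(format_criteria(x), sep = "\n")
  invisible(x)
}

format_criteria <- function(x, indent = "") {
  switch(x$type,
    leaf = paste0(indent, if (x$negated) "NOT " else "", x$kind, " {",
                  paste(paste0(x$codes$scheme, ":", x$codes$code), collapse = ", "), "}"),
    bool = c(paste0(indent, toupper(x$op)),
             unlist(lapply(x$children, format_criteria, indent = paste0(indent, "  ")))),
    temporal = c(paste0(indent, "WITHIN ", x$window_days, "d (", x$direction, ")"),
                 format_criteria(x$anchor, paste0(indent, "  anchor: ")),
                 format_criteria(x$related, paste0(indent, "  related: ")))
  )
}

#' Normalize a criteria tree
#'
#' Flattens nested boolean nodes of the same operator (an AND inside an
#' AND contributes its children directly). Idempotent; leaves and
#' temporal nodes are untouched.
#'
#' @param x A `criteria_node`.
#' @return The normalized `criteria_node`.
#' @export
qry_normalize <- function(x) {
  if (x$type != "bool") {
    return(x)
  }
  kids <- lapply(x$children, qry_normalize)
  flat <- list()
  for (k in kids) {
    if (k$type == "bool" && k$op == x$op) {
      flat <- c(flat, k$children)
    } else {
      flat <- c(flat, list(k))
    }
  }
  structure(list(type = "bool", op = x$op, children = flat), class = "criteria_node")
}

query_leaves <- function(x) {
  switch(x$type,
    leaf = list(x),
    bool = unlist(lapply(x$children, query_leaves), recursive = FALSE),
    temporal = c(list(x$anchor), list(x$related))
  )
}

# ---- study definition YAML --------------------------------------------------

parse_criteria_yaml <- function(x) {
  if (!is.null(x$op)) {
    kids <- lapply(x$children, parse_criteria_yaml)
    return(qry_bool(tolower(x$op), kids))
  }
  if (!is.null(x$anchor)) {
    return(qry_temporal(parse_criteria_yaml(x$anchor), parse_criteria_yaml(x$related),
                        direction = x$direction %||% "after",
                        window_days = x$window_days))
  }
  qry_leaf(x$kind, tibble(scheme = x$scheme, code = unlist(x$codes)),
           negated = isTRUE(x$negated))
}

#' Read a study definition
#'
#' A study definition configures one comparative characterization run:
#' foreground and background eligibility criteria, the grouping scheme
#' and level per statement kind, the statistics boxes to compute, risk
#' factor codes and the index-anchor criterion (whose earliest match
#' per patient defines the index date for before/after boxes). The
#' YAML mirrors the structure 1:1; see the shipped demo study in
#' `inst/extdata`.
#'
#' @param path YAML file path.
#' @return An object of class `study_definition`.
#' @export
read_study <- function(path) {
  y <- yaml::read_yaml(path)
  study_definition(
    study_id = y$study_id %||% "study",
    foreground = parse_criteria_yaml(y$foreground),
    background = parse_criteria_yaml(y$background),
    grouping = lapply(y$grouping, function(g) list(scheme = g$scheme, level = g$level)),
    statistics = unlist(y$statistics),
    risk_factors = purrr::map_dfr(y$risk_factors, function(r) {
      tibble(scheme = r$scheme, code = r$code, label = r$label %||% r$code)
    }),
    index_anchor = if (!is.null(y$index_anchor)) parse_criteria_yaml(y$index_anchor),
    reference_date = as.Date(y$reference_date %||% NA)
  )
}

#' @rdname read_study
#' @param study_id Short study identifier.
#' @param foreground,background Criteria trees ([qry_leaf()] and friends).
#' @param grouping Named list (by statement kind) of
#'   `list(scheme, level)` grouping configs.
#' @param statistics Character vector of requested boxes (`age`,
#'   `gender`, `country`, `common_conditions`, `common_medications`,
#'   `conditions_before_index`, `conditions_after_index`, ...).
#' @param risk_factors Tibble `scheme`, `code`, `label`.
#' @param index_anchor Leaf criterion defining the index date.
#' @param reference_date Date used for age computation.
#' @export
study_definition <- function(study_id, foreground, background, grouping,
                             statistics, risk_factors = NULL, index_anchor = NULL,
                             reference_date = as.Date(NA)) {
  if (!length(statistics)) {
    abort("statistics list must be non-empty", class = "casechar_config_error")
  }
  structure(
    list(study_id = study_id, foreground = foreground, background = background,
         grouping = grouping, statistics = statistics,
         risk_factors = risk_factors %||% tibble(scheme = character(),
                                                 code = character(),
                                                 label = character()),
         index_anchor = index_anchor, reference_date = reference_date),
    class = "study_definition"
  )
}
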