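# One-to-one formalization of a source XML document: every element
# becomes a node, every attribute (and non-blank text) a literal, so no
# information is lost before declarative conversion rules are applied.

#' Formalize a patient-summary XML document into a node graph
#'
#' Produces a lossless one-to-one graph representation of the document:
#' `nodes` (id, element name), `edges` (parent, child-element-name,
#' child, in document order), `literals` (node, attribute name, value;
#' non-blank text content is stored under `#text`) and the root id.
#' [ngraph_to_xml()] deterministically re-generates an XML document
#' equal to the input up to attribute order and whitespace.
#'
#' @param path Path to an XML file (or an `xml_document`).
#' @return An object of class `node_graph`.
#' @export
formalize_xml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else {
    tryCatch(xml2::read_xml(path),
             error = function(e) {
               abort(paste0("malformed XML in ", path, ": ", conditionMessage(e)),
                     class = "casechar_parse_error")
             })
  }
  # bulk extraction (documents run to tens of thousands of nodes;
  # per-node recursion in R would dominate runtime): every element in
  # document order, parent linkage recovered from unique XPaths
  all_el <- xml2::xml_find_all(doc, "//*")
  n <- length(all_el)
  ids <- sprintf("n%06d", seq_len(n))
  names_ <- xml2::xml_name(all_el)
  paths <- xml2::xml_path(all_el)
  parent_path <- sub("/[^/]+$", "", paths)
  pidx <- match(parent_path, paths)  # NA for the root
  has_parent <- !is.na(pidx)
  attrs <- xml2::xml_attrs(all_el)
  n_at <- lengths(attrs)
  l_node <- rep(ids, n_at)
  l_attr <- as.character(unlist(lapply(attrs, names), use.names = FALSE))
  l_value <- as.character(unlist(attrs, use.names = FALSE))
  if (!length(l_node)) {
    l_node <- l_attr <- l_value <- character()
  }
  is_leaf <- xml2::xml_length(all_el) == 0L
  txt <- xml2::xml_text(all_el)
  has_text <- is_leaf & nzchar(trimws(txt))
  structure(
    list(nodes = tibble(id = ids, name = names_),
         edges = tibble(parent = ids[pidx[has_parent]],
                        name = names_[has_parent],
                        child = ids[has_parent]),
         literals = tibble(
           node = c(l_node, ids[has_text]),
           attr = c(l_attr, rep("#text", sum(has_text))),
           value = c(l_value, txt[has_text])),
         root = ids[which(!has_parent)[1]]),
    class = "node_graph"
  )
}

#' @export
print.node_graph <- function(x, ...) {
  cat("<node_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges, ",
      nrow(x$literals), " literals\n", sep = "")
  invisible(x)
}

#' @rdname formalize_xml
#' @param graph A `node_graph`.
#' @return [ngraph_to_xml()]: an `xml2::xml_document`.
#' @export
ngraph_to_xml <- function(graph) {
  name_of <- stats::setNames(graph$nodes$name, graph$nodes$id)
  lits <- split(graph$literals, graph$literals$node)
  kids <- split(graph$edges, graph$edges$parent)
  build <- function(parent_xml, id) {
    el <- xml2::xml_add_child(parent_xml, name_of[[id]])
    lt <- lits[[id]]
    if (!is.null(lt)) {
      for (i in seq_len(nrow(lt))) {
        if (lt$attr[i] == "#text") {
          xml2::xml_text(el) <- lt$value[i]
        } else {
          xml2::xml_set_attr(el, lt$attr[i], lt$value[i])
        }
      }
    }
    ch <- kids[[id]]
    if (!is.null(ch)) {
      for (c_id in ch$child) build(el, c_id)
    }
    el
  }
  doc <- xml2::xml_new_root(name_of[[graph$root]])
  lt <- lits[[graph$root]]
  if (!is.null(lt)) {
    for (i in seq_len(nrow(lt))) {
      if (lt$attr[i] == "#text") xml2::xml_text(doc) <- lt$value[i]
      else xml2::xml_set_attr(doc, lt$attr[i], lt$value[i])
    }
  }
  ch <- kids[[graph$root]]
  if (!is.null(ch)) for (c_id in ch$child) build(doc, c_id)
  xml2::xml_root(doc)
}

# ---- conversion rules -------------------------------------------------------

rule_fields <- list(
  patient = c("patient_id", "birth_year", "gender", "country"),
  statement = c("patient_id", "code", "scheme_raw", "scheme", "label",
                "start", "end", "value_num", "value_unit")
)

#' Read declarative conversion rules
#'
#' Rules are YAML: each rule names a `target` (either `patient` or a
#' statement kind), a `match` pattern and a `bind` map from source
#' locations to common-model fields. For the XML dialect the pattern is
#' an element path from the root with optional attribute predicates
#' (`a/b[@type=problems]/observation`) and bindings are relative paths
#' ending in an attribute (`code/@code`), `@attr` for the matched node
#' itself, or `^el/@attr` for the nearest ancestor named `el`. For the
#' relational dialect the pattern is a table name and bindings are
#' column names. Patterns stay declarative: no embedded code.
#'
#' @param path YAML rule file.
#' @return A list of validated rules (class `conversion_rules`).
#' @export
read_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  validate_rules(rules)
}

validate_rules <- function(rules) {
  for (r in rules) {
    if (is.null(r$target) || !(r$target %in% c("patient", statement_kinds))) {
      abort(paste0("rule target must be 'patient' or a statement kind, got '",
                   r$target %||% "<missing>", "'"),
            class = "casechar_config_error")
    }
    allowed <- if (r$target == "patient") rule_fields$patient else rule_fields$statement
    bad <- setdiff(names(r$bind), allowed)
    if (length(bad)) {
      abort(paste0("rule for '", r$target, "' binds unknown field(s): ",
                   paste(bad, collapse = ", ")),
            class = "casechar_config_error")
    }
    if (is.null(r$match)) {
      abort("rule without a match pattern", class = "casechar_config_error")
    }
  }
  structure(rules, class = "conversion_rules")
}

# Split "a/b[@type=problems]/c" into segments with predicates.
parse_path <- function(pattern) {
  segs <- strsplit(pattern, "/", fixed = TRUE)[[1]]
  lapply(segs, function(s) {
    preds <- list()
    m <- regmatches(s, gregexpr("\\[@[^]]+\\]", s))[[1]]
    for (p in m) {
      kv <- sub("^\\[@([^=]+)=([^]]*)\\]$", "\\1\x01\\2", p)
      kv <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
      preds[[kv[1]]] <- kv[2]
    }
    list(name = sub("\\[.*$", "", s), preds = preds)
  })
}

# hashed-environment maps: node-id lookups must be O(1), documents run
# to tens of thousands of nodes
graph_index <- function(graph) {
  as_env <- function(x) list2env(x, hash = TRUE, parent = emptyenv())
  parent <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(graph$edges))) {
    assign(graph$edges$child[i], graph$edges$parent[i], envir = parent)
  }
  name_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(graph$nodes))) {
    assign(graph$nodes$id[i], graph$nodes$name[i], envir = name_of)
  }
  list(
    kids = as_env(split(graph$edges, graph$edges$parent)),
    lits = as_env(split(graph$literals, graph$literals$node)),
    parent = parent,
    name_of = name_of
  )
}

ix_get <- function(env, id) get0(id, envir = env, ifnotfound = NULL)

ix_parent <- function(ix, id) {
  get0(id, envir = ix$parent, ifnotfound = NA_character_)
}

lit_value <- function(ix, id, attr) {
  lt <- ix_get(ix$lits, id)
  if (is.null(lt)) return(NA_character_)
  v <- lt$value[lt$attr == attr]
  if (length(v)) v[1] else NA_character_
}

seg_matches <- function(ix, id, seg) {
  if (ix_get(ix$name_of, id) != seg$name) return(FALSE)
  for (a in names(seg$preds)) {
    if (!identical(lit_value(ix, id, a), seg$preds[[a]])) return(FALSE)
  }
  TRUE
}

match_path <- function(graph, ix, pattern) {
  segs <- parse_path(pattern)
  frontier <- if (seg_matches(ix, graph$root, segs[[1]])) graph$root else character()
  for (seg in segs[-1]) {
    nxt <- character()
    for (id in frontier) {
      ch <- ix_get(ix$kids, id)
      if (is.null(ch)) next
      for (c_id in ch$child) {
        if (seg_matches(ix, c_id, seg)) nxt <- c(nxt, c_id)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  frontier
}

# Resolve a binding path relative to node `id`; returns the value and
# the ids of nodes traversed (for residue accounting).
resolve_binding <- function(graph, ix, id, path) {
  used <- character()
  if (startsWith(path, "^")) {
    spec <- sub("^\\^", "", path)
    parts <- strsplit(spec, "/@", fixed = TRUE)[[1]]
    cur <- id
    repeat {
      cur <- ix_parent(ix, cur)
      if (is.na(cur)) return(list(value = NA_character_, used = used))
      if (ix_get(ix$name_of, cur) == parts[1]) break
    }
    return(list(value = lit_value(ix, cur, parts[2]), used = used))
  }
  if (startsWith(path, "@")) {
    return(list(value = lit_value(ix, id, sub("^@", "", path)), used = used))
  }
  parts <- strsplit(path, "/@", fixed = TRUE)[[1]]
  segs <- strsplit(parts[1], "/", fixed = TRUE)[[1]]
  cur <- id
  for (s in segs) {
    ch <- ix_get(ix$kids, cur)
    hit <- NULL
    if (!is.null(ch)) {
      for (c_id in ch$child) {
        if (ix_get(ix$name_of, c_id) == s) { hit <- c_id; break }
      }
    }
    if (is.null(hit)) return(list(value = NA_character_, used = used))
    cur <- hit
    used <- c(used, cur)
  }
  attr_name <- if (length(parts) > 1L) parts[2] else "#text"
  list(value = lit_value(ix, cur, attr_name), used = used)
}

parse_rule_date <- function(x, fmt, where, findings) {
  if (is.na(x)) return(list(date = as.Date(NA), findings = findings))
  d <- as.Date(x, format = fmt)
  if (is.na(d)) {
    findings[[length(findings) + 1L]] <-
      finding("warning", where, paste0("unparseable date '", x, "'; kept without date"))
  }
  list(date = d, findings = findings)
}

#' Apply conversion rules to a formalized document
#'
#' Runs every rule's pattern over the node graph; each match emits
#' exactly one demographic assignment or clinical statement. Raw
#' code-system identifiers bound via `scheme_raw` are normalized to
#' scheme ids through `scheme_lookup`. Unmatched source content is not
#' converted but reported in the residue table (element path + count).
#' Rule application is order-independent: the output cohort is
#' canonically sorted.
#'
#' @param graph A `node_graph` from [formalize_xml()].
#' @param rules A `conversion_rules` object ([read_rules()]).
#' @param scheme_lookup Tibble with columns `system_id`, `scheme_id`
#'   translating source code-system identifiers (OID-like strings) to
#'   scheme ids; defaults to the table shipped with the package.
#' @return List with elements `cohort`, `findings` (tibble) and
#'   `residue` (tibble of unconverted element paths + counts).
#' @export
apply_rules <- function(graph, rules, scheme_lookup = default_scheme_lookup()) {
  rules <- validate_rules(unclass(rules))
  ix <- graph_index(graph)
  findings <- list()
  patients <- list(); stmts <- list()
  consumed <- list()
  for (r in rules) {
    fmt <- r$date_format %||% "%Y%m%d"
    hits <- match_path(graph, ix, r$match)
    if (!length(hits)) next
    consumed[[length(consumed) + 1L]] <- hits
    # one value vector per bound field, one entry per matched node
    vals <- lapply(r$bind, function(path) {
      unname(vapply(hits, function(id) {
        res <- resolve_binding(graph, ix, id, path)
        if (length(res$used)) {
          consumed[[length(consumed) + 1L]] <<- res$used
        }
        res$value
      }, ""))
    })
    get_field <- function(field) {
      vals[[field]] %||% rep(NA_character_, length(hits))
    }
    if (r$target == "patient") {
      patients[[length(patients) + 1L]] <- tibble(
        patient_id = get_field("patient_id"),
        birth_year = as.integer(get_field("birth_year")),
        gender = get_field("gender"),
        country = get_field("country")
      )
    } else {
      scheme <- get_field("scheme")
      raw <- get_field("scheme_raw")
      has_raw <- !is.na(raw)
      if (any(has_raw)) {
        m <- match(raw, scheme_lookup$system_id)
        scheme[has_raw] <- ifelse(is.na(m[has_raw]), raw[has_raw],
                                  scheme_lookup$scheme_id[m[has_raw]])
        for (id in hits[has_raw & is.na(m)]) {
          findings[[length(findings) + 1L]] <- finding(
            "warning", paste0(r$match, "[", id, "]"),
            paste0("unknown code system; kept verbatim"))
        }
      }
      parse_dates <- function(x, what) {
        d <- as.Date(x, format = fmt)
        bad <- which(!is.na(x) & is.na(d))
        for (i in bad) {
          findings[[length(findings) + 1L]] <<- finding(
            "warning", paste0(r$match, "[", hits[i], "].", what),
            paste0("unparseable date '", x[i], "'; kept without date"))
        }
        d
      }
      stmts[[length(stmts) + 1L]] <- tibble(
        patient_id = get_field("patient_id"),
        kind = r$target, scheme = scheme, code = get_field("code"),
        label = get_field("label"),
        start = parse_dates(get_field("start"), "start"),
        end = parse_dates(get_field("end"), "end"),
        value_num = as.double(get_field("value_num")),
        value_unit = get_field("value_unit"),
        derived = FALSE
      )
    }
  }
  out <- cohort(
    patients = if (length(patients)) distinct(bind_rows(patients)) else patient_cols(),
    statements = if (length(stmts)) bind_rows(stmts) else statement_cols()
  )
  residue <- residue_report(graph, ix, unique(unlist(consumed, use.names = FALSE)))
  list(cohort = canonicalize_cohort(out),
       findings = if (length(findings)) bind_rows(findings) else
         finding(character(), character(), character())[0, ],
       residue = residue)
}

node_path <- function(ix, id) {
  parts <- ix_get(ix$name_of, id)
  cur <- id
  repeat {
    cur <- ix_parent(ix, cur)
    if (is.na(cur)) break
    parts <- c(ix_get(ix$name_of, cur), parts)
  }
  paste(parts, collapse = "/")
}

# Residue = maximal subtrees never touched by any rule. A node is
# covered when it or a descendant was consumed; residue roots are the
# uncovered nodes whose parent is covered.
residue_report <- function(graph, ix, consumed) {
  covered <- new.env(hash = TRUE, parent = emptyenv())
  for (id in consumed) assign(id, TRUE, envir = covered)
  frontier <- consumed
  while (length(frontier)) {
    nxt <- character()
    for (i in frontier) {
      p <- ix_parent(ix, i)
      if (!is.na(p) && is.null(get0(p, envir = covered, ifnotfound = NULL))) {
        assign(p, TRUE, envir = covered)
        nxt <- c(nxt, p)
      }
    }
    frontier <- nxt
  }
  is_covered <- function(id) !is.null(get0(id, envir = covered, ifnotfound = NULL))
  all_ids <- graph$nodes$id
  uncovered <- all_ids[!vapply(all_ids, is_covered, TRUE)]
  roots <- uncovered[vapply(uncovered, function(i) {
    p <- ix_parent(ix, i)
    is.na(p) || is_covered(p)
  }, TRUE)]
  if (!length(roots)) {
    return(tibble(path = character(), count = integer()))
  }
  paths <- unname(vapply(roots, function(i) node_path(ix, i), ""))
  count(tibble(path = paths), .data$path, name = "count")
}

#' Default code-system lookup table
#'
#' Maps OID-like code-system identifiers appearing in source XML to
#' common-model scheme ids. The shipped table covers the demo schemes;
#' [emit_source_dialects()] writes the matching table next to emitted
#' XML so the lookup always travels with the data.
#'
#' @param path Optional TSV path (`system_id  scheme_id`).
#' @return Tibble with columns `system_id`, `scheme_id`.
#' @export
default_scheme_lookup <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_systems.tsv", package = "casechar")
  as_tibble(readr::read_tsv(path, col_types = "cc", progress = FALSE))
}

# Stable OID-like identifier for a scheme, used when emitting the XML dialect.
scheme_oid <- function(scheme_id) {
  paste0("2.25.", fnv1a32(scheme_id))
}

#' Convert relational source tables to the common model
#'
#' The relational dialect is a set of CSV tables (`patients` plus one
#' table per statement kind) with ISO-8601 dates. Rules bind columns to
#' common-model fields. Rows whose `patient_id` does not resolve
#' against the patients table are skipped with a finding (foreign-key
#' violation), never converted silently.
#'
#' @param tables Named list of tibbles (or a directory path containing
#'   `<name>.csv` files).
#' @param rules `conversion_rules` whose `match` fields name tables.
#' @return Same structure as [apply_rules()] (`residue` lists unused
#'   tables/columns).
#' @export
convert_relational <- function(tables, rules) {
  if (is.character(tables)) {
    files <- list.files(tables, pattern = "\\.csv$", full.names = TRUE)
    nms <- sub("\\.csv$", "", basename(files))
    tables <- stats::setNames(lapply(files, function(f) {
      as_tibble(readr::read_csv(f, col_types = readr::cols(.default = readr::col_character()),
                                progress = FALSE))
    }), nms)
  }
  rules <- validate_rules(unclass(rules))
  if (!"patients" %in% names(tables)) {
    abort("mandatory table 'patients' missing", class = "casechar_parse_error")
  }
  findings <- list()
  patients <- patient_cols(); stmts <- list()
  used_tables <- character()
  known_ids <- character()
  # patient rules first so foreign keys can be checked
  ord <- order(vapply(rules, function(r) r$target != "patient", TRUE))
  for (r in rules[ord]) {
    tab <- tables[[r$match]]
    if (is.null(tab)) {
      abort(paste0("rule references missing table '", r$match, "'"),
            class = "casechar_parse_error")
    }
    used_tables <- c(used_tables, r$match)
    bad_cols <- setdiff(unlist(r$bind), names(tab))
    if (length(bad_cols)) {
      abort(paste0("table '", r$match, "' lacks column(s): ",
                   paste(bad_cols, collapse = ", ")),
            class = "casechar_config_error")
    }
    fmt <- r$date_format %||% "%Y-%m-%d"
    col <- function(field) {
      cn <- r$bind[[field]]
      if (is.null(cn)) rep(NA_character_, nrow(tab)) else tab[[cn]]
    }
    if (r$target == "patient") {
      patients <- bind_rows(patients, tibble(
        patient_id = col("patient_id"),
        birth_year = as.integer(col("birth_year")),
        gender = col("gender"), country = col("country")
      ))
      known_ids <- patients$patient_id
    } else {
      pid <- col("patient_id")
      dangling <- !pid %in% known_ids
      for (i in which(dangling)) {
        findings[[length(findings) + 1L]] <- finding(
          "warning", paste0(r$match, "[row ", i, "]"),
          paste0("dangling patient_id '", pid[i], "'; row skipped"))
      }
      keep <- which(!dangling)
      if (length(keep)) {
        parse_iso <- function(x) as.Date(x, format = fmt)
        stmts[[length(stmts) + 1L]] <- tibble(
          patient_id = pid[keep], kind = r$target,
          scheme = col("scheme")[keep], code = col("code")[keep],
          label = col("label")[keep],
          start = parse_iso(col("start")[keep]), end = parse_iso(col("end")[keep]),
          value_num = as.double(col("value_num")[keep]),
          value_unit = col("value_unit")[keep],
          derived = FALSE
        )
      }
    }
  }
  residue_tabs <- setdiff(names(tables), unique(used_tables))
  residue <- tibble(path = residue_tabs,
                    count = vapply(tables[residue_tabs], nrow, 0L))
  out <- cohort(patients = distinct(patients),
                statements = if (length(stmts)) bind_rows(stmts) else statement_cols())
  list(cohort = canonicalize_cohort(out),
       findings = if (length(findings)) bind_rows(findings) else
         finding(character(), character(), character())[0, ],
       residue = residue)
}
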