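#' Construct a concept scheme
#'
#' A concept scheme is one terminology system: an ordered set of named
#' levels (broadest first, e.g. a SOC > HLGT > HLT > PT analogue) and a
#' table of coded concepts, each at a declared level and optionally
#' linked to broader (parent) concepts within the same scheme. Levels
#' are declared per scheme rather than inferred from depth because real
#' terminologies have uneven depth; the broader graph may have multiple
#' parents per concept (multiaxial hierarchies) but must stay acyclic.
#'
#' @param scheme_id Short string identifying the scheme.
#' @param level_names Character vector of level labels, broadest first;
#'   non-empty and unique.
#' @param concepts Tibble with columns `code`, `label`, `level` and
#'   `broader` (a list-column of parent code character vectors, or a
#'   `|`-separated string column).
#' @return An object of class `concept_scheme`.
#' @export
concept_scheme <- function(scheme_id, level_names, concepts) {
  stopifnot(is.character(scheme_id), length(scheme_id) == 1L, nzchar(scheme_id))
  if (length(level_names) == 0L || anyDuplicated(level_names)) {
    abort("`level_names` must be non-empty and unique", class = "casechar_integrity_error")
  }
  concepts <- as_tibble(concepts)
  if (!all(c("code", "label", "level") %in% names(concepts))) {
    abort("`concepts` needs columns code, label, level", class = "casechar_integrity_error")
  }
  if (!"broader" %in% names(concepts)) {
    concepts$broader <- rep(list(character()), nrow(concepts))
  }
  if (is.character(concepts$broader)) {
    concepts$broader <- lapply(concepts$broader, function(x) {
      if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
    })
  }
  scheme <- structure(
    list(scheme_id = scheme_id, level_names = as.character(level_names),
         concepts = concepts),
    class = "concept_scheme"
  )
  validate_scheme(scheme)
}

validate_scheme <- function(scheme) {
  con <- scheme$concepts
  if (any(!nzchar(con$code)) || anyNA(con$code)) {
    abort("concept codes must be non-empty", class = "casechar_integrity_error")
  }
  if (anyDuplicated(con$code)) {
    abort(paste0("duplicate concept codes in scheme '", scheme$scheme_id, "'"),
          class = "casechar_integrity_error")
  }
  bad_level <- setdiff(unique(con$level), scheme$level_names)
  if (length(bad_level)) {
    abort(paste0("undeclared level(s): ", paste(bad_level, collapse = ", ")),
          class = "casechar_integrity_error")
  }
  level_rank <- stats::setNames(seq_along(scheme$level_names), scheme$level_names)
  rank <- level_rank[con$level]
  idx <- stats::setNames(seq_len(nrow(con)), con$code)
  for (i in seq_len(nrow(con))) {
    for (p in con$broader[[i]]) {
      j <- unname(idx[p])
      if (is.na(j)) {
        abort(paste0("broader edge from '", con$code[i], "' to absent code '", p, "'"),
              class = "casechar_integrity_error")
      }
      if (rank[[j]] >= rank[[i]]) {
        abort(paste0("broader parent '", p, "' of '", con$code[i],
                     "' is not at a strictly broader level"),
              class = "casechar_integrity_error")
      }
    }
  }
  g <- scheme_graph(scheme)
  if (igraph::ecount(g) > 0 && !igraph::is_dag(g)) {
    abort(paste0("broader graph of scheme '", scheme$scheme_id, "' has a cycle"),
          class = "casechar_integrity_error")
  }
  scheme
}

#' @export
print.concept_scheme <- function(x, ...) {
  cat("<concept_scheme> ", x$scheme_id, ": ", nrow(x$concepts), " concepts, levels ",
      paste(x$level_names, collapse = " > "), "\n", sep = "")
  invisible(x)
}

# igraph with edges child -> parent (i.e. along `broader`).
scheme_graph <- function(scheme) {
  con <- scheme$concepts
  n_par <- lengths(con$broader)
  edges <- cbind(rep(con$code, n_par), unlist(con$broader))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(con$code)
  if (length(edges)) {
    g <- g + igraph::edges(t(edges))
  }
  g
}

check_code <- function(scheme, code) {
  if (!code %in% scheme$concepts$code) {
    abort(paste0("unknown code '", code, "' in scheme '", scheme$scheme_id, "'"),
          class = "casechar_lookup_error")
  }
  invisible(TRUE)
}

#' Transitive narrower descendants of a code
#'
#' All codes reachable from `code` by following broader edges backwards
#' (i.e. the code's narrower subtree), excluding the code itself.
#'
#' @param scheme A [concept_scheme()].
#' @param code Code within the scheme.
#' @return Character vector of descendant codes (possibly empty).
#' @export
descendants <- function(scheme, code) {
  check_code(scheme, code)
  g <- scheme_graph(scheme)
  reach <- igraph::subcomponent(g, code, mode = "in")
  setdiff(names(reach), code)
}

#' Ancestors of a code at an exact level
#'
#' Transitive broader ancestors filtered to exactly `level`; the code
#' itself is included when it already sits at that level.
#'
#' @inheritParams descendants
#' @param level A level label declared by the scheme.
#' @return Character vector of codes at `level` (possibly empty).
#' @export
ancestors_at_level <- function(scheme, code, level) {
  check_code(scheme, code)
  if (!level %in% scheme$level_names) {
    abort(paste0("unknown level '", level, "' in scheme '", scheme$scheme_id, "'"),
          class = "casechar_config_error")
  }
  g <- scheme_graph(scheme)
  reach <- names(igraph::subcomponent(g, code, mode = "out"))
  con <- scheme$concepts
  reach[con$level[match(reach, con$code)] == level]
}

# ---- file formats -----------------------------------------------------------

#' Read a terminology scheme file
#'
#' The native format is TSV with a scheme header block:
#' ```
#' #scheme_id<TAB>MEDC
#' #levels<TAB>soc|hlgt|hlt|pt
#' code<TAB>label<TAB>level<TAB>broader
#' ```
#' where `broader` holds `|`-separated parent codes. Files ending in
#' `.ttl` are parsed as the Turtle-like interchange serialization
#' (skos:Concept / skos:broader / skos:inScheme vocabulary).
#'
#' @param path Path to a scheme file.
#' @return A [concept_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "casechar_parse_error")
  }
  if (grepl("\\.ttl$", path)) {
    return(read_scheme_ttl(path))
  }
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  get_h <- function(key) {
    row <- grep(paste0("^#", key, "\t"), header, value = TRUE)
    if (length(row) != 1L) {
      abort(paste0("scheme file missing '#", key, "' header: ", path),
            class = "casechar_parse_error")
    }
    sub(paste0("^#", key, "\t"), "", row)
  }
  scheme_id <- get_h("scheme_id")
  levels <- strsplit(get_h("levels"), "|", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body) || body[1] != "code\tlabel\tlevel\tbroader") {
    abort(paste0("malformed column header in ", path), class = "casechar_parse_error")
  }
  # keep trailing empty fields (broader is often blank)
  rows <- strsplit(paste0(body[-1], "\t\x03"), "\t", fixed = TRUE)
  rows <- lapply(rows, function(r) r[-length(r)])
  bad <- which(lengths(rows) != 4L)
  if (length(bad)) {
    abort(paste0("malformed row at line ", which(lines == body[-1][bad[1]])[1],
                 " of ", path),
          class = "casechar_parse_error")
  }
  concepts <- tibble(
    code = vapply(rows, `[[`, "", 1L),
    label = vapply(rows, `[[`, "", 2L),
    level = vapply(rows, `[[`, "", 3L),
    broader = vapply(rows, `[[`, "", 4L)
  )
  concept_scheme(scheme_id, levels, concepts)
}

#' Write a terminology scheme file
#'
#' @param scheme A [concept_scheme()].
#' @param path Destination; a `.ttl` suffix selects the Turtle-like
#'   interchange serialization.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  if (grepl("\\.ttl$", path)) {
    return(write_scheme_ttl(scheme, path))
  }
  con <- scheme$concepts
  lines <- c(
    paste0("#scheme_id\t", scheme$scheme_id),
    paste0("#levels\t", paste(scheme$level_names, collapse = "|")),
    "code\tlabel\tlevel\tbroader",
    paste(con$code, con$label, con$level,
          vapply(con$broader, paste, "", collapse = "|"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

# Minimal Turtle-like serialization: one concept per block using
# skos:Concept / skos:prefLabel / skos:inScheme / skos:broader and a
# casechar:level annotation. Round-trips exactly with read_scheme_ttl.
write_scheme_ttl <- function(scheme, path) {
  con <- scheme$concepts
  head <- c(
    "@prefix skos: <http://www.w3.org/2004/02/skos/core#> .",
    paste0("<scheme:", scheme$scheme_id, "> a skos:ConceptScheme ; casechar:levels \"",
           paste(scheme$level_names, collapse = "|"), "\" ."),
    ""
  )
  blocks <- vapply(seq_len(nrow(con)), function(i) {
    b <- con$broader[[i]]
    paste0(
      "<code:", con$code[i], "> a skos:Concept ;\n",
      "  skos:prefLabel \"", con$label[i], "\" ;\n",
      "  casechar:level \"", con$level[i], "\" ;\n",
      if (length(b)) {
        paste0(paste0("  skos:broader <code:", b, "> ;", collapse = "\n"), "\n")
      } else "",
      "  skos:inScheme <scheme:", scheme$scheme_id, "> ."
    )
  }, "")
  writeLines(c(head, blocks), path)
  invisible(path)
}

read_scheme_ttl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sch <- grep("skos:ConceptScheme", lines, value = TRUE)
  if (length(sch) != 1L) {
    abort(paste0("expected exactly one skos:ConceptScheme in ", path),
          class = "casechar_parse_error")
  }
  scheme_id <- sub("^<scheme:([^>]+)>.*$", "\\1", sch)
  levels <- strsplit(sub('.*casechar:levels "([^"]*)".*', "\\1", sch), "|",
                     fixed = TRUE)[[1]]
  starts <- grep("^<code:[^>]+> a skos:Concept", lines)
  concepts <- purrr::map_dfr(starts, function(s) {
    code <- sub("^<code:([^>]+)>.*$", "\\1", lines[s])
    block <- lines[s:min(length(lines), s + 20L)]
    end <- which(grepl("skos:inScheme", block))[1]
    block <- block[seq_len(end)]
    lab <- sub('.*skos:prefLabel "([^"]*)".*', "\\1",
               grep("skos:prefLabel", block, value = TRUE)[1])
    lev <- sub('.*casechar:level "([^"]*)".*', "\\1",
               grep("casechar:level", block, value = TRUE)[1])
    broader <- sub("^.*skos:broader <code:([^>]+)>.*$", "\\1",
                   grep("skos:broader", block, value = TRUE))
    tibble(code = code, label = lab, level = lev, broader = list(broader))
  })
  concept_scheme(scheme_id, levels, concepts)
}

#' Read / write cross-scheme mapping assertion files
#'
#' Mapping files are TSV with columns `source_scheme`, `source_code`,
#' `target_scheme`, `target_code`, `relation`. Each row is a directed,
#' source-tagged close-strength link between concepts of two schemes
#' (the relation tag names the curated mapping set it came from, e.g.
#' `omop_like`, `protect_like`, `crossmap_like`, `identical_code`).
#'
#' @param path TSV file path.
#' @return Tibble of mapping assertions.
#' @export
read_mappings <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("source_scheme", "source_code", "target_scheme", "target_code", "relation")
  if (!all(need %in% names(m))) {
    abort(paste0("mapping file missing columns: ",
                 paste(setdiff(need, names(m)), collapse = ", ")),
          class = "casechar_parse_error")
  }
  as_tibble(m[need])
}

#' @rdname read_mappings
#' @param mappings Tibble of mapping assertions.
#' @export
write_mappings <- function(mappings, path) {
  readr::write_tsv(mappings, path, progress = FALSE)
  invisible(path)
}
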