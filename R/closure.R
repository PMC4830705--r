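empty_closure <- function(kind = character()) {
  tibble(kind = kind, scheme_a = character(), code_a = character(),
         scheme_b = character(), code_b = character())[0, ]
}

sort_closure <- function(links) {
  arrange(links, .data$kind, .data$scheme_a, .data$code_a, .data$scheme_b, .data$code_b)
}

check_assertions <- function(schemes, assertions) {
  scheme_ids <- vapply(schemes, `[[`, "", "scheme_id")
  names(schemes) <- scheme_ids
  resolves <- function(s, c) {
    s %in% scheme_ids && c %in% schemes[[s]]$concepts$code
  }
  bad <- !mapply(resolves, assertions$source_scheme, assertions$source_code) |
    !mapply(resolves, assertions$target_scheme, assertions$target_code)
  if (any(bad)) {
    offending <- assertions[bad, ]
    abort(paste0("unresolvable mapping endpoint(s): ",
                 paste(paste0(offending$source_scheme, ":", offending$source_code,
                              " -> ", offending$target_scheme, ":", offending$target_code),
                       collapse = "; ")),
          class = "casechar_integrity_error")
  }
  same <- assertions$source_scheme == assertions$target_scheme &
    assertions$relation != "identical_code"
  if (any(same)) {
    abort("within-scheme mapping assertion outside relation=identical_code",
          class = "casechar_integrity_error")
  }
  schemes
}

#' Materialize the close-match transitive closure
#'
#' Derives the full set of cross-terminology close-match links from the
#' curated mapping assertions: each assertion contributes a link in the
#' direction(s) its relation tag is configured for (default: both), and
#' the result is closed under transitivity. Hierarchical `broader`
#' edges are never folded into close-match — deriving equivalences
#' through hierarchy is precisely the over-inference that motivates
#' keeping curated mapping sets in dedicated relations rather than
#' generic transitive/symmetric SKOS match properties.
#'
#' @param schemes List of [concept_scheme()] objects covering every
#'   assertion endpoint.
#' @param assertions Tibble of mapping assertions (see [read_mappings()]).
#' @param direction Named list: per-relation `"both"` or `"forward"`,
#'   with a `default` entry (`"both"` unless overridden).
#' @return Tibble of closure links with `kind = "close_match"`, sorted;
#'   symmetric and transitive under the default direction config.
#' @export
materialize_close_match <- function(schemes, assertions, direction = list()) {
  if (nrow(assertions) == 0L) {
    return(empty_closure())
  }
  check_assertions(schemes, assertions)
  default_dir <- direction$default %||% "both"
  dir_of <- function(rel) direction[[rel]] %||% default_dir
  dirs <- vapply(assertions$relation, dir_of, "")
  from <- scheme_key(assertions$source_scheme, assertions$source_code)
  to <- scheme_key(assertions$target_scheme, assertions$target_code)
  both <- dirs == "both"
  edges <- rbind(cbind(from, to), cbind(to[both], from[both]))
  nodes <- unique(c(from, to))
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(nodes) +
    igraph::edges(t(edges))
  reach <- igraph::ego(g, order = length(nodes), mode = "out", mindist = 1)
  pairs <- purrr::map_dfr(seq_along(nodes), function(i) {
    targets <- setdiff(names(reach[[i]]), nodes[i])
    if (!length(targets)) return(NULL)
    tibble(a = nodes[i], b = targets)
  })
  if (nrow(pairs) == 0L) {
    return(empty_closure())
  }
  a <- split_key(pairs$a)
  b <- split_key(pairs$b)
  sort_closure(tibble(kind = "close_match",
                      scheme_a = a$scheme_id, code_a = a$code,
                      scheme_b = b$scheme_id, code_b = b$code))
}

#' Materialize grouping links to a target scheme level
#'
#' For every concept of every loaded scheme, finds its close matches in
#' the target scheme (a concept already in the target scheme matches
#' itself, zero hops) and links it to each ancestor-or-self of those
#' matches at exactly `target_level`. One code may group under several
#' target-level codes (multiaxial hierarchies); all axes are kept.
#'
#' @param closure Output of [materialize_close_match()].
#' @param schemes List of [concept_scheme()] objects.
#' @param target_scheme Scheme id of the analyst's grouping terminology.
#' @param target_level Level label within the target scheme.
#' @return Tibble of closure links with `kind = "group_link"`; `scheme_b`
#'   is always `target_scheme` and every `code_b` sits at `target_level`.
#' @export
materialize_group_links <- function(closure, schemes, target_scheme, target_level) {
  names(schemes) <- vapply(schemes, `[[`, "", "scheme_id")
  tgt <- schemes[[target_scheme]]
  if (is.null(tgt)) {
    abort(paste0("unknown target scheme '", target_scheme, "'"),
          class = "casechar_config_error")
  }
  if (!target_level %in% tgt$level_names) {
    abort(paste0("unknown level '", target_level, "' in scheme '", target_scheme, "'"),
          class = "casechar_config_error")
  }
  # matches of every concept into the target scheme (cross-scheme hops)
  hits <- filter(closure, .data$kind == "close_match", .data$scheme_b == target_scheme)
  # zero-hop: target-scheme concepts match themselves
  self_hits <- tibble(scheme_a = target_scheme, code_a = tgt$concepts$code,
                      code_b = tgt$concepts$code)
  matched <- distinct(bind_rows(select(hits, "scheme_a", "code_a", "code_b"), self_hits))
  if (nrow(matched) == 0L) {
    return(empty_closure())
  }
  anc <- distinct(matched, .data$code_b)
  anc$groups <- lapply(anc$code_b, function(m) ancestors_at_level(tgt, m, target_level))
  out <- matched |>
    left_join(anc, by = "code_b") |>
    select("scheme_a", "code_a", "groups") |>
    tidyr::unnest(cols = "groups") |>
    distinct()
  if (nrow(out) == 0L) {
    return(empty_closure())
  }
  sort_closure(tibble(kind = "group_link",
                      scheme_a = out$scheme_a, code_a = out$code_a,
                      scheme_b = target_scheme, code_b = out$groups))
}

#' Expand a coded criterion into a source terminology
#'
#' Query localization primitive: returns every code in `source_scheme`
#' that close-matches `code`, together with all their narrower
#' descendants in `source_scheme` (sources typically record conditions
#' at finer granularity than the analyst's criterion). A code already
#' in `source_scheme` expands to itself plus descendants. An unmapped
#' code yields an empty set, never an error — the caller decides how to
#' report unsatisfiable criteria.
#'
#' @param code Length-2 character vector or list `(scheme_id, code)`.
#' @param source_scheme Scheme id to expand into.
#' @param closure Output of [materialize_close_match()].
#' @param schemes List of [concept_scheme()] objects.
#' @return Character vector of codes within `source_scheme`.
#' @export
expand_query_codes <- function(code, source_scheme, closure, schemes) {
  names(schemes) <- vapply(schemes, `[[`, "", "scheme_id")
  sid <- code[[1]]
  c0 <- code[[2]]
  sch <- schemes[[sid]]
  if (is.null(sch)) {
    abort(paste0("unknown scheme '", sid, "'"), class = "casechar_lookup_error")
  }
  check_code(sch, c0)
  src <- schemes[[source_scheme]]
  if (is.null(src)) {
    abort(paste0("unknown scheme '", source_scheme, "'"), class = "casechar_lookup_error")
  }
  seeds <- closure |>
    filter(.data$kind == "close_match", .data$scheme_a == sid, .data$code_a == c0,
           .data$scheme_b == source_scheme) |>
    pull("code_b")
  if (sid == source_scheme) {
    seeds <- c(seeds, c0)
  }
  seeds <- unique(seeds)
  if (!length(seeds)) {
    return(character())
  }
  desc <- unlist(lapply(seeds, function(s) descendants(src, s)), use.names = FALSE)
  sort(unique(c(seeds, desc)))
}

# ---- closure cache ----------------------------------------------------------

#' Materialize closure links with a TSV cache
#'
#' Writes/reads the materialized links as a sorted TSV keyed by a
#' content hash of the schemes, assertions and grouping config, so a
#' pipeline re-run with identical inputs loads a bit-stable cache and a
#' changed input transparently rebuilds it.
#'
#' @param schemes,assertions,direction As [materialize_close_match()].
#' @param groupings Tibble or data frame with columns `target_scheme`,
#'   `target_level`: the grouping link sets to materialize alongside.
#' @param cache_dir Directory for cache files (created if needed).
#' @return Tibble of all links (close_match + group_link rows).
#' @export
materialize_cached <- function(schemes, assertions, groupings = NULL,
                               direction = list(), cache_dir) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- content_hash(
    lapply(schemes, function(s) s[c("scheme_id", "level_names", "concepts")]),
    assertions, groupings, direction
  )
  path <- file.path(cache_dir, paste0("closure-", hash, ".tsv"))
  if (file.exists(path)) {
    return(read_closure(path))
  }
  links <- materialize_close_match(schemes, assertions, direction)
  if (!is.null(groupings)) {
    for (i in seq_len(nrow(groupings))) {
      links <- bind_rows(links, materialize_group_links(
        links, schemes, groupings$target_scheme[i], groupings$target_level[i]
      ))
    }
  }
  links <- sort_closure(links)
  write_closure(links, path)
  links
}

#' @rdname materialize_cached
#' @param links Closure link tibble.
#' @param path Cache TSV path (`kind  scheme_a  code_a  scheme_b  code_b`).
#' @export
write_closure <- function(links, path) {
  readr::write_tsv(sort_closure(links), path, progress = FALSE)
  invisible(path)
}

#' @rdname materialize_cached
#' @export
read_closure <- function(path) {
  as_tibble(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
}
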