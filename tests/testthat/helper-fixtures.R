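# Hand-built fixtures and independent oracles shared across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal 3-level chain scheme: one SOC-like root, one mid, one leaf.
chain_scheme <- function(id = "CH") {
  concept_scheme(id, c("top", "mid", "leaf"), tibble::tibble(
    code = c("T1", "M1", "L1"),
    label = c("top one", "mid one", "leaf one"),
    level = c("top", "mid", "leaf"),
    broader = list(character(), "T1", "M1")
  ))
}

# Research-style scheme with a multiaxial leaf (two parents at mid level).
multiaxial_scheme <- function(id = "MX") {
  concept_scheme(id, c("grp", "term"), tibble::tibble(
    code = c("G1", "G2", "P1"),
    label = c("group 1", "group 2", "term 1"),
    level = c("grp", "grp", "term"),
    broader = list(character(), character(), c("G1", "G2"))
  ))
}

# Random multi-scheme assertion graph for closure property tests.
random_mapping_world <- function(seed, n_schemes = 4, n_concepts = 200,
                                 n_assertions = 50) {
  withr::with_seed(seed, {
    per <- ceiling(n_concepts / n_schemes)
    schemes <- lapply(seq_len(n_schemes), function(k) {
      concept_scheme(paste0("S", k), "only", tibble::tibble(
        code = paste0("S", k, "c", seq_len(per)),
        label = paste0("concept ", seq_len(per)),
        level = "only", broader = rep(list(character()), per)
      ))
    })
    all_codes <- do.call(rbind, lapply(schemes, function(s) {
      data.frame(scheme = s$scheme_id, code = s$concepts$code)
    }))
    i <- sample.int(nrow(all_codes), n_assertions, replace = TRUE)
    j <- sample.int(nrow(all_codes), n_assertions, replace = TRUE)
    keep <- all_codes$scheme[i] != all_codes$scheme[j]
    assertions <- tibble::tibble(
      source_scheme = all_codes$scheme[i][keep], source_code = all_codes$code[i][keep],
      target_scheme = all_codes$scheme[j][keep], target_code = all_codes$code[j][keep],
      relation = sample(c("omop_like", "protect_like", "crossmap_like"),
                        sum(keep), replace = TRUE)
    )
    list(schemes = schemes, assertions = unique(assertions))
  })
}

# Independent oracle: symmetric BFS reachability over the raw assertion
# graph (no igraph, no package closure code).
bfs_closure_oracle <- function(assertions) {
  if (nrow(assertions) == 0L) return(character())
  key <- function(s, c) paste0(s, ":", c)
  adj <- new.env(parent = emptyenv())
  add <- function(a, b) assign(a, unique(c(mget(a, adj, ifnotfound = list(NULL))[[1]], b)), adj)
  for (r in seq_len(nrow(assertions))) {
    a <- key(assertions$source_scheme[r], assertions$source_code[r])
    b <- key(assertions$target_scheme[r], assertions$target_code[r])
    add(a, b); add(b, a)
  }
  nodes <- ls(adj)
  pairs <- character()
  for (start in nodes) {
    seen <- start
    queue <- start
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- mget(cur, adj, ifnotfound = list(NULL))[[1]]
      new <- setdiff(nb, seen)
      seen <- c(seen, new)
      queue <- c(queue, new)
    }
    reach <- setdiff(seen, start)
    if (length(reach)) pairs <- c(pairs, paste(start, reach, sep = "->"))
  }
  sort(pairs)
}

closure_as_pairs <- function(links) {
  cm <- links[links$kind == "close_match", ]
  sort(paste0(cm$scheme_a, ":", cm$code_a, "->", cm$scheme_b, ":", cm$code_b))
}

# Independent oracle: boolean matrix-power transitive closure of the
# narrower (parent -> child) relation of one scheme.
matrix_descendants_oracle <- function(scheme, code) {
  con <- scheme$concepts
  n <- nrow(con)
  idx <- stats::setNames(seq_len(n), con$code)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (p in con$broader[[i]]) A[idx[[p]], i] <- TRUE  # parent -> child
  }
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  sort(con$code[R[idx[[code]], ]])
}

# Independent oracle: per-patient, per-statement-pair exhaustive scan of
# an eligibility query (no joins, no set algebra reuse).
brute_force_eligible <- function(query, cohort) {
  if (inherits(query, "localized_query")) query <- query$query
  s <- cohort$statements
  match_stmts <- function(node, pid) {
    rows <- which(s$patient_id == pid & s$kind == node$kind)
    keep <- logical(length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      keep[k] <- any(node$codes$scheme == s$scheme[r] & node$codes$code == s$code[r])
    }
    rows[keep]
  }
  holds <- function(node, pid) {
    if (node$type == "leaf") {
      hit <- length(match_stmts(node, pid)) > 0
      return(if (node$negated) !hit else hit)
    }
    if (node$type == "bool") {
      vals <- vapply(node$children, holds, TRUE, pid = pid)
      return(if (node$op == "and") all(vals) else any(vals))
    }
    a_rows <- match_stmts(node$anchor, pid)
    r_rows <- match_stmts(node$related, pid)
    for (ar in a_rows) {
      if (is.na(s$start[ar])) next
      for (rr in r_rows) {
        if (is.na(s$start[rr])) next
        d <- as.integer(s$start[rr] - s$start[ar])
        ok <- switch(node$direction,
                     after = d >= 0 && d <= node$window_days,
                     before = d <= 0 && d >= -node$window_days,
                     either = abs(d) <= node$window_days)
        if (ok) return(TRUE)
      }
    }
    FALSE
  }
  ids <- cohort$patients$patient_id
  sort(ids[vapply(ids, function(p) holds(query, p), TRUE)])
}

# Small fully in-code cohort for unit tests.
toy_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    birth_year = c(1950L, 1960L, NA),
    gender = c("male", "female", "female"),
    country = c("A", "A", "B")
  )
  statements <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3"),
    kind = c("medication", "condition", "medication", "condition"),
    scheme = c("ATCA", "MEDC", "ATCA", "MEDC"),
    code = c("A2_1", "R4_1", "A2_1", "R4_2"),
    label = c("drug", "reaction", "drug", "confounder"),
    start = as.Date(c("2005-01-01", "2005-05-01", "2006-01-01", NA))
  )
  cohort(patients, statements)
}

demo_study <- function() {
  read_study(system.file("extdata", "demo_study.yaml", package = "casechar"))
}

xml_rules <- function() {
  read_rules(system.file("extdata", "rules", "xml_rules.yaml", package = "casechar"))
}

rel_rules <- function() {
  read_rules(system.file("extdata", "rules", "relational_rules.yaml",
                         package = "casechar"))
}
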