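flat_scheme <- function(id, codes) {
  concept_scheme(id, "only", tibble::tibble(
    code = codes, label = codes, level = "only",
    broader = rep(list(character()), length(codes))))
}

test_that("close-match closure is transitive and symmetric over 2-hop chains", {
  schemes <- list(flat_scheme("A", "a"), flat_scheme("B", "b"), flat_scheme("C", "c"))
  assertions <- tibble::tibble(
    source_scheme = c("A", "B"), source_code = c("a", "b"),
    target_scheme = c("B", "C"), target_code = c("b", "c"),
    relation = "omop_like"
  )
  links <- materialize_close_match(schemes, assertions)
  pairs <- closure_as_pairs(links)
  expect_true("A:a->C:c" %in% pairs)
  expect_true("C:c->A:a" %in% pairs)
  expect_length(pairs, 6L)  # all ordered pairs of {a,b,c}
})

test_that("empty assertion sets give an empty closure", {
  schemes <- list(chain_scheme())
  links <- materialize_close_match(schemes, tibble::tibble(
    source_scheme = character(), source_code = character(),
    target_scheme = character(), target_code = character(),
    relation = character()))
  expect_equal(nrow(links), 0L)
})

test_that("hierarchy alone never induces close matches (match/broader separation)", {
  # rich broader hierarchies, zero mapping assertions: closure must be
  # empty — equivalences must never be inferred through hierarchy.
  terms <- generate_terminologies(generator_spec(seed = 3))
  links <- materialize_close_match(unname(terms$schemes), terms$mappings[0, ])
  expect_equal(nrow(links), 0L)
})

test_that("closure equals symmetric BFS reachability on random graphs", {
  for (seed in c(7, 21, 33)) {
    world <- random_mapping_world(seed)
    links <- materialize_close_match(world$schemes, world$assertions)
    expect_equal(closure_as_pairs(links), bfs_closure_oracle(world$assertions),
                 info = paste("seed", seed))
  }
})

test_that("unresolvable assertion endpoints raise an integrity error", {
  schemes <- list(flat_scheme("A", "a"))
  assertions <- tibble::tibble(
    source_scheme = "A", source_code = "a",
    target_scheme = "B", target_code = "ghost", relation = "omop_like")
  expect_error(materialize_close_match(schemes, assertions),
               class = "casechar_integrity_error")
})

test_that("per-relation direction restriction keeps only asserted arcs", {
  schemes <- list(flat_scheme("A", "a"), flat_scheme("B", "b"))
  assertions <- tibble::tibble(
    source_scheme = "A", source_code = "a",
    target_scheme = "B", target_code = "b", relation = "crossmap_like")
  restricted <- materialize_close_match(schemes, assertions,
                                        direction = list(crossmap_like = "forward"))
  expect_equal(closure_as_pairs(restricted), "A:a->B:b")
  both <- materialize_close_match(schemes, assertions)
  expect_setequal(closure_as_pairs(both), c("A:a->B:b", "B:b->A:a"))
})

test_that("group links reach the target level, zero hops included", {
  ch <- chain_scheme("TGT")
  src <- flat_scheme("SRC", "s1")
  assertions <- tibble::tibble(
    source_scheme = "SRC", source_code = "s1",
    target_scheme = "TGT", target_code = "L1", relation = "omop_like")
  closure <- materialize_close_match(list(ch, src), assertions)
  gl <- materialize_group_links(closure, list(ch, src), "TGT", "mid")
  # s1 -> its match L1 -> mid-level ancestor M1; M1 itself links to M1
  expect_true(any(gl$scheme_a == "SRC" & gl$code_a == "s1" & gl$code_b == "M1"))
  expect_true(any(gl$scheme_a == "TGT" & gl$code_a == "M1" & gl$code_b == "M1"))
  # every linked group code is at exactly the target level
  expect_true(all(gl$code_b %in%
                    ch$concepts$code[ch$concepts$level == "mid"]))
  expect_error(materialize_group_links(closure, list(ch, src), "TGT", "nope"),
               class = "casechar_config_error")
})

test_that("multiaxial codes group under every axis", {
  mx <- multiaxial_scheme("TGT")
  src <- flat_scheme("SRC", "s1")
  assertions <- tibble::tibble(
    source_scheme = "SRC", source_code = "s1",
    target_scheme = "TGT", target_code = "P1", relation = "protect_like")
  closure <- materialize_close_match(list(mx, src), assertions)
  gl <- materialize_group_links(closure, list(mx, src), "TGT", "grp")
  got <- gl$code_b[gl$scheme_a == "SRC" & gl$code_a == "s1"]
  expect_setequal(got, c("G1", "G2"))
})

test_that("several source codes at mixed levels share one broad group", {
  # a haemorrhage-style topology: care codes from two schemes, none with
  # a direct link to the broad research group term, all grouping under
  # it through close matches and the research hierarchy
  research <- concept_scheme("RES", c("hlgt", "hlt", "pt"), tibble::tibble(
    code = c("G", "H1", "H2", "P1", "P2"),
    label = c("vascular haemorrhage analogue", "h1", "h2", "p1", "p2"),
    level = c("hlgt", "hlt", "hlt", "pt", "pt"),
    broader = list(character(), "G", "G", "H1", "H2")))
  care1 <- flat_scheme("CARE1", c("c1", "c2"))
  care2 <- flat_scheme("CARE2", "d1")
  assertions <- tibble::tibble(
    source_scheme = c("CARE1", "CARE1", "CARE2"),
    source_code = c("c1", "c2", "d1"),
    target_scheme = "RES", target_code = c("P1", "P2", "P1"),
    relation = c("omop_like", "omop_like", "crossmap_like"))
  schemes <- list(research, care1, care2)
  closure <- materialize_close_match(schemes, assertions)
  gl <- materialize_group_links(closure, schemes, "RES", "hlgt")
  for (src in list(c("CARE1", "c1"), c("CARE1", "c2"), c("CARE2", "d1"))) {
    expect_equal(gl$code_b[gl$scheme_a == src[1] & gl$code_a == src[2]], "G",
                 info = paste(src, collapse = ":"))
  }
})

test_that("query-code expansion returns matches plus their descendants", {
  tgt <- concept_scheme("SRC", c("top", "leaf"), tibble::tibble(
    code = c("s", "c1", "c2"), label = c("s", "c1", "c2"),
    level = c("top", "leaf", "leaf"), broader = list(character(), "s", "s")))
  res <- flat_scheme("RES", "r")
  assertions <- tibble::tibble(
    source_scheme = "RES", source_code = "r",
    target_scheme = "SRC", target_code = "s", relation = "protect_like")
  closure <- materialize_close_match(list(tgt, res), assertions)
  expect_setequal(expand_query_codes(c("RES", "r"), "SRC", closure, list(tgt, res)),
                  c("s", "c1", "c2"))
  # unmapped code: empty set, not an error
  res2 <- flat_scheme("RES2", "lonely")
  expect_equal(expand_query_codes(c("RES2", "lonely"), "SRC", closure,
                                  list(tgt, res, res2)), character())
  expect_error(expand_query_codes(c("RES", "ghost"), "SRC", closure, list(tgt, res)),
               class = "casechar_lookup_error")
})

test_that("expansion equals an exhaustive DFS oracle on random terminologies", {
  terms <- generate_terminologies(generator_spec(seed = 11))
  closure <- materialize_close_match(unname(terms$schemes), terms$mappings)
  schemes <- unname(terms$schemes)
  pts <- terms$schemes$MEDC$concepts$code[terms$schemes$MEDC$concepts$level == "pt"]
  care <- terms$schemes$ICD9A
  for (pt in pts[1:10]) {
    got <- expand_query_codes(c("MEDC", pt), "ICD9A", closure, schemes)
    seeds <- closure$code_b[closure$kind == "close_match" &
                              closure$scheme_a == "MEDC" & closure$code_a == pt &
                              closure$scheme_b == "ICD9A"]
    oracle <- unique(c(seeds, unlist(lapply(seeds, function(s) {
      matrix_descendants_oracle(care, s)
    }))))
    expect_setequal(got, oracle)
  }
})

test_that("expansion is monotone in the assertion set", {
  world <- random_mapping_world(13, n_schemes = 3, n_concepts = 60, n_assertions = 30)
  half <- world$assertions[seq_len(nrow(world$assertions) %/% 2), ]
  cl_half <- materialize_close_match(world$schemes, half)
  cl_full <- materialize_close_match(world$schemes, world$assertions)
  for (i in seq_len(10)) {
    src <- world$schemes[[1]]
    code <- src$concepts$code[i]
    e_half <- expand_query_codes(c("S1", code), "S2", cl_half, world$schemes)
    e_full <- expand_query_codes(c("S1", code), "S2", cl_full, world$schemes)
    expect_true(all(e_half %in% e_full))
  }
})

test_that("materialized links cache to a bit-stable sorted TSV", {
  terms <- generate_terminologies(generator_spec(seed = 4))
  dir <- withr::local_tempdir()
  l1 <- materialize_cached(unname(terms$schemes), terms$mappings, cache_dir = dir)
  f1 <- list.files(dir, full.names = TRUE)
  expect_length(f1, 1L)
  bytes1 <- readBin(f1, "raw", file.size(f1))
  l2 <- materialize_cached(unname(terms$schemes), terms$mappings, cache_dir = dir)
  expect_equal(as.data.frame(l2), as.data.frame(l1))
  expect_identical(readBin(f1, "raw", file.size(f1)), bytes1)
})
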