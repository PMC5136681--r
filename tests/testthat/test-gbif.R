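test_that("query parsing splits on '|', trims, dedupes, keeps order", {
  expect_identical(parse_query("Lembus"), "Lembus")
  expect_identical(parse_query("Lembus | Cohnilembus"), c("Lembus", "Cohnilembus"))
  expect_identical(parse_query("A||A"), "A")
  expect_error(parse_query(" | "), "empty query")
})

test_that("exact search echoes the recorded fixture records", {
  be <- fixture_backend()
  res <- search_names("Alphus", query_options("exact"), be)
  expect_identical(nrow(res), 2L)
  expect_setequal(res$usage_id, c("al1", "al2"))
  # other ranked modes return supersets of exact
  expect_true(nrow(search_names("Alph", query_options("suggest"), be)) >= 2L)
  expect_identical(
    search_names("alphus", query_options("fuzzy"), be)$usage_id,
    res$usage_id
  )
})

test_that("a rank filter is a union with unranked records", {
  be <- fixture_backend()
  all_x <- search_names("Xenus", query_options("exact"), be)
  expect_identical(nrow(all_x), 6L) # 3 genus, 2 unranked, 1 species
  filtered <- search_names("Xenus", query_options("exact", rank_filter = "genus"), be)
  expect_identical(nrow(filtered), 5L)
  expect_setequal(unique(filtered$rank), c("genus", "unranked"))
  # de-normalised records are tagged, never dropped or merged
  expect_true(any(filtered$denormalized))
})

test_that("contain mode returns the higher taxa of the match", {
  be <- fixture_backend()
  res <- search_names("Xenus minor", query_options("contain"), be)
  expect_setequal(res$literal, c("Xenus", "Familidae", "Nodea", "Insecta", "Arthropoda", "Animalia"))
})

test_that("vernacular search is language-aware", {
  be <- fixture_backend()
  res <- search_names("demo beetle",
    query_options("exact", include_vernacular = TRUE, language = "en"), be
  )
  expect_identical(res$usage_id, "x1")
})

test_that("synonym saturation reaches a fixed point", {
  be <- fixture_backend()
  # mutual synonyms: {Parella} saturates to {Parella, Parvex}
  res <- expand_synonyms("Parella", query_options(include_synonyms = TRUE), be)
  expect_setequal(attr(res, "literals"), c("Parella", "Parvex"))
  expect_setequal(res$usage_id, c("pa1", "pa2", "pv1", "pv2"))
  # chain A -> B -> C saturates in two growth rounds
  res2 <- expand_synonyms("Chaina", query_options(include_synonyms = TRUE), be)
  expect_setequal(attr(res2, "literals"), c("Chaina", "Chainb", "Chainc"))
  # a usage with no synonyms is an immediate fixed point
  res3 <- expand_synonyms("Alphus", query_options(include_synonyms = TRUE), be)
  expect_identical(attr(res3, "literals"), "Alphus")
  # seed order does not matter
  a <- expand_synonyms(c("Chaina", "Parella"), query_options(include_synonyms = TRUE), be)
  b <- expand_synonyms(c("Parella", "Chaina"), query_options(include_synonyms = TRUE), be)
  expect_identical(a, b)
  # iteration cap guards against runaway saturation
  expect_error(
    expand_synonyms("Chaina", query_options(include_synonyms = TRUE), be, max_rounds = 0L),
    "saturation cap"
  )
})

test_that("the basionym option pulls basionym literals in", {
  be <- fixture_backend()
  res <- search_names("Parella", query_options(include_basionym = TRUE), be)
  expect_true("Parbas" %in% res$literal)
})

test_that("the cache makes repeated queries free", {
  be <- fixture_backend()
  search_names("Xenus", query_options("exact"), be)
  n1 <- backend_calls(be)
  search_names("Xenus", query_options("exact"), be)
  expect_identical(backend_calls(be), n1)
  # a different mode is a different query
  search_names("Xenus", query_options("full_text"), be)
  expect_gt(backend_calls(be), n1)
})

test_that("fetch_hierarchy recovers path plus subtree and honours limits", {
  be <- fixture_backend()
  full <- fetch_hierarchy("x1", backend = be)
  expect_identical(tidy(full)$literal[tidy(full)$depth == 0], "Animalia")
  expect_setequal(
    full$nodes$literal,
    c("Animalia", "Arthropoda", "Insecta", "Nodea", "Familidae", "Xenus",
      "Xenus minor", "Xenus major")
  )
  # height zero cuts the higher-taxa path entirely
  zero <- fetch_hierarchy("x1", height = rank_spec(levels = 0), backend = be)
  expect_identical(zero$roots, "x1")
  expect_setequal(zero$nodes$literal, c("Xenus", "Xenus minor", "Xenus major"))
  # a named rank stops at that rank
  fam <- fetch_hierarchy("x1", height = rank_spec(rank = "family"), backend = be)
  expect_identical(tidy(fam)$literal[tidy(fam)$depth == 0], "Familidae")
  # unknown key is a recorded-fixture miss
  expect_error(fetch_hierarchy("nope", backend = be), "not recorded")
})

test_that("trimming keeps whichever limit retains fewer intermediate ranks", {
  # genus with 5 ancestors: levels=2 beats rank=kingdom
  tree <- source_tree(
    tibble::tibble(
      usage_id = as.character(1:6),
      literal = c("K", "P", "C", "O", "F", "G"),
      rank = c("kingdom", "phylum", "class", "order", "family", "genus"),
      parent_id = c(NA, "1", "2", "3", "4", "5")
    ),
    source_id = "s"
  )
  tr <- trim_by_rank(tree, "6", height = rank_spec(levels = 2, rank = "kingdom"))
  expect_identical(nrow(tr$nodes), 3L) # 2 ancestors + focus
  expect_identical(tr$roots, "4")

  # unranked intermediates count toward levels but never satisfy a rank:
  # limiting at class keeps usages below phylum
  unr <- source_tree(
    tibble::tibble(
      usage_id = as.character(1:6),
      literal = c("C", "u1", "u2", "u3", "F", "G"),
      rank = c("class", "unranked", "unranked", "unranked", "family", "genus"),
      parent_id = c(NA, "1", "2", "3", "4", "5")
    ),
    source_id = "s"
  )
  tru <- trim_by_rank(unr, "6", height = rank_spec(rank = "class"))
  expect_identical(nrow(tru$nodes), 6L) # all intermediates plus class kept
  expect_identical(tru$roots, "1")

  # levels = 0 upward: the focus becomes the root
  tr0 <- trim_by_rank(tree, "6", height = rank_spec(levels = 0))
  expect_identical(tr0$roots, "6")

  # downward: depth by rank stops below the named rank
  trd <- trim_by_rank(unr, "1", depth = rank_spec(rank = "family"))
  expect_setequal(trd$nodes$literal, c("C", "u1", "u2", "u3", "F"))
})

test_that("live backend refuses to build without its optional dependency", {
  # construction succeeds when httr is present; behaviour is identical in
  # shape to the fixture backend but never exercised offline
  skip_if_not_installed("httr")
  be <- live_backend(base_url = "http://localhost:1/v1")
  expect_s3_class(be, "taxa_backend")
  expect_identical(backend_calls(be), 0L)
})
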