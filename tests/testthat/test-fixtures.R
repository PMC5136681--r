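test_that("schematic fixtures match their published structure", {
  pair <- schematic_pair()
  expect_identical(nrow(pair$h1$nodes), 2L) # B -> D
  expect_identical(nrow(pair$h2$nodes), 3L) # B -> C -> D
  expect_identical(parent_path(pair$h2, "D"), c("C", "B"))
  for (t in pair) expect_identical(nrow(validate_source(t)), 0L)

  trio <- schematic_trio()
  for (t in trio) expect_identical(nrow(validate_source(t)), 0L)
  # B and S are absent from h1
  expect_false(any(c("B", "S") %in% trio$h1$nodes$literal))
  # S sits under mutually incompatible parental paths in h2 and h3
  expect_false(path_compatible(
    parent_path(trio$h2, "S"), parent_path(trio$h3, "S")
  ))
  cx23 <- build_composite(trio[c("h2", "h3")])
  expect_identical(sum(cx23$nodes$literal == "S"), 2L)
})

test_that("generation is deterministic and honours its knobs", {
  a <- simulate_hierarchies(seed = 99)
  b <- simulate_hierarchies(seed = 99)
  expect_identical(a, b) # byte-identical trees from the same seed
  expect_false(identical(a, simulate_hierarchies(seed = 100)))
  for (t in a) {
    expect_identical(nrow(validate_source(t)), 0L)
    expect_length(t$roots, 1L) # singly rooted
  }
  # realized overlap: the shared set is present in every tree
  shared <- attr(a, "shared")
  for (t in a) expect_true(all(shared %in% t$nodes$literal))
  expect_identical(length(shared), 15L)
})

test_that("zero inconsistency means zero duplicated composite literals", {
  for (s in 1:20) {
    trees <- simulate_hierarchies(seed = s, inconsistency_rate = 0)
    expect_identical(glance(build_composite(trees))$n_duplicated_literals, 0L)
  }
})

test_that("full overlap with no inconsistency makes every literal common", {
  trees <- simulate_hierarchies(
    seed = 4, overlap = 1, inconsistency_rate = 0, depth = c(4, 4)
  )
  fac <- classify(build_composite(trees))
  expect_setequal(fac$common$literal, trees[[1]]$nodes$literal)
  expect_identical(nrow(fac$different), 0L)
  expect_identical(nrow(fac$missing), 0L)
})

test_that("injected inconsistencies are exactly the flagged literals", {
  for (s in 1:20) {
    trees <- simulate_hierarchies(seed = s)
    fac <- classify(build_composite(trees))
    expect_setequal(fac$inconsistent$literal, attr(trees, "inconsistent"))
  }
})

test_that("infeasible parameter combinations are refused", {
  expect_error(
    simulate_hierarchies(seed = 1, overlap = 0, inconsistency_rate = 0.5),
    "infeasible"
  )
  expect_error(
    simulate_hierarchies(seed = 1, n_trees = 1, inconsistency_rate = 0.5),
    "infeasible"
  )
  expect_error(
    simulate_hierarchies(seed = 1, n_literals = 5, overlap = 0.6, inconsistency_rate = 0.9),
    "infeasible"
  )
  expect_error(simulate_hierarchies(n_trees = 2), "seed")
})

test_that("the synthetic genus checklists reproduce the described relationships", {
  trees <- demo_genus_checklists()
  expect_length(trees, 5L)
  n_species <- vapply(trees, function(t) {
    sum(t$nodes$rank == "species" & t$nodes$status != "synonym")
  }, integer(1))
  expect_identical(min(n_species), 1L)
  expect_identical(max(n_species), 16L)
  # two sources share an identical species set
  sp <- lapply(trees, function(t) {
    sort(t$nodes$literal[t$nodes$rank == "species" & t$nodes$status != "synonym"])
  })
  expect_identical(sp$itis, sp$irmng)
  expect_length(sp$itis, 6L)
  # one species is absent from one large source but present upstream
  expect_true("Exemplarius cinereus" %in% sp$aggregator)
  expect_false("Exemplarius cinereus" %in% sp$col)
  # the synonym-only species is attached via its accepted usage, not as a child
  col <- trees$col
  syn <- col$nodes[col$nodes$literal == "Exemplarius innocuus", ]
  expect_identical(syn$status, "synonym")
  genus_id <- col$nodes$usage_id[col$nodes$literal == "Exemplarius"]
  expect_false(syn$usage_id %in% col$children[[genus_id]])
  # the facets see it as missing from col (present as accepted elsewhere)
  fac <- classify(build_composite(trees))
  expect_true("Exemplarius innocuus" %in% fac$missing$literal)
  expect_true("Curculionidae" %in% fac$different$literal)
  expect_true("Exemplarius" %in% fac$common$literal)
  expect_identical(nrow(fac$inconsistent), 0L)
})
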