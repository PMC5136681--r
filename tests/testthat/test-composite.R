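test_that("path compatibility is subsequence embedding, both directions", {
  expect_true(path_compatible(character(0), c("A", "B")))
  expect_true(path_compatible(c("B"), c("C", "B")))
  expect_true(path_compatible(c("C", "B"), c("B"))) # symmetric
  expect_false(path_compatible(c("P", "Q"), c("Q", "P")))
  expect_false(path_compatible(c("X", "A"), c("Y", "A"))) # equal length, differing
  # property: agrees with an independent subsequence oracle on random paths
  set.seed(7)
  alphabet <- LETTERS[1:5]
  for (i in 1:200) {
    a <- sample(alphabet, sample(0:4, 1))
    b <- sample(alphabet, sample(0:4, 1))
    expect_identical(path_compatible(a, b), oracle_compatible(a, b))
    expect_true(path_compatible(a, a)) # reflexive
    expect_identical(path_compatible(a, b), path_compatible(b, a))
  }
})

test_that("a single hierarchy is copied node for node", {
  h <- schematic_trio()$h2
  cx <- build_composite(list(h))
  expect_identical(nrow(cx$nodes), nrow(h$nodes))
  expect_setequal(cx$nodes$literal, h$nodes$literal)
  # forward map is total; reverse recovers each usage
  expect_identical(nrow(cx$forward), nrow(h$nodes))
  expect_setequal(cx$forward$usage_id, h$nodes$usage_id)
})

test_that("merging a deep copy of the same hierarchy is idempotent", {
  h <- schematic_trio()$h2
  h2 <- h
  h2$source_id <- "copy"
  h2$nodes$source_id <- "copy"
  cx1 <- build_composite(list(h))
  cx2 <- build_composite(list(h, h2))
  expect_identical(cx2$nodes, cx1$nodes) # literal-labelled isomorphism
  # every composite node maps back to exactly two source usages
  counts <- table(cx2$forward$node_id)
  expect_true(all(counts == 2L))
})

test_that("inserting an intermediate name reuses the lower composite node", {
  cx <- build_composite(schematic_pair())
  td <- tidy(cx)
  expect_identical(sum(td$literal == "D"), 1L)
  d_id <- td$node_id[td$literal == "D"]
  pn <- cx$parental_name
  # one entry indexed by literals D and B, the other by D and C,
  # both resolving to the same composite node
  expect_setequal(pn$parent_literal[pn$literal == "D"], c("B", "C"))
  expect_true(all(pn$node_id[pn$literal == "D"] == d_id))
  # the direct B-D edge is not retained after insertion of C
  expect_identical(td$parent_literal[td$literal == "D"], "C")
})

test_that("incompatible assignments force duplicated composite nodes", {
  trio <- schematic_trio()
  cx23 <- build_composite(trio[c("h2", "h3")])
  expect_identical(sum(cx23$nodes$literal == "S"), 2L)
  sfx <- sort(cx23$nodes$suffix[cx23$nodes$literal == "S"])
  expect_identical(sfx, c(0L, 1L))
  # a root literal absent from the composite and incompatible with all
  # same-literal entries starts an independent tree under the super-root
  other <- mk_tree("solo", "Biota", parent = "Biota", child = "A")
  cx <- incorporate(build_composite(list(mk_tree("base", "root"))), other)
  expect_identical(length(cx$root_children), 2L)
})

test_that("merge_redundant_children merges same-literal siblings, keeping descendants", {
  plain <- mk_tree("s", "P", parent = c("P", "P"), child = c("X", "Y"))
  expect_identical(merge_redundant_children(plain, "P")$children[["P"]], c("X", "Y"))

  dup <- source_tree(
    tibble::tibble(
      usage_id = c("p", "x1", "x2", "z"),
      literal = c("P", "X", "X", "Z"),
      parent_id = c(NA, "p", "p", "x2")
    ),
    source_id = "s"
  )
  m <- merge_redundant_children(dup, "p")
  expect_identical(m$children[["p"]], "x1")
  expect_identical(m$children[["x1"]], "z")
  expect_false("x2" %in% m$nodes$usage_id)

  # three same-literal siblings: survivor takes the union of descendants,
  # total descendant count is conserved minus the merged duplicates
  trip <- source_tree(
    tibble::tibble(
      usage_id = c("p", "x1", "x2", "x3", "c1", "c2"),
      literal = c("P", "X", "X", "X", "C1", "C2"),
      parent_id = c(NA, "p", "p", "p", "x2", "x3")
    ),
    source_id = "s"
  )
  m3 <- merge_redundant_children(trip, "p")
  expect_identical(m3$children[["p"]], "x1")
  expect_setequal(m3$children[["x1"]], c("c1", "c2"))
  expect_identical(nrow(m3$nodes), nrow(trip$nodes) - 2L)
})

test_that("resolve_candidate is conservative: only a unique compatible match", {
  cx <- build_composite(schematic_pair())
  expect_true(is.na(resolve_candidate(cx, "Zz", c("B")))) # no entry at all
  d_id <- cx$nodes$node_id[cx$nodes$literal == "D"]
  expect_identical(resolve_candidate(cx, "D", c("B")), d_id)
  expect_identical(resolve_candidate(cx, "D", c("C", "B")), d_id)
  # two compatible candidates: refuse, forcing creation of a new node
  trio <- schematic_trio()
  cx23 <- build_composite(trio[c("h2", "h3")])
  # both S nodes have paths compatible with the bare root path ("A")
  expect_true(is.na(resolve_candidate(cx23, "S", c("A"))))
})

test_that("child order alignment is a stable partition on literal matches", {
  base <- mk_tree("b", "P", parent = c("P", "P"), child = c("X", "Y"))
  cx <- build_composite(list(base))
  flipped <- mk_tree("f", "P", parent = c("P", "P"), child = c("Y", "X"))
  cxf <- incorporate(cx, flipped)
  expect_identical(cxf$sources[["f"]]$children[["P"]], c("X", "Y"))

  noover <- mk_tree("n", "P", parent = c("P", "P"), child = c("Q", "R"))
  out <- align_child_order(build_composite(list(noover)), noover, "P")
  expect_identical(out$children[["P"]], c("Q", "R"))

  partial <- mk_tree("b", "P", parent = c("P", "P", "P"), child = c("Y", "Z", "X"))
  out2 <- align_child_order(cx, partial, "P")
  # composite children are (X, Y): matched first in composite order, then Z
  expect_identical(unname(out2$children[["P"]]), c("X", "Y", "Z"))
})

test_that("forward map is total and reverse_map is its exact inverse", {
  for (s in 1:15) {
    trees <- small_sim(s)
    cx <- build_composite(trees)
    for (tree in cx$sources) {
      f <- cx$forward[cx$forward$source_id == tree$source_id, ]
      expect_setequal(f$usage_id, tree$nodes$usage_id)
      # one hierarchy occupies a composite node at most once
      expect_false(anyDuplicated(f$node_id) > 0L)
    }
    rev <- reverse_map(cx)
    expect_identical(
      dplyr::arrange(rev, source_id, usage_id)[, c("source_id", "usage_id", "node_id")],
      dplyr::arrange(cx$forward, source_id, usage_id)[, c("source_id", "usage_id", "node_id")]
    )
    # conservation: every literal of every source is in the composite
    lits <- unique(unlist(lapply(trees, function(t) t$nodes$literal)))
    expect_true(all(lits %in% cx$nodes$literal))
  }
})

test_that("the composite is a pure function of the input sequence", {
  trees <- small_sim(3)
  cx1 <- build_composite(trees)
  cx2 <- build_composite(trees)
  expect_identical(cx1, cx2) # including duplicate suffixes
  # different incorporation order may differ, but is itself reproducible
  cx_rev1 <- build_composite(rev(trees))
  cx_rev2 <- build_composite(rev(trees))
  expect_identical(cx_rev1, cx_rev2)
})

test_that("composite node counts per literal match the brute-force oracle", {
  for (s in 1:40) {
    trees <- small_sim(s)
    cx <- build_composite(trees)
    got <- table(cx$nodes$literal)
    want <- oracle_literal_counts(trees)
    expect_identical(
      as.integer(got[sort(names(want))]),
      as.integer(want[sort(names(want))]),
      info = paste("seed", s)
    )
  }
})

test_that("degenerate inputs are handled per contract", {
  expect_error(build_composite(list()), "no hierarchies")
  h <- mk_tree("a", "Solo")
  cx <- build_composite(list(h))
  expect_identical(nrow(cx$nodes), 1L)
  expect_error(incorporate(cx, h), "duplicate source")
})
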