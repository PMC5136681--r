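test_that("assignment cells carry higher names, markers and multi-parents", {
  h <- schematic_trio()$h2
  expect_identical(assignment_cell("Nowhere", h), cell_absent())
  expect_identical(assignment_cell("A", h), cell_root())
  expect_identical(assignment_cell("S", h), "C")
  # one hierarchy, same literal under two distinct parents: both reported
  dup <- source_tree(
    tibble::tibble(
      usage_id = c("r", "x", "y", "l1", "l2"),
      literal = c("R", "X", "Y", "L", "L"),
      parent_id = c(NA, "r", "r", "x", "y")
    ),
    source_id = "d"
  )
  expect_identical(assignment_cell("L", dup), "X | Y")
})

test_that("with a single hierarchy every literal is vacuously common", {
  h <- schematic_trio()$h2
  fac <- classify(build_composite(list(h)))
  expect_setequal(fac$common$literal, h$nodes$literal)
  expect_identical(nrow(fac$different), 0L)
  expect_identical(nrow(fac$missing), 0L)
  expect_identical(nrow(fac$inconsistent), 0L)
})

test_that("the worked three-tree example classifies as expected", {
  trio <- schematic_trio()
  fac <- classify(build_composite(trio))
  expect_identical(fac$inconsistent$literal, "S")
  expect_setequal(fac$different$literal, c("C", "D"))
  expect_identical(fac$missing$literal, "B")
  expect_identical(fac$common$literal, "A")
  expect_setequal(fac$all$literal, c("A", "B", "C", "D", "S"))
  # cells: D is assigned to C in h1/h2 but to B in h3
  drow <- fac$different[fac$different$literal == "D", ]
  expect_identical(unname(unlist(drow[, c("h1", "h2", "h3")])), c("C", "C", "B"))
})

test_that("the insertion pair yields D different and C missing", {
  fac <- classify(build_composite(schematic_pair()))
  expect_identical(fac$different$literal, "D")
  drow <- fac$different
  expect_identical(drow$h1, "B")
  expect_identical(drow$h2, "C")
  expect_identical(fac$missing$literal, "C")
  expect_identical(fac$common$literal, "B") # shared root, no higher name anywhere
})

test_that("facets partition the literal universe on random fixtures", {
  for (s in 1:25) {
    trees <- small_sim(s)
    cx <- build_composite(trees)
    fac <- classify(cx)
    universe <- sort(unique(unlist(lapply(trees, function(t) t$nodes$literal))))
    parts <- c(fac$common$literal, fac$different$literal,
      fac$missing$literal, fac$inconsistent$literal)
    expect_identical(sort(parts), universe) # cover, pairwise disjoint
    expect_length(intersect(fac$common$literal, fac$different$literal), 0L)
    expect_length(intersect(fac$common$literal, fac$inconsistent$literal), 0L)
    expect_length(intersect(fac$missing$literal, fac$different$literal), 0L)
    # composite-consistency: inconsistent <=> >= 2 composite nodes
    counts <- table(cx$nodes$literal)
    expect_setequal(fac$inconsistent$literal, names(counts)[counts >= 2L])
    # synonyms facet is a subset of different
    expect_true(all(fac$synonyms$literal %in% fac$different$literal))
    # rows are ordered by the name literal alphabetically
    for (f in facet_names()) {
      expect_identical(fac[[f]]$literal, sort(fac[[f]]$literal))
    }
    # every row has at least one non-empty cell
    mat <- as.matrix(fac$all[, -1])
    expect_true(all(rowSums(mat != cell_absent()) >= 1L))
  }
})

test_that("adding a structural copy never moves a literal out of common", {
  trees <- small_sim(11)
  cx <- build_composite(trees)
  before <- classify(cx)$common$literal
  copy <- trees[[1]]
  copy$source_id <- "copy"
  copy$nodes$source_id <- "copy"
  cx2 <- incorporate(cx, copy)
  after <- classify(cx2)$common$literal
  expect_true(all(intersect(before, copy$nodes$literal) %in% after))
})

test_that("off-path higher names are flagged as potential synonyms", {
  trees <- synonym_case_trees()
  cx <- build_composite(trees)
  fac <- classify(cx)
  # B is duplicated (intra-tree inconsistency); L is reused across branches
  expect_identical(fac$inconsistent$literal, "B")
  expect_identical(sum(cx$nodes$literal == "L"), 1L)
  expect_identical(fac$synonyms$literal, "L")
  expect_true("L" %in% fac$different$literal)
  # t2 assigns L to C, which is not an ancestor literal of L's composite node
  lrow <- fac$synonyms[fac$synonyms$literal == "L", ]
  expect_identical(lrow$t1, "B")
  expect_identical(lrow$t2, "C")
})

test_that("classify rejects a stale composite", {
  trio <- schematic_trio()
  cx <- build_composite(trio[c("h1", "h2")])
  expect_error(classify(cx, trio), "stale composite")
})
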