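# build a source tree from (parent, child) literal pairs; ids = literals
mk_tree <- function(source_id, root, parent = character(0), child = character(0)) {
  nodes <- tibble::tibble(
    usage_id = c(root, child),
    literal = c(root, child),
    parent_id = c(NA_character_, parent)
  )
  source_tree(nodes, source_id = source_id)
}

# fixture reaching the potential-synonym (off-path) case: the literal B is
# duplicated inside t1 (two incompatible positions); t2 reaches the shared
# leaf L through the second B, so t2's parent C is not an ancestor literal
# of L's composite node.
synonym_case_trees <- function() {
  t1 <- source_tree(
    tibble::tibble(
      usage_id = c("a", "b1", "l", "y", "b2"),
      literal = c("A", "B", "L", "Y", "B"),
      parent_id = c(NA, "a", "b1", "a", "y")
    ),
    source_id = "t1"
  )
  t2 <- mk_tree("t2", "A",
    parent = c("A", "Y", "B", "C"),
    child = c("Y", "B", "C", "L")
  )
  list(t1 = t1, t2 = t2)
}

# small random hierarchy sets for property tests: <= 3 trees, <= 12 usages
# per tree, unique literals within each tree
small_sim <- function(seed) {
  simulate_hierarchies(
    n_trees = 2L + seed %% 2L, n_literals = 10L, depth = c(2L, 3L),
    overlap = 0.6, inconsistency_rate = 0.2, seed = seed
  )
}
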