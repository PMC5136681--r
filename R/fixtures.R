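# quick construction of a tree from (parent literal -> child literal) edges;
# usage ids equal literals (generated trees use each literal once per tree)
tree_from_edges <- function(source_id, root, edges = NULL, label = source_id) {
  rows <- tibble(usage_id = root, literal = root, parent_id = NA_character_)
  if (!is.null(edges) && nrow(edges)) {
    rows <- bind_rows(rows, tibble(
      usage_id = edges$child, literal = edges$child, parent_id = edges$parent
    ))
  }
  source_tree(rows, source_id = source_id, label = label)
}

#' Schematic two-hierarchy example: inserting an intermediate name
#'
#' Two miniature hierarchies over the same names: the first holds the path
#' B -> D, the second B -> C -> D. Merging them exercises the core of the
#' composite builder: one composite node D ends up indexed in the
#' parental-name table under both (D, B) and (D, C), and the direct B -> D
#' edge of the composite dissolves when C is inserted.
#'
#' @return named list of two [source_tree()] objects `h1`, `h2`.
#' @export
#' @examples
#' cx <- build_composite(schematic_pair())
#' classify(cx)$different # D differs: assigned to B vs C
schematic_pair <- function() {
  list(
    h1 = tree_from_edges("h1", "B", tibble(parent = "B", child = "D")),
    h2 = tree_from_edges("h2", "B", tibble(
      parent = c("B", "C"), child = c("C", "D")
    ))
  )
}

#' Schematic three-hierarchy example: vacancies and duplicated names
#'
#' Three miniature hierarchies illustrating aligned display: `h1` lacks the
#' names B and S entirely (their rows show vacancies in `h1`'s column), and
#' `h2`/`h3` assign S under incompatible parental paths (C under B versus D
#' under B), so the aligner tree carries two S nodes.
#'
#' @return named list of three [source_tree()] objects `h1`, `h2`, `h3`.
#' @export
#' @examples
#' cx <- build_composite(schematic_trio())
#' sum(tidy(cx)$literal == "S") # 2
schematic_trio <- function() {
  list(
    h1 = tree_from_edges("h1", "A", tibble(
      parent = c("A", "C"), child = c("C", "D")
    )),
    h2 = tree_from_edges("h2", "A", tibble(
      parent = c("A", "B", "C", "C"), child = c("B", "C", "D", "S")
    )),
    h3 = tree_from_edges("h3", "A", tibble(
      parent = c("A", "B", "D"), child = c("B", "D", "S")
    ))
  )
}

#' Generate random hierarchy sets with controlled overlap and inconsistency
#'
#' Draws `n_trees` singly rooted hierarchies over a pool of `n_literals`
#' name literals. A fraction `overlap` of the pool is shared by every tree:
#' a common scaffold made of a root and two equal-length "arms", plus shared
#' leaves attached identically everywhere. A fraction `inconsistency_rate`
#' of the shared literals is injected as incompatible assignments: such a
#' leaf hangs off arm one at some depth in the first tree and off arm two at
#' the same depth in every other tree -- two equal-length differing parental
#' paths, which can never be embedded into one another. The remaining
#' literals are tree-unique leaves. When the pool is only partially shared,
#' one shared leaf is additionally attached one level higher in the first
#' tree than elsewhere, a compatible difference that populates the
#' `different` facet without creating inconsistency.
#'
#' Generation is fully reproducible from `seed`; the injected inconsistent
#' literals are returned in the attribute `"inconsistent"` and are exactly
#' the literals the facet classification flags as inconsistent.
#'
#' @param n_trees number of hierarchies.
#' @param n_literals size of the literal pool.
#' @param depth length-2 integer range for the scaffold depth.
#' @param overlap fraction of literals shared across all trees, in `[0, 1]`.
#' @param inconsistency_rate fraction of shared literals given incompatible
#'   parental paths, in `[0, 1]`.
#' @param seed RNG seed (mandatory).
#' @return named list of [source_tree()] objects with attributes
#'   `"inconsistent"` (character vector of injected literals) and
#'   `"shared"` (the shared literal set).
#' @export
#' @examples
#' trees <- simulate_hierarchies(seed = 1)
#' glance(build_composite(trees))
simulate_hierarchies <- function(n_trees = 3, n_literals = 30, depth = c(3, 5),
                                 overlap = 0.5, inconsistency_rate = 0.1, seed) {
  if (missing(seed)) stop("`seed` is mandatory: generation must be reproducible", call. = FALSE)
  stopifnot(
    n_trees >= 1, n_literals >= n_trees, length(depth) == 2, depth[1] >= 2,
    depth[2] >= depth[1], overlap >= 0, overlap <= 1,
    inconsistency_rate >= 0, inconsistency_rate <= 1
  )
  n_shared <- round(overlap * n_literals)
  k <- round(inconsistency_rate * n_shared)
  if (inconsistency_rate > 0 && (n_shared == 0 || n_trees < 2)) {
    stop("infeasible parameters: inconsistency requires shared literals in >= 2 trees",
      call. = FALSE
    )
  }
  if (k > 0 && n_shared < 3 + k) {
    stop("infeasible parameters: not enough shared literals to host the scaffold",
      call. = FALSE
    )
  }
  if (n_shared == 0 && n_literals < n_trees) {
    stop("infeasible parameters: every tree needs at least one literal", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  pool <- sprintf("Taxon%03d", seq_len(n_literals))
  shared <- pool[seq_len(n_shared)]
  uniq <- setdiff(pool, shared)
  target_depth <- sample(seq(depth[1], depth[2]), 1L)

  # edges per tree as (parent, child) literal pairs
  edges <- rep(list(tibble(parent = character(0), child = character(0))), n_trees)
  roots <- character(n_trees)
  add_edge <- function(t, parent, child) {
    edges[[t]] <<- bind_rows(edges[[t]], tibble(parent = parent, child = child))
  }
  inconsistent <- character(0)

  if (n_shared >= 1) {
    root <- shared[[1L]]
    roots[] <- root
    avail <- shared[-1L]
    incons <- if (k > 0) tail(avail, k) else character(0)
    avail <- setdiff(avail, incons)
    arm_len <- max(0L, min(target_depth - 1L, length(avail) %/% 2L))
    if (k > 0) arm_len <- max(arm_len, 1L)
    arm1 <- head(avail, arm_len)
    arm2 <- head(setdiff(avail, arm1), arm_len)
    cons_leaves <- setdiff(avail, c(arm1, arm2))
    for (t in seq_len(n_trees)) {
      for (arm in list(arm1, arm2)) {
        if (length(arm)) {
          add_edge(t, c(root, head(arm, -1L)), arm)
        }
      }
    }
    # shared leaves, identical placement everywhere
    anchors <- c(root, arm1, arm2)
    leaf_parent <- if (length(cons_leaves)) {
      sample(anchors, length(cons_leaves), replace = TRUE)
    } else {
      character(0)
    }
    # one compatible difference: the first shared leaf sits one level higher
    # in the first tree (its grandparent) than in the other trees
    diff_leaf <- NULL
    if (overlap < 1 && length(cons_leaves) >= 1 && arm_len >= 2 && n_trees >= 2) {
      diff_leaf <- cons_leaves[[1L]]
      d <- if (arm_len == 2L) 2L else sample(2:arm_len, 1L)
      leaf_parent[[1L]] <- arm1[[d]]
    }
    for (i in seq_along(cons_leaves)) {
      for (t in seq_len(n_trees)) {
        p <- leaf_parent[[i]]
        if (!is.null(diff_leaf) && i == 1L && t == 1L) {
          p <- arm1[[match(p, arm1) - 1L]] # one level higher: compatible
        }
        add_edge(t, p, cons_leaves[[i]])
      }
    }
    # injected incompatible assignments: arm one at depth d in tree 1,
    # arm two at the same depth elsewhere
    if (k > 0) {
      d_at <- sample(seq_len(arm_len), k, replace = TRUE)
      for (j in seq_len(k)) {
        for (t in seq_len(n_trees)) {
          add_edge(t, if (t == 1L) arm1[[d_at[[j]]]] else arm2[[d_at[[j]]]], incons[[j]])
        }
      }
      inconsistent <- incons
    }
  }

  # tree-unique leaves, round-robin
  if (length(uniq)) {
    owner <- rep(seq_len(n_trees), length.out = length(uniq))
    for (i in seq_along(uniq)) {
      t <- owner[[i]]
      if (n_shared == 0 && !nzchar(roots[[t]])) {
        roots[[t]] <- uniq[[i]]
        next
      }
      present <- c(roots[[t]], edges[[t]]$child)
      add_edge(t, sample(present, 1L), uniq[[i]])
    }
  }
  if (any(!nzchar(roots))) {
    stop("infeasible parameters: a tree received no literals", call. = FALSE)
  }

  trees <- lapply(seq_len(n_trees), function(t) {
    tree_from_edges(sprintf("sim%d", t), roots[[t]], edges[[t]],
      label = sprintf("Simulated checklist %d", t)
    )
  })
  names(trees) <- vapply(trees, function(t) t$source_id, character(1))
  attr(trees, "inconsistent") <- inconsistent
  attr(trees, "shared") <- shared
  trees
}

#' Synthetic five-checklist genus example
#'
#' Reads the shipped synthetic genus checklists: five sources describing the
#' same (invented) weevil genus *Exemplarius* with 1 to 16 species,
#' two sources sharing an identical six-species set, one species absent from
#' one large source, one species carried only as a synonym of another, and
#' higher classifications of different depths. The fixture mirrors the
#' *relationships* seen when aggregators disagree about a genus, with
#' entirely synthetic names and counts; it is used for integration tests
#' and examples.
#'
#' @return named list of five [source_tree()] objects.
#' @export
demo_genus_checklists <- function() {
  dir <- system.file("extdata", "synthetic_genus", package = "taxalign", mustWork = TRUE)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  trees <- lapply(files, read_checklist)
  names(trees) <- vapply(trees, function(t) t$source_id, character(1))
  trees
}
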