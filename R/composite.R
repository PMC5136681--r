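#' Parental-path compatibility
#'
#' Two parental paths (ancestor literal sequences, parent first, root last)
#' are compatible when the shorter one is an ordered subsequence of the
#' longer one: the assignments differ only in intermediate names, so one can
#' be embedded into the other. The relation is reflexive and symmetric. An
#' empty path (a root node) is compatible with everything.
#'
#' @param a,b character vectors as returned by [parent_path()].
#' @return single logical.
#' @export
#' @examples
#' path_compatible(c("B"), c("C", "B")) # B -> D embeds in B -> C -> D
#' path_compatible(c("P", "Q"), c("Q", "P")) # crossed order: incompatible
path_compatible <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) > length(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  if (length(a) == 0L) return(TRUE)
  i <- 1L
  for (x in b) {
    if (i <= length(a) && identical(a[[i]], x)) i <- i + 1L
    if (i > length(a)) break
  }
  i > length(a)
}

# ---- mutable build state -----------------------------------------------
#
# The composite is built in an environment holding parallel vectors per
# composite node plus three hashed maps (the forward map, its inverse, and
# the double-indexed parental-name table). A frozen, value-semantics
# `composite_tree` object is produced by cx_freeze() and re-hydrated by
# cx_thaw() so that incorporate() behaves as a pure function.

cx_new_state <- function() {
  st <- new.env(parent = emptyenv())
  st$literal <- character(0)
  st$suffix <- integer(0)
  st$parent <- integer(0) # 0 = virtual super-root
  st$children <- list()
  st$root_children <- integer(0)
  st$forward <- new.env(parent = emptyenv()) # key src|usage -> node_id
  st$rev <- list() # node_id -> character vector of src|usage keys
  st$pn <- new.env(parent = emptyenv()) # key literal|parent_literal -> node ids
  st$lit_nodes <- new.env(parent = emptyenv()) # literal -> node ids
  st$order <- character(0)
  st$sources <- list()
  st
}

cx_n <- function(st) length(st$literal)

cx_children <- function(st, id) {
  if (id == 0L) st$root_children else st$children[[id]]
}

cx_new_node <- function(st, literal, parent) {
  id <- cx_n(st) + 1L
  existing <- st$lit_nodes[[literal]]
  st$literal[[id]] <- literal
  # same-literal duplicates are distinguished by suffixes, assigned in
  # creation order: 0 (printed bare) for the first, 1 for the second, ...
  st$suffix[[id]] <- length(existing)
  st$parent[[id]] <- parent
  st$children[[id]] <- integer(0)
  st$rev[[id]] <- character(0)
  if (parent == 0L) {
    st$root_children <- c(st$root_children, id)
  } else {
    st$children[[parent]] <- c(st$children[[parent]], id)
  }
  st$lit_nodes[[literal]] <- c(existing, id)
  id
}

cx_parent_path <- function(st, id) {
  path <- character(0)
  p <- st$parent[[id]]
  while (p != 0L) {
    path <- c(path, st$literal[[p]])
    p <- st$parent[[p]]
  }
  path
}

# is `a` a (strict or equal) descendant of `b`? super-root (0) contains all.
cx_is_descendant <- function(st, a, b) {
  if (b == 0L) return(TRUE)
  p <- a
  while (p != 0L) {
    if (p == b) return(TRUE)
    p <- st$parent[[p]]
  }
  FALSE
}

cx_node_sources <- function(st, id) {
  keys <- st$rev[[id]]
  if (!length(keys)) return(character(0))
  vapply(strsplit(keys, .sep, fixed = TRUE), `[[`, character(1), 1L)
}

cx_add_map <- function(st, node, source_id, usage_id, parent_literal) {
  st$forward[[map_key(source_id, usage_id)]] <- node
  st$rev[[node]] <- c(st$rev[[node]], map_key(source_id, usage_id))
  bkey <- map_key(st$literal[[node]], parent_literal)
  bucket <- st$pn[[bkey]]
  if (!node %in% bucket) st$pn[[bkey]] <- c(bucket, node)
  invisible(node)
}

# Re-parent a reused composite node when the new parental composite node
# refines its position (Fig-2 behaviour: reusing D under freshly inserted C
# dissolves the direct B-D edge; the parental-name table still remembers it).
cx_maybe_reparent <- function(st, node, new_parent) {
  cur <- st$parent[[node]]
  if (new_parent == cur || new_parent == node) {
    return(invisible(FALSE))
  }
  # only move downward: the new parent must sit strictly below the current one
  if (!cx_is_descendant(st, new_parent, cur)) {
    return(invisible(FALSE))
  }
  # cycle guard: never move a node into its own subtree
  if (cx_is_descendant(st, new_parent, node)) {
    return(invisible(FALSE))
  }
  if (cur == 0L) {
    st$root_children <- st$root_children[st$root_children != node]
  } else {
    st$children[[cur]] <- st$children[[cur]][st$children[[cur]] != node]
  }
  st$parent[[node]] <- new_parent
  st$children[[new_parent]] <- c(st$children[[new_parent]], node)
  invisible(TRUE)
}

# Candidate resolution, steps 1.2.1-1.2.3.
#
# Both compatibility branches compare the hierarchy node's parental path
# against each candidate's own *current* composite parental path (immediate
# parent included). The two branches differ only in the candidate list:
#  - 1.2.2: the (literal, parent-literal) bucket exists -> only its members;
#  - 1.2.3: no bucket shares the parental literal -> every composite node of
#    the literal. Testing the path above-and-including the differing parent
#    is what keeps e.g. ...->Artiodactyla->X and ...->Cetartiodactyla->X on
#    two separate composite nodes while still letting ...->X merge with
#    ...->Inserted->X.
# A candidate already carrying a usage of the source being incorporated is
# never reused (one hierarchy must occupy each composite row at most once).
cx_resolve <- function(st, literal, parent_literal, hier_path, exclude_source = NULL) {
  bucket <- st$pn[[map_key(literal, parent_literal)]]
  cands <- if (length(bucket)) bucket else st$lit_nodes[[literal]]
  if (!length(cands)) {
    return(NA_integer_) # step 1.2.1: caller creates a new node
  }
  if (!is.null(exclude_source)) {
    cands <- cands[!vapply(
      cands, function(id) exclude_source %in% cx_node_sources(st, id), logical(1)
    )]
  }
  ok <- cands[vapply(
    cands, function(id) path_compatible(hier_path, cx_parent_path(st, id)), logical(1)
  )]
  # modest and conservative: reuse only a unique surviving candidate
  if (length(ok) == 1L) ok[[1]] else NA_integer_
}

# ---- incorporation ------------------------------------------------------

cx_incorporate <- function(st, tree) {
  stopifnot(inherits(tree, "source_tree"))
  src <- tree$source_id
  if (src %in% st$order) {
    stop(sprintf("duplicate source: '%s' is already incorporated", src), call. = FALSE)
  }
  viol <- validate_source(tree)
  if (nrow(viol)) {
    stop(sprintf(
      "source '%s' is not a valid hierarchy: %s", src,
      paste(unique(viol$rule), collapse = ", ")
    ), call. = FALSE)
  }
  work <- tree

  map_one <- function(uid, plit, hpath, parental_comp) {
    cand <- cx_resolve(st, tree_literal(work, uid), plit, hpath, exclude_source = src)
    if (is.na(cand)) {
      comp <- cx_new_node(st, tree_literal(work, uid), parental_comp)
    } else {
      comp <- cand
      cx_maybe_reparent(st, comp, parental_comp)
    }
    cx_add_map(st, comp, src, uid, plit)
    comp
  }

  # breadth-first with a pre-fetch of one depth: a node is visited together
  # with the inspection of its children (steps 2.x) before they are queued,
  # so the parental-name lookup of step 1.2 only ever fires on roots.
  queue <- as.list(work$roots)
  while (length(queue)) {
    uid <- queue[[1L]]
    queue <- queue[-1L]

    comp <- st$forward[[map_key(src, uid)]]
    if (is.null(comp)) {
      # step 1.2 -- the super-root plays the parental composite node role
      comp <- map_one(uid, "", parent_path(work, uid), 0L)
    }

    if (length(tree_children(work, uid))) {
      # step 2.1: merge redundant same-literal siblings before matching
      work <- merge_redundant_children(work, uid)
      kids <- tree_children(work, uid)
      ulit <- tree_literal(work, uid)

      # step 2.2: literal-match children of the parental composite node and
      # rearrange the hierarchy children to the composite order
      matched <- character(0)
      avail <- kids
      for (ck in cx_children(st, comp)) {
        if (!length(avail)) break
        if (src %in% cx_node_sources(st, ck)) next
        hit <- avail[tree_literal(work, avail) == st$literal[[ck]]]
        if (length(hit)) {
          k <- hit[[1L]]
          cx_add_map(st, ck, src, k, ulit)
          matched <- c(matched, k)
          avail <- setdiff(avail, k)
        }
      }
      work$children[[uid]] <- c(matched, avail)

      # step 2.3: resolve the remaining children through the mapping tables
      hpath_kids <- c(ulit, parent_path(work, uid))
      for (k in avail) {
        map_one(k, ulit, hpath_kids, comp)
      }
      queue <- c(queue, as.list(tree_children(work, uid)))
    }
  }

  st$order <- c(st$order, src)
  st$sources[[src]] <- work
  invisible(st)
}

# ---- freeze / thaw ------------------------------------------------------

cx_freeze <- function(st) {
  n <- cx_n(st)
  fwd_keys <- sort(ls(st$forward))
  fwd <- if (length(fwd_keys)) {
    parts <- strsplit(fwd_keys, .sep, fixed = TRUE)
    tibble(
      source_id = vapply(parts, `[[`, character(1), 1L),
      usage_id = vapply(parts, `[[`, character(1), 2L),
      node_id = vapply(fwd_keys, function(k) st$forward[[k]], integer(1), USE.NAMES = FALSE)
    )
  } else {
    tibble(source_id = character(0), usage_id = character(0), node_id = integer(0))
  }
  pn_keys <- sort(ls(st$pn))
  pn <- if (length(pn_keys)) {
    parts <- strsplit(pn_keys, .sep, fixed = TRUE)
    tibble(
      literal = vapply(parts, `[[`, character(1), 1L),
      parent_literal = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", character(1)),
      node_id = lapply(pn_keys, function(k) st$pn[[k]])
    ) |>
      tidyr::unnest_longer("node_id")
  } else {
    tibble(literal = character(0), parent_literal = character(0), node_id = integer(0))
  }
  structure(
    list(
      nodes = tibble(
        node_id = seq_len(n),
        literal = st$literal,
        suffix = st$suffix,
        parent_id = st$parent
      ),
      children = st$children,
      root_children = st$root_children,
      forward = fwd,
      parental_name = pn,
      order = st$order,
      sources = st$sources
    ),
    class = "composite_tree"
  )
}

cx_thaw <- function(composite) {
  st <- cx_new_state()
  st$literal <- composite$nodes$literal
  st$suffix <- composite$nodes$suffix
  st$parent <- composite$nodes$parent_id
  st$children <- composite$children
  st$root_children <- composite$root_children
  st$rev <- rep(list(character(0)), cx_n(st))
  for (i in seq_len(nrow(composite$forward))) {
    k <- map_key(composite$forward$source_id[[i]], composite$forward$usage_id[[i]])
    node <- composite$forward$node_id[[i]]
    st$forward[[k]] <- node
    st$rev[[node]] <- c(st$rev[[node]], k)
  }
  for (i in seq_len(nrow(composite$parental_name))) {
    k <- map_key(
      composite$parental_name$literal[[i]],
      composite$parental_name$parent_literal[[i]]
    )
    st$pn[[k]] <- c(st$pn[[k]], composite$parental_name$node_id[[i]])
  }
  for (id in seq_len(cx_n(st))) {
    lit <- st$literal[[id]]
    st$lit_nodes[[lit]] <- c(st$lit_nodes[[lit]], id)
  }
  st$order <- composite$order
  st$sources <- composite$sources
  st
}

# ---- public operations --------------------------------------------------

#' Build the composite (aligner) tree from a sequence of hierarchies
#'
#' The first hierarchy is copied directly to make the initial composite
#' tree (modulo merging of redundant same-literal siblings); each subsequent
#' hierarchy is embedded by [incorporate()]. The result is a pure function
#' of the input sequence: the composite can depend on the order of
#' incorporation, but two runs over the same ordered inputs produce
#' identical composites, including duplicate suffixes.
#'
#' The composite is a forest hung under a virtual super-root so that
#' hierarchies with incompatible highest taxa coexist as independent trees;
#' the super-root never appears in exports or layouts.
#'
#' @param trees list of [source_tree()] objects with distinct `source_id`s.
#' @return an object of class `composite_tree` with elements `nodes`
#'   (tibble: `node_id`, `literal`, `suffix`, `parent_id`; `parent_id = 0`
#'   denotes the super-root), `forward` (tibble mapping
#'   `source_id`/`usage_id` to `node_id`), `parental_name` (the
#'   double-indexed literal/parent-literal table), `order`, and `sources`
#'   (the post-merge structural copies of the inputs).
#' @export
#' @examples
#' pair <- schematic_pair()
#' cx <- build_composite(pair)
#' tidy(cx)
build_composite <- function(trees) {
  if (inherits(trees, "source_tree")) trees <- list(trees)
  if (!length(trees)) stop("no hierarchies", call. = FALSE)
  st <- cx_new_state()
  for (tree in trees) cx_incorporate(st, tree)
  cx_freeze(st)
}

#' Incorporate one more hierarchy into an existing composite tree
#'
#' Scans the hierarchy breadth-first with a pre-fetch of one depth and
#' applies the mapping steps: forward-map lookup, candidate resolution via
#' the parental-name table ([resolve_candidate()]), redundant-sibling
#' merging ([merge_redundant_children()]) and child-order alignment.
#'
#' @param composite a `composite_tree` from [build_composite()].
#' @param tree a [source_tree()] not yet incorporated.
#' @return a new `composite_tree`; the input is not modified.
#' @export
incorporate <- function(composite, tree) {
  stopifnot(inherits(composite, "composite_tree"))
  if (!length(composite$order)) stop("composite is empty", call. = FALSE)
  st <- cx_thaw(composite)
  cx_incorporate(st, tree)
  cx_freeze(st)
}

#' Merge redundant same-literal children of one node
#'
#' Among the children of `parent_usage_id`, all siblings sharing a literal
#' are merged into the first-occurring one; the lower nodes of the removed
#' siblings are transferred to the survivor (appended after its own
#' children) and the removed usages disappear from the tree. Synonym
#' annotations pointing at a removed usage are re-pointed at the survivor.
#' Child order is otherwise preserved.
#'
#' @param tree a [source_tree()].
#' @param parent_usage_id usage whose children are inspected.
#' @return a new `source_tree`.
#' @export
merge_redundant_children <- function(tree, parent_usage_id) {
  stopifnot(inherits(tree, "source_tree"))
  if (!parent_usage_id %in% tree$nodes$usage_id) {
    stop(sprintf("unknown usage '%s'", parent_usage_id), call. = FALSE)
  }
  kids <- tree_children(tree, parent_usage_id)
  lits <- tree_literal(tree, kids)
  if (!anyDuplicated(lits)) {
    return(tree)
  }
  keep <- !duplicated(lits)
  survivors <- setNames(kids[keep][match(lits, lits[keep])], kids)
  for (r in kids[!keep]) {
    s <- survivors[[r]]
    moved <- tree_children(tree, r)
    if (length(moved)) {
      tree$children[[s]] <- c(tree_children(tree, s), moved)
      tree$nodes$parent_id[tree$nodes$usage_id %in% moved] <- s
    }
    tree$children[[r]] <- NULL
    tree$nodes$accepted_id[!is.na(tree$nodes$accepted_id) &
      tree$nodes$accepted_id == r] <- s
    lit_r <- tree_literal(tree, r)
    tree$by_literal[[lit_r]] <- setdiff(tree$by_literal[[lit_r]], r)
    tree$nodes <- tree$nodes[tree$nodes$usage_id != r, , drop = FALSE]
  }
  tree$children[[parent_usage_id]] <- kids[keep]
  tree
}

#' Resolve the composite-node candidate for a name usage
#'
#' Consults the parental-name table by (literal, immediate parent literal).
#' With no entry for the literal at all, returns `NA` (the caller creates a
#' new composite node). When entries sharing the parental literal exist,
#' only they are examined; otherwise every composite node of the literal is.
#' In both cases the usage's parental path is tested for compatibility
#' against each candidate's current composite parental path, and a candidate
#' is returned only when it is unique -- the merge is deliberately modest
#' and conservative.
#'
#' @param composite a `composite_tree`.
#' @param literal name literal being placed.
#' @param parent_path ancestor literal sequence of the usage (parent first);
#'   the immediate parent literal is its first element (`""` for roots).
#' @param exclude_source optional source id whose occupied composite nodes
#'   are not reusable.
#' @return a composite `node_id`, or `NA_integer_` when no unique candidate
#'   exists.
#' @export
resolve_candidate <- function(composite, literal, parent_path = character(0),
                              exclude_source = NULL) {
  stopifnot(inherits(composite, "composite_tree"))
  st <- cx_thaw(composite)
  plit <- if (length(parent_path)) parent_path[[1L]] else ""
  cx_resolve(st, normalize_literal(literal), plit,
    as.character(parent_path),
    exclude_source = exclude_source
  )
}

#' Reorder a node's children to match the composite child order
#'
#' Children of `parent_usage_id` whose literals match children of the
#' corresponding composite node are moved to the composite children's
#' order; unmatched children keep their relative order and follow the
#' matched ones. During [incorporate()] this step also registers the
#' matched (source child, composite child) pairs in the mapping tables;
#' the standalone function only reorders.
#'
#' @param composite a `composite_tree` that has `parent_usage_id` of `tree`
#'   in its forward map.
#' @param tree a [source_tree()].
#' @param parent_usage_id usage whose children are reordered.
#' @return a new `source_tree` with reordered children.
#' @export
align_child_order <- function(composite, tree, parent_usage_id) {
  stopifnot(inherits(composite, "composite_tree"), inherits(tree, "source_tree"))
  fwd <- composite$forward
  hit <- fwd$node_id[fwd$source_id == tree$source_id & fwd$usage_id == parent_usage_id]
  if (!length(hit)) {
    stop(sprintf("usage '%s' is not in the forward map", parent_usage_id), call. = FALSE)
  }
  comp_kids <- if (hit[[1L]] == 0L) composite$root_children else composite$children[[hit[[1L]]]]
  comp_lits <- composite$nodes$literal[comp_kids]
  kids <- tree_children(tree, parent_usage_id)
  matched <- character(0)
  avail <- kids
  for (clit in comp_lits) {
    hit_k <- avail[tree_literal(tree, avail) == clit]
    if (length(hit_k)) {
      matched <- c(matched, hit_k[[1L]])
      avail <- setdiff(avail, hit_k[[1L]])
    }
  }
  tree$children[[parent_usage_id]] <- c(matched, avail)
  tree
}

# ---- accessors & methods ------------------------------------------------

#' Reverse map of a composite tree
#'
#' The exact inverse of the forward map: which name usages (per source) each
#' composite node covers.
#'
#' @param composite a `composite_tree`.
#' @return tibble with columns `node_id`, `source_id`, `usage_id`.
#' @export
reverse_map <- function(composite) {
  stopifnot(inherits(composite, "composite_tree"))
  composite$forward |>
    select("node_id", "source_id", "usage_id") |>
    arrange(.data$node_id)
}

# ancestor literals of each composite node (list indexed by node_id)
composite_ancestor_literals <- function(composite) {
  parent <- composite$nodes$parent_id
  lit <- composite$nodes$literal
  lapply(seq_along(parent), function(id) {
    path <- character(0)
    p <- parent[[id]]
    while (p != 0L) {
      path <- c(path, lit[[p]])
      p <- parent[[p]]
    }
    path
  })
}

# pre-order node ids of the composite forest, optionally skipping collapsed
# subtrees (collapsed nodes themselves stay visible)
composite_preorder <- function(composite, collapsed = integer(0)) {
  out <- integer(0)
  walk <- function(id) {
    out[[length(out) + 1L]] <<- id
    if (!id %in% collapsed) {
      for (k in composite$children[[id]]) walk(k)
    }
  }
  for (r in composite$root_children) walk(r)
  out
}

#' @export
print.composite_tree <- function(x, ...) {
  dup <- x$nodes |>
    dplyr::count(.data$literal) |>
    filter(.data$n > 1L)
  cat(sprintf(
    "<composite_tree> %d nodes over %d hierarchies (%s); %d duplicated literal(s)\n",
    nrow(x$nodes), length(x$order), paste(x$order, collapse = ", "), nrow(dup)
  ))
  invisible(x)
}

#' @rdname build_composite
#' @param x a `composite_tree`.
#' @param ... unused.
#' @export
tidy.composite_tree <- function(x, ...) {
  par_lit <- rep(NA_character_, nrow(x$nodes))
  has_par <- x$nodes$parent_id > 0L
  par_lit[has_par] <- x$nodes$literal[x$nodes$parent_id[has_par]]
  n_us <- x$forward |>
    dplyr::count(.data$node_id, name = "n_usages")
  x$nodes |>
    mutate(parent_literal = par_lit) |>
    left_join(n_us, by = "node_id") |>
    mutate(n_usages = tidyr::replace_na(.data$n_usages, 0L))
}

#' @rdname build_composite
#' @export
glance.composite_tree <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_sources = length(x$order),
    n_trees = length(x$root_children),
    n_mapped_usages = nrow(x$forward),
    n_duplicated_literals = sum(table(x$nodes$literal) > 1L)
  )
}
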