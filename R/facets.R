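#' Cell markers used in assignment tables
#'
#' A cell of an assignment table holds the higher-name literal(s) of a name
#' literal in one hierarchy. Two markers are reserved: the empty string for
#' a literal absent from the hierarchy (a vacancy), and `"(root)"` for a
#' usage at the root of its hierarchy, which is shown without a higher name.
#'
#' @name cell-markers
#' @return a single string.
#' @export
cell_absent <- function() ""

#' @rdname cell-markers
#' @export
cell_root <- function() "(root)"

# separator used when one hierarchy holds several usages of a literal under
# distinct higher names: the cell carries the list, order-stable
.cell_sep <- " | "

#' Higher-name assignment of a literal in one hierarchy
#'
#' Returns the cell content for one (literal, hierarchy) pair: the empty
#' marker when the literal is absent, the root marker when the usage is the
#' hierarchy's root, and otherwise the distinct immediate higher literals in
#' node order (several when the hierarchy holds the literal under more than
#' one parent), joined by `" | "`.
#'
#' @param literal name literal.
#' @param tree a [source_tree()].
#' @return single character value.
#' @export
assignment_cell <- function(literal, tree) {
  stopifnot(inherits(tree, "source_tree"))
  literal <- normalize_literal(literal)
  ids <- tree$by_literal[[literal]]
  ids <- ids[tree$nodes$status[match(ids, tree$nodes$usage_id)] != "synonym"]
  if (!length(ids)) {
    return(cell_absent())
  }
  parents <- tree_parent(tree, ids)
  vals <- ifelse(is.na(parents), cell_root(), tree_literal(tree, parents))
  paste(unique(vals), collapse = .cell_sep)
}

# per-usage immediate higher literal values of a literal in one tree
cell_values <- function(literal, tree) {
  ids <- tree$by_literal[[literal]]
  ids <- ids[tree$nodes$status[match(ids, tree$nodes$usage_id)] != "synonym"]
  if (!length(ids)) {
    return(character(0))
  }
  parents <- tree_parent(tree, ids)
  unique(ifelse(is.na(parents), cell_root(), tree_literal(tree, parents)))
}

#' Classify name literals into comparison facets
#'
#' Builds the per-facet assignment tables of the comparison: for every name
#' literal occurring in any hierarchy, one row with the higher-name cell of
#' every hierarchy ([assignment_cell()]), distributed over six facets:
#'
#' * `all` -- every literal (the full search-result table);
#' * `inconsistent` -- literals the composite tree holds two or more nodes
#'   for, i.e. same lower literal under incompatible higher-name paths;
#'   extracted from the composite tree alone, so both inter- and
#'   intra-hierarchy inconsistencies are captured;
#' * `different` -- literals whose immediate higher literals differ across
#'   hierarchies while all parental paths remain mutually compatible (the
#'   higher-name-path conformal case); excludes `inconsistent`;
#' * `missing` -- literals absent from at least one hierarchy, without
#'   inconsistency and without higher-name difference among the hierarchies
#'   that do hold them (a difference dominates an absence);
#' * `common` -- literals sharing both the literal and the immediate higher
#'   literal in every hierarchy;
#' * `synonyms` -- heuristic "potential synonyms between hierarchies":
#'   literals where some usage's immediate higher literal is not on the
#'   ancestor literal path of its composite node. Such rows always also
#'   appear in `different`.
#'
#' `common`, `different`, `missing` and `inconsistent` partition the literal
#' universe. Rows are ordered alphabetically by literal.
#'
#' @param composite the `composite_tree` built from exactly these trees.
#' @param trees the incorporated hierarchies; defaults to the structural
#'   copies stored in the composite.
#' @return an object of class `facet_tables`: a named list of tibbles
#'   (facets `all`, `common`, `different`, `missing`, `inconsistent`,
#'   `synonyms`), each with a `literal` column and one column per
#'   `source_id`.
#' @export
#' @examples
#' cx <- build_composite(schematic_pair())
#' classify(cx)$different
classify <- function(composite, trees = composite$sources) {
  stopifnot(inherits(composite, "composite_tree"))
  if (inherits(trees, "source_tree")) trees <- list(trees)
  src_ids <- vapply(trees, function(t) t$source_id, character(1))
  names(trees) <- src_ids
  if (!setequal(src_ids, composite$order) || anyDuplicated(src_ids)) {
    stop("stale composite: trees do not match the incorporated sources", call. = FALSE)
  }
  for (s in src_ids) {
    if (!all(trees[[s]]$nodes$usage_id[trees[[s]]$nodes$status != "synonym"]
    %in% composite$forward$usage_id[composite$forward$source_id == s])) {
      # user passed pre-merge originals: fall back to the stored copies
      trees[[s]] <- composite$sources[[s]]
    }
  }
  trees <- trees[composite$order]
  src_ids <- composite$order

  hier_literals <- sort(unique(unlist(
    lapply(trees, function(t) t$nodes$literal[t$nodes$status != "synonym"]),
    use.names = FALSE
  )))

  node_count <- table(composite$nodes$literal)
  anc <- composite_ancestor_literals(composite)
  fwd <- composite$forward

  # per-usage off-path test for the potential-synonym heuristic
  off_path_literals <- character(0)
  for (s in src_ids) {
    t <- trees[[s]]
    hn <- t$nodes[t$nodes$status != "synonym", , drop = FALSE]
    f <- fwd[fwd$source_id == s, , drop = FALSE]
    nid <- f$node_id[match(hn$usage_id, f$usage_id)]
    plit <- tree_literal(t, hn$parent_id)
    has_parent <- !is.na(hn$parent_id)
    off <- vapply(which(has_parent), function(i) {
      !plit[[i]] %in% anc[[nid[[i]]]]
    }, logical(1))
    off_path_literals <- union(off_path_literals, hn$literal[has_parent][off])
  }

  cells <- lapply(trees, function(t) {
    vapply(hier_literals, assignment_cell, character(1), tree = t)
  })
  cell_mat <- do.call(cbind, cells) # literals x sources
  value_sets <- lapply(hier_literals, function(L) {
    unlist(lapply(trees, function(t) cell_values(L, t)), use.names = FALSE)
  })

  present_everywhere <- apply(cell_mat != cell_absent(), 1L, all)
  n_values <- vapply(value_sets, function(v) length(unique(v)), integer(1))
  inconsistent <- as.integer(node_count[hier_literals]) >= 2L
  different <- !inconsistent & n_values >= 2L
  missing <- !inconsistent & !different & !present_everywhere
  common <- !inconsistent & !different & present_everywhere
  synonyms <- !inconsistent & hier_literals %in% off_path_literals

  table_of <- function(keep) {
    tab <- tibble(literal = hier_literals[keep])
    for (j in seq_along(src_ids)) tab[[src_ids[[j]]]] <- cell_mat[keep, j]
    tab
  }
  structure(
    list(
      all = table_of(rep(TRUE, length(hier_literals))),
      common = table_of(common),
      different = table_of(different),
      missing = table_of(missing),
      inconsistent = table_of(inconsistent),
      synonyms = table_of(synonyms)
    ),
    labels = setNames(vapply(trees, function(t) t$label, character(1)), src_ids),
    class = "facet_tables"
  )
}

#' Facet names
#' @return character vector of the six facet names in display order.
#' @export
facet_names <- function() {
  c("all", "common", "different", "missing", "inconsistent", "synonyms")
}

#' @export
print.facet_tables <- function(x, ...) {
  counts <- vapply(x, nrow, integer(1))
  cat("<facet_tables>\n")
  for (f in names(counts)) cat(sprintf("  %-13s %d\n", f, counts[[f]]))
  invisible(x)
}

#' @rdname classify
#' @param x a `facet_tables` object.
#' @param ... unused.
#' @export
tidy.facet_tables <- function(x, ...) {
  purrr::imap(unclass(x), function(tab, facet) {
    tab |>
      tidyr::pivot_longer(-"literal",
        names_to = "source_id", values_to = "higher"
      ) |>
      mutate(facet = facet)
  }) |>
    bind_rows() |>
    select("facet", "literal", "source_id", "higher")
}

#' @rdname classify
#' @export
glance.facet_tables <- function(x, ...) {
  as_tibble(as.list(vapply(x, nrow, integer(1))))
}

#' Plot facet sizes
#'
#' Bar chart of the number of name literals per comparison facet.
#'
#' @param object a `facet_tables` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.facet_tables <- function(object, ...) {
  dat <- tibble(
    facet = factor(names(object), levels = facet_names()),
    n = vapply(object, nrow, integer(1))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$facet, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "name literals") +
    ggplot2::theme_minimal()
}
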