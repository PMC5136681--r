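#' Build a source tree from a table of name usages
#'
#' A source tree is the in-memory form of one taxonomic hierarchy (one
#' checklist, one dataset): a tibble of name usages plus the derived
#' parent/child adjacency and an index from name literal to usage ids.
#' Usages whose `status` is `"synonym"` are retained as annotations of their
#' accepted usage (via `accepted_id`) and do not take part in the hierarchy
#' structure, mirroring how checklists attach synonym rows through
#' `acceptedNameUsageID` rather than `parentNameUsageID`.
#'
#' The constructor is permissive: structurally broken input (cycles,
#' dangling parents, self-parents) is stored as-is so that
#' [validate_source()] can report the violations. Readers such as
#' [read_checklist()] call [validate_source()] and fail on violations.
#'
#' @param nodes data frame with columns `usage_id`, `literal` and optionally
#'   `rank`, `status` (`accepted`, `synonym`, `doubtful` or `unknown`),
#'   `parent_id` (`NA` for roots), `accepted_id` (for synonyms).
#' @param source_id dataset identifier (unique among compared hierarchies).
#' @param label human-readable dataset name; defaults to `source_id`.
#' @return an object of class `source_tree`.
#' @export
#' @examples
#' h <- source_tree(
#'   tibble::tibble(
#'     usage_id = c("1", "2"),
#'     literal = c("Animalia", "Chordata"),
#'     parent_id = c(NA, "1")
#'   ),
#'   source_id = "demo"
#' )
#' tidy(h)
source_tree <- function(nodes, source_id, label = source_id) {
  stopifnot(is.data.frame(nodes), nrow(nodes) >= 1L)
  stopifnot(is.character(source_id) || is.factor(source_id), length(source_id) == 1L)
  source_id <- as.character(source_id)

  nodes <- as_tibble(nodes)
  if (!all(c("usage_id", "literal") %in% names(nodes))) {
    stop("`nodes` must contain columns `usage_id` and `literal`", call. = FALSE)
  }
  for (col in c("rank", "status", "parent_id", "accepted_id")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
  }
  nodes <- nodes |>
    mutate(
      usage_id = as.character(.data$usage_id),
      literal = normalize_literal(.data$literal),
      rank = ifelse(is.na(.data$rank) | !nzchar(.data$rank),
        "unranked", tolower(as.character(.data$rank))
      ),
      status = normalize_status(.data$status),
      parent_id = empty_to_na(as.character(.data$parent_id)),
      accepted_id = empty_to_na(as.character(.data$accepted_id)),
      source_id = source_id
    ) |>
    select("usage_id", "literal", "rank", "status", "parent_id",
      "accepted_id", "source_id")

  hier <- nodes[nodes$status != "synonym", , drop = FALSE]
  roots <- hier$usage_id[is.na(hier$parent_id)]
  kids <- hier[!is.na(hier$parent_id), c("parent_id", "usage_id")]
  children <- split(kids$usage_id, factor(kids$parent_id, levels = unique(kids$parent_id)))
  by_literal <- split(nodes$usage_id, nodes$literal)

  structure(
    list(
      source_id = source_id,
      label = as.character(label),
      nodes = nodes,
      roots = roots,
      children = children,
      by_literal = by_literal
    ),
    class = "source_tree"
  )
}

normalize_status <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", as.character(x))))
  dplyr::case_when(
    grepl("synonym", x) ~ "synonym",
    x %in% c("accepted", "valid", "") ~ "accepted",
    x == "doubtful" ~ "doubtful",
    TRUE ~ "unknown"
  )
}

empty_to_na <- function(x) ifelse(!is.na(x) & !nzchar(trimws(x)), NA_character_, x)

#' @export
print.source_tree <- function(x, ...) {
  cat(sprintf(
    "<source_tree> %s (\"%s\"): %d usages (%d synonym annotations), %d root(s)\n",
    x$source_id, x$label, nrow(x$nodes),
    sum(x$nodes$status == "synonym"), length(x$roots)
  ))
  invisible(x)
}

#' @export
format.source_tree <- function(x, ...) {
  lines <- character(0)
  walk <- function(id, depth) {
    lit <- x$nodes$literal[match(id, x$nodes$usage_id)]
    lines <<- c(lines, paste0(strrep("  ", depth), lit))
    for (k in tree_children(x, id)) walk(k, depth + 1L)
  }
  for (r in x$roots) walk(r, 0L)
  lines
}

# ordered children of a usage (hierarchy nodes only)
tree_children <- function(tree, usage_id) {
  kids <- tree$children[[usage_id]]
  if (is.null(kids)) character(0) else kids
}

tree_literal <- function(tree, usage_id) {
  tree$nodes$literal[match(usage_id, tree$nodes$usage_id)]
}

tree_parent <- function(tree, usage_id) {
  tree$nodes$parent_id[match(usage_id, tree$nodes$usage_id)]
}

#' Ancestor literal sequence of a usage
#'
#' The parental path of a node: the ordered literals from its immediate
#' parent up to its root, exclusive of the node's own literal. Empty for
#' root nodes. Parental paths are what the composite-tree merge compares
#' when deciding whether two same-literal usages may share a composite node.
#'
#' @param tree a [source_tree()].
#' @param usage_id usage identifier.
#' @return character vector (possibly empty), parent first, root last.
#' @export
parent_path <- function(tree, usage_id) {
  path <- character(0)
  seen <- character(0)
  p <- tree_parent(tree, usage_id)
  while (!is.na(p) && !p %in% seen) {
    seen <- c(seen, p)
    path <- c(path, tree_literal(tree, p))
    p <- tree_parent(tree, p)
  }
  path
}

# depth of each hierarchy usage within its tree (root = 0); named integer
node_depths <- function(tree) {
  depths <- integer(0)
  walk <- function(id, d) {
    depths[[id]] <<- d
    for (k in tree_children(tree, id)) walk(k, d + 1L)
  }
  for (r in tree$roots) walk(r, 0L)
  depths
}

#' Validate the structural invariants of a source tree
#'
#' Reports, rather than throws: returns a tibble with one row per violation.
#' Checked rules: unique usage ids; non-empty literals; no self-parent; every
#' non-root parent resolves; no parent cycles; `accepted_id` only on synonym
#' usages; at least one root; the literal index is consistent with the node
#' table.
#'
#' @param tree a [source_tree()].
#' @return tibble with columns `usage_id`, `rule`, `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_source <- function(tree) {
  stopifnot(inherits(tree, "source_tree"))
  n <- tree$nodes
  v <- list()
  bad <- function(ids, rule, msg) {
    tibble(usage_id = as.character(ids), rule = rule, message = msg)
  }

  dup <- unique(n$usage_id[duplicated(n$usage_id)])
  if (length(dup)) v <- c(v, list(bad(dup, "duplicate_id", "usage_id is not unique")))

  blank <- n$usage_id[!nzchar(n$literal)]
  if (length(blank)) v <- c(v, list(bad(blank, "empty_literal", "literal is empty after whitespace normalization")))

  selfp <- n$usage_id[!is.na(n$parent_id) & n$parent_id == n$usage_id]
  if (length(selfp)) v <- c(v, list(bad(selfp, "self_parent", "usage is its own parent")))

  dangling <- n$usage_id[!is.na(n$parent_id) & !n$parent_id %in% n$usage_id]
  if (length(dangling)) v <- c(v, list(bad(dangling, "unresolved_parent", "parent_id does not resolve within the tree")))

  badacc <- n$usage_id[!is.na(n$accepted_id) & n$status != "synonym"]
  if (length(badacc)) v <- c(v, list(bad(badacc, "accepted_on_non_synonym", "accepted_id set but status is not synonym")))

  # cycles: follow parent chains with colouring (hierarchy usages only)
  hier <- n[n$status != "synonym", , drop = FALSE]
  parent <- setNames(hier$parent_id, hier$usage_id)
  state <- setNames(rep(0L, nrow(hier)), hier$usage_id) # 0 new, 1 active, 2 done
  cyc <- character(0)
  for (id in hier$usage_id) {
    if (state[[id]] != 0L) next
    chain <- character(0)
    cur <- id
    while (!is.na(cur) && !is.null(state[[cur]]) && state[[cur]] == 0L) {
      state[[cur]] <- 1L
      chain <- c(chain, cur)
      cur <- if (cur %in% names(parent)) parent[[cur]] else NA_character_
      if (is.na(cur) || !cur %in% names(state)) break
    }
    if (!is.na(cur) && cur %in% names(state) && state[[cur]] == 1L) {
      # chain from cur onward is a cycle
      cyc <- c(cyc, chain[seq(match(cur, chain), length(chain))])
    }
    state[chain] <- 2L
  }
  if (length(cyc)) v <- c(v, list(bad(unique(cyc), "cycle", "usage participates in a parent cycle")))

  if (length(tree$roots) == 0L && !length(cyc) && !length(dangling)) {
    v <- c(v, list(bad(NA_character_, "no_root", "tree has no root usage")))
  }

  # literal index consistency
  idx_ids <- unlist(tree$by_literal, use.names = FALSE)
  if (!setequal(idx_ids, n$usage_id) ||
    !all(rep(names(tree$by_literal), lengths(tree$by_literal)) ==
      n$literal[match(idx_ids, n$usage_id)])) {
    v <- c(v, list(bad(NA_character_, "literal_index", "by_literal index inconsistent with nodes")))
  }

  if (length(v)) bind_rows(v) else tibble(
    usage_id = character(0), rule = character(0), message = character(0)
  )
}

#' @rdname source_tree
#' @param x a `source_tree`.
#' @param ... unused.
#' @export
tidy.source_tree <- function(x, ...) {
  d <- node_depths(x)
  x$nodes |>
    mutate(depth = unname(d[match(.data$usage_id, names(d))]))
}

#' @rdname source_tree
#' @export
glance.source_tree <- function(x, ...) {
  tibble(
    source_id = x$source_id,
    label = x$label,
    n_usages = nrow(x$nodes),
    n_synonyms = sum(x$nodes$status == "synonym"),
    n_roots = length(x$roots),
    max_depth = max(c(node_depths(x), 0L))
  )
}
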