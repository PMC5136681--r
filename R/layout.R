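#' Synchronized row layout for aligned display
#'
#' Assigns one global row per visible composite node (pre-order over the
#' composite forest, parents above children) and places every mapped name
#' usage of every hierarchy on the row of its composite node. Vertical
#' placement is thus determined by the composite tree while horizontal
#' placement (`depth`) is decided by each hierarchy alone: a literal absent
#' from a hierarchy leaves a vacancy in that column, and removing a
#' hierarchy never changes the relative row order of the remaining
#' placements.
#'
#' @param composite a `composite_tree` from [build_composite()].
#' @param collapsed integer vector of composite `node_id`s whose subtrees
#'   are hidden (the collapsed node itself stays visible). Collapsing is
#'   synchronized across all hierarchies because it operates on composite
#'   nodes; see [synchronize_toggle()].
#' @return an object of class `row_layout`: `rows` (tibble `node_id`,
#'   `literal`, `suffix`, `row`), `placements` (tibble `source_id`,
#'   `usage_id`, `literal`, `row`, `depth` with `depth` the usage's depth in
#'   its own source tree, root = 0) and `total_rows`.
#' @export
#' @examples
#' cx <- build_composite(schematic_trio())
#' assign_rows(cx)
assign_rows <- function(composite, collapsed = integer(0)) {
  stopifnot(inherits(composite, "composite_tree"))
  collapsed <- as.integer(collapsed)
  visible <- composite_preorder(composite, collapsed)
  rows <- tibble(
    node_id = visible,
    literal = composite$nodes$literal[visible],
    suffix = composite$nodes$suffix[visible],
    row = seq_along(visible) - 1L
  )

  depths <- lapply(composite$sources, node_depths)
  placements <- composite$forward |>
    filter(.data$node_id %in% visible) |>
    left_join(rows[, c("node_id", "row")], by = "node_id") |>
    mutate(
      literal = composite$nodes$literal[.data$node_id],
      depth = purrr::map2_int(
        .data$source_id, .data$usage_id,
        function(s, u) depths[[s]][[u]]
      )
    ) |>
    arrange(.data$row, match(.data$source_id, composite$order)) |>
    select("source_id", "usage_id", "literal", "row", "depth")

  structure(
    list(rows = rows, placements = placements, total_rows = nrow(rows)),
    class = "row_layout"
  )
}

#' Toggle a composite node's expansion state
#'
#' Expansion or collapse operates on composite nodes, so every hierarchy
#' reflects it simultaneously. Idempotent: expanding an expanded node (or
#' collapsing a collapsed one) leaves the set unchanged.
#'
#' @param collapsed current integer set of collapsed composite node ids.
#' @param node composite node id to toggle.
#' @param expand `TRUE` to expand (remove from the set), `FALSE` to collapse.
#' @return the new collapsed set (sorted integer vector).
#' @export
synchronize_toggle <- function(collapsed, node, expand) {
  node <- as.integer(node)
  stopifnot(length(node) == 1L, !is.na(node))
  collapsed <- as.integer(collapsed)
  out <- if (expand) setdiff(collapsed, node) else union(collapsed, node)
  sort(out)
}

#' @export
print.row_layout <- function(x, ...) {
  cat(sprintf(
    "<row_layout> %d rows, %d placements over %d hierarchies\n",
    x$total_rows, nrow(x$placements), length(unique(x$placements$source_id))
  ))
  invisible(x)
}

#' @rdname assign_rows
#' @param x a `row_layout`.
#' @param ... unused.
#' @export
tidy.row_layout <- function(x, ...) {
  x$placements
}

#' @rdname assign_rows
#' @export
glance.row_layout <- function(x, ...) {
  tibble(
    total_rows = x$total_rows,
    n_placements = nrow(x$placements),
    n_sources = length(unique(x$placements$source_id)),
    n_vacancies = x$total_rows * length(unique(x$placements$source_id)) -
      nrow(x$placements)
  )
}

#' Render an alignment as indented text columns
#'
#' A plain-text analogue of the folder-metaphor display: the first column is
#' the aligner (composite) tree, followed by one column per hierarchy, with
#' vacancies left blank. Intended for terminals and debugging; the layout
#' itself is pure data.
#'
#' @param composite a `composite_tree`.
#' @param layout a `row_layout`; computed from `composite` when omitted.
#' @param indent number of spaces per depth level.
#' @return character vector, one element per row (plus header), invisibly
#'   printed with [cat()] by [print.row_layout()] consumers.
#' @export
render_alignment <- function(composite, layout = assign_rows(composite), indent = 2L) {
  srcs <- composite$order
  anc <- composite_ancestor_literals(composite)
  depth_comp <- lengths(anc)[layout$rows$node_id]
  aligner <- paste0(
    strrep(strrep(" ", indent), depth_comp),
    layout$rows$literal,
    ifelse(layout$rows$suffix > 0L, paste0(" #", layout$rows$suffix), "")
  )
  cols <- c(list(aligner = aligner), lapply(srcs, function(s) {
    col <- rep("", layout$total_rows)
    pl <- layout$placements[layout$placements$source_id == s, , drop = FALSE]
    col[pl$row + 1L] <- paste0(strrep(strrep(" ", indent), pl$depth), pl$literal)
    col
  }))
  names(cols) <- c("aligner", srcs)
  widths <- pmax(nchar(names(cols)), vapply(cols, function(c) max(nchar(c), 0L), integer(1)))
  pad <- function(x, w) formatC(x, width = -w)
  header <- paste(mapply(pad, names(cols), widths), collapse = " | ")
  body <- apply(
    mapply(pad, cols, widths, SIMPLIFY = TRUE), 1L,
    paste, collapse = " | "
  )
  c(header, body)
}

#' Plot a synchronized alignment
#'
#' One column per hierarchy plus the aligner column; one row per composite
#' node; text indented by within-hierarchy depth. Vacancies (missing name
#' usages) appear as blank cells.
#'
#' @param object a `row_layout`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.row_layout <- function(object, ...) {
  pl <- object$placements |>
    mutate(column = .data$source_id)
  al <- object$rows |>
    mutate(
      column = "aligner",
      label = ifelse(.data$suffix > 0L,
        paste0(.data$literal, " #", .data$suffix), .data$literal
      ),
      depth = 0
    )
  pl <- pl |> mutate(label = .data$literal)
  cols <- c("aligner", unique(pl$source_id))
  dat <- bind_rows(
    al[, c("column", "row", "depth", "label")],
    pl[, c("column", "row", "depth", "label")]
  ) |>
    mutate(column = factor(.data$column, levels = cols))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$depth, y = -.data$row,
      label = .data$label
    )
  ) +
    ggplot2::geom_text(hjust = 0, size = 3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$column)) +
    ggplot2::scale_x_continuous(limits = c(0, NA), expand = ggplot2::expansion(add = c(0.2, 2))) +
    ggplot2::labs(x = "depth within hierarchy", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
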