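# Independent brute-force oracle for the composite-node count per literal:
# group the parental paths of all usages of a literal (in incorporation
# order, breadth-first within each hierarchy) into classes, joining a class
# only when it is the unique class all of whose members can embed/be
# embedded; otherwise open a new class. Implemented without any composite
# machinery, with its own subsequence test.

# independent ordered-subsequence check (recursive formulation)
oracle_embeds <- function(a, b) { # is a a subsequence of b?
  if (!length(a)) {
    return(TRUE)
  }
  if (!length(b)) {
    return(FALSE)
  }
  if (a[[1]] == b[[1]]) oracle_embeds(a[-1], b[-1]) else oracle_embeds(a, b[-1])
}

oracle_compatible <- function(a, b) {
  if (length(a) <= length(b)) oracle_embeds(a, b) else oracle_embeds(b, a)
}

# breadth-first usage ids of a source tree (hierarchy nodes only)
oracle_bfs <- function(tree) {
  out <- character(0)
  q <- tree$roots
  while (length(q)) {
    id <- q[[1]]
    q <- q[-1]
    out <- c(out, id)
    kids <- tree$children[[id]]
    if (!is.null(kids)) q <- c(q, kids)
  }
  out
}

# literal path from a usage's parent to its root, using only the nodes table
oracle_parent_path <- function(tree, usage_id) {
  n <- tree$nodes
  path <- character(0)
  p <- n$parent_id[match(usage_id, n$usage_id)]
  while (!is.na(p)) {
    path <- c(path, n$literal[match(p, n$usage_id)])
    p <- n$parent_id[match(p, n$usage_id)]
  }
  path
}

oracle_literal_counts <- function(trees) {
  classes <- list() # literal -> list of classes (each a list of paths)
  for (tree in trees) {
    for (id in oracle_bfs(tree)) {
      lit <- tree$nodes$literal[match(id, tree$nodes$usage_id)]
      p <- oracle_parent_path(tree, id)
      cls <- classes[[lit]]
      if (is.null(cls)) cls <- list()
      ok <- which(vapply(cls, function(members) {
        all(vapply(members, oracle_compatible, logical(1), b = p))
      }, logical(1)))
      if (length(ok) == 1L) {
        cls[[ok]] <- c(cls[[ok]], list(p))
      } else {
        cls[[length(cls) + 1L]] <- list(p)
      }
      classes[[lit]] <- cls
    }
  }
  vapply(classes, length, integer(1))
}
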