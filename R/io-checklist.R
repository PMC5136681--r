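#' Checklist dialect: column names, delimiter, encoding
#'
#' Describes how a flat checklist table maps onto name-usage fields. The
#' defaults are the Darwin Core Taxon terms used by checklist exchange
#' (`taxonID`, `parentNameUsageID`, `scientificName`, `taxonRank`,
#' `taxonomicStatus`, `acceptedNameUsageID`). `taxonID` and `scientificName`
#' are mandatory; the remaining columns are optional in the file.
#'
#' @param delimiter field delimiter; `NULL` sniffs comma vs tab from the
#'   first line.
#' @param usage_id,parent_id,literal,rank,status,accepted_id column names in
#'   the file for each name-usage field.
#' @param encoding file encoding.
#' @return an object of class `checklist_dialect`.
#' @export
checklist_dialect <- function(delimiter = NULL,
                              usage_id = "taxonID",
                              parent_id = "parentNameUsageID",
                              literal = "scientificName",
                              rank = "taxonRank",
                              status = "taxonomicStatus",
                              accepted_id = "acceptedNameUsageID",
                              encoding = "UTF-8") {
  structure(
    list(
      delimiter = delimiter,
      columns = c(
        usage_id = usage_id, parent_id = parent_id, literal = literal,
        rank = rank, status = status, accepted_id = accepted_id
      ),
      encoding = encoding
    ),
    class = "checklist_dialect"
  )
}

sniff_delimiter <- function(path, encoding = "UTF-8") {
  first <- readLines(path, n = 1L, encoding = encoding, warn = FALSE)
  if (length(first) && stringr::str_count(first, "\t") >
    stringr::str_count(first, ",")) "\t" else ","
}

#' Read a Darwin Core style checklist into a source tree
#'
#' Each row becomes a name usage; rows with an empty parent become roots;
#' rows whose status is a synonym are attached through their accepted usage
#' (`acceptedNameUsageID`) as annotations, not as children -- a synonym is
#' not an accepted member of its higher taxon, but the relationship remains
#' recoverable via the accepted name. Row order does not matter: parent rows
#' may follow their children.
#'
#' @param path file path.
#' @param source_id dataset identifier; defaults to the file name.
#' @param label human-readable dataset name.
#' @param dialect a [checklist_dialect()].
#' @return a validated [source_tree()].
#' @export
read_checklist <- function(path, source_id = NULL, label = NULL,
                           dialect = checklist_dialect()) {
  stopifnot(inherits(dialect, "checklist_dialect"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(label)) label <- source_id
  delim <- dialect$delimiter %||% sniff_delimiter(path, dialect$encoding)
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = dialect$encoding),
    progress = FALSE, show_col_types = FALSE
  )
  cols <- dialect$columns
  missing_mandatory <- setdiff(cols[c("usage_id", "literal")], names(raw))
  if (length(missing_mandatory)) {
    stop(sprintf(
      "checklist lacks mandatory column(s): %s",
      paste(missing_mandatory, collapse = ", ")
    ), call. = FALSE)
  }
  pick <- function(field) {
    if (cols[[field]] %in% names(raw)) raw[[cols[[field]]]] else NA_character_
  }
  nodes <- tibble(
    usage_id = pick("usage_id"),
    literal = pick("literal"),
    rank = pick("rank"),
    status = pick("status"),
    parent_id = pick("parent_id"),
    accepted_id = pick("accepted_id")
  )
  tree <- source_tree(nodes, source_id = source_id, label = label)
  viol <- validate_source(tree)
  if (nrow(viol)) {
    stop(sprintf(
      "invalid checklist %s: %s", path,
      paste(sprintf("[%s] %s (%s)", viol$rule, viol$message,
        ifelse(is.na(viol$usage_id), "-", viol$usage_id)
      ), collapse = "; ")
    ), call. = FALSE)
  }
  tree
}

#' Write a source tree as a Darwin Core style checklist
#'
#' @param tree a [source_tree()].
#' @param path output file path.
#' @param dialect a [checklist_dialect()]; `NULL` delimiter writes commas.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(tree, path, dialect = checklist_dialect()) {
  stopifnot(inherits(tree, "source_tree"))
  cols <- dialect$columns
  out <- tree$nodes |>
    select("usage_id", "parent_id", "literal", "rank", "status", "accepted_id")
  names(out) <- cols[names(out)]
  delim <- dialect$delimiter %||% ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read a nested JSON tree into a source tree
#'
#' The format mirrors the nested name-usage JSON of species-API responses:
#' objects with `literal` (mandatory at the root), optional `id`, `rank`,
#' `status`, `children` (array of the same shape) and `synonyms` (array of
#' `{literal, rank}` annotations). Usages without an `id` receive
#' deterministic pre-order identifiers (`n1`, `n2`, ...), so write/read
#' round-trips are stable. Duplicate literals among children load verbatim;
#' merging is the composite builder's job.
#'
#' @param path JSON file path.
#' @param source_id dataset identifier; defaults to the file name.
#' @param label human-readable dataset name.
#' @return a validated [source_tree()].
#' @export
read_json_tree <- function(path, source_id = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(label)) label <- source_id
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$literal)) obj <- list(obj) # single root
  rows <- list()
  counter <- 0L
  emit <- function(node, parent_id) {
    if (is.null(node$literal)) stop("JSON node lacks `literal`", call. = FALSE)
    counter <<- counter + 1L
    id <- as.character(node$id %||% paste0("n", counter))
    rows[[length(rows) + 1L]] <<- tibble(
      usage_id = id,
      literal = as.character(node$literal),
      rank = as.character(node$rank %||% NA_character_),
      status = as.character(node$status %||% NA_character_),
      parent_id = parent_id,
      accepted_id = NA_character_
    )
    for (syn in node$synonyms %||% list()) {
      counter <<- counter + 1L
      rows[[length(rows) + 1L]] <<- tibble(
        usage_id = as.character(syn$id %||% paste0("n", counter)),
        literal = as.character(syn$literal),
        rank = as.character(syn$rank %||% NA_character_),
        status = "synonym",
        parent_id = NA_character_,
        accepted_id = id
      )
    }
    for (child in node$children %||% list()) emit(child, id)
  }
  for (root in obj) emit(root, NA_character_)
  tree <- source_tree(bind_rows(rows), source_id = source_id, label = label)
  viol <- validate_source(tree)
  if (nrow(viol)) {
    stop(sprintf(
      "invalid JSON tree %s: %s", path,
      paste(unique(viol$rule), collapse = ", ")
    ), call. = FALSE)
  }
  tree
}

#' Write a source tree as a nested JSON tree
#'
#' Inverse of [read_json_tree()]: re-reading reproduces the tree (ids,
#' literals, ranks, statuses, child order and synonym annotations).
#'
#' @param tree a [source_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_json_tree <- function(tree, path) {
  stopifnot(inherits(tree, "source_tree"))
  n <- tree$nodes
  syn_of <- split(
    n$usage_id[n$status == "synonym" & !is.na(n$accepted_id)],
    n$accepted_id[n$status == "synonym" & !is.na(n$accepted_id)]
  )
  as_obj <- function(id) {
    i <- match(id, n$usage_id)
    obj <- list(
      id = n$usage_id[[i]], literal = n$literal[[i]],
      rank = n$rank[[i]], status = n$status[[i]]
    )
    syns <- syn_of[[id]]
    if (length(syns)) {
      obj$synonyms <- lapply(syns, function(sid) {
        j <- match(sid, n$usage_id)
        list(id = n$usage_id[[j]], literal = n$literal[[j]], rank = n$rank[[j]])
      })
    }
    kids <- tree_children(tree, id)
    if (length(kids)) obj$children <- lapply(kids, as_obj)
    obj
  }
  forest <- lapply(tree$roots, as_obj)
  if (length(forest) == 1L) forest <- forest[[1L]]
  jsonlite::write_json(forest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
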