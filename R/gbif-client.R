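#' Name-search query options
#'
#' Mirrors the search controls of species-API queries: one matching mode
#' plus checkboxes for including basionyms, synonyms and vernacular names.
#' The `contain` mode differs from the others: it returns the name usages
#' containing the query literal -- a list of higher taxa in essence.
#'
#' @param match_mode one of `exact`, `fuzzy`, `suggest`, `full_text`,
#'   `contain`.
#' @param include_basionym also pull literals related through basionyms.
#' @param include_synonyms saturate the result through recursive synonym
#'   queries ([expand_synonyms()]).
#' @param include_vernacular also match vernacular names.
#' @param language optional language code restricting vernacular matches.
#' @param rank_filter optional rank name; applied as a union with unranked
#'   records, since unranked usages cannot be excluded by rank.
#' @return an object of class `query_options`.
#' @export
query_options <- function(match_mode = c("exact", "fuzzy", "suggest", "full_text", "contain"),
                          include_basionym = FALSE,
                          include_synonyms = FALSE,
                          include_vernacular = FALSE,
                          language = NULL,
                          rank_filter = NULL) {
  structure(
    list(
      match_mode = match.arg(match_mode),
      include_basionym = isTRUE(include_basionym),
      include_synonyms = isTRUE(include_synonyms),
      include_vernacular = isTRUE(include_vernacular),
      language = language,
      rank_filter = if (is.null(rank_filter)) NULL else tolower(rank_filter)
    ),
    class = "query_options"
  )
}

#' Split a query string into name literals
#'
#' Queries name one or more scientific names separated by `'|'`. Literals
#' are whitespace-normalized, empties dropped, order preserved and
#' duplicates removed keeping the first occurrence.
#'
#' @param text query string.
#' @return character vector of literals.
#' @export
#' @examples
#' parse_query("Lembus | Cohnilembus")
parse_query <- function(text) {
  parts <- normalize_literal(strsplit(paste(text, collapse = "|"), "|", fixed = TRUE)[[1L]])
  parts <- unique(parts[nzchar(parts)])
  if (!length(parts)) stop("empty query", call. = FALSE)
  parts
}

# ---- backends ------------------------------------------------------------

new_backend <- function(class, data) {
  structure(
    list(
      data = data,
      cache = new.env(parent = emptyenv()),
      calls = new.env(parent = emptyenv())
    ),
    class = c(class, "taxa_backend")
  )
}

#' Recorded-fixture backend
#'
#' A hermetic, offline stand-in for a live name-usage service: all queries
#' are answered from a recorded store, a JSON file (or equivalent list) with
#' `datasets` (id to label), `usages` (records with `key`, `literal`,
#' `rank`, `status`, `parentKey`, `acceptedKey`, `datasetKey`, optional
#' `basionym` and `denormalized`) and optional `vernaculars` (`key`, `name`,
#' `language`). The shipped miniature store is a hand-authored synthetic
#' fixture, not a dump of any real aggregator. Results are accumulated into
#' a per-backend cache; repeating a query issues no new store lookups (see
#' [backend_calls()]).
#'
#' Records flagged `denormalized` (higher-taxon records manufactured from a
#' flat classification string) are tagged in the output but never
#' auto-merged: unification of look-alike records stays with the user.
#'
#' @param store path to a JSON store, or the parsed list.
#' @return a backend object.
#' @export
fixture_backend <- function(store = default_fixture_store()) {
  if (is.character(store)) {
    if (!file.exists(store)) stop(sprintf("fixture store not found: %s", store), call. = FALSE)
    store <- jsonlite::fromJSON(store, simplifyVector = FALSE)
  }
  usages <- bind_rows(lapply(store$usages, function(u) {
    tibble(
      usage_id = as.character(u$key),
      literal = normalize_literal(u$literal),
      rank = tolower(as.character(u$rank %||% "unranked")),
      status = normalize_status(as.character(u$status %||% "accepted")),
      parent_id = as.character(u$parentKey %||% NA_character_),
      accepted_id = as.character(u$acceptedKey %||% NA_character_),
      source_id = as.character(u$datasetKey),
      basionym = as.character(u$basionym %||% NA_character_),
      denormalized = isTRUE(u$denormalized)
    )
  }))
  if (anyDuplicated(usages$usage_id)) stop("fixture store has duplicate keys", call. = FALSE)
  vern <- bind_rows(lapply(store$vernaculars %||% list(), function(v) {
    tibble(
      usage_id = as.character(v$key),
      name = normalize_literal(v$name),
      language = as.character(v$language %||% NA_character_)
    )
  }))
  datasets <- unlist(store$datasets %||% list())
  new_backend("fixture_backend", list(
    usages = usages, vernaculars = vern,
    datasets = setNames(as.character(datasets), names(datasets))
  ))
}

#' Path of the miniature fixture store shipped with the package
#' @return file path.
#' @export
default_fixture_store <- function() {
  system.file("extdata", "gbif_fixture", "store.json",
    package = "taxalign", mustWork = TRUE
  )
}

#' Live species-API backend
#'
#' Thin HTTP client for a GBIF Species API v1 compatible service
#' (`species/search`, `species/{key}`, `/parents`, `/children`,
#' `/synonyms`), paginated at `page_size` with a politeness delay between
#' pages. Requires the `httr` package and network access; every test and
#' example in this package runs on [fixture_backend()] instead, so the full
#' suite is hermetic.
#'
#' @param base_url service root.
#' @param timeout request timeout in seconds.
#' @param page_size records per page (the API's documented maximum by
#'   default).
#' @param delay seconds to sleep between successive page requests.
#' @return a backend object.
#' @export
live_backend <- function(base_url = "https://api.gbif.org/v1",
                         timeout = 60, page_size = 1000, delay = 0.2) {
  if (!requireNamespace("httr", quietly = TRUE)) {
    stop("live_backend requires the 'httr' package", call. = FALSE)
  }
  new_backend("live_backend", list(
    base_url = sub("/$", "", base_url),
    timeout = timeout, page_size = page_size, delay = delay
  ))
}

#' Number of raw (uncached) backend lookups performed so far
#' @param backend a backend object.
#' @return integer count.
#' @export
backend_calls <- function(backend) {
  sum(unlist(as.list(backend$calls)), 0L)
}

# cached dispatch: key = endpoint + canonical parameter string
backend_call <- function(backend, endpoint, param) {
  key <- map_key(endpoint, param)
  hit <- backend$cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  backend$calls[[key]] <- 1L
  res <- backend_fetch(backend, endpoint, param)
  backend$cache[[key]] <- res
  res
}

backend_fetch <- function(backend, endpoint, param) UseMethod("backend_fetch")

empty_usages <- function() {
  tibble(
    usage_id = character(0), literal = character(0), rank = character(0),
    status = character(0), parent_id = character(0), accepted_id = character(0),
    source_id = character(0), basionym = character(0), denormalized = logical(0)
  )
}

#' @export
backend_fetch.fixture_backend <- function(backend, endpoint, param) {
  u <- backend$data$usages
  p <- strsplit(param, .sep, fixed = TRUE)[[1L]]
  switch(endpoint,
    search = {
      literal <- p[[1L]]
      mode <- p[[2L]]
      hits <- switch(mode,
        exact = u$literal == literal,
        fuzzy = tolower(u$literal) == tolower(literal) |
          utils::adist(u$literal, literal) <= 1L,
        suggest = startsWith(u$literal, literal),
        full_text = stringr::str_detect(
          tolower(u$literal), stringr::fixed(tolower(literal))
        ),
        contain = u$literal == literal,
        stop(sprintf("unknown match mode '%s'", mode), call. = FALSE)
      )
      res <- u[hits, , drop = FALSE]
      if (mode == "contain") {
        # the usages *containing* the match: its higher taxa, in essence
        anc <- unique(unlist(lapply(res$usage_id, function(k) {
          setdiff(fixture_ancestors(u, k), k)
        })))
        res <- u[match(anc, u$usage_id), , drop = FALSE]
      }
      res
    },
    vernacular = {
      v <- backend$data$vernaculars
      if (!nrow(v)) {
        return(empty_usages())
      }
      name <- p[[1L]]
      lang <- p[[2L]]
      keep <- v$name == name
      if (nzchar(lang)) keep <- keep & !is.na(v$language) & v$language == lang
      u[u$usage_id %in% v$usage_id[keep], , drop = FALSE]
    },
    get = {
      res <- u[u$usage_id == param, , drop = FALSE]
      if (!nrow(res)) stop(sprintf("not recorded: usage '%s'", param), call. = FALSE)
      res
    },
    parents = {
      if (!param %in% u$usage_id) stop(sprintf("not recorded: usage '%s'", param), call. = FALSE)
      anc <- fixture_ancestors(u, param)
      anc <- setdiff(anc, param)
      u[match(anc, u$usage_id), , drop = FALSE]
    },
    children = {
      if (!param %in% u$usage_id) stop(sprintf("not recorded: usage '%s'", param), call. = FALSE)
      u[!is.na(u$parent_id) & u$parent_id == param & u$status != "synonym", , drop = FALSE]
    },
    synonyms = {
      if (!param %in% u$usage_id) stop(sprintf("not recorded: usage '%s'", param), call. = FALSE)
      u[!is.na(u$accepted_id) & u$accepted_id == param, , drop = FALSE]
    },
    stop(sprintf("unknown endpoint '%s'", endpoint), call. = FALSE)
  )
}

# ancestor keys of a usage within one fixture dataset, self first
fixture_ancestors <- function(u, key) {
  out <- character(0)
  cur <- key
  while (!is.na(cur) && cur %in% u$usage_id && !cur %in% out) {
    out <- c(out, cur)
    cur <- u$parent_id[match(cur, u$usage_id)]
  }
  out
}

#' @export
backend_fetch.live_backend <- function(backend, endpoint, param) {
  b <- backend$data
  p <- strsplit(param, .sep, fixed = TRUE)[[1L]]
  get_json <- function(path, query = list()) {
    resp <- httr::GET(
      paste0(b$base_url, "/", path),
      query = query, httr::timeout(b$timeout)
    )
    if (httr::http_error(resp)) {
      stop(sprintf(
        "species API error %s for %s", httr::status_code(resp), path
      ), call. = FALSE)
    }
    jsonlite::fromJSON(
      httr::content(resp, as = "text", encoding = "UTF-8"),
      simplifyVector = FALSE
    )
  }
  paged <- function(path, query = list()) {
    out <- list()
    offset <- 0L
    repeat {
      page <- get_json(path, c(query, list(limit = b$page_size, offset = offset)))
      out <- c(out, page$results %||% list())
      if (isTRUE(page$endOfRecords) || !length(page$results %||% list())) break
      offset <- offset + b$page_size
      Sys.sleep(b$delay)
    }
    out
  }
  as_usage <- function(r) {
    tibble(
      usage_id = as.character(r$key),
      literal = normalize_literal(r$canonicalName %||% r$scientificName %||% ""),
      rank = tolower(as.character(r$rank %||% "unranked")),
      status = normalize_status(as.character(r$taxonomicStatus %||% "accepted")),
      parent_id = as.character(r$parentKey %||% NA_character_),
      accepted_id = as.character(r$acceptedKey %||% NA_character_),
      source_id = as.character(r$datasetKey %||% "unknown"),
      basionym = as.character(r$basionym %||% NA_character_),
      denormalized = isTRUE(r$origin == "DENORMED_CLASSIFICATION")
    )
  }
  switch(endpoint,
    search = bind_rows(lapply(paged("species/search", list(q = p[[1L]])), as_usage)),
    vernacular = bind_rows(lapply(
      paged("species/search", list(q = p[[1L]], qField = "VERNACULAR")), as_usage
    )),
    get = as_usage(get_json(paste0("species/", param))),
    parents = bind_rows(lapply(rev(get_json(paste0("species/", param, "/parents"))), as_usage)),
    children = bind_rows(lapply(paged(paste0("species/", param, "/children")), as_usage)),
    synonyms = bind_rows(lapply(paged(paste0("species/", param, "/synonyms")), as_usage)),
    stop(sprintf("unknown endpoint '%s'", endpoint), call. = FALSE)
  )
}

# ---- search operations ---------------------------------------------------

#' Search name usages by literal
#'
#' Searches each literal under the chosen matching mode, optionally matching
#' vernacular names, and applies the rank filter as a union with unranked
#' records (a rank filter cannot exclude usages that carry no rank). When
#' the synonym or basionym options are set, the result is saturated through
#' [expand_synonyms()]. Results accumulate in the backend cache, so repeated
#' queries issue no new backend lookups.
#'
#' @param literals character vector of name literals (see [parse_query()]).
#' @param options a [query_options()].
#' @param backend a backend from [fixture_backend()] or [live_backend()].
#' @return tibble of name-usage records, deduplicated by usage key, ordered
#'   by source and key.
#' @export
search_names <- function(literals, options = query_options(), backend = fixture_backend()) {
  stopifnot(inherits(options, "query_options"))
  literals <- normalize_literal(literals)
  if (options$include_synonyms || options$include_basionym) {
    return(expand_synonyms(literals, options, backend))
  }
  search_names_plain(literals, options, backend)
}

search_names_plain <- function(literals, options, backend) {
  res <- bind_rows(lapply(literals, function(L) {
    hits <- backend_call(backend, "search", map_key(L, options$match_mode))
    if (options$include_vernacular) {
      hits <- bind_rows(
        hits,
        backend_call(backend, "vernacular", map_key(L, options$language %||% ""))
      )
    }
    hits
  }))
  if (!nrow(res)) {
    return(empty_usages())
  }
  if (!is.null(options$rank_filter)) {
    res <- res |>
      filter(.data$rank == options$rank_filter | .data$rank == "unranked")
  }
  res |>
    distinct(.data$usage_id, .keep_all = TRUE) |>
    arrange(.data$source_id, .data$usage_id)
}

#' Saturate a literal set through recursive synonym queries
#'
#' Fixed-point iteration: search the current literals, request the synonyms
#' of every result usage, add their literals (and basionym literals, when
#' enabled) as new seeds, and repeat until the literal set stops growing.
#' Termination is guaranteed by the finite literal universe of the backend;
#' a safety cap aborts runaway iterations. The result is a pure function of
#' the seed *set*: seed order does not matter.
#'
#' @param seed_literals initial name literals.
#' @param options a [query_options()]; `include_basionym` adds basionym
#'   literals each round.
#' @param backend a backend object.
#' @param max_rounds iteration cap.
#' @return tibble of name-usage records for the saturated literal set, with
#'   the final literal set in attribute `"literals"`.
#' @export
expand_synonyms <- function(seed_literals, options = query_options(include_synonyms = TRUE),
                            backend = fixture_backend(), max_rounds = 10L) {
  literals <- sort(unique(normalize_literal(seed_literals)))
  literals <- literals[nzchar(literals)]
  if (!length(literals)) stop("empty query", call. = FALSE)
  plain <- query_options(
    match_mode = options$match_mode,
    include_vernacular = options$include_vernacular,
    language = options$language,
    rank_filter = options$rank_filter
  )
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds) stop("saturation cap exceeded", call. = FALSE)
    usages <- search_names_plain(literals, plain, backend)
    new_lits <- usages$literal
    if (nrow(usages)) {
      if (options$include_synonyms) {
        syns <- bind_rows(lapply(usages$usage_id, function(k) {
          backend_call(backend, "synonyms", k)
        }))
        if (nrow(syns)) new_lits <- c(new_lits, syns$literal)
      }
      if (options$include_basionym && "basionym" %in% names(usages)) {
        new_lits <- c(new_lits, usages$basionym[!is.na(usages$basionym)])
      }
    }
    grown <- sort(unique(c(literals, normalize_literal(new_lits))))
    grown <- grown[nzchar(grown)]
    if (identical(grown, literals)) break
    literals <- grown
  }
  out <- search_names_plain(literals, plain, backend)
  attr(out, "literals") <- literals
  out
}

#' Retrieve the hierarchy around a name usage
#'
#' Walks the parent chain upward and the child links downward from the
#' focus usage on the backend, then trims the result by height and depth
#' with [trim_by_rank()]. By default the highest and deepest records
#' available are recovered. The returned hierarchy is the ancestor path
#' plus the focus subtree, from the focus usage's own dataset.
#'
#' @param usage a usage key, or a one-row usage tibble as returned by
#'   [search_names()].
#' @param height a [rank_spec()] limiting levels above the focus;
#'   `rank_spec()` (no limit) by default. `levels = 0` cuts the higher-taxa
#'   path entirely.
#' @param depth a [rank_spec()] limiting levels below the focus.
#' @param backend a backend object.
#' @return a [source_tree()] containing the focus usage.
#' @export
fetch_hierarchy <- function(usage, height = rank_spec(), depth = rank_spec(),
                            backend = fixture_backend()) {
  key <- if (is.data.frame(usage)) usage$usage_id[[1L]] else as.character(usage)
  rec <- backend_call(backend, "get", key)
  parents <- backend_call(backend, "parents", key) # immediate parent first
  nodes <- bind_rows(rec, parents)
  queue <- key
  while (length(queue)) {
    k <- queue[[1L]]
    queue <- queue[-1L]
    kids <- backend_call(backend, "children", k)
    if (nrow(kids)) {
      nodes <- bind_rows(nodes, kids)
      queue <- c(queue, kids$usage_id)
    }
  }
  nodes <- distinct(nodes, .data$usage_id, .keep_all = TRUE)
  # the tree is local to the focus usage's dataset
  src <- rec$source_id[[1L]]
  label <- unname(backend$data$datasets[src])
  if (!length(label) || is.na(label)) label <- src
  top <- if (nrow(parents)) parents$usage_id[[nrow(parents)]] else key
  nodes$parent_id[nodes$usage_id == top] <- NA_character_
  # order rows root-first so child order is the backend order
  ord <- c(rev(parents$usage_id), setdiff(nodes$usage_id, parents$usage_id))
  nodes <- nodes[match(ord, nodes$usage_id), , drop = FALSE]
  tree <- source_tree(
    nodes[, c("usage_id", "literal", "rank", "status", "parent_id", "accepted_id")],
    source_id = src, label = label
  )
  trim_by_rank(tree, key, height = height, depth = depth)
}

#' Trim a hierarchy around a focus usage by level count and/or rank
#'
#' Upward, ancestors are kept until either the level count or the named
#' rank is reached -- whichever retains fewer nodes, because some
#' taxonomies use many intermediate ranks. Unranked intermediates count
#' toward a level limit but never satisfy a rank limit, so a rank-limited
#' path may retain usages below the named rank. Downward is symmetric over
#' the focus subtree. The trimmed tree is the kept ancestor path plus the
#' kept focus subtree; synonym annotations of kept usages are retained.
#'
#' @param tree a [source_tree()].
#' @param focus_usage_id the usage the limits are relative to.
#' @param height a [rank_spec()] for levels above the focus.
#' @param depth a [rank_spec()] for levels below the focus.
#' @param order rank order table, highest first.
#' @return a new [source_tree()] rooted at the highest kept ancestor.
#' @export
trim_by_rank <- function(tree, focus_usage_id, height = rank_spec(),
                         depth = rank_spec(), order = linnaean_ranks()) {
  stopifnot(inherits(tree, "source_tree"), inherits(height, "rank_spec"),
    inherits(depth, "rank_spec"))
  n <- tree$nodes
  if (!focus_usage_id %in% n$usage_id) {
    stop(sprintf("focus usage '%s' not in tree", focus_usage_id), call. = FALSE)
  }

  rank_of <- function(ids) n$rank[match(ids, n$usage_id)]

  # --- upward ---
  anc <- character(0)
  p <- tree_parent(tree, focus_usage_id)
  while (!is.na(p) && !p %in% anc) {
    anc <- c(anc, p)
    p <- tree_parent(tree, p)
  }
  kept_up <- length(anc)
  if (!is.null(height$levels)) kept_up <- min(kept_up, height$levels)
  if (!is.null(height$rank)) {
    target <- rank_index(height$rank, order)
    k <- 0L
    for (i in seq_along(anc)) {
      idx <- rank_index(rank_of(anc[[i]]), order)
      if (is.na(idx)) { # unranked: keep walking, never satisfies the limit
        k <- i
      } else if (idx > target) { # still below the named rank
        k <- i
      } else if (idx == target) {
        k <- i
        break
      } else { # above the named rank: stop before it
        break
      }
    }
    if (!is.na(target)) kept_up <- min(kept_up, k)
  }
  kept_anc <- head(anc, kept_up)

  # --- downward ---
  desc_levels <- NULL
  desc_rank <- NULL
  collect_desc <- function(limit_levels, limit_rank_idx) {
    out <- character(0)
    walk <- function(id, d) {
      for (k in tree_children(tree, id)) {
        idx <- rank_index(rank_of(k), order)
        if (!is.null(limit_levels) && d + 1L > limit_levels) next
        if (!is.null(limit_rank_idx) && !is.na(idx) && idx > limit_rank_idx) next
        out[[length(out) + 1L]] <<- k
        # a node at exactly the named rank is kept but not descended past
        if (!is.null(limit_rank_idx) && !is.na(idx) && idx == limit_rank_idx) next
        walk(k, d + 1L)
      }
    }
    walk(focus_usage_id, 0L)
    out
  }
  if (is.null(depth$levels) && is.null(depth$rank)) {
    kept_desc <- collect_desc(NULL, NULL)
  } else {
    sets <- list()
    if (!is.null(depth$levels)) sets <- c(sets, list(collect_desc(depth$levels, NULL)))
    if (!is.null(depth$rank)) {
      tr <- rank_index(depth$rank, order)
      sets <- c(sets, list(if (is.na(tr)) collect_desc(NULL, NULL) else collect_desc(NULL, tr)))
    }
    # fewer-wins: represent whichever limit retains fewer nodes
    kept_desc <- sets[[which.min(vapply(sets, length, integer(1)))]]
  }

  keep <- c(rev(kept_anc), focus_usage_id, kept_desc)
  syn <- n$usage_id[n$status == "synonym" & !is.na(n$accepted_id) &
    n$accepted_id %in% keep]
  out <- n[n$usage_id %in% c(keep, syn), , drop = FALSE]
  out <- out[order(match(out$usage_id, c(keep, syn))), , drop = FALSE]
  new_root <- if (length(kept_anc)) kept_anc[[kept_up]] else focus_usage_id
  out$parent_id[out$usage_id == new_root] <- NA_character_
  source_tree(out[, c("usage_id", "literal", "rank", "status", "parent_id", "accepted_id")],
    source_id = tree$source_id, label = tree$label
  )
}
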