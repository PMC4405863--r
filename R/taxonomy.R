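#' Load an OBO taxonomy
#'
#' Reads an OBO 1.2/1.4 flat file and builds a rooted is_a taxonomy.  Only
#' `[Term]` stanzas are considered; obsolete terms and all relationship types
#' other than `is_a` are ignored, so GO, ChEBI, SBO and any other
#' taxonomy-shaped ontology are handled uniformly.  If the ontology has more
#' than one natural root, a synthetic root with id `"<prefix>:ROOT"` is
#' inserted at depth 0 with the natural roots as its children.
#'
#' Alongside the graph structure, the loader precomputes for every concept
#' `c` the quantities used throughout the package:
#' \describe{
#'   \item{freq}{number of concepts subsumed by `c`, self-inclusive; on DAGs
#'     each multi-path descendant is counted once}
#'   \item{p}{concept probability `freq / N`, where `N` is the total concept
#'     count of the taxonomy}
#'   \item{ic}{information content `-log2(p)` in bits; 0 at the root}
#'   \item{depth}{shortest is_a path length from the root}
#' }
#'
#' @param path path to an OBO flat file.
#' @param prefix ontology prefix tag (e.g. `"GO"`, `"CHEBI"`, `"SBO"`), used
#'   to label the taxonomy and to name the synthetic root.
#' @return an object of class `"taxonomy"`: a list with elements `prefix`,
#'   `ids`, `name`, `parents`, `children`, `root`, `synthetic_root`, `N`,
#'   `graph` (an igraph DAG with edges parent -> child), and the named
#'   numeric vectors `depth`, `freq`, `p`, `ic`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: GO:0000001", "name: root",
#'              "", "[Term]", "id: GO:0000002", "name: child",
#'              "is_a: GO:0000001 ! root"), obo)
#' tax <- load_obo(obo, prefix = "GO")
#' tax$N
#' @export
load_obo <- function(path, prefix) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read OBO file: ", path)
  }
  stopifnot(is.character(prefix), length(prefix) == 1L, nzchar(prefix))
  lines <- readLines(path, warn = FALSE)

  terms <- parse_obo_terms(lines)
  if (length(terms) == 0L) {
    stop("no non-obsolete [Term] stanzas found in ", path)
  }
  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term id in OBO file: ", ids[duplicated(ids)][1L])
  }
  names(terms) <- ids
  nm <- vapply(terms, function(t) t$name %||% t$id, "")

  # is_a edges; targets that were dropped (obsolete/missing) are skipped
  edges <- do.call(rbind, lapply(terms, function(t) {
    pa <- intersect(t$is_a, ids)
    if (length(pa)) cbind(parent = pa, child = t$id) else NULL
  }))

  build_taxonomy(ids, nm, edges, prefix)
}

# Parse [Term] stanzas out of OBO lines; returns a list of
# list(id, name, is_a, obsolete) with obsolete terms already dropped.
parse_obo_terms <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  stanza_starts <- grep("^\\[", lines)
  terms <- list()
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k]
    if (lines[from] != "[Term]") next
    to <- if (k < length(stanza_starts)) stanza_starts[k + 1L] - 1L else length(lines)
    block <- lines[(from + 1L):to]
    get1 <- function(tag) {
      m <- grep(paste0("^", tag, ":"), block, value = TRUE)
      if (length(m)) sub(paste0("^", tag, ":\\s*"), "", m[1L]) else NULL
    }
    id <- get1("id")
    if (is.null(id) || !nzchar(id)) next
    obs <- get1("is_obsolete")
    if (!is.null(obs) && grepl("true", obs, fixed = TRUE)) next
    is_a <- grep("^is_a:", block, value = TRUE)
    is_a <- sub("^is_a:\\s*", "", is_a)
    is_a <- sub("\\s*[!{].*$", "", is_a)   # trailing comment / qualifier block
    is_a <- trimws(is_a)
    terms[[length(terms) + 1L]] <- list(id = id, name = get1("name"),
                                        is_a = is_a[nzchar(is_a)])
  }
  terms
}

# Assemble a taxonomy object from ids, names and a parent/child edge matrix.
build_taxonomy <- function(ids, nm, edges, prefix) {
  if (!is.null(edges) && any(edges[, "parent"] == edges[, "child"])) {
    bad <- edges[edges[, "parent"] == edges[, "child"], "child"][1L]
    stop("is_a cycle detected involving concept ", bad)
  }
  roots <- setdiff(ids, if (is.null(edges)) character() else edges[, "child"])
  if (length(roots) == 0L) {
    stop("is_a cycle detected: taxonomy has no root")
  }
  synthetic <- FALSE
  if (length(roots) > 1L) {
    synthetic <- TRUE
    synth <- paste0(prefix, ":ROOT")
    if (synth %in% ids) stop("cannot insert synthetic root: id ", synth, " exists")
    ids <- c(synth, ids)
    nm <- c(setNames(paste(prefix, "synthetic root"), synth), nm)
    edges <- rbind(cbind(parent = synth, child = sort(roots)), edges)
    roots <- synth
  }

  if (is.null(edges)) {
    g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(ids)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, "parent"], to = edges[, "child"],
                 stringsAsFactors = FALSE),
      directed = TRUE, vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  }
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)][1L]
    stop("is_a cycle detected involving concept ", bad)
  }

  depth <- igraph::distances(g, v = roots, mode = "out")[1L, ]
  if (any(!is.finite(depth))) {
    unreach <- names(depth)[!is.finite(depth)]
    stop("concepts not reachable from root ", roots, ": ",
         paste(utils::head(unreach, 3L), collapse = ", "))
  }

  parents <- children <- setNames(vector("list", length(ids)), ids)
  for (id in ids) parents[[id]] <- children[[id]] <- character()
  if (!is.null(edges)) {
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, "parent"]; c <- edges[i, "child"]
      parents[[c]] <- c(parents[[c]], p)
      children[[p]] <- c(children[[p]], c)
    }
    parents <- lapply(parents, function(x) sort(unique(x)))
    children <- lapply(children, function(x) sort(unique(x)))
  }

  N <- length(ids)
  freq <- vapply(ids, function(id)
    length(igraph::subcomponent(g, id, mode = "out")), 0L)
  p <- freq / N
  ic <- -log2(p)

  structure(list(prefix = prefix, ids = ids, name = nm,
                 parents = parents, children = children,
                 root = roots, synthetic_root = synthetic, N = N,
                 graph = g, depth = depth[ids], freq = freq[ids],
                 p = p[ids], ic = ic[ids]),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %s: %d concepts, root %s%s, max depth %d\n",
              x$prefix, x$N, x$root,
              if (x$synthetic_root) " (synthetic)" else "",
              max(x$depth)))
  invisible(x)
}

check_concept <- function(t, id) {
  missing <- setdiff(id, t$ids)
  if (length(missing)) {
    stop("unknown concept id: ", paste(missing, collapse = ", "))
  }
  invisible(id)
}

#' Self-inclusive descendants / ancestors of a concept
#'
#' Descendants follow is_a edges downwards, ancestors upwards; both include
#' the concept itself.  On DAGs each reachable concept appears once.
#'
#' @param t a [load_obo()] taxonomy.
#' @param id a concept id.
#' @return character vector of concept ids.
#' @export
descendants <- function(t, id) {
  check_concept(t, id)
  names(igraph::subcomponent(t$graph, id, mode = "out"))
}

#' @rdname descendants
#' @export
ancestors <- function(t, id) {
  check_concept(t, id)
  names(igraph::subcomponent(t$graph, id, mode = "in"))
}

#' Static per-concept quantities
#'
#' Returns the subsumed-concept count `freq` (self-inclusive), the concept
#' probability `p = freq / N`, the information content `ic = -log2(p)` in
#' bits, and the depth (shortest is_a path from the root) of one concept.
#'
#' @param t a taxonomy.
#' @param id a concept id.
#' @return a list with elements `freq`, `p`, `ic`, `depth`.
#' @examples
#' # the root subsumes everything: p = 1, ic = 0
#' @export
concept_statics <- function(t, id) {
  check_concept(t, id)
  list(freq = unname(t$freq[id]), p = unname(t$p[id]),
       ic = unname(t$ic[id]), depth = unname(t$depth[id]))
}

#' Least common subsumer of two concepts
#'
#' The deepest concept that is an ancestor (self-inclusive) of both inputs.
#' On DAGs several common ancestors can share the maximal depth; ties are
#' broken by the lexicographically smallest id so the result is
#' deterministic.
#'
#' @param t a taxonomy.
#' @param c1,c2 concept ids.
#' @return the id of the least common subsumer.
#' @export
least_common_subsumer <- function(t, c1, c2) {
  check_concept(t, c(c1, c2))
  common <- intersect(ancestors(t, c1), ancestors(t, c2))
  common <- sort(common)
  common[which.max(t$depth[common])]
}

#' Shortest is_a path length between two concepts
#'
#' The path is routed through the least common subsumer:
#' `l = dist(c1, lcs) + dist(c2, lcs)` with shortest is_a distances.
#'
#' @param t a taxonomy.
#' @param c1,c2 concept ids.
#' @return integer path length (0 when `c1 == c2`).
#' @export
path_length <- function(t, c1, c2) {
  check_concept(t, c(c1, c2))
  if (c1 == c2) return(0)
  lcs <- least_common_subsumer(t, c1, c2)
  d <- igraph::distances(t$graph, v = lcs, to = c(c1, c2), mode = "out")
  unname(d[1L, c1] + d[1L, c2])
}

#' Dump taxonomy statics to JSON
#'
#' Writes one record per concept (id, freq, p, ic, depth) for caching or
#' inspection.
#'
#' @param t a taxonomy.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_taxonomy_json <- function(t, path) {
  df <- data.frame(id = t$ids, name = unname(t$name[t$ids]),
                   freq = unname(t$freq[t$ids]), p = unname(t$p[t$ids]),
                   ic = unname(t$ic[t$ids]), depth = unname(t$depth[t$ids]),
                   stringsAsFactors = FALSE)
  jsonlite::write_json(list(prefix = t$prefix, N = t$N, root = t$root,
                            concepts = df),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
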