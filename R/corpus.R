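#' Build the annotation index of a model corpus
#'
#' Parses a set of SBML files and tallies, for the ontology of the given
#' taxonomy, how often each concept is referenced.  The index carries four
#' per-concept quantities:
#' \describe{
#'   \item{direct}{entity frequency: number of annotation records pointing
#'     directly at the concept}
#'   \item{ef}{aggregated entity frequency: sum of `direct` over the concept
#'     and all its descendants (as a set, so multi-path descendants on DAGs
#'     count once)}
#'   \item{ep}{entity probability `ef(c) / ef(root)`; 1 at the root whenever
#'     any annotation exists}
#'   \item{doc_freq}{number of models containing at least one direct
#'     reference to the concept or one of its descendants}
#' }
#' Records whose concept id carries the taxonomy's prefix but is absent from
#' the taxonomy, and records whose URI could not be parsed, are kept in
#' `unresolved`.  Records for other ontologies are ignored (their count is
#' reported in `n_foreign`).
#'
#' @param paths character vector of SBML file paths (non-empty).
#' @param t the taxonomy whose ontology is indexed.
#' @param qualifiers optional whitelist of qualifier names (e.g.
#'   `c("bqbiol:is")`); by default every bqbiol/bqmodel qualifier and
#'   sboTerm attribute counts.
#' @param include_model_level count annotations attached to the `<model>`
#'   element itself (default `TRUE`).
#' @return an object of class `"corpus_index"`.
#' @export
build_corpus_index <- function(paths, t, qualifiers = NULL,
                               include_model_level = TRUE) {
  stopifnot(inherits(t, "taxonomy"))
  if (length(paths) == 0L) stop("empty model list")
  recs <- do.call(rbind, lapply(paths, parse_sbml_annotations))
  index_from_records(recs, t, qualifiers = qualifiers,
                     include_model_level = include_model_level,
                     models = unique(vapply(paths, function(p)
                       model_id_of(p), "")))
}

model_id_of <- function(path) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, "./*[local-name()='model']")
  id <- xml2::xml_attr(model, "id")
  if (is.na(id)) id <- tools::file_path_sans_ext(basename(path))
  id
}

# Core index construction from a record data.frame (shared with df_filter).
index_from_records <- function(recs, t, qualifiers = NULL,
                               include_model_level = TRUE, models = NULL) {
  if (is.null(recs)) recs <- parse_sbml_annotations_empty()
  if (!is.null(qualifiers)) {
    recs <- recs[recs$qualifier %in% qualifiers, , drop = FALSE]
  }
  if (!include_model_level) {
    recs <- recs[recs$level != "model", , drop = FALSE]
  }
  if (is.null(models)) models <- unique(recs$model_id)
  models <- sort(unique(models))

  mine <- recs$ontology == t$prefix & recs$ok
  known <- mine & recs$concept_id %in% t$ids
  unresolved <- recs[(mine & !known) | !recs$ok, , drop = FALSE]
  n_foreign <- sum(!mine & recs$ok)
  resolved <- recs[known, , drop = FALSE]

  ids <- t$ids
  direct <- setNames(integer(length(ids)), ids)
  if (nrow(resolved)) {
    tab <- table(resolved$concept_id)
    direct[names(tab)] <- as.integer(tab)
  }

  ef <- setNames(numeric(length(ids)), ids)
  for (cid in names(direct)[direct > 0L]) {
    anc <- ancestors(t, cid)
    ef[anc] <- ef[anc] + direct[cid]
  }
  root_ef <- ef[t$root]
  ep <- if (root_ef > 0) ef / root_ef else ef * 0

  doc_freq <- setNames(integer(length(ids)), ids)
  per_model <- split(resolved$concept_id, factor(resolved$model_id, levels = models))
  for (m in models) {
    cids <- unique(per_model[[m]])
    if (length(cids) == 0L) next
    anc <- unique(unlist(lapply(cids, ancestors, t = t), use.names = FALSE))
    doc_freq[anc] <- doc_freq[anc] + 1L
  }

  structure(list(prefix = t$prefix, root = t$root, models = models,
                 n_models = length(models), records = resolved,
                 direct = direct, ef = ef, ep = ep, doc_freq = doc_freq,
                 unresolved = unresolved, n_foreign = n_foreign,
                 n_records = nrow(resolved)),
            class = "corpus_index")
}

parse_sbml_annotations_empty <- function() {
  data.frame(model_id = character(), element_id = character(),
             element_name = character(), level = character(),
             qualifier = character(), ontology = character(),
             concept_id = character(), uri = character(), ok = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf(paste0("<corpus_index> %s: %d models, %d resolved records",
                     " (%d unresolved, %d foreign), EF(root) = %g\n"),
              x$prefix, x$n_models, x$n_records, nrow(x$unresolved),
              x$n_foreign, x$ef[x$root]))
  invisible(x)
}

#' Document-frequency vocabulary reduction
#'
#' Removes rarely used concepts from a corpus index: every concept whose
#' aggregated document frequency is below `min_df` has its direct annotation
#' records dropped, and `ef`, `ep` and `doc_freq` are recomputed from the
#' remaining records.  With the default `min_df = 1` (or 0) the index is
#' returned unchanged.
#'
#' @param idx a [build_corpus_index()] result.
#' @param t the taxonomy the index was built on.
#' @param min_df minimum number of models a concept must occur in (directly
#'   or via a descendant) to be kept.
#' @return a filtered `"corpus_index"`.
#' @export
df_filter <- function(idx, t, min_df = 1L) {
  stopifnot(inherits(idx, "corpus_index"), inherits(t, "taxonomy"))
  if (!is.numeric(min_df) || length(min_df) != 1L || min_df < 0) {
    stop("min_df must be a non-negative integer")
  }
  if (min_df <= 1L) return(idx)
  drop <- names(idx$direct)[idx$direct > 0L & idx$doc_freq < min_df]
  recs <- idx$records[!(idx$records$concept_id %in% drop), , drop = FALSE]
  out <- index_from_records(recs, t, models = idx$models)
  out$unresolved <- idx$unresolved
  out$n_foreign <- idx$n_foreign
  out
}
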