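#' Depth distribution of annotations
#'
#' Every resolved annotation record contributes the depth of its concept
#' once; the result is the per-depth histogram plus the average depth of
#' annotation, the statistic used to judge how specific a corpus'
#' annotations are.
#'
#' @param t a taxonomy.
#' @param idx a corpus index built on `t`.
#' @return a list of class `"depth_distribution"` with `counts` (data.frame
#'   `depth`, `count`), `average` (mean depth over records, `NaN` when the
#'   index is empty) and `n_records`.
#' @export
depth_distribution <- function(t, idx) {
  stopifnot(inherits(t, "taxonomy"), inherits(idx, "corpus_index"))
  depths <- unname(t$depth[idx$records$concept_id])
  counts <- if (length(depths)) {
    tab <- table(depths)
    data.frame(depth = as.integer(names(tab)), count = as.integer(tab))
  } else {
    data.frame(depth = integer(), count = integer())
  }
  structure(list(counts = counts, average = mean(depths),
                 n_records = length(depths)),
            class = "depth_distribution")
}

#' @export
print.depth_distribution <- function(x, ...) {
  cat(sprintf("<depth_distribution> %d records, average depth %.2f\n",
              x$n_records, x$average))
  if (nrow(x$counts)) print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Concept and annotation share of the top-level branches
#'
#' The branches are the children of the root.  For each branch the function
#' reports which fraction of the taxonomy's concepts it subsumes
#' (`concept_share`, from `freq`) and which fraction of the corpus'
#' annotation records map under it (`annotation_share`, from the branch
#' head's aggregated entity frequency).  The two shares are independent
#' quantities: a branch holding few concepts may still attract most
#' annotations.  Annotations sitting directly on the root are reported in
#' an explicit `"(root)"` bucket.  On trees both shares sum to 1; on DAGs a
#' concept may live under several branches, the shares are then reported
#' unnormalized and flagged.
#'
#' @param t a taxonomy whose root has at least one child.
#' @param idx a corpus index built on `t`.
#' @return a data.frame of class `"branch_distribution"` with columns
#'   `branch`, `name`, `n_concepts`, `concept_share`, `annotations`
#'   (aggregated EF), `annotation_share`, plus attribute `normalized`.
#' @export
branch_distribution <- function(t, idx) {
  stopifnot(inherits(t, "taxonomy"), inherits(idx, "corpus_index"))
  branches <- t$children[[t$root]]
  if (length(branches) == 0L) {
    stop("taxonomy root has no children; no branches to report")
  }
  is_tree <- all(lengths(t$parents[setdiff(t$ids, t$root)]) == 1L)
  root_ef <- unname(idx$ef[t$root])
  conc_share <- unname(t$freq[branches]) / (t$N - 1L)
  ann_share <- if (root_ef > 0) unname(idx$ef[branches]) / root_ef else
    rep(0, length(branches))
  out <- data.frame(
    branch = c(branches, "(root)"),
    name = c(unname(t$name[branches]), "annotations on the root itself"),
    n_concepts = c(unname(t$freq[branches]), NA_integer_),
    concept_share = c(conc_share, NA_real_),
    annotations = c(unname(idx$ef[branches]), unname(idx$direct[t$root])),
    annotation_share = c(ann_share,
                         if (root_ef > 0) unname(idx$direct[t$root]) / root_ef
                         else 0),
    stringsAsFactors = FALSE)
  attr(out, "normalized") <- is_tree
  class(out) <- c("branch_distribution", "data.frame")
  out
}

#' Average depth of a feature set
#'
#' The mean depth of the selected concepts -- the "avg depth" statistic used
#' to compare how specific the features chosen by different extraction
#' methods are.
#'
#' @param fs a non-empty `"feature_set"`.
#' @return mean feature depth.
#' @export
average_feature_depth <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  if (nrow(fs$features) == 0L) {
    stop("average depth of an empty feature set is undefined")
  }
  mean(fs$features$depth)
}

#' Feature overlap between several feature sets (Venn cells)
#'
#' For every non-empty subset of the input sets, counts the concepts that
#' occur in exactly those sets and in no other.
#'
#' @param sets a named list of two or more feature sets from the same
#'   ontology.
#' @return a data.frame with one row per Venn cell: columns `sets`
#'   (comma-separated set names), `degree` (number of sets in the cell) and
#'   `count`.  Cell counts sum to the size of the union.
#' @export
feature_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  lapply(sets, function(s) stopifnot(inherits(s, "feature_set")))
  onts <- unique(vapply(sets, `[[`, "", "ontology"))
  if (length(onts) > 1L) {
    stop("feature sets from mixed ontologies: ", paste(onts, collapse = ", "))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  ids <- lapply(sets, function(s) s$features$id)
  universe <- sort(unique(unlist(ids, use.names = FALSE)))
  member <- vapply(ids, function(x) universe %in% x,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  cells <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(cells) <- names(sets)
  cells <- cells[rowSums(cells) > 0L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    pattern <- unlist(cells[r, ])
    inside <- if (length(universe))
      apply(member, 1L, function(m) all(m == pattern)) else logical()
    data.frame(sets = paste(names(sets)[pattern], collapse = ","),
               degree = sum(pattern), count = sum(inside),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$degree, out$sets), , drop = FALSE]
}
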