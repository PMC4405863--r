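#' Extract characteristic ontology features for a model corpus
#'
#' Condenses an ontology -- optionally weighted by the annotation index of a
#' model corpus -- into at most `max_features` characteristic concepts.
#' Four methods are available:
#' \describe{
#'   \item{1}{static top-down clustering driven by the concept probability
#'     `p(c)` only; independent of any corpus}
#'   \item{2}{top-down clustering driven by the entity probability `ep(c)`;
#'     only concepts with aggregated entity frequency `EF > 0` are visited}
#'   \item{3}{bottom-up clustering: directly annotated concepts are merged
#'     upwards, least-used subtrees first, until the budget is met}
#'   \item{4}{score-based grouping: each annotated concept climbs towards
#'     its best-scoring parent for as long as that improves
#'     `Score_T(c) = IC(c) * EF(c)` and is represented by the concept where
#'     the score peaks; a general concept must therefore be supported by
#'     enough annotations to absorb its children, which counters
#'     overgeneralization}
#' }
#' Methods 2 and 3 are exact mirror images of each other (top-down splitting
#' versus bottom-up merging along the same entity-probability order) and
#' return identical feature sets whenever no entity-probability ties occur
#' among competing split/merge candidates; ties are detected and flagged in
#' the result.
#'
#' @param t a [load_obo()] taxonomy.
#' @param idx a [build_corpus_index()] result (ignored by method 1).
#' @param method extraction method, one of 1:4.
#' @param max_features maximum number of features (>= 1); 15 and 5 are the
#'   customary budgets.
#' @param corpus_id optional label stored in the result.
#' @return an object of class `"feature_set"`: a list with `ontology`,
#'   `method`, `max_features`, `corpus_id`, `tie_detected`, `truncated`,
#'   and `features`, a data.frame (ordered by id) with columns `id`, `depth`,
#'   `ef`, `ep`, `ic`, `score`.
#' @export
extract_features <- function(t, idx = NULL, method = 2L, max_features = 15L,
                             corpus_id = NULL) {
  stopifnot(inherits(t, "taxonomy"))
  if (!method %in% 1:4) stop("method must be one of 1, 2, 3, 4")
  if (!is.numeric(max_features) || max_features < 1) {
    stop("max_features must be >= 1")
  }
  max_features <- as.integer(max_features)
  if (method != 1L) {
    if (is.null(idx)) stop("methods 2-4 require a corpus index")
    stopifnot(inherits(idx, "corpus_index"))
    if (idx$prefix != t$prefix) {
      stop("corpus index (", idx$prefix, ") does not match taxonomy (",
           t$prefix, ")")
    }
  }
  switch(method,
         method1_static(t, max_features, corpus_id),
         method2_topdown(t, idx, max_features, corpus_id),
         method3_bottomup(t, idx, max_features, corpus_id),
         method4_scored(t, idx, max_features, corpus_id))
}

#' @rdname extract_features
#' @export
method1_static <- function(t, max_features = 15L, corpus_id = NULL) {
  frontier <- t$root
  repeat {
    cand <- frontier[vapply(frontier,
                            function(c) length(t$children[[c]]) > 0L, NA)]
    if (length(cand) == 0L) break
    cand <- cand[order(-t$p[cand], cand)]
    split_done <- FALSE
    for (c in cand) {
      new_frontier <- union(setdiff(frontier, c), t$children[[c]])
      if (length(new_frontier) <= max_features) {
        frontier <- new_frontier
        split_done <- TRUE
        break
      }
    }
    if (!split_done) break
  }
  new_feature_set(t, frontier, idx = NULL, method = 1L,
                  max_features = max_features, corpus_id = corpus_id)
}

#' @rdname extract_features
#' @export
method2_topdown <- function(t, idx, max_features = 15L, corpus_id = NULL) {
  ef <- idx$ef
  if (ef[t$root] == 0) {
    warning("corpus index holds no resolved annotations; empty feature set")
    return(new_feature_set(t, character(), idx, 2L, max_features, corpus_id))
  }
  res <- descend_frontier(t, idx, frontier = t$root,
                          retired = character(), max_features)
  new_feature_set(t, res$frontier, idx, 2L, max_features, corpus_id,
                  tie_detected = res$tie)
}

# Skip-style top-down frontier descent: repeatedly split the frontier
# concept with the largest ep whose expansion still fits the budget; a
# split replaces the concept by its EF>0 children and, when the concept is
# itself annotated, keeps it as a non-splittable member so its own records
# stay represented.  Ties on ep are broken towards the lexicographically
# smallest id and flagged.
descend_frontier <- function(t, idx, frontier, retired, max_features) {
  ef <- idx$ef
  tie <- FALSE
  repeat {
    cand <- setdiff(frontier, retired)
    cand <- cand[vapply(cand, function(c) any(ef[t$children[[c]]] > 0), NA)]
    split_done <- FALSE
    while (length(cand) > 0L) {
      top_ep <- max(idx$ep[cand])
      top <- sort(cand[idx$ep[cand] == top_ep])
      if (length(top) > 1L) tie <- TRUE
      c <- top[1L]
      kids <- t$children[[c]]
      kids <- kids[ef[kids] > 0]
      new_frontier <- union(setdiff(frontier, c), kids)
      keep_self <- idx$direct[c] > 0L
      if (keep_self) new_frontier <- union(new_frontier, c)
      if (length(new_frontier) <= max_features) {
        if (keep_self) retired <- c(retired, c)
        frontier <- new_frontier
        split_done <- TRUE
        break
      }
      cand <- setdiff(cand, c)   # over budget: skip, try the next one
    }
    if (!split_done) break
  }
  list(frontier = frontier, retired = retired, tie = tie)
}

#' @rdname extract_features
#' @export
method3_bottomup <- function(t, idx, max_features = 15L, corpus_id = NULL) {
  ef <- idx$ef
  if (ef[t$root] == 0) {
    warning("corpus index holds no resolved annotations; empty feature set")
    return(new_feature_set(t, character(), idx, 3L, max_features, corpus_id))
  }
  reps <- names(idx$direct)[idx$direct > 0L]
  tie <- FALSE
  while (length(reps) > max_features) {
    cand <- mergeable_parents(t, ef, reps)
    if (length(cand) == 0L) break   # defensive; cannot occur on a DAG
    low_ep <- min(idx$ep[cand])
    # lexicographically largest at equal ep: the exact mirror of method 2,
    # which splits the lexicographically smallest at equal ep
    low <- sort(cand[idx$ep[cand] == low_ep], decreasing = TRUE)
    if (length(low) > 1L) tie <- TRUE
    p <- low[1L]
    kids <- t$children[[p]]
    kids <- kids[ef[kids] > 0]
    reps <- union(setdiff(reps, kids), p)
  }
  # Budget-filling refinement (shared with method 2): once merging has met
  # the budget, spend any remaining budget by re-splitting the least
  # general clusters, i.e. run the top-down descent from the merged
  # frontier.  Annotated representatives whose EF>0 subtrees are fully
  # expanded are already "split" and must not be expanded again.
  covered <- function(d) {
    d %in% reps || any(reps %in% setdiff(descendants(t, d), d))
  }
  retired <- reps[idx$direct[reps] > 0L & vapply(reps, function(r) {
    kids <- t$children[[r]]
    kids <- kids[ef[kids] > 0]
    length(kids) > 0L && all(vapply(kids, covered, NA))
  }, NA)]
  res <- descend_frontier(t, idx, frontier = reps, retired = retired,
                          max_features)
  new_feature_set(t, res$frontier, idx, 3L, max_features, corpus_id,
                  tie_detected = tie || res$tie)
}

# Parents whose split is currently undoable: all EF>0 children are
# representatives and no deeper representative survives below them.
mergeable_parents <- function(t, ef, reps) {
  cand <- unique(unlist(t$parents[reps], use.names = FALSE))
  cand <- cand[ef[cand] > 0]
  keep <- vapply(cand, function(p) {
    kids <- t$children[[p]]
    kids <- kids[ef[kids] > 0]
    if (length(kids) == 0L || !all(kids %in% reps)) return(FALSE)
    below <- setdiff(descendants(t, p), p)
    all(intersect(reps, below) %in% kids)
  }, NA)
  cand[keep]
}

#' Overgeneralization-aware concept score
#'
#' `Score_T(c) = IC(c) * EF(c)`: a general concept must be supported by more
#' annotations to outscore a specific one.  The root always scores 0 because
#' its information content is 0.
#'
#' @param t a taxonomy.
#' @param idx a corpus index built on `t`.
#' @param id a concept id.
#' @return the score, a non-negative real.
#' @export
score_T <- function(t, idx, id) {
  check_concept(t, id)
  unname(t$ic[id] * idx$ef[id])
}

#' @rdname extract_features
#' @export
method4_scored <- function(t, idx, max_features = 15L, corpus_id = NULL) {
  annotated <- names(idx$direct)[idx$direct > 0L]
  if (length(annotated) == 0L) {
    warning("corpus index holds no resolved annotations; empty feature set")
    return(new_feature_set(t, character(), idx, 4L, max_features, corpus_id))
  }
  score <- t$ic * idx$ef

  # Greedy agglomeration: climb towards the parent with the best score while
  # that strictly improves on the current concept, i.e. stop at the first
  # score maximum.  Climbing to the global ancestor optimum would collapse
  # onto the top-level branches (tiny IC, huge EF) and overgeneralize -- the
  # exact failure mode the score is designed to prevent.
  best_parent <- function(c) {
    pa <- t$parents[[c]]
    if (length(pa) == 0L) return(NA_character_)
    pa <- pa[score[pa] == max(score[pa])]
    pa <- pa[t$depth[pa] == max(t$depth[pa])]       # tie: deepest ...
    sort(pa)[1L]                                    # ... then lexicographic
  }
  climb <- function(c) {
    repeat {
      p <- best_parent(c)
      if (is.na(p) || score[p] <= score[c]) return(c)
      c <- p
    }
  }
  feats <- sort(unique(vapply(annotated, climb, "")))
  truncated <- FALSE
  if (length(feats) > max_features) {
    # the method is only required to select *up to* max_features: keep the
    # highest-scoring representatives (tie: deeper, then lexicographic)
    ord <- order(-score[feats], -t$depth[feats], feats)
    feats <- sort(feats[ord][seq_len(max_features)])
    truncated <- TRUE
  }
  new_feature_set(t, feats, idx, 4L, max_features, corpus_id,
                  truncated = truncated)
}

# Shared feature-set constructor.  Drops the synthetic root (it is not a
# real ontology concept) and orders features by id.
new_feature_set <- function(t, ids, idx, method, max_features,
                            corpus_id = NULL, tie_detected = FALSE,
                            truncated = FALSE) {
  if (t$synthetic_root) ids <- setdiff(ids, t$root)
  ids <- sort(unique(ids))
  if (is.null(corpus_id) && !is.null(idx)) {
    corpus_id <- paste0(idx$n_models, " models")
  }
  features <- data.frame(
    id = ids,
    depth = if (length(ids)) unname(t$depth[ids]) else numeric(),
    ef = if (is.null(idx)) rep(NA_real_, length(ids)) else unname(idx$ef[ids]),
    ep = if (is.null(idx)) rep(NA_real_, length(ids)) else unname(idx$ep[ids]),
    ic = if (length(ids)) unname(t$ic[ids]) else numeric(),
    stringsAsFactors = FALSE)
  features$score <- if (is.null(idx)) rep(NA_real_, length(ids)) else
    features$ic * features$ef
  structure(list(ontology = t$prefix, method = method,
                 max_features = max_features,
                 corpus_id = corpus_id %||% "",
                 tie_detected = tie_detected, truncated = truncated,
                 features = features),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s method %d: %d feature(s) (budget %d)%s\n",
              x$ontology, x$method, nrow(x$features), x$max_features,
              if (x$tie_detected) " [ep tie detected]" else ""))
  if (nrow(x$features)) print(x$features, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.feature_set <- function(x, ...) x$features

#' Number of features in a feature set
#' @param x a `"feature_set"`.
#' @return integer count.
#' @export
n_features <- function(x) {
  stopifnot(inherits(x, "feature_set"))
  nrow(x$features)
}
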