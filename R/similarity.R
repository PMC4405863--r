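#' Path-length/depth semantic similarity (closed form)
#'
#' The Li-style similarity of two taxonomy concepts combines an exponential
#' decay in the shortest is_a path length `l` between them with a saturating
#' dependence on the depth `h` of their least common subsumer:
#' \deqn{S = e^{-\alpha l} \cdot \tanh(\beta h)}
#' With `h = 0` (the only shared ancestor is the root) the similarity is 0
#' for any path length.  Defaults are `alpha = 0.2`, `beta = 0.6`.
#'
#' @param l shortest path length between the concepts (through their LCS).
#' @param h depth of the least common subsumer.
#' @param alpha path-length decay rate (>= 0).
#' @param beta depth saturation rate (>= 0).
#' @return similarity in `[0, 1)`.
#' @export
li_similarity <- function(l, h, alpha = 0.2, beta = 0.6) {
  stopifnot(alpha >= 0, beta >= 0, l >= 0, h >= 0)
  exp(-alpha * l) * tanh(beta * h)
}

#' Semantic similarity of two concepts
#'
#' Evaluates [li_similarity()] on the taxonomy, with `l` the shortest is_a
#' path through the least common subsumer and `h` the depth of that
#' subsumer.  Identical concepts have similarity exactly 1 (identity
#' convention: a feature compared with itself is a perfect match, even
#' though the raw closed form saturates below 1).
#'
#' @param t a taxonomy.
#' @param c1,c2 concept ids.
#' @param alpha,beta see [li_similarity()].
#' @return similarity in `[0, 1]`; 1 iff `c1 == c2`.
#' @export
concept_similarity <- function(t, c1, c2, alpha = 0.2, beta = 0.6) {
  check_concept(t, c(c1, c2))
  if (c1 == c2) return(1)
  lcs <- least_common_subsumer(t, c1, c2)
  h <- unname(t$depth[lcs])
  if (h == 0) return(0)
  d <- igraph::distances(t$graph, v = lcs, to = c(c1, c2), mode = "out")
  l <- unname(d[1L, c1] + d[1L, c2])
  li_similarity(l, h, alpha, beta)
}

#' Pairwise similarity matrix of two feature sets
#'
#' @param t a taxonomy.
#' @param A,B feature sets from the same ontology as `t`.
#' @param alpha,beta see [li_similarity()].
#' @return an `n_features(A)` x `n_features(B)` matrix with the feature ids
#'   as dimnames.
#' @export
similarity_matrix <- function(t, A, B, alpha = 0.2, beta = 0.6) {
  stopifnot(inherits(A, "feature_set"), inherits(B, "feature_set"))
  if (A$ontology != B$ontology || A$ontology != t$prefix) {
    stop("feature sets must come from the ontology of the taxonomy (",
         t$prefix, "); got ", A$ontology, " and ", B$ontology)
  }
  a <- A$features$id
  b <- B$features$id
  m <- matrix(0, nrow = length(a), ncol = length(b), dimnames = list(a, b))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      m[i, j] <- concept_similarity(t, a[i], b[j], alpha, beta)
    }
  }
  m
}

#' Maximum-weight bipartite assignment
#'
#' Solves the assignment problem on a (possibly rectangular) non-negative
#' weight matrix with the Hungarian algorithm (Jonker-Volgenant shortest
#' augmenting paths on the square-padded matrix).  The returned matching
#' always has size `min(nrow, ncol)`, i.e. every feature of the smaller set
#' is aligned, even through zero-weight pairs.
#'
#' @param m numeric matrix of finite, non-negative weights.
#' @return a list with `pairs` (two-column integer matrix of matched
#'   row/col indices, ordered by row) and `total` (sum of matched weights).
#' @export
hungarian_assignment <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) {
    return(list(pairs = matrix(integer(), ncol = 2L,
                               dimnames = list(NULL, c("row", "col"))),
                total = 0))
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("assignment weights must be finite and non-negative")
  }
  nr <- nrow(m); nc <- ncol(m)
  n <- max(nr, nc)
  big <- max(m)
  cost <- matrix(big, n, n)           # dummy cells behave like weight 0
  cost[seq_len(nr), seq_len(nc)] <- big - m
  col_to_row <- solve_lap_min(cost)
  pairs <- cbind(row = col_to_row, col = seq_len(n))
  pairs <- pairs[pairs[, "row"] <= nr & pairs[, "col"] <= nc, , drop = FALSE]
  pairs <- pairs[order(pairs[, "row"]), , drop = FALSE]
  list(pairs = pairs, total = sum(m[pairs]))
}

# Jonker-Volgenant / Hungarian for the square min-cost assignment.
# Returns col -> row matching as an integer vector.
solve_lap_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # col potentials, index 1 = virtual col 0
  p <- integer(n + 1L)     # p[j+1]: row matched to col j (0 = free)
  way <- integer(n + 1L)   # way[j+1]: previous col on the augmenting path
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}

#' Compare two feature sets
#'
#' Builds the pairwise [similarity_matrix()], aligns features with the
#' Hungarian method so that the summed similarity is maximal, and
#' aggregates: `total = (sum of matched similarities) / max(|A|, |B|)`.
#' Dividing by the larger set size penalizes unmatched features and makes
#' the self-similarity of any non-empty set exactly 1.
#'
#' @param t a taxonomy.
#' @param A,B feature sets from the same ontology.
#' @param alpha,beta see [li_similarity()].
#' @return an object of class `"similarity_report"`: a list with `matrix`,
#'   `assignment` (data.frame of matched pairs with per-pair similarity),
#'   `total`, `alpha`, `beta`, `ontology`.
#' @export
set_similarity <- function(t, A, B, alpha = 0.2, beta = 0.6) {
  if (n_features(A) == 0L || n_features(B) == 0L) {
    warning("empty feature set: total similarity is 0")
    m <- similarity_matrix(t, A, B, alpha, beta)
    return(structure(list(matrix = m,
                          assignment = data.frame(a_index = integer(),
                                                  b_index = integer(),
                                                  a_id = character(),
                                                  b_id = character(),
                                                  similarity = numeric()),
                          total = 0, alpha = alpha, beta = beta,
                          ontology = t$prefix),
                     class = "similarity_report"))
  }
  m <- similarity_matrix(t, A, B, alpha, beta)
  asg <- hungarian_assignment(m)
  assignment <- data.frame(
    a_index = asg$pairs[, "row"],
    b_index = asg$pairs[, "col"],
    a_id = rownames(m)[asg$pairs[, "row"]],
    b_id = colnames(m)[asg$pairs[, "col"]],
    similarity = m[asg$pairs],
    stringsAsFactors = FALSE)
  structure(list(matrix = m, assignment = assignment,
                 total = asg$total / max(nrow(m), ncol(m)),
                 alpha = alpha, beta = beta, ontology = t$prefix),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %s: |A| = %d, |B| = %d, total = %.4f\n",
              x$ontology, nrow(x$matrix), ncol(x$matrix), x$total))
  if (nrow(x$assignment)) print(x$assignment, row.names = FALSE)
  invisible(x)
}
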