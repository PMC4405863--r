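#' Write / read a feature set as JSON
#'
#' The JSON dump carries the ontology prefix, method, budget, corpus label,
#' the per-feature table (id, depth, EF, ep, ic, score) and the average
#' feature depth, and round-trips through [read_feature_set()].
#'
#' @param fs a `"feature_set"`.
#' @param path output / input file path.
#' @return `path` (write) or a `"feature_set"` (read).
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  jsonlite::write_json(
    list(ontology = fs$ontology, method = fs$method,
         max_features = fs$max_features, corpus_id = fs$corpus_id,
         tie_detected = fs$tie_detected, truncated = fs$truncated,
         n_features = nrow(fs$features),
         average_depth = if (nrow(fs$features)) mean(fs$features$depth) else NA,
         features = fs$features),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  features <- x$features
  if (is.null(features) || length(features) == 0L || !is.data.frame(features)) {
    features <- data.frame(id = character(), depth = numeric(),
                           ef = numeric(), ep = numeric(), ic = numeric(),
                           score = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(ontology = x$ontology, method = x$method,
                 max_features = x$max_features, corpus_id = x$corpus_id,
                 tie_detected = isTRUE(x$tie_detected),
                 truncated = isTRUE(x$truncated),
                 features = features),
            class = "feature_set")
}

#' Write a feature set as TSV with shortened ids
#'
#' One row per feature with both the full concept id and the customary
#' shortened form (prefix and leading zeros stripped, e.g. `SBO:0000064`
#' becomes `64`).
#'
#' @param fs a `"feature_set"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- fs$features
  df <- cbind(short_id = sub("^[A-Za-z]+:0*", "", df$id), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a similarity report as JSON
#'
#' @param rep a `"similarity_report"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_report <- function(rep, path) {
  stopifnot(inherits(rep, "similarity_report"))
  jsonlite::write_json(
    list(ontology = rep$ontology, alpha = rep$alpha, beta = rep$beta,
         total = rep$total,
         a_ids = rownames(rep$matrix), b_ids = colnames(rep$matrix),
         matrix = unname(apply(rep$matrix, 1L, function(r) r,
                               simplify = FALSE)),
         assignment = rep$assignment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a depth distribution histogram as TSV
#'
#' @param dd a `"depth_distribution"`.
#' @param path output file.
#' @param label optional corpus/ontology label column.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(dd, path, label = NULL) {
  stopifnot(inherits(dd, "depth_distribution"))
  df <- dd$counts
  if (!is.null(label)) df <- cbind(set = label, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write unresolved annotation records as TSV
#'
#' @param idx a `"corpus_index"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_unresolved_tsv <- function(idx, path) {
  stopifnot(inherits(idx, "corpus_index"))
  utils::write.table(idx$unresolved, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
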