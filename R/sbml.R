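#' Normalize MIRIAM / identifiers.org resource URIs
#'
#' Maps annotation resource URIs onto `(ontology prefix, concept id)` pairs.
#' Three dialects are recognized:
#' \itemize{
#'   \item `urn:miriam:<namespace>:<id>` (percent-encoded `:` is decoded)
#'   \item `http(s)://identifiers.org/<namespace>/<id>`
#'   \item `http(s)://identifiers.org/<PREFIX>:<id>`
#' }
#' The namespaces `go`/`obo.go`, `chebi`/`obo.chebi` and
#' `sbo`/`biomodels.sbo` map to the prefixes `GO`, `CHEBI` and `SBO`;
#' any other namespace is tallied under ontology `"other"`.  The function is
#' total: text that matches no dialect is returned with `ok = FALSE` and the
#' raw input as `concept_id`.
#'
#' @param uri character vector of resource URIs.
#' @return a data.frame with columns `uri`, `ontology`, `concept_id`, `ok`.
#' @examples
#' normalize_identifier(c("http://identifiers.org/chebi/CHEBI:4167",
#'                        "urn:miriam:obo.go:GO%3A0051234"))
#' @export
normalize_identifier <- function(uri) {
  ns_map <- c(go = "GO", obo.go = "GO",
              chebi = "CHEBI", obo.chebi = "CHEBI",
              sbo = "SBO", biomodels.sbo = "SBO")
  one <- function(u) {
    raw <- u
    if (is.na(u) || !nzchar(u)) {
      return(list(uri = raw, ontology = "other", concept_id = raw, ok = FALSE))
    }
    u <- tryCatch(utils::URLdecode(u), error = function(e) u)
    ns <- id <- NULL
    m <- regmatches(u, regexec("^urn:miriam:([^:]+):(.+)$", u))[[1L]]
    if (length(m) == 3L) {
      ns <- m[2L]; id <- m[3L]
    } else {
      m <- regmatches(u, regexec("^https?://identifiers\\.org/([^/]+)/(.+)$", u))[[1L]]
      if (length(m) == 3L) {
        ns <- m[2L]; id <- m[3L]
      } else {
        m <- regmatches(u, regexec("^https?://identifiers\\.org/([A-Za-z.]+):(.+)$", u))[[1L]]
        if (length(m) == 3L) {
          ns <- m[2L]; id <- paste0(m[2L], ":", m[3L])
        }
      }
    }
    if (is.null(ns)) {
      return(list(uri = raw, ontology = "other", concept_id = raw, ok = FALSE))
    }
    prefix <- unname(ns_map[tolower(ns)])
    if (is.na(prefix) && toupper(ns) %in% c("GO", "CHEBI", "SBO")) {
      prefix <- toupper(ns)
    }
    if (is.na(prefix)) {
      return(list(uri = raw, ontology = "other", concept_id = id, ok = TRUE))
    }
    cid <- canonical_concept_id(id, prefix)
    if (is.na(cid)) {
      return(list(uri = raw, ontology = prefix, concept_id = id, ok = FALSE))
    }
    list(uri = raw, ontology = prefix, concept_id = cid, ok = TRUE)
  }
  rows <- lapply(as.character(uri), one)
  data.frame(uri = vapply(rows, `[[`, "", "uri"),
             ontology = vapply(rows, `[[`, "", "ontology"),
             concept_id = vapply(rows, `[[`, "", "concept_id"),
             ok = vapply(rows, `[[`, NA, "ok"),
             stringsAsFactors = FALSE)
}

# "GO:0006402", "0006402" or "GO_0006402" -> "GO:0006402"; NA if malformed.
canonical_concept_id <- function(id, prefix) {
  id <- gsub("_", ":", id)
  if (grepl("^[0-9]+$", id)) id <- paste0(prefix, ":", id)
  if (grepl(paste0("^", prefix, ":[0-9]+$"), id)) id else NA_character_
}

#' Extract annotation records from one SBML file
#'
#' Walks the model and all its elements and emits one record per
#' `(element, qualifier, resource URI)` triple found in RDF annotation
#' blocks, plus one record with qualifier `"sboTerm"` per element carrying
#' the `sboTerm` attribute.  Duplicate resources on the same element are
#' preserved: each occurrence is one annotation.  URIs are normalized with
#' [normalize_identifier()].
#'
#' @param path path to an SBML Level 2+ file.
#' @return a data.frame of annotation records with columns `model_id`,
#'   `element_id`, `element_name`, `level` (`"model"` or `"element"`),
#'   `qualifier`, `ontology`, `concept_id`, `uri`, `ok`.  Zero rows when the
#'   model carries no annotations.
#' @export
parse_sbml_annotations <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e)))
  if (xml2::xml_name(doc) != "sbml") {
    stop("not an SBML document (root element <", xml2::xml_name(doc), ">): ", path)
  }
  model <- xml2::xml_find_first(doc, "./*[local-name()='model']")
  if (inherits(model, "xml_missing")) {
    stop("not an SBML document (no <model> element): ", path)
  }
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- xml2::xml_attr(model, "metaid")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  rows <- list()
  add <- function(element_id, element_name, level, qualifier, uri) {
    rows[[length(rows) + 1L]] <<- data.frame(
      element_id = element_id, element_name = element_name, level = level,
      qualifier = qualifier, uri = uri, stringsAsFactors = FALSE)
  }

  # sboTerm attributes
  sbo_nodes <- xml2::xml_find_all(doc, "//*[@sboTerm]")
  for (nd in sbo_nodes) {
    info <- element_identity(nd, model)
    add(info$id, info$name, info$level, "sboTerm", xml2::xml_attr(nd, "sboTerm"))
  }

  # RDF resource references
  lis <- xml2::xml_find_all(
    doc, "//*[local-name()='li' and @*[local-name()='resource']]")
  for (li in lis) {
    uri <- xml2::xml_attr(li, "resource")
    qual <- qualifier_name(li)
    host <- annotation_host(li)
    if (is.null(host)) next
    info <- element_identity(host, model)
    add(info$id, info$name, info$level, qual, uri)
  }

  if (length(rows) == 0L) {
    return(data.frame(model_id = character(), element_id = character(),
                      element_name = character(), level = character(),
                      qualifier = character(), ontology = character(),
                      concept_id = character(), uri = character(),
                      ok = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  norm <- normalize_identifier(df$uri)
  # sboTerm attribute values are bare ids, not URIs
  is_sbo_attr <- df$qualifier == "sboTerm"
  if (any(is_sbo_attr)) {
    cid <- vapply(df$uri[is_sbo_attr], canonical_concept_id, "", prefix = "SBO")
    norm$ontology[is_sbo_attr] <- "SBO"
    norm$concept_id[is_sbo_attr] <- ifelse(is.na(cid), df$uri[is_sbo_attr], cid)
    norm$ok[is_sbo_attr] <- !is.na(cid)
  }
  data.frame(model_id = model_id, element_id = df$element_id,
             element_name = df$element_name, level = df$level,
             qualifier = df$qualifier, ontology = norm$ontology,
             concept_id = norm$concept_id, uri = df$uri, ok = norm$ok,
             stringsAsFactors = FALSE)
}

# id / kind of the SBML element that owns an annotation or sboTerm
element_identity <- function(node, model) {
  id <- xml2::xml_attr(node, "metaid")
  if (is.na(id)) id <- xml2::xml_attr(node, "id")
  nm <- xml2::xml_name(node)
  if (is.na(id)) id <- nm
  level <- if (identical(xml2::xml_path(node), xml2::xml_path(model)))
    "model" else "element"
  list(id = id, name = nm, level = level)
}

# climb from an rdf:li to the SBML element containing the <annotation>
annotation_host <- function(li) {
  nd <- li
  repeat {
    nd <- xml2::xml_parent(nd)
    if (inherits(nd, "xml_missing")) return(NULL)
    if (xml2::xml_name(nd) == "annotation") return(xml2::xml_parent(nd))
  }
}

# canonical qualifier name, e.g. "bqbiol:is"; falls back to the local name
qualifier_name <- function(li) {
  bag <- xml2::xml_parent(li)
  qel <- xml2::xml_parent(bag)
  if (inherits(qel, "xml_missing")) return(NA_character_)
  local <- xml2::xml_name(qel)
  full_ns <- xml2::xml_ns(xml2::xml_root(li))
  prefixed <- xml2::xml_name(qel, ns = full_ns)
  prefix <- if (grepl(":", prefixed, fixed = TRUE))
    sub(":.*$", "", prefixed) else ""
  canon <- prefix
  if (nzchar(prefix)) {
    nsuri <- unname(full_ns[prefix])
    if (!is.na(nsuri)) {
      if (grepl("biology-qualifiers", nsuri)) canon <- "bqbiol"
      if (grepl("model-qualifiers", nsuri)) canon <- "bqmodel"
    }
  }
  if (nzchar(canon)) paste0(canon, ":", local) else local
}
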