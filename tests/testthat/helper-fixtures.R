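# Shared fixture builders and independent oracles.

# Write an OBO file from "ID", "ID is_a PARENT[,PARENT2]" clauses.
obo_fixture <- function(clauses, extra = character()) {
  path <- tempfile(fileext = ".obo")
  lines <- c("format-version: 1.2", "")
  for (cl in clauses) {
    parts <- strsplit(cl, " is_a ", fixed = TRUE)[[1L]]
    id <- parts[1L]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: term ", id))
    if (length(parts) == 2L) {
      for (p in strsplit(parts[2L], ",", fixed = TRUE)[[1L]]) {
        lines <- c(lines, paste0("is_a: ", p, " ! parent"))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(c(lines, extra), path)
  path
}

# Four-concept tree GO:1 -> GO:2 -> {GO:3, GO:4} used across modules.
tiny_tax <- function() {
  load_obo(obo_fixture(c("GO:0000001", "GO:0000002 is_a GO:0000001",
                         "GO:0000003 is_a GO:0000002",
                         "GO:0000004 is_a GO:0000002")), "GO")
}

# Build a corpus index directly from named direct-annotation counts,
# bypassing SBML parsing (one synthetic model per call unless model_of
# maps concepts to model ids).
idx_from_counts <- function(tax, counts, model_of = NULL) {
  if (length(counts) == 0L) {
    return(sbmlfeatures:::index_from_records(NULL, tax, models = "m1"))
  }
  concept <- rep(names(counts), counts)
  model <- if (is.null(model_of)) rep("m1", length(concept)) else
    model_of[concept]
  recs <- data.frame(model_id = model,
                     element_id = paste0("e", seq_along(concept)),
                     element_name = "species", level = "element",
                     qualifier = "bqbiol:is", ontology = tax$prefix,
                     concept_id = concept, uri = "", ok = TRUE,
                     stringsAsFactors = FALSE)
  sbmlfeatures:::index_from_records(recs, tax, models = unique(model))
}

# Minimal hand-written SBML document, independent of the package's
# generator: `species` is a list of character vectors of resource URIs
# (one annotation block per species), `sbo` a character vector of sboTerm
# attribute values for reactions, `model_ann` URIs attached to the model
# element itself via bqmodel:isDescribedBy.
sbml_fixture <- function(model_id = "m1", species = list(), sbo = character(),
                         model_ann = character()) {
  path <- tempfile(fileext = ".xml")
  rdf_block <- function(about, qual_open, qual_close, uris) {
    c('<annotation>',
      '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
      ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/"',
      ' xmlns:bqmodel="http://biomodels.net/model-qualifiers/">',
      sprintf('<rdf:Description rdf:about="#%s">', about),
      qual_open, '<rdf:Bag>',
      sprintf('<rdf:li rdf:resource="%s"/>', uris),
      '</rdf:Bag>', qual_close,
      '</rdf:Description>', '</rdf:RDF>', '</annotation>')
  }
  sp <- unlist(lapply(seq_along(species), function(i) {
    sid <- sprintf("%s_s%d", model_id, i)
    c(sprintf('<species id="%s" metaid="%s" compartment="c">', sid, sid),
      rdf_block(sid, '<bqbiol:is>', '</bqbiol:is>', species[[i]]),
      '</species>')
  }))
  rx <- unlist(lapply(seq_along(sbo), function(i) {
    sprintf('<reaction id="%s_r%d" metaid="%s_r%d" sboTerm="%s"/>',
            model_id, i, model_id, i, sbo[i])
  }))
  ma <- if (length(model_ann)) {
    rdf_block(model_id, '<bqmodel:isDescribedBy>', '</bqmodel:isDescribedBy>',
              model_ann)
  }
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
               sprintf('<model id="%s" metaid="%s">', model_id, model_id),
               ma,
               '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
               if (length(sp)) c('<listOfSpecies>', sp, '</listOfSpecies>'),
               if (length(rx)) c('<listOfReactions>', rx, '</listOfReactions>'),
               '</model>', '</sbml>'), path)
  path
}

# Independent descendant enumeration by repeated edge expansion (no
# igraph): edges is a two-column parent/child matrix.
brute_descendants <- function(edges, id) {
  out <- id
  repeat {
    kids <- edges[edges[, 1L] %in% out, 2L]
    add <- setdiff(kids, out)
    if (length(add) == 0L) return(sort(out))
    out <- c(out, add)
  }
}

# Brute-force maximum-weight assignment by permutation enumeration.
brute_assignment <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr <= nc) {
    perms <- gtools_permutations(nc, nr)
    best <- -Inf
    for (i in seq_len(nrow(perms))) {
      w <- sum(m[cbind(seq_len(nr), perms[i, ])])
      if (w > best) best <- w
    }
  } else {
    return(brute_assignment(t(m)))
  }
  best
}

# all ordered selections of r items from n (base R; small n only)
gtools_permutations <- function(n, r) {
  if (r == 0L) return(matrix(integer(), 1L, 0L))
  out <- matrix(seq_len(n), ncol = 1L)
  for (k in seq_len(r - 1L)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(rep(out[i, ], length(rest)), nrow = length(rest),
                   byrow = TRUE), rest)
    }))
  }
  out
}

# Deepest-first deterministic pick of a focal subtree: the root child
# subsuming the most concepts.
pick_focus <- function(tax) {
  kids <- tax$children[[tax$root]]
  kids[order(-tax$freq[kids], kids)][1L]
}
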