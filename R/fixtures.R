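#' Specification for a synthetic taxonomy / corpus fixture
#'
#' Bundles and validates the parameters of the seeded generators.  The
#' defaults describe a small but structured study condition modelled on
#' curated corpora: a deep taxonomy of 400 concepts with 2--3 children per
#' node (bio-ontologies are deep, and annotations average depth 5--8), and
#' a corpus of 12 models carrying 6--12 annotations each.  Concepts are
#' sampled with a bias towards deeper (more specific) concepts, and most
#' records are drawn from a shared, family-clustered annotation vocabulary
#' because thematically similar models keep re-annotating the same few
#' ontology regions.
#'
#' @param seed integer seed; every generator call is deterministic given it.
#' @param n_concepts number of ontology concepts (>= 2).
#' @param branching integer pair: min/max children per internal node.
#' @param n_models number of models in a generated corpus.
#' @param annotations_per_model integer pair: min/max annotation records per
#'   model.
#' @param vocab_size number of concepts in the corpus' shared annotation
#'   vocabulary: thematically related models keep re-annotating the same
#'   specific concepts, so each corpus draws most records from a small
#'   recurring vocabulary with Zipf-like reuse.
#' @param vocab_families the vocabulary is clustered: its concepts are
#'   sampled from the subtrees of this many family head concepts, because a
#'   thematic corpus annotates a handful of ontology regions (families of
#'   sibling concepts), not isolated scattered ids.
#' @param vocab_frac fraction of each model's annotations drawn from the
#'   shared vocabulary (the rest is depth-biased background).
#' @param focus `"broad"` (sample from the whole taxonomy) or a concept id:
#'   thematic corpora then draw at least `focus_frac` of their annotations
#'   from that concept's subtree.
#' @param focus_frac fraction of annotations drawn from the focal subtree
#'   for thematic corpora (default 1: fully focused).
#' @param dag_extra_edges number of additional is_a edges (>= 0); 0 yields a
#'   tree, more turns the taxonomy into a DAG (never a cycle).
#' @param prefix ontology prefix of the generated concepts; one of `"GO"`,
#'   `"CHEBI"`, `"SBO"` so that generated resource URIs resolve.
#' @param dialect URI dialect for RDF annotations:
#'   `"identifiers.org"` or `"miriam"` URNs.
#' @param sbo_attr_frac fraction of annotations emitted as `sboTerm`
#'   attributes instead of RDF resources (only honoured when
#'   `prefix == "SBO"`).
#' @return a list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed, n_concepts = 400L, branching = c(2L, 3L),
                         n_models = 12L, annotations_per_model = c(6L, 12L),
                         vocab_size = 15L, vocab_families = 6L,
                         vocab_frac = 0.8,
                         focus = "broad", focus_frac = 1,
                         dag_extra_edges = 0L, prefix = "GO",
                         dialect = c("identifiers.org", "miriam"),
                         sbo_attr_frac = 0.2) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_concepts < 2L) stop("n_concepts must be >= 2")
  branching <- as.integer(branching)
  if (length(branching) != 2L || branching[1L] < 1L ||
      branching[2L] < branching[1L]) {
    stop("branching must be an increasing pair of positive integers")
  }
  annotations_per_model <- as.integer(annotations_per_model)
  if (length(annotations_per_model) != 2L || annotations_per_model[1L] < 1L ||
      annotations_per_model[2L] < annotations_per_model[1L]) {
    stop("annotations_per_model must be an increasing pair of positive integers")
  }
  if (dag_extra_edges < 0L) stop("dag_extra_edges must be >= 0")
  if (focus_frac < 0 || focus_frac > 1) stop("focus_frac must be in [0, 1]")
  if (vocab_size < 1L) stop("vocab_size must be >= 1")
  if (vocab_families < 1L) stop("vocab_families must be >= 1")
  if (vocab_frac < 0 || vocab_frac > 1) stop("vocab_frac must be in [0, 1]")
  if (!is.character(prefix) || length(prefix) != 1L ||
      !prefix %in% c("GO", "CHEBI", "SBO")) {
    stop("prefix must be one of GO, CHEBI, SBO ",
         "(generated URIs must resolve through the namespace map)")
  }
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 branching = branching, n_models = as.integer(n_models),
                 annotations_per_model = annotations_per_model,
                 vocab_size = as.integer(vocab_size),
                 vocab_families = as.integer(vocab_families),
                 vocab_frac = vocab_frac,
                 focus = focus, focus_frac = focus_frac,
                 dag_extra_edges = as.integer(dag_extra_edges),
                 prefix = prefix, dialect = match.arg(dialect),
                 sbo_attr_frac = sbo_attr_frac),
            class = "fixture_spec")
}

#' Generate a seeded random taxonomy and write it as OBO
#'
#' Builds a single-rooted random taxonomy: nodes are attached in
#' breadth-first order with a number of children drawn uniformly from the
#' `branching` range, which keeps depth logarithmic in the concept count.
#' `dag_extra_edges` additional is_a edges (child gains a second parent
#' that is not one of its descendants) turn the tree into a DAG without
#' introducing cycles.  The OBO file is written deterministically --
#' identical spec and seed give identical bytes -- and read back through
#' [load_obo()], so the returned taxonomy is guaranteed to round-trip.
#'
#' @param spec a [fixture_spec()].
#' @param path output OBO file path.
#' @return the loaded `"taxonomy"`, with the OBO path in attribute
#'   `"obo_path"`.
#' @export
generate_taxonomy <- function(spec, path = tempfile(fileext = ".obo")) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_concepts
  ids <- sprintf("%s:%07d", spec$prefix, seq_len(n))
  parent_of <- rep(NA_integer_, n)
  withr::with_seed(spec$seed, {
    queue <- 1L
    next_free <- 2L
    while (next_free <= n) {
      if (length(queue) == 0L) stop("infeasible branching specification")
      node <- queue[1L]
      queue <- queue[-1L]
      k <- sample1(seq(spec$branching[1L], spec$branching[2L]))
      k <- min(k, n - next_free + 1L)
      kids <- seq.int(next_free, next_free + k - 1L)
      parent_of[kids] <- node
      queue <- c(queue, kids)
      next_free <- next_free + k
    }
    extra <- list()
    if (spec$dag_extra_edges > 0L && n > 3L) {
      for (e in seq_len(spec$dag_extra_edges)) {
        child <- sample1(2:n)
        below <- descendants_int(parent_of, child)
        cand <- setdiff(seq_len(n), c(below, parent_of[child]))
        if (length(cand) == 0L) next
        extra[[length(extra) + 1L]] <- c(sample1(cand), child)
      }
    }
  })
  edges <- cbind(parent = ids[parent_of[-1L]], child = ids[-1L])
  for (e in extra) edges <- rbind(edges, c(ids[e[1L]], ids[e[2L]]))

  lines <- c("format-version: 1.2",
             paste0("ontology: ", tolower(spec$prefix)), "")
  for (i in seq_len(n)) {
    parents <- sort(unique(edges[edges[, "child"] == ids[i], "parent"]))
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: synthetic concept ", i),
               if (length(parents)) paste0("is_a: ", parents,
                                           " ! synthetic parent"),
               "")
  }
  writeLines(lines, path, useBytes = TRUE)
  tax <- load_obo(path, spec$prefix)
  attr(tax, "obo_path") <- path
  tax
}

# draw one element of x (safe for length-1 vectors)
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# descendants of node `i` (inclusive) in a parent-pointer tree
descendants_int <- function(parent_of, i) {
  out <- i
  frontier <- i
  repeat {
    kids <- which(parent_of %in% frontier)
    if (length(kids) == 0L) return(out)
    out <- c(out, kids)
    frontier <- kids
  }
}

#' Generate a seeded toy SBML corpus for a taxonomy
#'
#' Writes `n_models` minimal SBML Level 3 Version 1 documents whose species
#' and reactions carry RDF annotations (and, for SBO with
#' `sbo_attr_frac > 0`, sboTerm attributes) pointing at concepts sampled
#' from the taxonomy.  The sampling emulates two properties of curated
#' model corpora: concepts are depth-biased (weight `(depth + 1)^2`, so
#' deeper, more specific concepts are annotated more often), and models of
#' one corpus re-use a shared annotation vocabulary of `vocab_size`
#' concepts with Zipf-like weights (`vocab_frac` of each model's records),
#' since thematically similar models share semantic annotations.  Thematic
#' corpora (`focus` set to a concept id) take their vocabulary from the
#' focal subtree and draw at least `ceiling(focus_frac * n)` of each
#' model's annotations from it, so the guaranteed focal share is never
#' below `focus_frac`.
#'
#' @param spec a [fixture_spec()]; `n_models >= 1` is required here.
#' @param t the taxonomy generated from (or matching) `spec`.
#' @param dir output directory for the SBML files (created if needed).
#' @return character vector of SBML file paths, with attributes `"tally"`
#'   (named integer: the generator's internal per-concept annotation count)
#'   and `"n_records"` (total records written).
#' @export
generate_corpus <- function(spec, t, dir = tempfile("corpus")) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(t, "taxonomy"))
  if (spec$n_models < 1L) stop("n_models must be >= 1")
  focal <- NULL
  if (!identical(spec$focus, "broad")) {
    if (!spec$focus %in% t$ids) {
      stop("focus concept ", spec$focus, " not present in the taxonomy")
    }
    focal <- descendants(t, spec$focus)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- setdiff(t$ids, if (t$synthetic_root) t$root else character())
  w <- (unname(t$depth[ids]) + 1)^2
  focal_ids <- intersect(ids, focal %||% character())
  other_ids <- setdiff(ids, focal_ids)

  paths <- character(spec$n_models)
  tally <- setNames(integer(length(t$ids)), t$ids)
  n_records <- 0L
  corpus_seed <- (spec$seed %% (.Machine$integer.max - 1L)) + 1L
  pick <- function(pool, k) {
    if (k == 0L || length(pool) == 0L) return(character())
    sample(pool, k, replace = TRUE, prob = (unname(t$depth[pool]) + 1)^2)
  }
  withr::with_seed(corpus_seed, {
    vocab_pool <- if (is.null(focal)) ids else focal_ids
    n_fam <- min(spec$vocab_families, length(vocab_pool))
    heads <- sample(vocab_pool, n_fam,
                    prob = (unname(t$depth[vocab_pool]) + 1)^2)
    per_family <- ceiling(spec$vocab_size / n_fam)
    vocab <- unique(unlist(lapply(heads, function(h) {
      members <- intersect(descendants(t, h), vocab_pool)
      members[sample.int(length(members),
                         min(per_family, length(members)))]
    }), use.names = FALSE))
    zipf <- 1 / seq_along(vocab)
    for (m in seq_len(spec$n_models)) {
      n_ann <- sample1(seq(spec$annotations_per_model[1L],
                           spec$annotations_per_model[2L]))
      n_vocab <- min(n_ann, round(spec$vocab_frac * n_ann))
      from_vocab <- if (n_vocab > 0L)
        sample(vocab, n_vocab, replace = TRUE, prob = zipf) else character()
      n_bg <- n_ann - n_vocab
      if (is.null(focal)) {
        background <- pick(ids, n_bg)
      } else {
        # honour the focal floor: vocabulary draws are focal already
        n_focal_bg <- max(0L, min(n_bg, ceiling(spec$focus_frac * n_ann) - n_vocab))
        background <- c(pick(focal_ids, n_focal_bg),
                        pick(other_ids, n_bg - n_focal_bg))
        if (length(background) < n_bg) {   # degenerate pools
          background <- c(background,
                          pick(focal_ids, n_bg - length(background)))
        }
      }
      concepts <- c(from_vocab, background)
      as_attr <- if (spec$prefix == "SBO" && spec$sbo_attr_frac > 0) {
        seq_along(concepts) <= floor(spec$sbo_attr_frac * length(concepts))
      } else {
        rep(FALSE, length(concepts))
      }
      model_id <- sprintf("model_%03d", m)
      xml <- sbml_document(model_id, concepts, as_attr, spec$dialect)
      paths[m] <- file.path(dir, paste0(model_id, ".xml"))
      writeLines(xml, paths[m], useBytes = TRUE)
      tab <- table(concepts)
      tally[names(tab)] <- tally[names(tab)] + as.integer(tab)
      n_records <- n_records + length(concepts)
    }
  })
  attr(paths, "tally") <- tally
  attr(paths, "n_records") <- n_records
  paths
}

annotation_uri <- function(concept_id, dialect) {
  prefix <- sub(":.*$", "", concept_id)
  if (dialect == "identifiers.org") {
    sprintf("http://identifiers.org/%s/%s", tolower(prefix), concept_id)
  } else {
    ns <- c(GO = "obo.go", CHEBI = "obo.chebi", SBO = "biomodels.sbo")[prefix]
    sprintf("urn:miriam:%s:%s", ns, sub(":", "%3A", concept_id))
  }
}

# Minimal valid SBML L3V1 document.  Annotations are distributed over
# species (RDF bqbiol:is) and reactions (sboTerm attribute, SBO only).
sbml_document <- function(model_id, concepts, as_attr, dialect) {
  species <- character()
  reactions <- character()
  s_i <- r_i <- 0L
  for (k in seq_along(concepts)) {
    if (as_attr[k]) {
      r_i <- r_i + 1L
      reactions <- c(reactions, sprintf(
        '      <reaction id="%s_r%d" metaid="%s_r%d" reversible="false" sboTerm="%s"/>',
        model_id, r_i, model_id, r_i, concepts[k]))
    } else {
      s_i <- s_i + 1L
      sid <- sprintf("%s_s%d", model_id, s_i)
      species <- c(species, sprintf(paste0(
        '      <species id="%s" metaid="%s" compartment="c" ',
        'hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">\n',
        '        <annotation>\n',
        '          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
        '                   xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">\n',
        '            <rdf:Description rdf:about="#%s">\n',
        '              <bqbiol:is>\n',
        '                <rdf:Bag>\n',
        '                  <rdf:li rdf:resource="%s"/>\n',
        '                </rdf:Bag>\n',
        '              </bqbiol:is>\n',
        '            </rdf:Description>\n',
        '          </rdf:RDF>\n',
        '        </annotation>\n',
        '      </species>'),
        sid, sid, sid, annotation_uri(concepts[k], dialect)))
    }
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s" metaid="%s">', model_id, model_id),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    if (length(species)) c('    <listOfSpecies>', species,
                           '    </listOfSpecies>'),
    if (length(reactions)) c('    <listOfReactions>', reactions,
                             '    </listOfReactions>'),
    '  </model>',
    '</sbml>')
}
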