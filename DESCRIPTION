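Package: sbmlfeatures
Title: Annotation-Based Feature Extraction and Comparison for Sets of SBML Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harvests MIRIAM-style ontology annotations and sboTerm attributes
    from SBML models, condenses them into a bounded set of characteristic
    ontology concepts using four clustering and scoring strategies over is_a
    taxonomies (Gene Ontology, ChEBI, SBO, or any OBO taxonomy), and compares
    model sets through feature-to-feature semantic similarity aggregated by
    optimal assignment. Also provides annotation statistics (depth and branch
    distributions, feature overlaps) and seeded generators for synthetic
    taxonomies and toy SBML corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
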