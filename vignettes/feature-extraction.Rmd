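---
title: "Annotation-based feature extraction from sets of SBML models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-based feature extraction from sets of SBML models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlfeatures)
```

## The problem

Curated model repositories distribute SBML models whose elements are linked
to bio-ontology concepts through MIRIAM-style RDF annotations and `sboTerm`
attributes.  Thematically similar models tend to share annotations, so the
annotations of a whole *set* of models can be condensed into a handful of
ontology concepts that characterize the set -- its *characteristic
features*.  Feature sets in turn make sets of models comparable to each
other, something that keyword retrieval and model-to-model comparison do
not offer.  This package implements the full pipeline: ontology loading,
annotation harvesting, four feature-extraction methods, and feature-set
comparison, together with annotation statistics and seeded synthetic
fixtures that make every stage testable without network access.

## The quantities

All methods operate on a rooted is_a taxonomy with `N` concepts.  For a
concept `c`:

* `freq(c)` -- the number of concepts subsumed by `c`, including `c`
  itself.  Self-inclusion is deliberate: it is the only reading under which
  the root's probability is exactly 1 and its information content exactly
  0.  On DAGs the descendant *set* is counted, so a concept reachable along
  several paths counts once.
* `p(c) = freq(c) / N` -- the probability that a uniformly chosen concept
  falls under `c`.
* `IC(c) = -log2 p(c)` -- the information content in bits; deeper, rarer
  concepts carry more information.
* `EF(c)` -- the aggregated entity frequency of a model corpus: the number
  of annotation records pointing at `c` or any of its descendants (again as
  a set).  Its normalized form is the entity probability
  `ep(c) = EF(c) / EF(root)`.
* `Score_T(c) = IC(c) * EF(c)` -- a representativeness score under which a
  general concept must be supported by more annotations to outscore a
  specific one; it is the package's instrument against
  overgeneralization.
* `depth(c)` -- the shortest is_a path from the root.  DAGs admit several
  root paths; the shortest one is deterministic and cheap, and it is the
  depth used everywhere, including the similarity measure below.

Two concepts are compared with a path-length/depth similarity

\[ S(c_1, c_2) = e^{-\alpha l}\,\tanh(\beta h), \]

where `l` is the shortest is_a path between the concepts routed through
their least common subsumer (LCS), `h` the depth of that LCS, and the
defaults `alpha = 0.2`, `beta = 0.6` follow the established
parameterization of this measure.  Concepts whose only shared ancestor is
the root (`h = 0`) are maximally dissimilar (`S = 0`).  Identical concepts
are defined to have `S = 1`: the raw closed form saturates below 1 even
for a concept paired with itself, which would make a feature set fail to
match itself perfectly, so the identity convention is applied before the
formula.

## The four extraction methods

All methods return at most `max_features` concepts; 15 is the default
budget and 5 the customary alternative.

**Method 1 (static top-down)** starts from the frontier `{root}` and
repeatedly replaces the frontier concept of largest `p` by its children,
skipping any split that would push the frontier beyond the budget and
stopping when no legal split remains.  It depends only on the ontology and
is therefore a corpus-independent baseline that describes the shape of the
ontology itself.

**Method 2 (corpus-weighted top-down)** runs the same frontier descent
ranked by `ep` instead of `p` and restricted to concepts with `EF > 0`.
Two refinements matter:

* When an *annotated* concept is split, it stays in the frontier as a
  non-splittable member.  Dropping it would leave its own records
  unrepresented, and coverage -- every annotated concept is a
  descendant-or-self of some feature -- is an invariant we test.
* Splits that would exceed the budget are skipped, not fatal, so the
  method fills its budget whenever enough annotated structure exists.

**Method 3 (bottom-up)** initializes one cluster per directly annotated
concept and repeatedly merges the least-used subtree upwards: among all
parents whose `EF > 0` children are all current representatives (and whose
subtree holds no deeper surviving representative), the one with the
smallest `ep` absorbs its children.  When the budget is met, any remaining
budget is spent by the same top-down refinement that Method 2 uses.
Methods 2 and 3 are exact mirror images: splitting in descending `ep`
order and merging in ascending `ep` order traverse the same sequence of
frontiers in opposite directions, and because a split never shrinks the
frontier, both stop at the same place.  The mirror extends to
tie-breaking: Method 2 splits the lexicographically smallest of equal-`ep`
candidates, Method 3 merges the lexicographically largest.  Residual
divergence is only possible when equally probable candidates compete, and
any such tie is detected during the run and flagged in the result
(`tie_detected`), which our tests use: tie-free corpora must agree
exactly, and any divergence must carry the flag.

**Method 4 (score-based)** assigns each annotated concept to a
representative by greedy agglomeration: the concept climbs towards its
best-scoring parent for as long as that strictly improves `Score_T`, and
settles where the score peaks.  Heavily re-used specific concepts are
their own peaks and represent themselves; sparsely annotated concepts
merge into the nearest well-supported ancestor.  Climbing to the *global*
ancestor optimum instead would collapse every corpus onto its top-level
branches -- near the root, `EF` approaches the total record count while
`IC` shrinks only logarithmically, so the product keeps growing -- which
is precisely the overgeneralization the score exists to prevent; we
implemented both and kept the greedy climb, which reproduces the expected
behavior (features deeper than Method 2's, never deeper than the
annotations themselves).  When more representatives than `max_features`
survive, the highest-scoring ones are kept (ties: deeper first, then
lexicographic) and the result is flagged `truncated`; the method is only
required to select *up to* the budget.

Everything is deterministic: random seeds appear in fixture generation
only, never in extraction, and all ties break lexicographically.

## Harvesting and indexing annotations

`parse_sbml_annotations()` emits one record per `(element, qualifier,
resource URI)` occurrence in RDF annotation blocks -- duplicates count,
since we count annotations rather than distinct concepts -- plus one
record per `sboTerm` attribute.  Both MIRIAM URNs
(`urn:miriam:obo.go:GO%3A0051234`) and identifiers.org URIs in the
path and prefix dialects are normalized; unknown namespaces are tallied as
`"other"`, and unparseable text is kept in the unresolved table rather
than silently dropped.  All bqbiol/bqmodel qualifiers count by default
(a whitelist can restrict them), and model-level annotations are counted
unless switched off -- the alternative would discard, e.g., publication
references without any principled reason.

`build_corpus_index()` resolves records against one taxonomy at a time (a
feature set never mixes ontologies) and computes `direct`, `EF`, `ep` and
the aggregated document frequency `doc_freq` (the number of models citing
the concept or a descendant; aggregation upwards matches its
vocabulary-reduction role).  On trees `EF(root)` equals the number of
resolved records -- a conservation law our tests assert.  On DAGs a
multi-parent concept contributes once to each ancestor, so sums across
sibling branches may exceed `EF(root)`; conservation is asserted on trees
only.  `df_filter()` removes concepts seen in fewer than `min_df` models
(default 1, a no-op) and recomputes the index from the surviving records.

## Comparing feature sets

`set_similarity()` evaluates the concept similarity for every feature pair,
aligns the two sets with the Hungarian method so that the summed
similarity is maximal, and aggregates

\[ \mathrm{total} = \frac{\sum_{\text{matched pairs}} S}{\max(|A|, |B|)}. \]

The normalization by the larger set size is our choice among the
consistent options: it penalizes unmatched features and makes
self-similarity exactly 1.  It is isolated in one function, so replacing
it is a one-line change.  Features enter the assignment unweighted --
feature lists are reported as bare concept ids, and an EF-weighted
variant would make totals incomparable across corpora of different sizes.
The assignment solver is a Jonker--Volgenant implementation on the
square-padded matrix; padding guarantees a matching of size
`min(|A|, |B|)` even through zero-similarity pairs, and the solver is
checked against a brute-force permutation oracle in the tests.

## What the synthetic fixtures emulate

The generators produce OBO taxonomies and toy SBML corpora that are
deterministic given a seed (byte-identical files on repeated calls).  The
default study conditions are chosen to mirror, at desk scale, the data
regime of curated repositories:

* **Taxonomy**: 400 concepts, 2--3 children per node.  Narrow branching
  yields the depth that real bio-ontologies have; annotation depths then
  average 5--8, matching published depth distributions of curated model
  annotations.  Optional extra is_a edges produce DAGs (never cycles);
  multi-rooted inputs get a synthetic root whose depth-0 placement makes
  concepts from different top-level branches maximally dissimilar.
* **Corpus**: 12 models with 6--12 annotations each (about 110 records, a
  scaled-down curated thematic set).  Concepts are sampled depth-biased
  (weight `(depth+1)^2`), and 80% of each model's records come from a
  shared vocabulary of 15 concepts clustered into 6 concept families with
  Zipf-like reuse -- thematically similar models keep re-annotating the
  same few ontology regions, which is the premise the whole method rests
  on.  Thematic corpora draw their vocabulary from a focal subtree and
  guarantee the focal fraction deterministically (default 1.0: fully
  focused, which is also the only default under which "all features of a
  focused corpus lie in its subtree" can be asserted at 100%).
* **Budgets**: specificity comparisons between Methods 2 and 4 are run at
  `max_features = 5`.  What matters is the ratio of budget to distinct
  annotated concepts (about 5/30 here, matching the published regime of
  15 features against hundreds of distinct annotations); a budget of 15
  against 30 distinct concepts would saturate Method 2 and reproduce the
  known small-ontology saturation artifact instead of the phenomenon.

The fixtures deliberately do **not** emulate: real ontology scale (tens of
thousands of concepts), `part_of` and other non-is_a relations,
cross-ontology links, qualifier semantics (`bqbiol:is` versus
`isVersionOf` carry equal weight), or biologically meaningful model
structure (the SBML documents are minimal but valid).  Passing tests
therefore demonstrate the algorithmic properties of the pipeline --
conservation, duality of the two clustering directions, specificity
ordering of the methods, distinctness of thematic corpora -- not numeric
agreement with any particular ontology release or repository snapshot.

## Numerical and degenerate-input choices

* Obsolete OBO terms and non-is_a relationship lines are ignored; is_a
  cycles abort loading with a named cycle member.
* An empty corpus (or one emptied by `df_filter`) yields an empty feature
  set with a warning; comparing with an empty set warns and returns total
  0.
* LCS ties on DAGs break towards the lexicographically smallest id; all
  extraction tie-breaks are lexicographic and documented above.
* `ep` is defined as 0 everywhere when `EF(root) = 0` (rather than 0/0).
* The synthetic root never appears in a feature set.

## Problem sizes used in the test suite

The suite runs the duality study on 100 seeded corpora (150-concept
taxonomies, 8 models), the specificity and generalization studies on 50
focused corpora at the default conditions, the distinctness study on 50
seeds with four corpora each, and the assignment oracle on 200 random
matrices up to 6x6.  These sizes give stable rates while keeping the whole
suite in the low minutes on a single core.

## Limitations

The methods apply to taxonomy-shaped ontologies only; importing OWL
ontologies or reasoning over non-hierarchical relations is out of scope
(read OBO releases instead).  Feature-value vectors per model for ranked
retrieval, cross-ontology feature sets, and annotation writing are
likewise out of scope.  The aggregation formula for the total set
similarity is one consistent choice, not the only one; results should be
compared across corpora only with the same normalization.
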