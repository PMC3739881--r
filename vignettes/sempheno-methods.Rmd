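---
title: "Semantic species descriptions: model, reasoning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic species descriptions: model, reasoning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sempheno)
```

## The problem and the model

A taxonomic treatment encodes a species' phenotype as "Character name:
state." sentences organized by body region, backed by a character
matrix whose rows (OTUs — operational taxonomic units) stand for sets of
examined museum specimens. `sempheno` represents this whole structure
formally so that it can be queried by an automated reasoner.

Phenotypes follow the entity–quality (EQ) convention in its
entity-based form: an anatomical entity `E` bears a quality `Q`, written
in a Manchester-style syntax as `E and bearer_of some Q`, and attached
to the organism through `has_part`. When the quality-bearing structure
(the *primary locator*) only makes sense inside a containing structure
(*secondary locators*), the containers nest as a chain of `has_part`
restrictions:

```{r}
cfg <- sempheno_config()
labs <- ontology_labels(mini_ontology())
e <- compose_qualitative(c(labs[["mesosoma"]],
                           labs[["ventro-lateral region"]]),
                         labs[["foveate"]])
render_manchester(e, cfg$prefixes, labs)
```

The nested `has_part` form (rather than a `part_of` post-composition)
keeps the entity adjacent to its quality for a human reader and lets the
reasoner place the locator inside the same organism as the entity — a
fact the test suite checks explicitly on canonical models.

A phenotype class `P` is always asserted as a **subclass** of its EQ
expression, never an equivalent: the expression is a necessary
condition, not a complete definition. The link to a character state
`CS` is the universally quantified assertion `CS Type (denotes only
P)`. Because an OTU `denotes` each of its specimens and a state is
connected to its OTU through the matrix cell, the configured property
chain

```
state_of ∘ belongs_to_TU ∘ denotes  ⊑  denotes
```

materializes `denotes(CS, specimen)` edges, and `denotes only P` then
classifies every such specimen into `P`. Phenotype knowledge is
asserted once, on states, and flows to specimens by inference.

## Template structures and their boundaries

Four templates cover the character forms of matrices like this one:

* **qualitative** — the nested chain above;
* **presence/absence** — presence is `has_part some E` at the end of the
  chain. The model contains no negation, so absence is encoded as the
  quality `absent` borne by the innermost containing structure, with
  the missing part recorded machine-readably on the phenotype record
  (`absent_part`). With no containing structure the expression
  degenerates to `bearer_of some absent` on the organism itself. This
  follows coarse EQ practice and avoids unsound inferences; the cost is
  that the quality-partition query cannot see a bare organism-level
  absence (no `has_part` step), which the synthetic ground truth
  reflects;
* **count** — `has_part exactly n E`;
* **relative measurement** — `has_part some (e1 and bearer_of some
  (quality and towards some e2))`. OWL class expressions have
  tree-shaped models, so this cannot require `e2` to belong to the same
  organism — an instance merely needs *some* such structure to exist.
  Each relative state therefore also carries a rule (body: `has_part(o,
  x)`, `has_part(o, y)`, `x : e1`, `y : e2`, magnitude-relation(x, y);
  head: `o : P`) that documents the intended semantics. Rules are
  stored and serialized in a small reified vocabulary but never fired
  in ordinary reasoning; a declarative record is all the data set needs.

`classify_template()` matches most-specific-first: count (requires
`exactly`), relative (requires the `towards` nesting), presence/absence
(keyed to the configured `absent` quality, or a pure `has_part` chain),
then qualitative; everything else — unions of templates, bare classes —
is `nonstandard`. Precedence cannot be ambiguous because each earlier
grammar requires a construct the later ones exclude.

## Reasoning: two independent routes

`is_subsumed()` decides subsumption structurally for the fragment the
model needs: named hierarchies (with told complex superclasses such as
`'ventro-lateral region' SubClassOf part_of some mesosoma` unfolded into
the conjunct set), `and`/`or`, monotone existentials, and property
chains matched against a told first-step conjunct with recursion into
the filler — transitivity is simply the chain `r ∘ r ⊑ r`, and the
recursion always descends into a subexpression, so it terminates.
`only` appears in this data model solely as `denotes only P` and is
compared structurally (same property, subsumed filler); `exactly` is
compared structurally at equal cardinality and equivalent filler, with
the sound weakening `exactly n (n ≥ 1) ⊑ some`.

`oracle_subsumed()` is the package's independent check: it builds the
canonical model of the sub-expression — one individual per existential,
saturated under the hierarchy, told axioms, transitivity and chains —
and model-checks the sup-expression at the root. For the EL core this
is a complete decision procedure, and the acceptance suite requires
zero disagreements between the two routes on thousands of seeded random
instances. Number restrictions and universals have no sound
canonical-model oracle (minimal models under-count alternatives), which
is why the oracle rejects them and the fuzz stays inside the EL core;
`only`/`exactly` get targeted unit tests instead.

Two queries drive the analytics, exactly in their printed two-disjunct
and single forms: a character describes entity `E` when one of its
states' definitions is subsumed by `(has_part some E) or (has_part some
(part_of some E))`, and quality `Q` via `has_part some (bearer_of some
Q)`. `has_part` and `part_of` are transitive in the default
configuration (as in the standard relations ontology); the
`has_part ∘ part_of ⊑ has_part` folding chain is supported but off by
default — the explicit two-disjunct query makes it unnecessary.

## Tunable parameters

All model properties are configuration entries (`sempheno_config()`),
because concrete ontology IRIs drift across releases: `has_part`,
`part_of`, `bearer_of`, `denotes`, the `towards`-style property, the
three magnitude relations (increased/decreased/similar), the `absent`
quality, the top class, and the three steps of the denotes chain. All
default to IRIs in the package's `example.com` mini namespaces and can
be remapped to real HAO/PATO/RO/CDAO/IAO IRIs through a JSON config
(`read_config()`). The namespace map that buckets class-usage counts
lives in the same place.

## The packaged fixtures

The five treatments ship as plain text in the canonical rendering the
package itself produces (sections Body length / Head / Mesosoma /
Metasoma, one sentence per line, polymorphic states joined by `"; "`),
so `parse_treatment()` and `render_treatment()` are exact inverses at
the coding level. Parsing all five and merging characters by exact
label yields 43 characters and a complete 5 × 43 matrix — the merge is
deliberately exact-match because the treatments are machine-rendered
and label-stable; fuzzy matching would only create silent aliasing.

The "Material Examined" sections use a lenient grammar (`COUNTRY:
region: counts. catalog numbers (coden)`); fragments that do not parse
are retained verbatim on the specimen record rather than rejected, and
the occurrence filter matches country, subdivision and the verbatim
fragment, so a holotype written with a comma instead of a colon still
counts for its locality.

The identification key is an explicit couplet graph in JSON. The
typeset key disagrees with the printed descriptions in two places (a
frontal-carinae state in the second couplet, and the setiferous-patch
states of the final couplet, where the species' own diagnosis supports
the opposite assignment); the fixture encodes the reading consistent
with the descriptions, restores the terminal leaf label the layout
drops into a figure caption, and normalizes one typo ("paralell"). Lead
semantics are conjunctive — a lead is satisfied only if every test
matches — with any-match under polymorphism; that resolves the one
species whose description says `absent; present` against a lead
requiring `present`.

The mini ontology is a synthetic stand-in emulating the *structure* of
the real anatomy/quality/spatial ontologies (a transitive `part_of`
tree, quality subtrees under shape/size/color/texture) at fixture
scale. Green tests against it establish that the machinery is correct
on such structures — not that any number computed against the real
ontologies' content is reproduced. The two analytics of the original
study that depend on that external content (the cross-study class-usage
row and the published template-category totals, which require the
deposited annotation set) are encoded as red acceptance tests until the
supplementary data are supplied locally; the name-based template
heuristic in `build_study()` intentionally reports its own
pre-reconciliation counts (14 presence/absence, 1 count, 4 relative,
23 qualitative, 1 unannotated body-length character), and a
category-override table is the designated reconciliation mechanism.

## The synthetic generator as a stated world

`generate_study()` fixes its world by a single seed: a part_of tree of
12 anatomy classes (depth ≤ 3), 8 quality leaves, 4 OTUs with 2
specimens each, a 10/5/2/3
qualitative/presence/count/relative character mix, and a 10%
polymorphism rate — proportions chosen once to mirror a small
morphological matrix of this kind, with acceptance runs scaling the
counts down for speed, never toward a result. Ground truth is computed
during generation from the construction itself (which chain classes
are `has_part`-reachable, which quality ancestors are borne, which
specimen–phenotype pairs the codings imply), never by calling the
reasoner; the tests then require the inference pipeline to reproduce
it exactly. What the generator does not emulate: real ontologies'
multiple inheritance, annotation errors, partially coded matrices
(every OTU is fully coded), and nonstandard expression shapes.

## Numerical and representational choices

* All outputs are sorted lexicographically (byte order, locale-free);
  reports format percentages to one decimal while keeping exact values.
* Rendering preserves authored operand order and parenthesizes every
  non-named operand, so `parse ∘ render` is the identity on ASTs and
  `render ∘ parse` is idempotent on strings; expressions are never
  normalized or sorted.
* IRIs are the identity keys everywhere; labels are display-only.
  Phenotype class IRIs are minted deterministically from the state IRI
  (suffix `#phenotype`) so re-annotation is stable across runs.
* The Turtle and RDF/XML serializations are restricted dialects written
  and read by the package itself (no RDF library exists in the target R
  stack); round trips are checked by blank-node-respecting graph
  isomorphism (colour refinement plus backtracking), which is exact at
  fixture scale.
* NEXUS export assigns per-character state symbols (up to 32; beyond
  that the writer refuses, naming the character) and writes
  polymorphism as `{01}`; CSV joins states with `"; "`. Both re-read
  losslessly at the coding level, and CSV is byte-stable under
  write–read–write.
* The OTU–specimen link is one `denotes` edge per member specimen (an
  OTU denotes the set through its members); a set-valued reading would
  change nothing downstream except the edge count.

## Known limitations

The reasoner is deliberately incomplete outside its fragment: no
negation, no general universals, no number-restriction reasoning beyond
structural comparison, no consistency checking. Relative-measurement
semantics are documented by rules, not enforced — a reasoner using only
the class expressions cannot distinguish "antenna longer than *its*
eye" from "longer than *some* eye". Specimen parsing is heuristic by
design and validated only against the packaged material; treatments in
other formatting conventions will need their own front end.
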