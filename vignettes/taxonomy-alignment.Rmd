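---
title: "Aligning and comparing multiple taxonomic hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning and comparing multiple taxonomic hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxalign)
```

## The problem

Biodiversity data are indexed by scientific names, but every checklist
carries its own classification: the same genus may sit in different
families, aggregators manufacture higher-taxon records from flat
classification strings, and synonyms blur which usages denote the same
taxon. A *name usage* -- one appearance of a name literal in one data
source, with its local parent and status -- is the atomic record. Comparing
several checklists therefore means reconciling trees of name usages that
agree on many literals and disagree on structure.

`taxalign` reconciles them *ostensively and conservatively*: it never
decides which classification is right. It builds a single **composite
tree** (the "aligner") covering every name usage of every hierarchy under
comparison, merging usages of the same literal only when their
classifications can be embedded into one another, and keeping them apart --
as duplicated, suffixed nodes -- whenever they cannot. The composite is a
bookkeeping device for alignment and diffing, not a taxonomic hypothesis;
when the input hierarchies are mutually inconsistent, the composite is
deliberately *not* a sensible taxonomy.

## The merge procedure

Hierarchies are incorporated in sequence. The first is copied directly;
each subsequent tree is scanned breadth-first with a pre-fetch of one
depth: a node is visited together with its children, so children are mapped
(or created) while their parent's composite node is at hand, and only the
root ever needs a cold lookup.

Three mapping tables are maintained:

* the **forward map**, (source, usage) → composite node;
* the **reverse map**, its exact inverse;
* the **parental-name table**, a double index (literal, parent literal) →
  composite nodes, which caches candidate nodes even after the direct
  parent--child edge has been dissolved by an inserted intermediate.

For each unmapped usage the candidate composite node is resolved as
follows. If the parental-name table has entries under the usage's own
(literal, parent literal) pair, only those candidates are examined;
otherwise every composite node of the literal is. In both branches the
usage's **parental path** -- the literal sequence from its parent to its
root -- is tested for compatibility against the candidate's current
composite parental path, and the candidate is reused only when it is
*unique*. Zero or several surviving candidates both create a new node: the
merge is modest and conservative, preferring duplication over a wrong
join. Same-literal duplicates receive suffixes in creation order.

**Path compatibility** is ordered-subsequence embedding: two paths are
compatible when the shorter is a subsequence of the longer, i.e. the
assignments differ only in intermediate names. Two equal-length paths are
compatible only when identical; this is what keeps, say,
`...→Artiodactyla→X` and `...→Cetartiodactyla→X` on two separate composite
nodes while `...→X` happily merges with `...→Inserted→X`.

Two further rules are worth spelling out, because the procedure's prose
leaves them open and we had to fix a behaviour:

* **Both resolution branches test the candidate's own parental path,
  immediate parent included.** The two branches of the candidate lookup
  differ only in *which* candidates are examined (the bucket sharing the
  parent literal, or all nodes of the literal). Testing the path
  above-but-excluding the differing parent would silently merge usages
  whose immediate parents conflict at equal depth, collapsing exactly the
  duplications the aligner exists to expose.
* **A candidate already occupied by the hierarchy being incorporated is
  never reused.** Mapping two usages of one source to one composite node
  would put two of its names on the same display row and hide intra-source
  duplications; keeping them apart preserves the property that
  inconsistencies *within* a single checklist are also reproduced in the
  aligner.

When a reused node's new parental composite node lies strictly below its
current parent, the node is re-parented downward (an inserted intermediate
takes over the edge); the parental-name table retains the old pair, so
later hierarchies using the shallower classification still find the node.
Before matching, same-literal siblings within the incoming hierarchy are
merged aggressively (first occurrence survives, descendants transfer),
since such redundancy otherwise multiplies candidates.

The composite is a *forest* under a virtual super-root, so hierarchies
whose highest taxa are incompatible (one rooted at `root`, another at
`Biota`) coexist as independent trees. The result is a pure function of
the ordered input sequence; the order may influence the outcome (a usage
with no intermediates can attach to either of two refined branches), which
is why the comparison functions expose and record the incorporation order.

## Layout

Rows are assigned by pre-order traversal of the composite forest: vertical
position is decided by the composite, horizontal position (indentation
depth) by each hierarchy alone. A literal absent from a hierarchy leaves a
vacancy in that column, and removing a column never reshuffles the others.
Collapsing operates on composite nodes, so it is synchronized across all
hierarchies by construction. The layout is pure data (`assign_rows()`
returns tibbles); `render_alignment()` and `autoplot()` are thin consumers.

## Facets

Every literal occurring anywhere is classified by `classify()`:

* **inconsistent** -- the composite holds ≥ 2 nodes of the literal. Read
  off the composite alone; covers inter- and intra-hierarchy conflicts.
  Note that a row in this facet means *some* of its usages conflict, not
  that every pair does.
* **different** -- immediate higher literals differ but all paths embed
  (a higher-name-path conformal difference); excludes `inconsistent`.
* **missing** -- absent from at least one hierarchy, with no difference or
  inconsistency among those that have it. A literal both missing somewhere
  *and* differently assigned elsewhere lands in `different`: difference
  dominates absence.
* **common** -- same literal, same immediate higher literal, everywhere.
* **synonyms** -- the heuristic "potential synonyms between hierarchies":
  a usage's higher literal that is not on the ancestor literal path of its
  composite node. Conservative merging makes this rare -- it requires a
  cross-branch reuse, typically in the shadow of a duplicated higher
  literal -- and such rows always also appear in `different`. These are
  *candidates* for synonymy across taxonomic views, not declared synonyms.

`common`, `different`, `missing` and `inconsistent` partition the literal
universe. Cells carry the higher literal(s) of the row's literal per
hierarchy, with two reserved markers: `""` for absence and `"(root)"` for
a root usage (displayed without a higher name, but machine-distinguishable
so CSV round-trips are exact). Rows sort alphabetically by literal, unlike
the aligner column, which keeps first-seen sibling order -- two different,
deliberate orderings.

Synonym rows of a checklist (`taxonomicStatus = synonym`) are kept as
annotations of their accepted usage rather than as children: a synonym is
not an accepted member of its higher taxon, but the relationship stays
recoverable through the accepted name. The facet universe covers hierarchy
(non-synonym) usages.

## Trimming by height and depth

Retrieved or loaded hierarchies can be trimmed around a focus usage by a
level count, a named rank, or both (`rank_spec()`, `trim_by_rank()`). With
both given, whichever limit retains fewer nodes wins, because some
taxonomies interpose many intermediate ranks between the major ones.
Unranked usages count toward a level limit but never satisfy a rank limit,
so a path trimmed at `class` may retain unranked usages below `phylum`.
`levels = 0` upward cuts the higher-taxa path entirely -- the recommended
way to inspect same-literal siblings that the aggressive sibling merge
would otherwise unify. The rank table ships with ~33 Linnaean ranks
including the common intermediates; unknown rank strings compare as
unranked.

## The offline client

`search_names()`, `expand_synonyms()` and `fetch_hierarchy()` run against a
pluggable backend. The shipped `fixture_backend()` answers everything from
a recorded JSON store (a hand-authored synthetic miniature -- no real
aggregator data), so the entire test suite and all examples are hermetic;
`live_backend()` is a thin, paginated HTTP client with the same surface.
Results accumulate in a per-backend cache keyed by endpoint and canonical
query, so repeating a query issues zero new lookups.

Search semantics follow the usual species-API controls: one match mode
(`exact`, `fuzzy`, `suggest`, `full_text`, or `contain` -- the latter
returning the higher taxa containing the match), a rank filter applied as a
*union* with unranked records (rank cannot exclude usages that carry no
rank), and vernacular matching with an optional language. Synonym
expansion is a fixed-point iteration: query, collect synonym (and
optionally basionym) literals, re-query, stop when the literal set is
saturated; a cap of 10 rounds guards against pathological stores, and the
result depends only on the seed *set*, not its order. Records flagged as
manufactured from de-normalised classifications are tagged, never merged:
unification of look-alike records is left to the user.

## The synthetic-data generator

`simulate_hierarchies()` emulates a set of checklists over a shared name
pool: a common scaffold (root plus two equal-length arms) present in every
tree, shared leaves placed identically, a controlled fraction of literals
injected as *incompatible* assignments (arm one at depth *d* in the first
tree, arm two at the same depth elsewhere -- equal-length differing paths,
provably un-embeddable), one compatible placement difference when the pool
is partially shared, and tree-unique leaves. Defaults (3 trees, 30
literals, depth 3--5, overlap 0.5, inconsistency 0.1) describe a small
checklist-comparison regime; they were chosen once as a plausible desk-size
scenario and are not tuned. Property tests and the acceptance script run
the generator at 10--20 literals over 100 seeds, which keeps the whole
suite well under a minute for these checks while exercising every merge
branch.

What the generator does *not* emulate: authorship leaking into literals,
fuzzy spelling variation, rank disagreement, data inflation from
de-normalised records, or order-dependent attachment of intermediate-free
paths. Passing tests on generated data therefore certify the merge,
layout and facet logic -- not robustness to dirty real-world name strings,
which the design deliberately leaves to upstream name parsing.

A brute-force oracle (grouping usages by literal and maximal compatible
path class, implemented without any composite machinery) independently
predicts the number of composite nodes per literal; the suite checks
agreement on small random sets over 100 seeds.

## Numerical and degenerate-input choices

* Literal comparison is case-sensitive and whitespace-normalized only;
  readers are responsible for canonical (authorship-free) names. The
  paperless alternative -- case-folding or authorship stripping -- belongs
  in a name parser, not here.
* Ties in candidate resolution (0 or ≥ 2 compatible candidates) always
  create a new node; suffixes count up from 1 for the second duplicate.
* Composite children keep first-seen order; new children append;
  re-parented nodes append to their new parent.
* A single-node hierarchy is legal; empty input is an error (`"no
  hierarchies"`); incorporating the same `source_id` twice is an error.
* Checklist readers accept any row order, fail on duplicate or dangling
  identifiers and on parent cycles, and sniff comma/tab delimiters; ids
  are opaque strings throughout.
* Exports: one CSV per facet (RFC 4180, UTF-8, exact round-trip) or one
  workbook with a sheet per facet, written as minimal Office Open XML with
  inline strings (no spreadsheet-writing dependency exists in the stack;
  `readxl` verifies the workbook in the tests).

## Known limitations

* No best-fit selection among multiple candidates: ambiguous usages
  always duplicate. Smarter tie-breaking would need evidence beyond name
  literals.
* No rank-aware matching; two usages of one literal at different ranks
  merge if their paths embed.
* The composite depends on incorporation order where the inputs are
  genuinely ambiguous; the order is therefore explicit and logged.
* The synonym facet is a heuristic over structure, not nomenclature; it
  cannot see synonymies that leave no structural trace.
* Nomenclatural codes are not modelled, so hemihomonyms (one literal valid
  in two codes) simply appear as either consistent or duplicated names,
  depending on their classifications.

## A worked example

```{r}
trio <- schematic_trio()
cx <- build_composite(trio)
cat(render_alignment(cx), sep = "\n")
glance(classify(cx))
```
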