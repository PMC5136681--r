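# taxalign

Aligned, faceted comparison of multiple taxonomic hierarchies in R.

Checklists disagree: the same genus sits in different families depending on
the data source, aggregators manufacture higher-taxon records from flat
classification strings, and synonyms hide which records denote the same
taxon. `taxalign` is for anyone — curator, aggregator, or downstream user of
name-indexed data — who needs to see *where* several classifications agree
and where they do not, without first deciding which one is right.

## What it computes

The core object is the **composite ("aligner") tree**: a single tree (a
forest under a virtual super-root) covering every *name usage* — one
appearance of a name literal in one source, with its local parent — of all
hierarchies under comparison. Hierarchies are incorporated in sequence by a
breadth-first scan; an unmapped usage of literal *L* with parental path *p*
(the literal sequence from its parent to its root) is matched against
candidate composite nodes of *L* through a double-indexed
(literal, parent-literal) table, and reused **only when a unique candidate's
composite parental path is compatible with *p***. Compatibility is
ordered-subsequence embedding: *p* ≤ *q* may merge iff *p* is a subsequence
of *q*, so classifications differing only in intermediate names align, while
equal-length conflicting paths never do. Ambiguity (zero or several
compatible candidates) always creates a new, suffix-distinguished node —
the merge is conservative by design, and duplicated literals in the
composite are exactly the **inconsistent** assignments.

On top of the composite, the package computes:

* a synchronized **row layout** — vertical position from the composite,
  indentation from each hierarchy, vacancies where a name is absent
  (`assign_rows()`, `render_alignment()`, `autoplot()`);
* **facet tables** over all name literals — `common`, `different`,
  `missing`, `inconsistent`, potential `synonyms`, and `all` — with one
  column of higher-name assignments per hierarchy (`classify()`), exported
  as CSV files or an Excel workbook (`export_tables()`);
* offline-first **name queries** in species-API style — match modes,
  rank-filter-as-union, recursive synonym/basionym saturation, hierarchy
  retrieval with height/depth trimming by levels or rank
  (`search_names()`, `expand_synonyms()`, `fetch_hierarchy()`,
  `trim_by_rank()`) — against a recorded fixture store or a live endpoint;
* reproducible **synthetic hierarchy sets** with controlled overlap and
  inconsistency for testing and benchmarking (`simulate_hierarchies()`).

## A worked example

Three small hierarchies: `h1` lacks the names B and S, and `h2`/`h3` place
S under incompatible paths.

```r
library(taxalign)
trio <- schematic_trio()
cx <- build_composite(trio)
cat(render_alignment(cx), sep = "\n")
#> aligner      | h1    | h2      | h3
#> A            | A     | A       | A
#>   B          |       |   B     |   B
#>     C        |   C   |     C   |
#>       D      |     D |       D |     D
#>         S #1 |       |         |       S
#>       S      |       |       S |
```

The aligner column shows the composite: S appears twice (`S` and `S #1`)
because its two assignments cannot be embedded into one another, and each
hierarchy's names sit on the shared row of their composite node, leaving
vacancies (e.g. rows B and S in `h1`). The facets summarize the comparison:

```r
classify(cx)
#> <facet_tables>
#>   all           5
#>   common        1
#>   different     2
#>   missing       1
#>   inconsistent  1
#>   synonyms      0
classify(cx)$different
#> # A tibble: 2 × 4
#>   literal h1    h2    h3
#>   <chr>   <chr> <chr> <chr>
#> 1 C       A     B     ""
#> 2 D       C     C     "B"
```

Read: A is common to all three; B is merely missing from `h1`; C and D are
assigned to *different* (but compatible) higher names — D under C in
`h1`/`h2` but directly under B in `h3` — and S is inconsistent. Empty cells
mark absence; `(root)` marks a hierarchy's root. `export_tables()` writes
these tables as `all.csv`, `common.csv`, … or as one workbook with a sheet
per facet.

Darwin Core-style checklists load with `read_checklist()` (nested JSON trees
with `read_json_tree()`); `demo_genus_checklists()` ships a five-source
synthetic genus example, and `inst/cli/taxalign.R` wraps the pipeline
(`search`, `compare`, `fixture`, `export` subcommands) for shell use.

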