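---
title: "Comparing concept-annotated medical forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing concept-annotated medical forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formcompare)
```

## The model

A medical form is treated as an ordered list of data items; everything
else about the form (layout, fonts, pagination) is disregarded because
the question the comparison answers is one of *semantic*
interoperability: which data collected by two forms could be exchanged
or pooled. Each item is represented by three components:

* **name** — the human-readable label; compared only after
  canonicalisation (Unicode NFC, whitespace collapsing, case folding),
  since capitalisation and spacing carry no meaning;
* **concept codes** — one (precoordination) or several
  (postcoordination) codes from a medical terminology, read from ODM
  `Alias` elements with a configurable annotation context (default
  `"UMLS"`). Codes are opaque identifiers here: the package neither
  validates them against a terminology release nor exploits relations
  between concepts;
* **value domain** — the data type (boolean, date, time, string, float,
  integer), an optional code list (the permissible coded values), and an
  optional measurement unit.

Item pairs are classified by three nested equalities: different code
sets ⇒ *differing*; same codes but different domains ⇒ *similar*; same
codes and domains ⇒ *matching*, or *identical* when the normalised names
agree as well. The assumption doing the real work is that concept codes
are assigned consistently across forms; inter-coder disagreement in
real annotation practice directly becomes misclassification, and no
rule here can repair it. Items with no code at all cannot take part and
are reported in a separate uncoded list.

Two deliberate strictness choices: concept-code sets compare by **exact
set equality** (a postcoordinated item `{A, B}` does not partially match
`{A}` — partial-overlap credit would need a similarity threshold the
categorical model does not define), and code lists compare by their
coded-value sets plus, where both sides annotate an entry, the entry's
concept codes — display texts are ignored because they are
language-dependent while codes are stable.

## Best-fit matching of two forms

"Best fitting" is made precise as a one-to-one pairing: each item may be
claimed at most once, otherwise category counts would double-count and
no longer sum to the form size. The pairing is built in three priority
passes — identical, then matching, then similar — each solving a
maximum-cardinality bipartite matching (Kuhn's augmenting-path
algorithm) over the still-unpaired eligible items. Eligibility always
requires equal code sets, so the problem decomposes by code class;
within a pass ties are broken in document order, making the output
deterministic. Coded items unpaired after the three passes are
differing.

The lexicographic priority (maximise identical first, then matching,
then similar) is the natural reading of a best-fit report: an identical
pair is strictly more useful for pooling data than a matching one, and
so on. The test suite verifies on small forms, by brute-force
enumeration of all injective pairings, that the greedy three-pass scheme
attains this lexicographic optimum, and that counts are invariant under
swapping the argument forms.

```{r example}
pair <- worked_example_pair()
report <- match_items(pair$forms[[1]], pair$forms[[2]])
glance(report)
```

## Form sets, distances and clustering

`compare_form_set()` compares every unordered pair once and mirrors the
counts into three symmetric matrices (equivalent to comparing all
ordered pairs, by the symmetry above). Diagonals follow a fixed
convention: the identical matrix's diagonal is the form's coded-item
count, the other diagonals are zero, and diagonals are excluded from
colour scaling and from the distance maximum so self-comparison does not
swamp the off-diagonal structure.

Because a small form can never share many items with anyone, the
*relative* view divides each entry by the smaller of the two forms'
coded-item counts, mapping into [0, 1]; a form with zero coded items
would divide by zero and instead gets a zeroed row/column with a
warning.

The distance between two forms is defined from the number of items they
have in common: `d(i, j) = C − common(i, j)` with `C` the largest
off-diagonal common count. This keeps the intended ordering — the pair
sharing the most items is closest, disjoint pairs sit at the maximum
`C` — while staying on the count scale the matrices use. It is a design
choice where several were defensible (e.g. `1 − common/min(sizes)`); the
implementation isolates it in `to_distance()` so it can be swapped. When
no pair shares anything the distances collapse to zero and clustering is
flagged as degenerate rather than refused.

Clustering itself is standard agglomerative hierarchical clustering
(`stats::hclust`; complete linkage by default, average and single
available), validated in the tests against a naive re-implementation
that repeatedly merges the closest cluster pair. Trees can be exported
as Newick with branch lengths derived from merge heights.

```{r formset}
set7 <- evaluation_form_set(seed = 1)
res <- compare_form_set(set7)
glance(res)
autoplot(res, matrix_name = "identical")
dendrogram_plot(cluster_forms(to_distance(res$matrices$identical)))
```

## ODM I/O conventions

The standard does not prescribe where concept annotations live, and real
exports differ. The choices here, all surfaced as arguments:

* codes are read from `Alias` elements matched on their `Context`
  attribute (the standard ODM extension point for external
  vocabularies); the accepted context list is configurable;
* elements are matched on local names, so documents with or without the
  CDISC namespace parse identically;
* `DataType` values are lower-cased before mapping; unknown types map to
  `"other"` with a warning rather than an error, so one exotic item does
  not block a whole form;
* only the first `MeasurementUnitRef` of an item is used (warning if
  more are present) — one unit per domain is the model the similar
  category rests on;
* a dangling `CodeListRef` is a hard structural error, not an empty
  domain: silently dropping a code list would turn similar items into
  matching ones.

`write_odm()` emits deterministic ODM 1.3 (fixed `CreationDateTime`), so
the same study always produces byte-identical files, and a write→parse
round trip preserves comparison behaviour exactly — a property the
acceptance suite checks.

## What the synthetic generator emulates

No annotated real form corpus is redistributable here, so validation
rests on generated fixtures with *planted, exactly recoverable*
structure: every planted identical/matching/similar pair has its own
concept code, all remaining coded items draw from disjoint code pools,
names carry a unique running index, and item order is shuffled. Exact
recovery (comparator output = generator parameters) is therefore a sharp
correctness test, not an approximation; it is swept over 200 random
feasible specifications in the acceptance suite. In `gen_form_set()`
overlap targets are restricted to pairwise-independent pools (each
shared pool feeds exactly one form pair) — arbitrary overlap systems are
hard to realise and unnecessary for validation.

Presets mirror three reference scenarios: the two 8-item example forms
(counts 1/2/2 with 3 uncoded items), a 21- vs 31-item pair with 4
identical, 5 matching, 3 similar and hence 9 differing items from the
first form's perspective, and a 7-form set with 285 items (min 5,
max 87, rounded mean 41) carrying planted overlaps of 48 and 18
identical items. These sizes are also the problem sizes the test suite
runs at; they complete in seconds.

What the generator does **not** emulate: realistic annotation noise
(inter-coder disagreement, partially overlapping postcoordination),
multilingual names, code lists with near-miss value sets, or skewed
code-frequency distributions of real repositories. Passing tests
demonstrate the algorithms are implemented correctly, not that real
forms are annotated well enough for the comparison to be clinically
reliable — with sloppy annotation the differing count inflates and the
clusters lose meaning. The small "adversarial" forms used in the
property tests (tiny code/name/domain pools, forced collisions) probe
the matching logic harder than realistic data would, in the opposite
direction.

## Numerical and degenerate-input choices

* Rounded mean item counts are reported alongside the exact fraction
  (`summary_stats()`), using R's default round-half-to-even.
* Empty forms, all-uncoded forms, zero-overlap sets and 1×1 matrices
  are legal inputs everywhere; they produce empty reports, zeroed
  relative rows (with a warning), degenerate-distance warnings and
  single-cell grids respectively.
* Grid-image colour is a linear red→yellow ramp over the off-diagonal
  value range (absolute mode) or fixed [0, 1] (relative mode); a
  constant matrix widens the scale by one unit to keep the mapping
  defined, rendering uniformly red.
* Clustering determinism under tied distances follows `hclust`'s fixed
  merge order; tests pin it by asserting repeated runs are identical.

## Limitations

* Concept codes are opaque: no UMLS release is consulted, so synonymous
  concepts under different CUIs remain differing.
* The four categories are crisp; there is no graded similarity score,
  and no partial credit for overlapping postcoordination.
* One annotation context is compared at a time; cross-terminology
  mapping (e.g. SNOMED-annotated vs UMLS-annotated forms) is out of
  scope.
* HL7 CDA input is not supported; only ODM 1.3 study metadata is read.
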