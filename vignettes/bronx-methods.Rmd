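---
title: "Exposé-based barcode identification: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposé-based barcode identification: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronx)
```

## The model

The engine treats a reference sequence not as a string to be aligned but
as a collection of *characters in context*: at every position `p` it
extracts `n` pretext nucleotides, then a text of every length `x = 1..y`,
then `n` postext nucleotides, provided the window fits. The analogy is a
morphological description — "hairs *on the midvein*" — where the flanks
say *where* an observation was made and the text says *what* was
observed. All windows observed across every sampled sequence of a
terminal (a species, a genus, or a user-defined group) are pooled into
that terminal's composite exposé, with set semantics: a combination
counts once no matter how many specimens show it.

Three consequences drive the design:

1. **No alignment is ever computed.** Context matching replaces
   positional homology, so structurally unalignable markers are handled
   the same way as well-behaved ones.
2. **Shared variation yields ties.** If two species both exhibit a
   haplotype, every window of a query drawn from that haplotype matches
   both exposés equally; the winner set has two members and the result is
   flagged ambiguous. We consider this a feature, not a failure: the data
   genuinely cannot separate the species.
3. **Higher levels inherit.** A genus exposé is the union of its species'
   exposés, so a query from an unsampled species of a sampled genus still
   finds most of its context at genus level.

Queries are scanned on both strands with the text length fixed at `x`.
Each query window contributes at most +1 to each terminal: +1 when the
exact (pretext, text, postext) combination is stored; otherwise, if the
(pretext, postext) pair is absent from that terminal's exposé but the
pretext is present, a *nearest-postext fallback* consults the stored
combination with the shortest text for that pretext (the postext that
begins physically closest downstream in the source sequence) and awards
+1 when the stored and query texts agree on their first
`min(|stored|, x)` symbols. Scores are therefore bounded by the number of
query windows, `2 * (L - 2n - x + 1)` for a clean query of length `L`.

Windows containing any IUPAC ambiguity symbol — on either the reference
or the query side — are never stored and never scored. This is also what
keeps concatenated markers separate: markers are combined into one
sequence with a spacer of 15 `N`s, and every window touching the spacer
is dropped, so context never leaks across the junction.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 6 nt | pretext/postext length; 12 invariant positions anchor each window, long enough that random 12-mer collisions are rare in a ~1 kb marker, short enough that within-genus variation does not destroy all anchors |
| `y` | 8 nt | maximum stored text length; bounds index size (windows per sequence grow linearly in `y`) |
| `x` | 3 nt | fixed query text length; must satisfy `x <= y` |
| `spacer` | 15 `N` | marker-join spacer; anything `>= 2n + y - 1` positions of the junction is already excluded by the ambiguity rule, the default is simply comfortably larger than `n` |

The alignment baseline defaults to match +1, mismatch −1, gap open 5,
gap extend 2, with a gap of length `L` costing `open + extend*(L-1)`.
These are conventional similarity-scheme values; the published benchmark
this package's evaluation framework models used external aligners at
their defaults, so small divergences in alignments (and hence in
p-distances near the decision boundary) are expected and documented
rather than tuned away.

## Decisions where the procedure was genuinely open

Several details of the engine are not fixed by its published description;
the package resolves them as follows, each isolated behind one function
so a different reading is a one-line change.

* **"Physically nearest" postext** is taken as the stored combination
  with the *shortest text* for the pretext (its postext starts closest
  downstream), ties broken lexicographically by postext then text for
  determinism (`nearest_fallback()`).
* **Fallback match condition**: the stored text is compared to the query
  text by *prefix* over `min(|stored|, x)` symbols. Exact-equality or
  context-only credit are plausible alternatives; the prefix rule is the
  middle ground and is flagged for sensitivity analysis.
* **Fallback scope**: the fallback is evaluated per terminal — a terminal
  holding the exact (pretext, postext) pair is never given fallback
  credit for that window, while other terminals holding only the pretext
  still are.
* **Query-side ambiguity codes** are skipped, mirroring the reference
  side.
* **Completeness score** for choosing the one reference specimen per
  species is the count of unambiguous A/C/G/T symbols of the primary
  marker, ties broken by lexicographically smallest specimen id.
* **Combined mini-barcode queries** are the per-marker fragments joined
  with the same 15-N spacer used for full-length references.
* **Arcsine transform** is the averaged-endpoint form
  `(asin(sqrt(k/(n+1))) + asin(sqrt((k+1)/(n+1))))/2`, degrees by
  default, with variance `820.7/(n + 0.5)` feeding the Tukey-type
  studentized-range comparison (`qtukey` at `df = Inf`); radians are
  available.
* **Independence unit**: confidence intervals use species-tests, not
  query sequences, as trials — each species is one Bernoulli trial under
  the severity rule (success only if *all* its queries are correct and
  unambiguous; ambiguous and unidentified both count as incorrect).

One stated property of exact-match scoring deserves a caveat: adding a
sequence to a terminal's exposé can never lower its exact-match score,
but it *can* lower its fallback score, because a newly stored
(pretext, postext) pair with a conflicting text blocks the fallback for
that window. The monotonicity tests therefore exercise the exact-match
route; the fallback's non-monotonicity is inherent to the rule, not a
bug. Similarly, a perfect self-match scores `L - 2n - x + 1` windows per
matching strand — proportional to, but not equal to, the query length.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; `U` is normalized to `T`,
  case is folded, terminal `N` runs are stripped (idempotently) on every
  input path.
* Sequences shorter than `2n + x` yield zero query windows and an
  `unidentified` result, not an error.
* A p-distance over zero comparable sites is reported as 0 with an
  `incomparable` flag rather than an error, because a short fragment may
  legitimately fail to overlap a reference.
* Zero-distance (or any equal-distance) ties in the baseline are
  ambiguous: the barcode-gap criterion in its presence/absence form.
* Database persistence is a single canonically-ordered JSON file with a
  format/version header; loading a saved database reproduces
  identifications exactly (property-tested).

## What the simulator emulates — and what it does not

`generate_dataset()` grows a hierarchy root → genus → species →
specimen with independent per-site substitutions (uniform over the three
alternative bases), at most one geometric-length indel per species branch
and marker, and optional species pairs whose specimens are copied
verbatim to model shared haplotypes. Defaults — 5 genera × 3 species ×
2 specimens, 1300 bp + 620 bp markers, divergence 0.05/0.02/0.002 per
site at the genus/species/within level, indel probability 0.1 with mean
length 3 — are chosen to resemble a small two-marker plastid study: a
matK-sized variable marker plus an rbcL-sized conserved one, congeneric
species ~4% apart pairwise, conspecific haplotypes ~0.4% apart.

The simulator deliberately omits rate heterogeneity across sites, codon
structure, coalescent sampling, sequencing error and pseudogenes. Passing
tests on simulated data therefore demonstrate the *mechanics* — exact
self-recovery when species are distinct, honest ambiguity when haplotypes
are shared, graceful degradation on 100–200 bp fragments — not the
success rates to expect on real herbarium data, where misidentified
vouchers, patchy sampling and taxonomically meaningless variation
dominate the error budget. The acceptance script's simulated study sizes
(15 species, ~1.9 kb combined sequences, 30 full-length and 30
mini-barcode queries; property tests on ≤60 bp instances and ≤7 bp
alignment pairs) were chosen so the full suite exercises every code path
at tens-of-seconds scale while remaining large enough that scores are in
the thousands and sampling noise cannot mask a defect.

## Known limitations

* The nearest-postext fallback is the least constrained part of the
  procedure; its three open readings above can shift mini-barcode scores
  by a few percent and deserve a sensitivity study on real data.
* Scoring is presence-based; no significance or e-value accompanies a
  score, so a low-score unique winner and a high-score unique winner are
  both reported "unambiguous". The score and window count are returned so
  users can impose their own floor.
* The pairwise baseline's global alignment of a 100–200 bp fragment
  against a full-length reference places heavy terminal gaps; with indels
  treated as missing data this reduces to the aligned overlap, but a
  misplaced fragment alignment can inflate distances. Local mode is
  provided for exactly this case.
* Only the unit-increment scoring function ships; differential weighting
  of text versus context is a documented extension point
  (`score_query(..., fallback = )` isolates the one knob that exists).
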