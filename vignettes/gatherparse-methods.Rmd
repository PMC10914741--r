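---
title: "Parsing duplicated occurrence records into collection events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing duplicated occurrence records into collection events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatherparse)
```

## The problem

Herbarium specimens are collected in duplicate: one field gathering (one
collector, one collection number, one place and date) is distributed to
several institutions, each of which digitises its sheet independently. When
an aggregator such as GBIF merges those databases, a single gathering can
surface as dozens of records carrying conflicting determinations,
transcription variants of the collector's name, and divergent or corrupted
coordinates. Counting those records as independent occurrences inflates
record numbers and distorts richness estimates, especially at fine spatial
scales.

`gatherparse` reduces an occurrence download to unique collection events
("gatherings"). The workflow has five stages, each usable on its own:

1. **Ingest** — read the tab-delimited GBIF dialect, canonicalize missing
   values, project onto a field profile.
2. **Name reconciliation** — standardize scientific-name strings and match
   them against a WCVP-style names backbone, resolving synonyms to accepted
   names.
3. **Collector dictionary** — extract and standardize the primary
   collector's surname from free-text `recordedBy` strings, optionally
   overridden by a curated dictionary keyed on the raw string.
4. **Event key and voucher selection** — group records under
   `FAMILY_SURNAME_NUMBER`, score every group member, keep the best record
   as the *digital voucher*, agree a consensus taxon, and fill the
   voucher's empty fields from its duplicates.
5. **Partition and summarise** — label every record `useable`, `unusable`
   or `duplicate`; optionally compare taxon richness on a degree grid
   before and after parsing.

## The collection-event key

The key is the concatenation `FAMILY_SURNAME_NUMBER`, e.g.
`MYRTACEAE_GARDNER_417`. Collection date would discriminate better but is
too often missing from aggregated data to be useful; the family name
protects against common surnames combined with low collection numbers.
All three parts are diacritic-folded and uppercased. A key missing any part
is *incomplete*: such records are never grouped — each receives its own
record id as a singleton key, so an unnumbered specimen ("s.n.") can never
merge with another unnumbered specimen by accident. A record whose
collector surname cannot be recovered at all is additionally tagged
`UNKNOWN-COLLECTOR` via the `gp_unknown_collector` column.

Surname extraction is a heuristic over the dialects found in real
`recordedBy` strings: the first collector is isolated (splitting on `;`,
`|`, `&`, `" and "` and numbered-list prefixes; team suffixes such as
"et al." are stripped first), then the text before the first comma is
taken when a comma exists, otherwise the last word that is not an initial.
Particles therefore survive only in the comma dialect ("de Melo, P." gives
`DE MELO`, but "P. de Melo" gives `MELO`); this asymmetry is documented
rather than guessed away, and the curated dictionary is the mechanism for
fixing it where it matters. Dictionary lookup is deliberately exact on the
raw string — never fuzzy — so different team spellings remain separately
curatable.

## Scoring and voucher selection

Each record gets two scores:

* **Spatial score** ∈ {0, −1, −3, −9}: the worst score over the record's
  GBIF geospatial issue tokens, per a 33-category table (impact classes
  none/low/medium/exclude map to 0/−1/−3/−9). −9 means unusable for
  spatial analysis. A record with no interpretable coordinate pair is
  treated as −9 regardless of issues, since coordinates are a precondition
  for spatial use. The table ships as a config CSV and can be replaced;
  `COUNTRY_INVALID` is deliberately not in it — it feeds the completeness
  score instead.
* **Completeness score** ∈ [0, 10]: one point each for a non-empty
  collector, collection number, year, institution code, catalogue number,
  locality, municipality, state/province and field notes, plus one point
  when the `COUNTRY_INVALID` issue is absent.

The digital voucher of a group is the member with the highest total
(spatial + completeness). Ties break by higher completeness, then by
smallest record id; this makes selection a pure function of the group,
invariant under row order, which the tests verify against a brute-force
scan.

The **consensus taxon** counts the accepted names (post-synonym
resolution, so two synonyms of one species vote together) applied to group
members at or below species rank; the most frequent wins, exact ties
resolve alphabetically so the choice is automatic, and a group with no
species-level determination is `UNIDENTIFIED`. Counting resolved rather
than verbatim names is a deliberate choice: the backbone is applied before
parsing, and the alternative (verbatim counting) would let spelling
variants of one name split the vote.

**Merging** fills fields that are *empty in the voucher* from the
duplicate with the highest total score that has the field populated (ties
again by record id). Non-empty voucher cells are never overwritten, so the
merge is monotone and idempotent — re-running the workflow on its own
voucher output is a no-op, which is tested. The mergeable set is limited
to fields describing the gathering itself (habitat, field notes, locality,
municipality, state/province, country code, date parts, elevation);
coordinates move only as an atomic latitude+longitude pair together with
the donor's issue string, so a merged voucher can never carry a latitude
from one sheet and a longitude from another.

## Partitions

Every record ends in exactly one partition: a voucher with a resolved
consensus taxon and a spatial score above −9 is `useable`; a voucher
failing either condition is `unusable`; every other group member is a
`duplicate`. Incomplete-key singletons can still be useable — they are
simply gatherings without recovered duplicates. The three partition sizes
always sum to the input row count, and each event key contributes exactly
one non-duplicate record.

## Richness grids

`grid_richness()` counts distinct taxa per grid cell, assigning each
record to the cell `(floor(lon/c)*c, floor(lat/c)*c)` with `c = 1` degree
by default — half-open cells with the west/south edge inclusive, which is
unambiguous at negative coordinates. `richness_percent_diff()` reports
`100 * (a − b) / a` per cell relative to the first (pre-parse) grid, with
cells absent from one grid counted as zero and cells empty in the
reference reported `NA`. Deduplication can only remove taxa from a cell,
never add them; the tests assert this monotonicity.

## The synthetic-data generator

`generate_occurrences()` emulates the duplicate structure of aggregated
herbarium data: a configurable number of gatherings, each copied to 1–32
institutions, with per-copy corruption probabilities for the error modes
observed in real aggregators — swapped or zeroed coordinates (injected
together with their matching GBIF issue token), centroid-coarsened
coordinates, conflicting or synonymous determinations, lost collection
numbers or collectors, and per-field blanking. Collector names are
rendered in several `recordedBy` dialects ("Surname, I.", "I. Surname",
team lists, "et al.") so the surname parser is exercised end-to-end. All
randomness flows from a single scenario seed and the previous RNG state is
restored, so generation is reproducible and side-effect free.

What the generator does **not** emulate: the spatial clumping, gappy
digitisation and institution-correlated error profiles of real data, or
the long tail of `recordedBy` free-text pathologies. Passing the
parameter-recovery tests therefore demonstrates the workflow's logic is
correct under known structure, not that real-data error rates are
recovered.

Default study conditions used in the tests and the acceptance script: the
clean recovery scenario uses 200 gatherings with 3 duplicates each and
zero corruption; the noisy scenario uses 400 gatherings, 1–6 duplicates,
and moderate corruption rates (10% conflicting identifications, 15%
synonym substitutions, 3–5% coordinate corruptions, 25% per-field
blanking) — rates a curator of aggregated tropical-plant data would
recognise as realistic. These sizes keep the whole suite inside a couple
of minutes while leaving every code path exercised.

## Numerical and degenerate-input choices

* Missing values (`""`, `NA`, `\N`, `NULL`) canonicalize to `""`; all
  occurrence fields are handled as text, and coordinates are parsed
  numerically only where needed (spatial gating, gridding).
* Empty tables flow through every stage and summarise to zeros.
* Unknown issue tokens are retained in summaries and score 0, so the
  workflow degrades gracefully when GBIF adds vocabulary.
* Synonym resolution is a single hop: a synonym pointing at another
  synonym (or a dangling id) is reported `ambiguous`, never chased, so no
  cycle can hang the batch path.
* Name matching ignores authorship; among homonyms the single Accepted row
  wins, anything else is `ambiguous` — conservative flagging beats silent
  misassignment. An infraspecific string that misses in full falls back to
  its binomial, with the fallback recorded per record.

## Known limitations

* Duplicates of one gathering identified in *different families* produce
  different keys and cannot merge; the family field is taken from the
  GBIF backbone interpretation to minimise (but not eliminate) this.
* The standardized surname does not identify a unique person; homonymous
  collectors with coinciding collection numbers within a family would
  merge. The curated dictionary mitigates, not solves, this.
* No coordinate validation of its own is performed beyond reading GBIF's
  issue flags; records with plausible-looking but wrong coordinates pass
  through and should be screened with a dedicated coordinate-cleaning
  tool downstream.
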