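---
title: "Designing clade-specific diagnostic DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing clade-specific diagnostic DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladebar)
```

## The problem and the model

Distance-based DNA barcoding assumes a barcoding gap: intraspecific
variation smaller than interspecific divergence. In evolutionarily complex
genera — recent radiations, hybridisation, chloroplast capture, incomplete
lineage sorting — that gap is absent and the pharmacopoeial species itself
may be polyphyletic on the plastid tree. `cladebar` implements the
character-based alternative: identification targets are *Operational
Phylogenetic Units* (OPUs), clades chosen on a whole-plastome phylogeny,
and the barcode is a small matrix of nucleotide states at positions
carrying *diagnostic characters*.

A state $s$ at column $j$ is diagnostic for OPU $G$ when

1. every non-missing member of $G$ carries $s$ at $j$ (fixed within), and
2. no non-missing member of any other OPU carries $s$ at $j$ (absent
   without).

This is the classical "simple pure" diagnostic character. Columns that are
not diagnostic for any single OPU but are fixed for different states in at
least two OPUs still separate those OPUs, so they contribute to
*profile-based* discrimination: an OPU is identifiable when its vector of
states over the selected positions (its profile) differs from every other
OPU's profile. The two notions are reported separately — an OPU can have a
unique profile without possessing any single diagnostic SNP, and
conversely.

## Pipeline and tunable parameters

Candidate regions are found by scanning the alignment:

* `classify_columns()` — a column is **variable** when at least two of
  `A,C,G,T` occur; **parsimony-informative** (PIS) when at least two
  states occur in at least two samples each. `N` and `-` are missing data
  by default (`gap_as_state` promotes the gap to a fifth state; masked
  alignments code uncertainty as `N`, and counting gaps as characters
  inflates variability across indel-rich spacers).
* `scan_windows(window_size = 500)` — non-overlapping tiles ("bins") from
  column 0; the trailing partial window uses its true length as the
  variability denominator. Units are alignment columns (bp).
* `select_candidates(min_variability = 0.05, max_masked = 0.03)` — both
  thresholds are strict inequalities (variability strictly above 5%,
  masked data strictly below 3%); a 500-bp window with exactly 25 SNPs is
  rejected. The masked fraction is computed over *cells*
  (samples × columns), since masking is applied per region across samples;
  a column-based variant would hide a block masked in half the samples.
* `merge_candidates()` — maximal runs of abutting selected windows become
  one region (two bins → 1000 bp, four bins → 2000 bp).
* `refine_region(subwindow = 50, min_sub_variability = 0.02)` — the region
  is re-tiled at 50 bp and the longest run of sub-windows at or above 2%
  variability is kept. Published workflows show the *outcome* of such
  refinement (a 2000-bp candidate cut down to a 790-bp core), not the
  rule; the end-trimming rule here is this package's own design, chosen
  because it is deterministic, monotone in the threshold, and reproduces
  the trim-the-flanks behaviour. When nothing reaches the threshold the
  single best sub-window is returned with a warning rather than an empty
  region.

Diagnosis and classification:

* `find_diagnostic_positions(max_missing_in_group = 0.5)` — an OPU's state
  at a column is its shared base when all non-missing members agree, with
  at least one observed member and at most 50% missing inside the group.
  The tolerance is exposed because real plastome alignments carry masked
  blocks; 0.5 keeps a clade with patchy coverage callable while an
  all-missing group is always `N` and never diagnostic.
* `minimal_diagnostic_set(exhaustive_limit = 20)` — uniqueness of a
  profile is monotone in the position set, so the full matrix attains the
  maximum number of identifiable OPUs; the search finds a smallest subset
  attaining it. Up to 20 candidates the search is exact (subsets
  enumerated by increasing cardinality; ties broken lexicographically by
  column index for reproducibility); beyond that a greedy cover of
  separable OPU pairs is used and then pruned. Tests compare both routes
  against a brute-force subset oracle.
* `redundant_diagnostic_set(r = 2)` — augments the minimal set with up to
  `r` individually diagnostic positions per OPU. A minimal set is fragile:
  one failed Sanger read at one position can void a call. With `r = 2` the
  packaged nine-position reference matrix is reproduced exactly from its
  own seven-position minimum, which is why the published matrix carries
  paired diagnostic positions for the key clade.
* `classify_query(max_mismatch = 0)` — pass/fail semantics: one
  conflicting resolved position excludes an OPU, matching how a
  pharmacopoeial standard is applied. `N` in the query never excludes
  (missing data must only widen the compatible set — a property test);
  an OPU cell of `N` or `polymorphic` carries no exclusionary information
  and matches anything. `max_mismatch` exists for degraded material but
  defaults to 0. Calls: `unique`, `ambiguous`, `no_match`, and
  `unidentifiable` when every query state is missing.

Haplotype collapsing (`collapse_haplotypes()`) uses exact sequence
identity; `N` matches only `N`. Ambiguity-tolerant matching is available
(`collapse_missing = TRUE`) but is greedy and order-dependent, and is
documented as such — exactness was preferred as the default because it is
reproducible and conservative for the question "does this species have a
haplotype of its own?". Distances between haplotypes skip columns where
either sequence is missing.

## What the simulator emulates — and what it does not

`simulate_alignment()` builds alignments on a *constant* random background
with planted structure: clade-diagnostic columns (fixed inside one OPU,
fixed for a different base outside), variable-but-not-informative columns
(one minor-state carrier), PIS columns (two carriers), and masked `N`
blocks. The background is constant rather than drawn from a substitution
model because published barcode tables state exact counts of variable and
PIS sites; the generator must hit those counts exactly, not in
expectation. Carriers of minor states are drawn from OPUs with at least
two members, each keeping a major-state member, so unplanted columns are
never diagnostic and never separate two OPUs — this is what makes
perfect-recovery tests meaningful. Masked blocks must avoid variable
columns so the truth record stays exact.

Consequences for interpretation: simulated alignments have no homoplasy,
no recombination, no indel structure, no rate heterogeneity, and their
missing data is block-shaped rather than read-depth-shaped. Passing the
recovery tests therefore shows the *search is correct*, not that real
plastome alignments will yield clean diagnostics; on real data, within-OPU
polymorphism and masking are exactly what the `polymorphic`/`N` state
calls and the missing tolerance are for. Quantities that depend on the
original 85-plastome alignment (the 0–124 SNPs-per-bin range, 21 → 13
candidate bins, the particular nine published positions) cannot be
recomputed without it and are not asserted anywhere; the package instead
checks the properties those numbers exemplify.

## Numerical choices and degenerate inputs

* Percentages are `100·count/length` rounded **half-up** to two decimals
  (`percent()`); R's default banker's rounding disagrees with every
  published half-case, e.g. 0.125% → 0.13.
* Coordinates are 0-based half-open internally (and in BED output);
  all human-facing reports (column summaries, `region:position` labels)
  are 1-based inclusive.
* IUPAC ambiguity codes other than `N` are demoted to `N` with a warning
  rather than rejected — upstream consensus callers emit them, and
  treating them as missing is the conservative reading.
* Ragged FASTA, duplicate ids and empty files are hard errors; a window
  size larger than the alignment yields a single window; a region with no
  variation refines to its best sub-window with a warning; a matrix whose
  profiles are all identical yields an empty minimal set with every OPU
  reported unresolvable.
* All randomness is seeded; the simulator restores the caller's RNG
  state.

## Problem sizes used in the test suite

The suite runs simulated alignments at the published barcode lengths
(501–1530 columns, 85 samples) for the statistics checks, and smaller
random alignments (4–12 samples, 10–400 columns) for property tests: 200
replicates of window-count conservation, 20 seeds of planted-diagnostic
recovery, and exhaustive-oracle comparisons on matrices with up to 12
positions. These sizes give sub-minute runs while exercising every code
path; the operations themselves are vectorised column scans and scale
linearly in samples × columns (a 160 kbp × 85 plastome alignment is a
~14M-cell matrix, well within a desktop session).

## Known limitations

* OPUs must be supplied; the package does not derive clades from a tree.
* No primer design, annotation snapping, alignment construction or
  phylogeny inference — inputs are an alignment and a grouping.
* The diagnostic definition is single-column; combinations of states that
  are jointly but not individually diagnostic are captured only through
  profile uniqueness, not through logic mining.
* `collapse_missing` haplotype merging is order-dependent by design.
* Classification of mixtures (pooled shotgun material) is out of scope;
  queries are single consensus sequences or state profiles.
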