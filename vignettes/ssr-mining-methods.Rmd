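---
title: "Mining genic microsatellites and developing markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genic microsatellites and developing markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrminer)
```

This vignette records how the package defines each computation, which
parameters matter, and where the design was genuinely open — the kind of
detail a maintainer needs and a function reference cannot hold.

## Assembly statistics

`assembly_stats()` reports sequence count, total and mean length, N50, GC
fraction and a length histogram.

* **N50** is the smallest member of the largest-length prefix whose
  cumulative sum reaches half of the total assembled bases; equivalently
  the largest length $L$ such that sequences of length $\ge L$ hold at
  least half the bases.  The half-total threshold is compared as
  `2 * cumsum >= total` so an odd total is never truncated by integer
  division, and the reported N50 is always the length of some sequence in
  the set.
* **GC fraction** excludes `N` residues from the denominator: ambiguous
  bases carry no composition information, and including them would bias
  GC downward on low-quality assemblies.
* **Length bins** default to the conventional transcriptome reporting bins
  201–500, 501–1000, 1001–1500, 1501–2000, >2000 bp.  Assemblers commonly
  impose a 201 bp floor, but arbitrary input need not: anything at or
  below 200 bp is counted in an extra leading bin rather than silently
  dropped, so the histogram is always a partition of the input.

## The repeat scanner

`find_perfect_ssrs()` reports every *maximal perfect* tandem repeat of a
*primitive* unit of 1–6 bp whose repeat count reaches the unit-length
threshold.  The default thresholds — 11, 6, 5, 5, 4, 4 repeats for unit
lengths 1–6 — are the standard marker-development settings for genic SSR
surveys in legume transcriptomes; they are exposed in
`threshold_config()` because colder or hotter settings are legitimate for
other purposes (the test suite itself uses permissive thresholds to make
repeats dense in random sequence).

Precise semantics, pinned so that an independent implementation can
reproduce the output byte for byte:

* Only primitive units are reported: a run of twelve A's is one
  mononucleotide locus, never an `"AA"` dinucleotide locus.  `ATAT` is
  `(AT)^2` and is never a unit.
* `N` breaks perfection; no locus spans an `N`.
* Within one unit length the scan is leftmost-greedy: walk the sequence,
  extend the candidate unit at the current position as far as it repeats
  in full units, accept it if it passes the threshold and jump past it,
  otherwise advance one position.  A run reportable in several frames
  (`AGAGAG…` as `AG` from the first base or `GA` from the second) is
  therefore reported once, in its leftmost frame.
* Across unit lengths, overlaps are resolved greedily by (unit length,
  start): the smallest-unit interpretation wins and accepted intervals
  never overlap, which keeps summary tables free of double counting.
  Loci of different classes may abut.
* Loci touching a sequence end (zero flank) are still loci.  Whether a
  repeat exists is biology; whether it can become a marker is policy, and
  the flank filter is applied later by `design_markers()`.

The implementation locates candidate runs with a backreference regular
expression and falls back to a one-position restart when a matched unit is
non-primitive; the test suite holds it equal to an explicit per-position
brute-force oracle on thousands of seeded random sequences, and the same
per-position semantics above are what that oracle implements.

Coordinates are 1-based inclusive everywhere — internal tables, TSV and
GFF3 — the R/Bioconductor (IRanges) convention.  A single convention end
to end removes the most common class of off-by-one defects; GFF3 output is
produced by `rtracklayer` from a `GRanges` and needs no conversion.

## Motif classes

`canonical_motif()` maps a unit to the lexicographically smallest string
among all cyclic rotations of the unit and of its reverse complement, and
labels the class `canonical/revcomp(canonical)` — `AAG`, `AGA`, `GAA`,
`CTT`, `TTC`, `TCT` all become `AAG/CTT`.  Published tables sometimes
display the second half of the label as a *rotation* of the reverse
complement (e.g. `ACTC/AGTG` where this package prints `ACTC/GAGT`); class
*membership* is identical, only the display of the right-hand half
differs, and a deterministic rule was preferred over matching any one
journal's typography.

## Compound SSRs

`merge_compound()` chains consecutive loci on one sequence whose gap is at
most `max_compound_gap` bases.  The default of 100 bp is the de facto
community setting for compound SSR calling; published surveys frequently
omit the distance they used, which is exactly why the parameter is
exposed, and why `compound_gap_sweep()` recomputes the tallies across a
gap range.  Groups mixing motif classes are flagged `mixed` — the
classical "compound SSR of different motifs" — while same-class groups
are flagged `same_motif` and are *not* counted as compound in the
headline tally, though each group counts as a single independent unit
when counting sequences with two or more independent SSRs.

## Marker design

`design_marker()` enumerates every primer pair — all placements and all
lengths from `min_len` to `max_len` in both flanks — and keeps pairs whose
members sit in the 50–60 °C melting window, differ by at most 4 °C, and
bracket the whole repeat with a 100–300 bp product.  Two quality rules
beyond the published constraint set are applied, because without them
degenerate inputs (e.g. poly-A flanks) yield absurd "valid" primers: no
single-base run of five or more within a primer, and the 3'-terminal base,
when G or C, may not close a run of three or more of itself.  Both are
switchable in `primer_spec()`.

Melting temperatures use deterministic closed forms — the Wallace rule
$2(A{+}T) + 4(G{+}C)$ below 14 bases and $64.9 + 41(GC - 16.4)/L$
otherwise — rather than nearest-neighbour thermodynamics.  Closed forms
are exactly reproducible and sufficient for constraint screening; dimer
and hairpin screening is explicitly out of scope.

Among passing pairs the winner has mean Tm closest to the midpoint of the
Tm window, with ties broken by total deviation from the optimal length,
then leftmost forward start, leftmost reverse end, shorter forward, then
shorter reverse primer.  Any total order would do; this one prefers
thermodynamically centred, optimally sized, left-anchored pairs and makes
the function a pure function of its inputs, which the suite checks by
comparing against an independent exhaustive enumeration.

The flanking-length rule is read inclusively (`flank >= 150 bp`) by
default.  Published wordings are often self-contradictory ("greater than
150" beside "appropriate length (>100 bp)"); the inclusive reading is the
safer marker-design default, and `strict_flank = TRUE` preserves the
strict one.  Mononucleotide loci are designable by default but
`design_markers(unit_lens = 2:6)` masks them out, since many groups
exclude homopolymers from marker panels; the package exposes the mask
rather than hard-coding either practice.

## Panel statistics

For each marker, with allele frequencies $p_i$ estimated from the $2n$
allele observations of the scored (non-missing) calls:

* **Na** — number of distinct allele labels observed;
* **Ho** — fraction of scored calls whose two alleles differ; missing
  calls are excluded listwise per marker, matching per-marker scoring of
  gel data;
* **PIC** — Botstein's bounded definition
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, computed through the
  power-sum identity $\sum_{i<j} 2p_i^2p_j^2 = (\sum_i p_i^2)^2 - \sum_i
  p_i^4$.  PIC is 0 exactly when the marker is monomorphic, is always
  below 1, and never exceeds the expected heterozygosity
  $1-\sum_i p_i^2$.

Some published SSR validation tables print PIC values above 1, which is
impossible under any bounded definition and signals a nonstandard formula
or multi-band scoring upstream.  This package implements only the bounded
definition and makes no attempt to reverse-engineer such values; the test
suite validates the statistics against closed forms and simulation truth
instead of against published panel tables.

Allele labels are opaque strings (band sizes, typically); no size binning
is performed — binning policy belongs to the upstream scoring step.

## Synthetic data: what it emulates, what it does not

`generate_sequences()` draws i.i.d. background at GC 0.467 — the clean-read
GC content typical of legume transcriptomes — with lognormal lengths
(median ≈ 600 bp) truncated to 201–3000 bp, emulating a unigene length
profile, and implants repeats of known motif, count and position.  The
window of `clean_flank` (160 bp) around each implant is rejection-sampled
until it contains exactly the implanted locus, so the truth table is exact
by construction: recall can be asserted at 100%.  Chance repeats *outside*
those windows are deliberately left in place — forbidding them globally
would distort background composition — so precision is reconciled against
a brute-force scanner oracle, never against the implant list alone.

What the generator does **not** emulate: codon structure, the 5'/3' UTR
bias of real genic SSRs, assembly artefacts, sequencing error, or linkage
between markers.  Passing tests therefore demonstrate algorithmic
correctness on sequences with realistic composition and known truth — not
biological performance on any particular transcriptome.

`simulate_genotypes()` draws each call autozygous (one draw duplicated)
with probability $F$ and as two independent draws otherwise, with i.i.d.
missingness; expected observed heterozygosity is then
$(1-F)(1-\sum p_i^2)$, which the suite recovers within three Monte Carlo
standard errors at $n = 10{,}000$.  The default $F = 0.9$ reflects a
strongly self-pollinating crop.  All generators are pure functions of
(plan, seed); the R generator state is saved and restored around every
call.

## Numerical and degenerate-input choices

* Frequency vectors for PIC must sum to 1 within $10^{-8}$; allele
  frequencies produced internally sum to 1 exactly by construction.
* Empty sequence collections, all-missing markers, ragged genotype rows,
  empty allele labels, duplicate FASTA ids, and sequence data before the
  first header are errors, not warnings.
* IUPAC ambiguity codes are mapped to `N` on input with a single counting
  warning; repeat detection treats `N` as a hard break.
* Repeat-count summary bins are 4–10 and `>10` (meaning ≥ 11, where the
  mononucleotide minimum of 11 places every mono locus); counts below 4,
  possible only under non-default thresholds, get an explicit leading
  `<4` bin rather than being dropped.

## Problem sizes used in checks

The shipped validation runs at deliberately modest sizes chosen to
exercise every code path densely: scanner-versus-oracle equivalence on
about a thousand seeded random sequences of 100–2000 bp, exhaustive class
invariance over all primitive motifs up to 6 bp, implant recovery on
hundreds of implants, design-versus-enumeration equality on a hundred
fixture loci, and a 3000-sequence synthetic transcriptome in the
acceptance script.  Larger inputs change runtimes, not semantics: the
scanner is linear in total sequence length per unit length, and design
cost is quadratic only in flank length, which the product-size constraint
caps.

## Known limitations

* Only perfect repeats are detected; imperfect/approximate SSRs are out
  of scope.
* Primer screening is constraint-based; no thermodynamic dimer/hairpin
  model.
* Compound tallies depend on the interruption distance; when comparing
  against published counts whose distance is unstated, use
  `compound_gap_sweep()`.
* Contig-level statistics require a contig FASTA; unigene files alone
  cannot reproduce them.
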