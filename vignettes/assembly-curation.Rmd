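---
title: "Curating a new long-read assembly against an established reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a new long-read assembly against an established reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a *de novo* long-read assembly is produced for an individual of the same
inbred strain that underlies an established reference genome, the comparison
between the two is itself the scientific product. Differences fall into a few
classes, each with its own analysis:

* **Gap fills** — the reference contains runs of `N` where clone-based
  sequencing failed; a scaffold of the new assembly that anchors cleanly on
  both sides of such a gap supplies the missing sequence, and the length of
  that sequence rarely equals the estimated gap length.
* **Reference errors** — a variant called at the same site in a large
  fraction of independently sequenced strains, against one reference, is more
  parsimoniously a mistake in the reference than a mutation shared by every
  strain. If the new assembly carries the ALT base at the lifted position,
  the site is *resolved* in the new assembly's favor.
* **Structural variants** — SV calls supported by two independent
  technologies form a consensus set worth reporting per class.
* **Unalignable sequence** — assembly sequence that no alignment method can
  place on the reference is strongly enriched for repeats, particularly
  satellite and microsatellite arrays, which mutate by replication slippage
  at rates orders of magnitude above the SNV rate.
* **Assembly quality metrics** — N50 before/after scaffolding, contig
  statistics after splitting scaffolds at N-runs of length ≥ 10, k-mer
  completeness.

asmcurate implements every one of these computations as testable functions,
plus a synthetic-data generator that plants all of the above with
machine-readable ground truth, so that the entire pipeline can be validated
end to end without any external data.

## The micro-aligner

Production pipelines use minimap2 or BLAT for the underlying alignments; this
package carries its own minimizer seed-and-chain aligner so the pipeline is
closed at desk scale. The design:

* **Anchors** are exact k-mer matches between minimizer sketches (default
  `k = 15`, window `w = 10`); an invertible hash avoids the poly-A bias of
  lexicographic minima. k-mers containing `N` never anchor, and seeds with
  more than `max_occ = 64` target hits are treated as repetitive and skipped
  — satellite and microsatellite arrays are therefore unanchored and are
  bridged (or left uncovered) rather than seeding spurious matches.
* **Chaining** is a sparse dynamic program over anchors sorted by target
  position: the score adds non-overlapping anchor coverage and subtracts the
  gap penalty `|Δq − Δt|`; per-step gaps are bounded by `max_gap = 2000`.
  Chains are extracted greedily from the highest-scoring endpoints; a chain
  that diverges from an already-extracted chain is scored by its own
  contribution, not by the shared prefix, which suppresses near-duplicate
  parallel chains through repeat slippage diagonals.
* **Records**: each maximal constant-diagonal run of a chain becomes one
  gap-free PAF record. Interior run boundaries are extended toward each
  inter-run gap with an X-drop scan (match +1, mismatch −2, drop 20), capped
  so adjacent runs never cross. Because `N` matches nothing, these
  extensions stop *exactly* at reference gap edges — the property that makes
  fill extraction exact on noise-free data. Terminal extensions are capped
  at 500 bp: anchors always sit within about one minimizer window of the
  true alignment ends, and longer terminal extensions would only duplicate
  space that belongs to a neighboring chain.
* **Limitations**: no affine-gap base-level alignment between anchors and no
  CIGAR strings. This is adequate for low-divergence same-strain pairs and
  is checked against an exhaustive Smith–Waterman oracle on 200 bp pairs at
  5% divergence (endpoints agree within `k`).

## Chains, nets, and liftover

`build_chains()` merges co-linear gap-free records into chains scored by
total matched bases. Several chains may be open at once while sweeping the
target axis, because repeat cross-matches interleave with the true chain;
each record joins the strongest eligible open chain (then the nearest, then
the one with least diagonal drift), where eligibility bounds the inter-record
gaps (`max_join_gap`, default 100 kb), the implied indel (`max_join_drift`,
default 5 kb), and tolerated overlap (`join_slop`, default 1 kb, trimmed from
the later record and never more than half of it).

Netting assigns target space greedily to chains in descending score,
truncating lower-scoring chains to unowned space; ties break toward the
longer target span, then the lexicographically smaller query name. After
netting, every target base is owned by at most one chain — asserted by
interval sweep in the tests. `map_positions()` then lifts coordinates by
linear offset inside owned blocks (reflectively on minus-strand blocks: a
single base maps to the base it aligns to, not base+1); positions between
blocks of the owning chain report `deleted`, unowned positions `unaligned`.

Round-tripping a position through nets built in both directions is exact,
with one caveat worth stating: inside a tandem duplication either copy is a
valid image of the duplicated sequence, so the forward and backward nets can
legitimately disagree there. The test suite asserts exact round-trips
outside planted duplication neighborhoods and ≥99% agreement overall.

## Gap filling

The procedure mirrors reference-gap curation practice: maximal N-runs ≥ 10
in the reference (minus any exclusion mask for centromere/telomere gaps) are
padded with flanks on both sides, assembly scaffolds are aligned to the
padded regions, and a candidate must

a. be the **reciprocal best hit** — the scaffold is the region's best
   partner and vice versa, where a pair is scored by its best *co-linear
   chain* (summing raw records would let a large repeat-rich scaffold
   dominate every region);
b. reach a minimum total alignment length (inclusive threshold); and
c. place **uniquely** in the whole-assembly net — at least 90% of the
   scaffold's netted bases in one target locus, where a locus is a cluster
   of netted intervals separated by less than 100 kb (chain fragmentation
   at long repeat blocks must not masquerade as multi-mapping).

Production scale uses 50 kb flanks and an 80 kb alignment threshold; the
desk-scale defaults divide both by ten (5 kb / 8 kb) to match the 2 Mb
synthetic chromosomes.

Confirmation re-aligns the padded regions to the scaffolds and requires the
signed length difference observed in one direction to equal the negation of
the other within ±10 bp — the programmatic form of inspecting "the opposite
indel pattern" in a genome browser, with a per-candidate table exported for
manual review. The fill is the scaffold sequence between the inner ends of
the two flank alignments (a single record spanning the whole gap, possible
when the fill length equals the gap length exactly, is preferred over
separate flanks; when an indel splits a flank into several records, the
innermost record defines the boundary). The reported discrepancy is
`fill length − gap length`; on noise-free synthetic data every planted fill
is recovered byte-exactly, which the acceptance suite asserts at the default
scale (2 × 2 Mb, 10 gaps).

## Recurring variants and resolution

`select_recurring()` keeps sites where the fraction of samples with a
homozygous-ALT call is at least 0.75 (inclusive), excluding missing
genotypes from the denominator — the source material is silent on missing
data, so this choice is explicit and configurable. With `homozygous_only`
(the default) any site with a heterozygous call among non-missing samples is
excluded entirely.

`classify_resolved()` lifts each site through the net and compares the ALT
allele (reverse-complemented on minus-strand mappings) with the assembly
base: equal → `resolved`, different → `unresolved`, unliftable →
`unmappable` with the liftover reason. Indels are compared as spanned
haplotype strings over lifted flanking anchors; this path is experimental,
as the recurring-variant analysis is SNV-focused. Summaries report
percentages with half-up rounding to one decimal, over either all considered
sites or only the remappable ("net") subset.

Frameshift classification of CDS indels is the mod-3 rule: a placement with
any CDS gap whose length is not a multiple of 3 counts as frameshifting
(FS); otherwise, with at least one CDS gap, non-frameshifting (NFS); gaps
outside CDS are ignored.

## SV consensus and repeat analysis

`merge_callsets()` performs greedy 1-to-1 matching of two callsets in
ascending total breakpoint distance: a pair merges when SV types match and
both breakpoints are within 1,000 bp (inclusive; the convention of the
standard merging tool in this space, which does not publish its exact graph
strategy — ties break deterministically by chrom, start, caller tag). The
merged record takes mean breakpoints; unmatched calls are retained with
support 1, so the two-caller "common" set is the `support == 2` subset.
Class summaries use the lower median, so an even-sized class reports an
attained size.

`consensus_unaligned()` intersects per-base the unaligned-interval sets of
several alignment methods. `repeat_composition()` reports per-class bp and
percentages (half-up, 2 decimals) of a region against a labeled repeat
annotation, resolving overlapping annotations first-listed-class-wins after
sorting by (start, class). `class_enrichment()` is the Pearson chi-square on
the 2×2 class/non-class × genome table, no continuity correction, p from the
upper tail of χ²(1); expected cells below 5 set a reliability flag rather
than failing. No multiplicity correction is applied across classes; the
class count is disclosed alongside.

## Transcript novelty

Junctions are intron-based (donor = exon end, acceptor = next exon start,
0-based half-open). Classification precedence is `novel_locus` (no exon
overlap with any reference exon) over `novel_exon` (at least one exon with
zero reference-exon overlap; a `slack` parameter relaxes "zero" if desired)
over `splice_shift` (an unannotated junction — typically sharing one
coordinate with a reference junction; any unannotated junction without a
novel exon lands here) over `annotated`. The precedence order is a package
decision: the source analyses do not state which label wins when a
transcript has both a novel exon and a shifted splice site.

## The synthetic substrate

`make_reference()` builds uniform random chromosomes and writes repeat
blocks until each class reaches its target fraction within ±2%:

* *satellite*: tandem copies of one fixed random 120 bp monomer
  (blocks 0.5–2 kb) — one monomer genome-wide, as real satellite arrays are
  homogeneous enough to defeat unique anchoring;
* *microsatellite*: random 2–6 bp motifs (blocks 100–400 bp) — slippage
  ambiguity in miniature;
* *LINE-like*: substrings (1–4 kb) of one fixed 4 kb master, each copy
  mutated at 10% of positions — a dispersed, diverged repeat family that
  produces realistic cross-matches between loci.

Gaps (default 10 across 2 × 2 Mb chromosomes, lengths 200–1,500 bp) replace
recorded true-fill sequence with `N`, avoid repeat blocks, and keep
`2·flank + 1 kb` separation so padded regions never overlap.
`derive_assembly()` replants the fills (half of them with a ±20–150 bp
length delta inside the fill), applies drift SNVs (2×10⁻⁴/bp), small indels
(2×10⁻⁵/bp, 1–10 bp), and SVs (6 DEL, 5 DUP, 3 INV, 6 INS per genome at the
default spec; an SV overlapping a gap or another edit is rejected and
resampled, with the count logged), then splits each chromosome into
scaffolds at midpoints between gap fills so each scaffold spans exactly one
gap plus its flanks. The exact edit ledger doubles as a perfect liftover
(`truth_chainset()`), and total length conservation —
`assembly = reference − ΣN + Σfill + Σindel/SV deltas` — is asserted
exactly.

`make_strain_vcfs()` emits 2,194 recurrent sites for a 24-strain panel;
round-half-up(0.126 × 2,194) = 276 of them are planted reference errors
(they coincide with planted assembly SNVs, so the assembly carries the ALT
base at the lifted position), the rest are true shared variants (assembly
carries REF). Per-site recurrence is drawn uniformly in [0.75, 1] and
realized with a ceiling so the threshold is met after rounding; decoy sites
(below threshold, or het-contaminated) exercise the selection step. The
site counts and error fraction mirror the scale of the descendant-panel
analysis the package reproduces; sample size (24 strains) matches the
pedigree panel. The default genotype missingness is zero so that planted
recovery is exact; a `missing_rate` field exists for stress tests.

What the generator does *not* emulate: sequencing error (there are no
reads), haplotype structure, GC bias, segmental duplications beyond the
planted SV classes, and real repeat libraries. Passing tests therefore
demonstrate the correctness of the curation logic under planted truth, not
the aligner's performance on real mammalian genomes.

## Numerical conventions and determinism

* All internal coordinates are 0-based half-open; VCF positions and
  "Chr:start-end" reports are 1-based inclusive (a gap reported as
  172,624,657–172,626,416 has length end − start + 1 = 1,760 — this fixes
  the convention).
* Every reported percentage and ratio uses round-half-up (ratios to 1
  decimal, percentages to 1 decimal, composition tables to 2).
* Nxx is the smallest length L such that sequences ≥ L cover ≥ x% of the
  total; the lower median is used for SV sizes.
* k-mer completeness uses canonical k-mers (minimum of forward and
  reverse-complement 2-bit encodings, exact in doubles up to k = 26;
  default k = 21), excluding k-mers containing N on both sides.
* Each generator stage seeds the RNG from `seed + stage offset`, so
  identical configurations produce bit-identical outputs; the pipeline
  report embeds the seed and every parameter.

## Problem sizes

The default study conditions are 2 chromosomes × 2 Mb with 10 planted gaps,
2,194 recurrent sites over 24 strains, and 20 planted SVs. A full pipeline
run — simulation, whole-assembly alignment, chain/net, gap filling, variant
resolution, SV consensus and repeat analysis — completes in a few minutes on
one CPU; unit tests use a 1 × 200 kb configuration. Paper-scale inputs
(50 kb flanks, 80 kb thresholds, chromosome-scale sequences) are expressible
through the same configuration fields.

## Known limitations

* The aligner's uniqueness and reciprocal-best-hit behavior is validated on
  synthetic repeats; real centromeric satellite or segmental duplications
  are harder.
* Liftover inside tandem duplications is ambiguous by nature (see above).
* Indel resolution via lifted haplotype comparison assumes both anchors lift
  on one chain; complex loci will report `unmappable` rather than guessing.
* Chain construction consumes gap-free records; records containing internal
  indels (from other aligners) are trimmed to their shorter span rather
  than split.
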