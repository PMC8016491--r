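---
title: "Calling structural variants from genome assembly alignments"
author: "contigsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling structural variants from genome assembly alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigsv)
```

## The problem and the model

A haplotype-resolved diploid assembly consists of two contig sets, one per
parental haplotype. Aligning each set to a reference genome exposes every
difference between genome and reference, and because both alleles are present
as assembled sequence, structural variants (SVs, rearrangements larger than
roughly 50 bp) can be both *detected* and *genotyped* directly: an SV seen on
both haplotypes is homozygous, an SV seen on one is heterozygous. contigsv
implements this idea as a four-stage pipeline over coordinate-sorted SAM/BAM
contig alignments.

**Collect.** SV signatures are extracted per haplotype from two kinds of
alignment discordancy:

* *Intra-alignment*: a long `I` or `D` CIGAR operation inside a single
  alignment record is direct evidence for an insertion or deletion. The
  aligner has already placed the gap; we only threshold its length.
* *Inter-alignment*: when an SV is too large or too complex for a gapped
  alignment, the aligner splits the contig into a primary plus supplementary
  records. Sorting the segments along the contig (clips, including hard
  clips, recover full-query coordinates) and comparing consecutive segments
  reveals the variant. With `q_gap` the contig distance and `r_gap` the
  reference distance between two same-strand, same-chromosome neighbours:
  a reference gap (`r_gap` large, `q_gap` small) is a deletion; a contig gap
  (`q_gap` large, `r_gap` small) is an insertion whose sequence is read from
  the contig; both at once is a replacement, reported as one deletion plus
  one insertion; a reference *overlap* (`r_gap` strongly negative) means the
  contig passed the same reference twice — a tandem duplication over the
  overlapped interval. Segment *triples* capture the two remaining classes:
  collinear flanks with an opposite-strand middle segment filling the gap
  between them form an inversion over the middle segment's interval;
  near-adjacent collinear flanks with a middle segment mapping to a distant
  locus form an interspersed duplication — the distant interval is the copy's
  source and the flank junction its insertion point. Anything left —
  orientation switches without the inversion geometry, interchromosomal
  junctions, same-chromosome jumps beyond `max_sv_size` — is reported
  losslessly as a reciprocal pair of breakends (BND), each record describing
  one side of the novel adjacency.

**Pair.** Signatures from opposite haplotypes are compared. Two signatures
are pairing candidates when they have the same class and chromosome, lie
within `pairing_max_span_distance`, and the *normalized edit distance* of
their variant sequences — Levenshtein distance divided by the longer length —
is at most `pairing_max_edit_fraction`. For deletion-type signatures the
variant sequence is implied by the reference, so the relative length
difference substitutes for the edit distance; breakends compare adjacency
endpoints and orientations instead. Matching is greedy by ascending distance
with fully specified tie-breaking (ascending position, then haplotype-1 input
order), so output is reproducible; signatures per locus are few, and the test
suite confirms against exhaustive enumeration that the greedy matching
reaches maximum cardinality on small instances.

**Genotype.** Each matched pair becomes one homozygous (`1/1`) candidate;
each unmatched signature becomes a heterozygous (`0/1`) candidate. For
haploid assemblies there is no second haplotype to compare against, so the
pair and genotype stages are skipped and signatures are written out directly
with a half-missing genotype (`./1` by default).

**Output.** Candidates are written as VCF 4.2. Insertions and deletions are
sequence-resolved (padding base conventions as in the VCF specification),
with deletions above `symbolic_del_threshold` falling back to symbolic
`<DEL>`; inversions and duplications are symbolic (`<INV>`, `<DUP:TANDEM>`,
`<DUP:INT>` with the source interval in `INFO/DUPSRC`); each breakend
adjacency produces two records with bracketed mate ALT strings and mutual
`MATEID` references. All internal coordinates are 0-based half-open;
conversion to 1-based happens only here.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `min_sv_size` | bp | 40 | smallest gap/discordancy reported |
| `max_sv_size` | bp | 100 000 | largest same-chromosome jump called as DEL/DUP; beyond it, breakends |
| `query_gap_tolerance` | bp | 50 | contig slack (gap or overlap) ignored when classifying reference gaps |
| `reference_gap_tolerance` | bp | 50 | reference slack ignored when classifying contig gaps and testing collinearity |
| `pairing_max_span_distance` | bp | 1 000 | maximum position difference for cross-haplotype pairing and within-haplotype deduplication |
| `pairing_max_edit_fraction` | — | 0.3 | maximum normalized edit distance for merging |

The size thresholds follow the conventions of assembly-based SV callers'
command lines; the pairing defaults are deliberately permissive because the
two alleles of a real genome legitimately differ by small indels and
substitutions inside the variant sequence. At 0.5% allele divergence the
normalized edit distance of a shared insertion is around 0.005 — far below
the 0.3 threshold — so homozygous calls are robust to realistic
heterozygosity. All six values are exposed as flags of the `exec/contigsv`
command-line tool and as arguments of `sv_params()`.

Two genuinely open representation choices are made explicit and
flag-controlled: haploid-mode genotypes are written `./1` (presence without
zygosity; `--haploid-gt 1/1` for tools that reject half-missing genotypes),
and merged homozygous candidates take their coordinates and sequence from the
haplotype-1 signature (the two alleles may legitimately differ; a
deterministic representative keeps output reproducible).

## Numerical and geometric conventions

* Consecutive split segments may *overlap* slightly on the contig (aligner
  artifacts). Overlaps up to `query_gap_tolerance` are trimmed symmetrically
  around the midpoint before classification; larger overlaps void the pair.
* The insertion anchor is the reference base immediately left of the
  interruption, on the *reference-left* flank. This makes the reported locus
  invariant under reverse-complementing the contig, a property the test suite
  checks explicitly.
* Segment pairs explained by a surrounding triple are excluded from pair
  classification entirely. The middle segment of an interspersed duplication
  whose source lies on the same chromosome would otherwise be re-interpreted
  as a large deletion by the pair rules; suppressing only the
  breakend-producing branches would not prevent that.
* Each adjacency is collected as two mate signatures (one per breakend, so
  either side can be deduplicated and paired locally) but genotyped once: the
  lexicographically first breakend is flagged canonical and carries the
  candidate; the VCF writer re-creates both reciprocal records.
* Replacement junctions (reference gap and contig gap at once) produce one
  deletion plus one insertion; the six output classes contain no compound
  type.
* Deletions starting at position 0 of a chromosome have no left padding base
  and fall back to the symbolic representation.

## What the synthetic module emulates — and what it does not

`generate_reference()` draws a uniform-composition random genome;
`implant_svs()` plants non-overlapping events of all six classes, separated
by a configurable guard distance (default 500 bp), homozygously or on one
haplotype; `emit_alignments()` then constructs the *ideal* SAM records
analytically — gapped CIGARs for indels, split (soft/hard-clipped) records
with the correct strands and placements for inversions, duplications and
fusion-contig translocation junctions — without running an aligner. An
optional per-haplotype substitution rate adds allele divergence to stress the
pairing threshold.

This emulates exactly the discordancy geometries the collector must decode,
with known truth, and `evaluate_calls()` scores calls by a simple
position-plus-length window matcher (defaults: 10 bp, 30%) with genotype
concordance among true positives. What it deliberately does **not** model:
sequencing or assembly errors beyond point substitutions, repeat-mediated or
nested SVs, aligner breakpoint jitter, clustered events closer than the guard
distance, and reference bias. Perfect scores on these fixtures therefore
demonstrate that the coordinate arithmetic, classification geometry, pairing
and serialization are correct — not that real-assembly performance equals
1.0. The evaluator is also a simplified matcher (no sequence-similarity
scoring as in dedicated benchmarking tools), sufficient for noise-free
fixtures.

The integration tests and the acceptance script use a 2 × 250 kb genome with
80 events (30 deletions, 30 insertions, 6 inversions, 6 tandem and 4
interspersed duplications, 4 interchromosomal adjacencies; 50–5 000 bp,
about half homozygous). That size keeps a full diploid run around a few
seconds while leaving room for every class at realistic SV lengths; the
edit-distance oracle cross-check runs 1 000 random string pairs up to length
200 against a quadratic dynamic-programming implementation kept independent
of the production code path (which delegates to base R's `adist`).

## Known limitations

* Nested and complex rearrangements are not resolved; their split-alignment
  footprints surface as combinations of the six primitive classes or as
  breakend pairs.
* Balanced translocations are reported as independent adjacencies, not
  reconstructed as events.
* No phasing output (PS tags) and no multi-sample merging.
* Signatures are taken from alignments as given: no mapping-quality modelling
  beyond the `min_mapq` filter, no re-alignment, and no use of alignment
  mismatch density.
* CRAM and PAF inputs are not supported.
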