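# contigsv

Structural variant (SV) detection and genotyping from genome assembly
alignments, in R.

## What it does and for whom

Long-read assemblers now routinely produce haplotype-resolved diploid
assemblies: two contig sets, one per parental haplotype. Aligning those
contigs to a reference genome (e.g. with minimap2) exposes every structural
difference between the assembled genome and the reference, and — because both
alleles are present as sequence — allows direct genotyping: a variant carried
by both haplotypes is homozygous, a variant carried by one is heterozygous.

contigsv is for anyone holding such contig-to-reference alignments (SAM/BAM,
coordinate-sorted) who wants genotyped calls for six SV classes:

* **INS** — insertions (sequence-resolved)
* **DEL** — deletions (sequence-resolved, symbolic above a size cap)
* **INV** — inversions
* **DUP:TANDEM** — tandem duplications
* **DUP:INT** — interspersed duplications (a distant copy inserted at a new locus)
* **BND** — translocation breakends, each record one side of a novel adjacency

## The method

Four stages:

1. **Collect** — per haplotype, SV signatures are extracted from
   *intra-alignment* discordancies (long `I`/`D` CIGAR operations within one
   record) and *inter-alignment* discordancies (discordant positions and
   orientations between the split alignment segments of one contig, ordered
   along the contig via their clip lengths). For consecutive segments with
   contig gap `q_gap` and reference gap `r_gap`: a reference gap is a DEL, a
   contig gap an INS, a reference overlap a DUP:TANDEM; an opposite-strand
   middle segment between collinear flanks is an INV, a distant middle
   segment between adjacent flanks a DUP:INT; anything else becomes a
   reciprocal BND pair.
2. **Pair** (diploid only) — signatures from opposite haplotypes are merged
   when the normalized Levenshtein distance of their variant sequences,
   `d = lev(h1, h2) / max(|h1|, |h2|)`, is at most 0.3 and they lie within
   1 kb (length-ratio fallback where no sequence exists; endpoint matching
   for BND).
3. **Genotype** — paired signatures become homozygous candidates (`1/1`),
   unpaired ones heterozygous (`0/1`). Haploid input skips stages 2–3 and
   writes `./1`.
4. **Output** — sorted VCF 4.2 with reciprocal `MATEID`-linked breakend
   records.

A synthetic-genome module (`generate_reference`, `implant_svs`,
`emit_alignments`, `evaluate_calls`) builds benchmark fixtures with known
truth — ideal gapped/split SAM records constructed analytically, no aligner
needed — and scores calls by precision, recall, F1 and genotype concordance.

## Worked example

```r
library(contigsv)

# a synthetic 2 x 100 kb genome with 16 implanted SVs of all six classes
ref  <- generate_reference(n_chroms = 2, chrom_length = 100000, seed = 7)
spec <- rbind(sv_spec("DEL", 5, 100, 2000), sv_spec("INS", 5, 100, 2000),
              sv_spec("INV", 2, 300, 2000), sv_spec("DUP_TANDEM", 2, 300, 2000),
              sv_spec("DUP_INT", 1, 300, 1000), sv_spec("BND", 1))
fx <- implant_svs(ref, spec, seed = 7)
Biostrings::writeXStringSet(ref, "reference.fa")
write_sam(emit_alignments(fx$hap1, fx$truth, ref, haplotype = 1), "hap1.sam")
write_sam(emit_alignments(fx$hap2, fx$truth, ref, haplotype = 2), "hap2.sam")

calls <- run_diploid("hap1.sam", "hap2.sam", "reference.fa", "calls.vcf")
#> read 8 + 7 alignment segments
#> haplotype 1 signatures: DEL=5 DUP_INT=1 DUP_TANDEM=2 INS=4 INV=1
#> haplotype 2 signatures: BND=2 DEL=4 DUP_TANDEM=1 INS=3 INV=1
#> candidates: 16 (hom_alt=7 het=9)

head(sv_table(calls), 4)
#>      sv_type ref_name start   end sv_length haplotype genotype
#> 1 DUP_TANDEM     chr1  9072 10785      1713        NA  hom_alt
#> 2        INS     chr1 19929 19929      1805        NA      het
#> 3        DEL     chr1 29020 29710       690        NA  hom_alt
#> 4        BND     chr1 40924 40924         0        NA      het

ev <- evaluate_calls(calls, fx$truth, position_tolerance = 10)
sprintf("precision %.2f recall %.2f F1 %.2f genotype concordance %.2f",
        ev$precision, ev$recall, ev$f1, ev$gt_concordance)
#> "precision 1.00 recall 1.00 F1 1.00 genotype concordance 1.00"
```

The per-haplotype signature counts show the raw evidence (the 2 `BND`
signatures on haplotype 2 are the two mates of one adjacency); `candidates`
is the genotyped call set, and the evaluation line says every implanted event
was recovered at the right locus, length and zygosity. `calls.vcf` contains
the same calls as a standards-conformant VCF.

A shell front end with the same defaults is installed at
`exec/contigsv`:

```sh
contigsv diploid --reference reference.fa --output calls.vcf hap1.sam hap2.sam
contigsv haploid --reference reference.fa --output calls.vcf assembly.sam
```

## Scope

Alignments are an input: contigsv does not run an aligner. CRAM/PAF input,
phasing tags, multi-sample merging and nested-SV resolution are out of scope.
See `vignettes/assembly-sv-calling.Rmd` for the model, parameter and
convention details.
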