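# End-to-end pipelines: haploid (collect -> output) and diploid
# (collect per haplotype -> pair -> genotype -> output).

log_counts <- function(label, sigs) {
  if (!length(sigs)) {
    message(label, ": no signatures")
    return(invisible(NULL))
  }
  tab <- table(vapply(sigs, function(s) s$sv_type, character(1)))
  message(label, ": ", paste(names(tab), tab, sep = "=", collapse = " "))
}

#' Run the diploid SV-calling pipeline
#'
#' Reads the two haplotypes' contig alignments, collects SV signatures per
#' haplotype, deduplicates within each haplotype, pairs signatures across
#' haplotypes by edit distance, genotypes them (paired: homozygous, unpaired:
#' heterozygous) and writes a VCF.
#'
#' @param hap1_alignments,hap2_alignments Paths to the coordinate-sorted
#'   SAM/BAM alignments of haplotype 1 and 2 contigs.
#' @param reference_path Path to the reference FASTA.
#' @param output Output VCF path.
#' @param sample_name Sample column name in the VCF.
#' @param params An [sv_params()] object.
#' @param min_mapq Minimum mapping quality for alignment records.
#' @param symbolic_del_threshold Deletions above this size are written as
#'   symbolic `<DEL>` records.
#' @return The list of [sv_candidate()]s, invisibly.
#' @export
run_diploid <- function(hap1_alignments, hap2_alignments, reference_path,
                        output, sample_name = "SAMPLE",
                        params = sv_params(), min_mapq = 0L,
                        symbolic_del_threshold = 10000L) {
  reference <- Biostrings::readDNAStringSet(reference_path)
  names(reference) <- sub("\\s.*$", "", names(reference))
  segs1 <- read_alignments(hap1_alignments, haplotype = 1L, min_mapq = min_mapq)
  segs2 <- read_alignments(hap2_alignments, haplotype = 2L, min_mapq = min_mapq)
  message("read ", length(segs1), " + ", length(segs2), " alignment segments")
  sigs1 <- dedup_within_haplotype(collect_signatures(segs1, params), params)
  sigs2 <- dedup_within_haplotype(collect_signatures(segs2, params), params)
  log_counts("haplotype 1 signatures", sigs1)
  log_counts("haplotype 2 signatures", sigs2)
  cands <- pair_and_genotype(sigs1, sigs2, params)
  gts <- vapply(cands, function(c) c$genotype, character(1))
  message("candidates: ", length(cands), " (hom_alt=", sum(gts == "hom_alt"),
          " het=", sum(gts == "het"), ")")
  write_vcf(cands, reference, sample_name, output,
            symbolic_del_threshold = symbolic_del_threshold)
  invisible(cands)
}

#' Run the haploid SV-calling pipeline
#'
#' Reads one set of contig alignments and writes the collected, deduplicated
#' signatures directly to a VCF; pairing and genotyping are skipped because a
#' single contig set carries no zygosity information.
#'
#' @param alignments Path to the coordinate-sorted SAM/BAM alignments.
#' @param haploid_gt Genotype string to write (default `"./1"`: presence
#'   without zygosity).
#' @inheritParams run_diploid
#' @return The list of [sv_candidate()]s, invisibly.
#' @export
run_haploid <- function(alignments, reference_path, output,
                        sample_name = "SAMPLE", params = sv_params(),
                        min_mapq = 0L, haploid_gt = "./1",
                        symbolic_del_threshold = 10000L) {
  reference <- Biostrings::readDNAStringSet(reference_path)
  names(reference) <- sub("\\s.*$", "", names(reference))
  segs <- read_alignments(alignments, haplotype = NA_integer_,
                          min_mapq = min_mapq)
  message("read ", length(segs), " alignment segments")
  sigs <- dedup_within_haplotype(collect_signatures(segs, params), params)
  log_counts("signatures", sigs)
  cands <- signatures_to_candidates(sigs)
  message("candidates: ", length(cands))
  write_vcf(cands, reference, sample_name, output, haploid_gt = haploid_gt,
            symbolic_del_threshold = symbolic_del_threshold)
  invisible(cands)
}
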