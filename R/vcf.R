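# OUTPUT: serialize genotyped candidates as a sorted VCF 4.2 file with the
# six SV classes. Internally all coordinates are 0-based half-open; this is
# the only module that converts to 1-based VCF positions and padding bases.

vcf_gt <- function(genotype, haploid_gt = "./1") {
  switch(genotype, hom_alt = "1/1", het = "0/1", unknown = haploid_gt)
}

ref_base <- function(reference, chrom, pos0) {
  # pos0 is 0-based
  as.character(Biostrings::subseq(reference[[chrom]], pos0 + 1L, pos0 + 1L))
}

ref_slice <- function(reference, chrom, start0, end0) {
  as.character(Biostrings::subseq(reference[[chrom]], start0 + 1L, end0))
}

bracket_alt <- function(ref_base, mate_ref, mate_pos1, local_side, mate_side) {
  mate <- paste0(mate_ref, ":", mate_pos1)
  if (local_side == "right" && mate_side == "left") {
    paste0(ref_base, "[", mate, "[")
  } else if (local_side == "right" && mate_side == "right") {
    paste0(ref_base, "]", mate, "]")
  } else if (local_side == "left" && mate_side == "right") {
    paste0("]", mate, "]", ref_base)
  } else {
    paste0("[", mate, "[", ref_base)
  }
}

#' Format one candidate as VCF record line(s)
#'
#' Deletions and insertions are written sequence-resolved (REF holds the
#' deleted bases plus a padding base, or ALT the padding base plus the
#' inserted bases); deletions above `symbolic_del_threshold` fall back to the
#' symbolic `<DEL>` allele to bound file size. Inversions and duplications are
#' symbolic. A breakend candidate produces two lines — the record and its
#' reciprocal mate — cross-referenced via `MATEID`.
#'
#' @param cand An [sv_candidate()].
#' @param reference A [Biostrings::DNAStringSet] of the reference genome.
#' @param ids Character vector of record IDs: length 1, or 2 for breakends.
#' @param mate_ids For breakends, the two MATEID values (reciprocal of
#'   `ids`); ignored otherwise.
#' @param sample_gt The sample GT string.
#' @param symbolic_del_threshold Deletions longer than this are written as
#'   symbolic `<DEL>` records.
#' @return Character vector of one or two tab-separated VCF data lines.
#' @export
format_record <- function(cand, reference, ids, mate_ids = NULL,
                          sample_gt = "0/1", symbolic_del_threshold = 10000L) {
  chrom <- cand$ref_name
  if (!chrom %in% names(reference)) {
    stop("candidate on unknown reference sequence: ", chrom)
  }
  clen <- Biostrings::width(reference)[match(chrom, names(reference))]
  if (cand$end > clen || cand$start < 0L) {
    stop("candidate locus outside reference bounds: ",
         chrom, ":", cand$start, "-", cand$end)
  }
  line <- function(pos1, id, ref, alt, info) {
    paste(chrom, pos1, id, ref, alt, ".", "PASS", info, "GT", sample_gt,
          sep = "\t")
  }

  if (cand$sv_type == "BND") {
    a <- cand$adj
    pos1_local <- a$local_pos + 1L
    pos1_mate <- a$mate_pos + 1L
    rb_local <- ref_base(reference, a$local_ref, a$local_pos)
    rb_mate <- ref_base(reference, a$mate_ref, a$mate_pos)
    alt_local <- bracket_alt(rb_local, a$mate_ref, pos1_mate,
                             a$local_side, a$mate_side)
    alt_mate <- bracket_alt(rb_mate, a$local_ref, pos1_local,
                            a$mate_side, a$local_side)
    l1 <- paste(a$local_ref, pos1_local, ids[1L], rb_local, alt_local, ".",
                "PASS", paste0("SVTYPE=BND;MATEID=", mate_ids[1L]),
                "GT", sample_gt, sep = "\t")
    l2 <- paste(a$mate_ref, pos1_mate, ids[2L], rb_mate, alt_mate, ".",
                "PASS", paste0("SVTYPE=BND;MATEID=", mate_ids[2L]),
                "GT", sample_gt, sep = "\t")
    return(c(l1, l2))
  }

  if (cand$sv_type == "DEL") {
    len <- cand$end - cand$start
    pad0 <- cand$start - 1L
    if (len > symbolic_del_threshold || pad0 < 0L) {
      pos1 <- max(cand$start, 1L)
      rb <- ref_base(reference, chrom, pos1 - 1L)
      info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=%d", cand$end, -len)
      return(line(pos1, ids[1L], rb, "<DEL>", info))
    }
    ref <- ref_slice(reference, chrom, pad0, cand$end)
    alt <- substr(ref, 1L, 1L)
    info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=%d", cand$end, -len)
    return(line(cand$start, ids[1L], ref, alt, info))
  }

  if (cand$sv_type == "INS") {
    pad0 <- cand$start - 1L
    rb <- ref_base(reference, chrom, max(pad0, 0L))
    alt <- if (nzchar(cand$alt_seq)) paste0(rb, cand$alt_seq) else "<INS>"
    info <- sprintf("SVTYPE=INS;SVLEN=%d", cand$sv_length)
    if (!nzchar(cand$alt_seq)) {
      info <- sprintf("SVTYPE=INS;END=%d;SVLEN=%d", cand$start, cand$sv_length)
    }
    return(line(max(cand$start, 1L), ids[1L], rb, alt, info))
  }

  pad0 <- max(cand$start - 1L, 0L)
  rb <- ref_base(reference, chrom, pad0)
  pos1 <- max(cand$start, 1L)
  if (cand$sv_type == "INV") {
    info <- sprintf("SVTYPE=INV;END=%d;SVLEN=%d", cand$end, cand$sv_length)
    return(line(pos1, ids[1L], rb, "<INV>", info))
  }
  if (cand$sv_type == "DUP_TANDEM") {
    info <- sprintf("SVTYPE=DUP:TANDEM;END=%d;SVLEN=%d",
                    cand$end, cand$sv_length)
    return(line(pos1, ids[1L], rb, "<DUP:TANDEM>", info))
  }
  if (cand$sv_type == "DUP_INT") {
    info <- sprintf("SVTYPE=DUP:INT;END=%d;SVLEN=%d;DUPSRC=%s:%d-%d",
                    cand$end, cand$sv_length,
                    cand$src_ref, cand$src_start + 1L, cand$src_end)
    return(line(pos1, ids[1L], rb, "<DUP:INT>", info))
  }
  stop("unknown SV type: ", cand$sv_type)
}

vcf_header <- function(reference, sample_name, command = NULL) {
  contig_lines <- sprintf("##contig=<ID=%s,length=%d>",
                          names(reference), Biostrings::width(reference))
  c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    paste0("##source=contigsv-", as.character(utils::packageVersion("contigsv"))),
    if (!is.null(command)) paste0("##commandline=\"", command, "\""),
    contig_lines,
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##ALT=<ID=DUP:INT,Description=\"Interspersed duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=DUPSRC,Number=1,Type=String,Description=\"Origin locus of the duplicated sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
}

#' Write genotyped SV candidates to a VCF file
#'
#' Produces a VCF 4.2 file with one contig header line per reference sequence
#' (in reference order), records sorted by (contig order, position, ID), and
#' per-type ordinal record IDs. Breakend candidates are written as two
#' mutually referencing records.
#'
#' @param candidates List of [sv_candidate()]s.
#' @param reference A [Biostrings::DNAStringSet] (names must cover all
#'   candidate chromosomes).
#' @param sample_name Sample column name.
#' @param path Output file path.
#' @param haploid_gt Genotype string written for candidates with unknown
#'   zygosity (haploid mode); `"./1"` encodes presence without zygosity.
#' @param symbolic_del_threshold See [format_record()].
#' @param command Optional command-line string echoed into the header.
#' @return The output path, invisibly.
#' @export
write_vcf <- function(candidates, reference, sample_name = "SAMPLE",
                      path, haploid_gt = "./1",
                      symbolic_del_threshold = 10000L, command = NULL) {
  counters <- c(DEL = 0L, INS = 0L, INV = 0L, DUP_TANDEM = 0L,
                DUP_INT = 0L, BND = 0L)
  id_prefix <- c(DEL = "DEL", INS = "INS", INV = "INV",
                 DUP_TANDEM = "DUP.TANDEM", DUP_INT = "DUP.INT", BND = "BND")
  recs <- character(0)
  chrom <- character(0)
  pos <- integer(0)
  for (cand in sort_candidates(candidates)) {
    counters[cand$sv_type] <- counters[cand$sv_type] + 1L
    k <- counters[cand$sv_type]
    gt <- vcf_gt(cand$genotype, haploid_gt)
    if (cand$sv_type == "BND") {
      ids <- paste0("BND.", k, ".", 1:2)
      lines <- format_record(cand, reference, ids, mate_ids = rev(ids),
                             sample_gt = gt,
                             symbolic_del_threshold = symbolic_del_threshold)
      recs <- c(recs, lines)
      chrom <- c(chrom, cand$adj$local_ref, cand$adj$mate_ref)
      pos <- c(pos, cand$adj$local_pos + 1L, cand$adj$mate_pos + 1L)
    } else {
      id <- paste0(id_prefix[cand$sv_type], ".", k)
      lines <- format_record(cand, reference, id, sample_gt = gt,
                             symbolic_del_threshold = symbolic_del_threshold)
      recs <- c(recs, lines)
      chrom <- c(chrom, cand$ref_name)
      pos <- c(pos, max(cand$start, 1L))
    }
  }
  if (length(recs)) {
    ids <- vapply(strsplit(recs, "\t"), `[`, character(1), 3L)
    ord <- order(match(chrom, names(reference)), pos, ids)
    recs <- recs[ord]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(vcf_header(reference, sample_name, command), con)
  if (length(recs)) writeLines(recs, con)
  invisible(path)
}
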