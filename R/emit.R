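# Analytic SAM emission: turn implanted haplotype genomes into the ideal
# gapped/split alignment records an assembly aligner would produce, without
# running an aligner. These are exactly the discordancy geometries that the
# signature-collection module decodes.

# Internal builder collecting segments of the contig currently being walked.
new_contig_builder <- function(name, q0) {
  list(name = name, q0 = q0, segments = list())
}

#' Emit ideal SAM alignments for one haplotype
#'
#' Walks each haplotype chromosome alongside its implanted events and
#' constructs the corresponding alignment segments analytically. In
#' `"gapped"` style, insertions and deletions inside a contig are encoded as
#' `I`/`D` CIGAR operations of a single record; in `"split"` style every
#' breakpoint splits the contig into separate records. Inversions,
#' duplications and translocation adjacencies always produce split records
#' (a single gapped record cannot express them): the inverted middle segment
#' maps to the reverse strand, the interspersed-duplication middle segment
#' maps to its source locus, and each translocation adjacency yields a fusion
#' contig spanning the junction. The longest segment of each contig becomes
#' the soft-clipped primary record carrying the full contig sequence;
#' the remaining segments become hard-clipped supplementary records.
#'
#' @param hap_seqs Named character vector of haplotype chromosome sequences
#'   (from [implant_svs()]).
#' @param truth Truth `data.frame` from [implant_svs()].
#' @param reference The reference [Biostrings::DNAStringSet].
#' @param haplotype `1L` or `2L`: which haplotype's events to realize.
#' @param style `"gapped"` or `"split"` (for insertions/deletions).
#' @param contig_length Approximate maximum contig length in bp; chromosomes
#'   are cut between events once a contig exceeds it. `Inf` keeps one contig
#'   per chromosome.
#' @param bnd_flank Fusion-contig flank length; must match the value used by
#'   [implant_svs()].
#' @return Character vector of SAM lines (header plus coordinate-sorted
#'   records).
#' @export
emit_alignments <- function(hap_seqs, truth, reference, haplotype = 1L,
                            style = c("gapped", "split"),
                            contig_length = Inf, bnd_flank = 2000L) {
  style <- match.arg(style)
  ref <- as.character(reference)
  chrom_names <- names(ref)
  carried <- truth$zygosity == "hom" |
    truth$zygosity == paste0("het_hap", haplotype)

  records <- list()

  add_contig_records <- function(contig_name, contig_seq, segments) {
    if (!length(segments)) return(invisible(NULL))
    qlen <- nchar(contig_seq)
    spans <- vapply(segments, function(s) s$q_end - s$q_start, integer(1))
    primary <- which.max(spans)
    for (k in seq_along(segments)) {
      s <- segments[[k]]
      is_primary <- k == primary
      lead <- s$q_start
      trail <- qlen - s$q_end
      if (s$strand == "-") { tmp <- lead; lead <- trail; trail <- tmp }
      ops <- s$ops; lens <- s$lens
      if (s$strand == "-") { ops <- rev(ops); lens <- rev(lens) }
      clip_op <- if (is_primary) "S" else "H"
      if (lead > 0L) { ops <- c(clip_op, ops); lens <- c(lead, lens) }
      if (trail > 0L) { ops <- c(ops, clip_op); lens <- c(lens, trail) }
      if (is_primary) {
        seq <- if (s$strand == "+") contig_seq else revcomp(contig_seq)
      } else {
        seq <- substr(contig_seq, s$q_start + 1L, s$q_end)
        if (s$strand == "-") seq <- revcomp(seq)
      }
      flag <- 0L
      if (s$strand == "-") flag <- flag + 16L
      if (!is_primary) flag <- flag + 2048L
      records[[length(records) + 1L]] <<- list(
        qname = contig_name, flag = flag, rname = s$ref_name,
        pos = s$ref_open + 1L, cigar = cigar_string(ops, lens), seq = seq
      )
    }
  }

  for (chrom in chrom_names) {
    hapseq <- hap_seqs[[chrom]]
    ev <- truth[carried & truth$ref_name == chrom &
                  truth$sv_type != "BND", , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    ref_len <- nchar(ref[[chrom]])

    contig_idx <- 0L
    cur_ref <- 0L; cur_q <- 0L
    seg_ref_name <- chrom; seg_ref_open <- 0L; seg_q_open <- 0L
    seg_strand <- "+"
    ops <- character(0); lens <- integer(0)
    segments <- list()
    contig_q0 <- 0L

    push_op <- function(op, len) {
      if (len > 0L) { ops[[length(ops) + 1L]] <<- op; lens <<- c(lens, len) }
    }
    close_seg <- function() {
      if (length(ops)) {
        segments[[length(segments) + 1L]] <<- list(
          ref_name = seg_ref_name, ref_open = seg_ref_open, ref_end = cur_ref,
          q_start = seg_q_open - contig_q0, q_end = cur_q - contig_q0,
          strand = seg_strand, ops = unlist(ops), lens = lens
        )
      }
      ops <<- character(0); lens <<- integer(0)
    }
    open_seg <- function(ref_name, ref_pos, strand = "+") {
      seg_ref_name <<- ref_name; seg_ref_open <<- ref_pos
      seg_q_open <<- cur_q; seg_strand <<- strand
    }
    finish_contig <- function() {
      close_seg()
      contig_idx <<- contig_idx + 1L
      cname <- sprintf("%s_hap%d_ctg%d", chrom, haplotype, contig_idx)
      cseq <- substr(hapseq, contig_q0 + 1L, cur_q)
      add_contig_records(cname, cseq, segments)
      segments <<- list()
      contig_q0 <<- cur_q
    }

    open_seg(chrom, 0L)
    events <- if (nrow(ev)) seq_len(nrow(ev)) else integer(0)
    for (i in events) {
      e <- ev[i, ]
      match_len <- e$start - cur_ref
      # cut the contig between events once it has grown long enough
      if (is.finite(contig_length) &&
          (cur_q - contig_q0) + match_len %/% 2L > contig_length &&
          match_len >= 2L) {
        half <- match_len %/% 2L
        push_op("M", half); cur_ref <- cur_ref + half; cur_q <- cur_q + half
        finish_contig()
        open_seg(chrom, cur_ref)
        match_len <- match_len - half
      }
      push_op("M", match_len)
      cur_ref <- cur_ref + match_len; cur_q <- cur_q + match_len

      if (e$sv_type == "DEL") {
        if (style == "gapped") {
          push_op("D", e$sv_length)
        } else {
          close_seg()
          open_seg(chrom, e$start + e$sv_length)
        }
        cur_ref <- cur_ref + e$sv_length
      } else if (e$sv_type == "INS") {
        if (style == "gapped") {
          push_op("I", e$sv_length)
          cur_q <- cur_q + e$sv_length
        } else {
          close_seg()
          cur_q <- cur_q + e$sv_length
          open_seg(chrom, e$start)
        }
      } else if (e$sv_type == "INV") {
        close_seg()
        open_seg(chrom, e$start, strand = "-")
        push_op("M", e$sv_length)
        cur_ref <- cur_ref + e$sv_length; cur_q <- cur_q + e$sv_length
        close_seg()
        open_seg(chrom, e$end)
      } else if (e$sv_type == "DUP_TANDEM") {
        # first copy is matched in place, then the alignment jumps back
        push_op("M", e$sv_length)
        cur_ref <- cur_ref + e$sv_length; cur_q <- cur_q + e$sv_length
        close_seg()
        cur_ref <- e$start
        open_seg(chrom, e$start)
      } else if (e$sv_type == "DUP_INT") {
        close_seg()
        open_seg(e$src_ref, e$src_start)
        saved_ref <- cur_ref
        cur_ref <- e$src_start
        push_op("M", e$sv_length)
        cur_ref <- cur_ref + e$sv_length; cur_q <- cur_q + e$sv_length
        close_seg()
        cur_ref <- saved_ref
        open_seg(chrom, e$start)
      }
    }
    push_op("M", ref_len - cur_ref)
    cur_q <- cur_q + (ref_len - cur_ref)
    cur_ref <- ref_len
    finish_contig()
    stopifnot(cur_q == nchar(hapseq))  # bookkeeping must balance
  }

  # fusion contigs for translocation adjacencies
  bnd <- truth[carried & truth$sv_type == "BND", , drop = FALSE]
  if (nrow(bnd)) {
    for (i in seq_len(nrow(bnd))) {
      e <- bnd[i, ]
      xa <- e$start + 1L  # half-open end of the local flank
      seq_a <- substr(ref[[e$ref_name]], xa - bnd_flank + 1L, xa)
      seq_b <- substr(ref[[e$mate_ref]], e$mate_pos + 1L,
                      e$mate_pos + bnd_flank)
      cname <- sprintf("fusion%d_hap%d", i, haplotype)
      segs <- list(
        list(ref_name = e$ref_name, ref_open = xa - bnd_flank, ref_end = xa,
             q_start = 0L, q_end = bnd_flank, strand = "+",
             ops = "M", lens = bnd_flank),
        list(ref_name = e$mate_ref, ref_open = e$mate_pos,
             ref_end = e$mate_pos + bnd_flank,
             q_start = bnd_flank, q_end = 2L * bnd_flank, strand = "+",
             ops = "M", lens = bnd_flank)
      )
      add_contig_records(cname, paste0(seq_a, seq_b), segs)
    }
  }

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom_names, nchar(ref)))
  if (!length(records)) return(header)
  rname <- vapply(records, `[[`, character(1), "rname")
  pos <- vapply(records, `[[`, integer(1), "pos")
  ord <- order(match(rname, chrom_names), pos)
  lines <- vapply(records[ord], function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, 60L, r$cigar,
          "*", 0L, 0L, r$seq, "*", sep = "\t")
  }, character(1))
  c(header, lines)
}

#' Write SAM lines to a file
#'
#' @param lines Character vector from [emit_alignments()].
#' @param path Output path (should end in `.sam`).
#' @return The path, invisibly.
#' @export
write_sam <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}
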