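# Alignment segments and CIGAR coordinate arithmetic.
#
# All coordinates are 0-based half-open on both the reference and the
# full-length forward strand of the query contig; conversion to 1-based
# happens only at VCF output.

QUERY_OPS <- c("M", "=", "X", "I", "S")  # consume query (stored sequence)
REF_OPS <- c("M", "=", "X", "D")         # consume reference
CLIP_OPS <- c("S", "H")

#' Parse a CIGAR string into operations and lengths
#'
#' @param cigar A single CIGAR string, e.g. `"5S100M2D30M"`.
#' @return A list with character vector `ops` and integer vector `lengths`.
#' @keywords internal
parse_cigar <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lengths <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  list(ops = ops, lengths = lengths)
}

cigar_string <- function(ops, lengths) {
  paste0(lengths, ops, collapse = "")
}

#' Query interval on the forward strand of the contig
#'
#' Computes where a CIGAR's aligned bases sit on the full-length,
#' forward-oriented query sequence. For reverse-strand alignments the clip
#' roles are mirrored so that coordinates always refer to the contig's own
#' orientation, which is what ordering split alignment segments along the
#' contig requires.
#'
#' @param ops Character vector of CIGAR operations.
#' @param lengths Integer vector of operation lengths (same length as `ops`).
#' @param strand `"+"` or `"-"`.
#' @return A list with `query_start`, `query_end` (0-based half-open on the
#'   forward strand) and `query_length` (full contig length including clips).
#' @examples
#' query_interval_on_forward_strand(c("H", "M", "H"), c(100L, 50L, 30L), "+")
#' @export
query_interval_on_forward_strand <- function(ops, lengths, strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(length(ops) > 0L, length(ops) == length(lengths))
  is_clip <- ops %in% CLIP_OPS
  lead_clip <- 0L
  trail_clip <- 0L
  if (all(is_clip)) stop("malformed CIGAR: no aligned operation")
  inner <- range(which(!is_clip))
  # clips may only flank the alignment
  if (any(is_clip[seq(inner[1L], inner[2L])])) {
    stop("malformed CIGAR: clip operation inside the alignment")
  }
  if (inner[1L] > 1L) lead_clip <- sum(lengths[seq_len(inner[1L] - 1L)])
  if (inner[2L] < length(ops)) {
    trail_clip <- sum(lengths[seq(inner[2L] + 1L, length(ops))])
  }
  aligned <- sum(lengths[ops %in% c("M", "=", "X", "I")])
  query_length <- aligned + lead_clip + trail_clip
  if (strand == "+") {
    qs <- lead_clip
  } else {
    qs <- trail_clip
  }
  list(query_start = qs, query_end = qs + aligned, query_length = query_length)
}

#' Construct an alignment segment
#'
#' One contig-to-reference alignment record normalized to forward-query
#' coordinates. Used both by the SAM/BAM reader and by the synthetic
#' alignment generator.
#'
#' @param query_name Contig identifier.
#' @param ref_name Reference sequence identifier.
#' @param ref_start,ref_end 0-based half-open reference interval.
#' @param query_start,query_end 0-based half-open interval on the forward
#'   strand of the full-length contig.
#' @param query_length Full contig length in bp (aligned bases plus clips).
#' @param strand `"+"` or `"-"`.
#' @param ops,lengths CIGAR operations and lengths.
#' @param seq Stored record sequence (reference orientation, as in SAM), or
#'   `NA` when absent.
#' @param haplotype `1L`, `2L` or `NA` for unlabelled/haploid input.
#' @param mapq Mapping quality, 0-255.
#' @param supplementary Logical; `TRUE` for supplementary records.
#' @return An object of class `alignment_segment`.
#' @export
alignment_segment <- function(query_name, ref_name, ref_start, ref_end,
                              query_start, query_end, query_length,
                              strand, ops, lengths, seq = NA_character_,
                              haplotype = NA_integer_, mapq = 60L,
                              supplementary = FALSE) {
  stopifnot(query_start < query_end, ref_start < ref_end,
            strand %in% c("+", "-"))
  structure(list(
    query_name = query_name, ref_name = ref_name,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    query_length = as.integer(query_length),
    strand = strand, ops = ops, lengths = as.integer(lengths),
    seq = seq, haplotype = as.integer(haplotype), mapq = as.integer(mapq),
    supplementary = isTRUE(supplementary)
  ), class = "alignment_segment")
}

#' @export
print.alignment_segment <- function(x, ...) {
  cat(sprintf("<alignment_segment> %s q[%d,%d)/%d %s:%d-%d (%s)%s\n",
              x$query_name, x$query_start, x$query_end, x$query_length,
              x$ref_name, x$ref_start, x$ref_end, x$strand,
              if (x$supplementary) " suppl" else ""))
  invisible(x)
}

# Reverse-complement a nucleotide string (character in, character out).
revcomp <- function(x) {
  if (is.na(x) || !nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Mirror a segment onto the reverse-complemented contig: query coordinates
# flip around the contig, the strand toggles, reference coordinates stay.
flip_segment <- function(seg) {
  qs <- seg$query_length - seg$query_end
  qe <- seg$query_length - seg$query_start
  seg$query_start <- qs
  seg$query_end <- qe
  seg$strand <- if (seg$strand == "+") "-" else "+"
  seg$ops <- rev(seg$ops)
  seg$lengths <- rev(seg$lengths)
  seg
}
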