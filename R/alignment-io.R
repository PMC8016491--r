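# SAM/BAM input: normalize alignment records to forward-query coordinates.

#' Read contig-to-reference alignments
#'
#' Reads a coordinate-sorted SAM or BAM file of assembly contig alignments and
#' normalizes every primary or supplementary record into an
#' [alignment_segment()] with coordinates on the reference and on the
#' full-length forward strand of the contig. Secondary and unmapped records
#' are skipped. Hard and soft clips are both used to recover full-query
#' coordinates, so supplementary records (which assembly aligners typically
#' hard-clip) are placed correctly along the contig.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file with a valid
#'   header containing `@SQ` lines.
#' @param haplotype Haplotype label to attach to every segment: `1L`, `2L`,
#'   or `NA` for haploid/unlabelled input.
#' @param min_mapq Minimum mapping quality; records below are skipped.
#'   Defaults to 0 because assembly alignments are few and long.
#' @return A list of `alignment_segment` objects in file order.
#' @export
read_alignments <- function(path, haplotype = NA_integer_, min_mapq = 0L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  param <- Rsamtools::ScanBamParam(
    what = what,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  recs <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(recs$qname)
  out <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    mapq <- recs$mapq[i]
    if (!is.na(mapq) && mapq < min_mapq) next
    flag <- recs$flag[i]
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    suppl <- bitwAnd(flag, 2048L) > 0L
    cig <- parse_cigar(recs$cigar[i])
    qiv <- tryCatch(
      query_interval_on_forward_strand(cig$ops, cig$lengths, strand),
      error = function(e) NULL
    )
    if (is.null(qiv)) {
      warning("skipping record with unresolvable query coordinates: ",
              recs$qname[i])
      next
    }
    ref_start <- recs$pos[i] - 1L  # SAM POS is 1-based
    ref_span <- sum(cig$lengths[cig$ops %in% REF_OPS])
    seq <- as.character(recs$seq[i])
    if (!nzchar(seq) || identical(seq, "*")) seq <- NA_character_
    kept <- kept + 1L
    out[[kept]] <- alignment_segment(
      query_name = recs$qname[i],
      ref_name = as.character(recs$rname[i]),
      ref_start = ref_start, ref_end = ref_start + ref_span,
      query_start = qiv$query_start, query_end = qiv$query_end,
      query_length = qiv$query_length,
      strand = strand, ops = cig$ops, lengths = cig$lengths,
      seq = seq, haplotype = haplotype,
      mapq = if (is.na(mapq)) 255L else mapq,
      supplementary = suppl
    )
  }
  out[seq_len(kept)]
}

#' Read reference sequence names and lengths from an alignment header
#'
#' @param path SAM or BAM file.
#' @return Named integer vector of reference sequence lengths in header order.
#' @keywords internal
read_sequence_dictionary <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  hdr$targets
}
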