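#' Detection and pairing parameters
#'
#' Bundle the thresholds that govern signature extraction, cross-haplotype
#' pairing and within-haplotype deduplication.
#'
#' @param min_sv_size Smallest structural variant reported, in bp. Alignment
#'   gaps and segment discordancies shorter than this are considered
#'   concordant.
#' @param max_sv_size Largest same-chromosome reference jump interpreted as a
#'   deletion/duplication, in bp. Larger jumps are reported as a pair of
#'   breakends instead.
#' @param query_gap_tolerance Maximum unaligned (or overlapping) stretch on
#'   the contig, in bp, ignored when classifying a reference gap between two
#'   alignment segments.
#' @param reference_gap_tolerance Maximum reference displacement, in bp,
#'   ignored when classifying a contig gap (insertion) or when testing
#'   segment collinearity.
#' @param pairing_max_span_distance Maximum reference-position difference, in
#'   bp, for two signatures from opposite haplotypes to be considered for
#'   pairing (and for within-haplotype deduplication).
#' @param pairing_max_edit_fraction Maximum normalized edit distance (edit
#'   distance divided by the longer sequence length) for two signatures to be
#'   merged. Unitless, in \[0, 1\].
#'
#' @return An object of class `sv_params`, a validated list of the six
#'   thresholds.
#' @examples
#' p <- sv_params(min_sv_size = 50)
#' p$min_sv_size
#' @export
sv_params <- function(min_sv_size = 40L,
                      max_sv_size = 100000L,
                      query_gap_tolerance = 50L,
                      reference_gap_tolerance = 50L,
                      pairing_max_span_distance = 1000L,
                      pairing_max_edit_fraction = 0.3) {
  p <- list(
    min_sv_size = as.integer(min_sv_size),
    max_sv_size = as.integer(max_sv_size),
    query_gap_tolerance = as.integer(query_gap_tolerance),
    reference_gap_tolerance = as.integer(reference_gap_tolerance),
    pairing_max_span_distance = as.integer(pairing_max_span_distance),
    pairing_max_edit_fraction = as.numeric(pairing_max_edit_fraction)
  )
  stopifnot(
    !anyNA(unlist(p)),
    p$min_sv_size >= 0L, p$max_sv_size >= p$min_sv_size,
    p$query_gap_tolerance >= 0L, p$reference_gap_tolerance >= 0L,
    p$pairing_max_span_distance >= 0L,
    p$pairing_max_edit_fraction >= 0, p$pairing_max_edit_fraction <= 1
  )
  structure(p, class = "sv_params")
}

#' @export
print.sv_params <- function(x, ...) {
  cat("SV detection parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
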