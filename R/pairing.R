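# PAIR and GENOTYPE: deduplicate signatures within a haplotype, pair similar
# signatures across haplotypes by the edit distance of their variant
# sequences, and derive genotypes from the pairing outcome (paired ->
# homozygous, unpaired -> heterozygous).

#' Levenshtein edit distance between two nucleotide strings
#'
#' Unit-cost substitutions, insertions and deletions. Empty strings are
#' allowed; the distance to the empty string is the other string's length.
#'
#' @param a,b Character scalars.
#' @return Integer edit distance.
#' @examples
#' edit_distance("AAACCC", "AACGCC")  # 2
#' @export
edit_distance <- function(a, b) {
  if (is.na(a)) a <- ""
  if (is.na(b)) b <- ""
  as.integer(utils::adist(a, b))
}

#' Similarity of two SV signatures
#'
#' Two signatures are pairing candidates when they have the same type and
#' chromosome, lie within `pairing_max_span_distance` of each other, and the
#' normalized distance between their variant sequences is at most
#' `pairing_max_edit_fraction`. The distance is the Levenshtein edit distance
#' divided by the longer sequence length; for deletion-type signatures whose
#' sequence is not stored, the relative length difference
#' `|len1 - len2| / max(len1, len2)` is used instead. Breakends pair when both
#' adjacency endpoints agree within `pairing_max_span_distance` and the
#' orientations match (distance 0).
#'
#' @param s1,s2 [sv_signature()] objects.
#' @param params An [sv_params()] object.
#' @return List with `candidate` (logical) and `distance` (normalized,
#'   `NA` when not a candidate for positional/type reasons).
#' @export
signature_similarity <- function(s1, s2, params = sv_params()) {
  no <- list(candidate = FALSE, distance = NA_real_)
  if (s1$sv_type != s2$sv_type || s1$ref_name != s2$ref_name) return(no)

  if (s1$sv_type == "BND") {
    a1 <- s1$adj; a2 <- s2$adj
    ok <- !is.null(a1) && !is.null(a2) &&
      a1$mate_ref == a2$mate_ref &&
      a1$local_side == a2$local_side && a1$mate_side == a2$mate_side &&
      abs(a1$local_pos - a2$local_pos) <= params$pairing_max_span_distance &&
      abs(a1$mate_pos - a2$mate_pos) <= params$pairing_max_span_distance
    return(list(candidate = ok, distance = if (ok) 0 else NA_real_))
  }

  if (abs(s1$start - s2$start) > params$pairing_max_span_distance) return(no)

  has_seq <- nzchar(s1$alt_seq) && nzchar(s2$alt_seq)
  if (has_seq) {
    denom <- max(nchar(s1$alt_seq), nchar(s2$alt_seq))
    d <- if (denom == 0L) 0 else edit_distance(s1$alt_seq, s2$alt_seq) / denom
  } else {
    denom <- max(s1$sv_length, s2$sv_length)
    d <- if (denom == 0L) 0 else abs(s1$sv_length - s2$sv_length) / denom
  }
  list(candidate = d <= params$pairing_max_edit_fraction, distance = d)
}

#' Construct a genotyped SV candidate
#'
#' @param sig Representative [sv_signature()] providing coordinates, length
#'   and sequences.
#' @param genotype `"hom_alt"`, `"het"` or `"unknown"` (haploid mode).
#' @param support List of contributing signatures (one or two haplotypes).
#' @return An object of class `sv_candidate`.
#' @export
sv_candidate <- function(sig, genotype, support = list(sig)) {
  stopifnot(genotype %in% c("hom_alt", "het", "unknown"))
  structure(list(
    sv_type = sig$sv_type, ref_name = sig$ref_name,
    start = sig$start, end = sig$end, sv_length = sig$sv_length,
    alt_seq = sig$alt_seq, src_ref = sig$src_ref,
    src_start = sig$src_start, src_end = sig$src_end, adj = sig$adj,
    genotype = genotype, support = support
  ), class = "sv_candidate")
}

# Keep one BND signature per adjacency (the canonical side); the VCF writer
# re-creates the mate line.
drop_bnd_mates <- function(sigs) {
  Filter(function(s) s$sv_type != "BND" || isTRUE(s$adj$canonical), sigs)
}

#' Deduplicate signatures within one haplotype
#'
#' Overlapping contigs of one haplotype can report the same variant more than
#' once. Signatures that would satisfy [signature_similarity()] against an
#' already-kept signature are dropped; the representative with the longest
#' supporting alignment wins (ties broken by leftmost position, then input
#' order).
#'
#' @param signatures List of [sv_signature()]s sharing one haplotype label.
#' @param params An [sv_params()] object.
#' @return Filtered list of signatures.
#' @export
dedup_within_haplotype <- function(signatures, params = sv_params()) {
  n <- length(signatures)
  if (n <= 1L) return(signatures)
  seg_len <- vapply(signatures, function(s) {
    if (is.na(s$seg_len)) 0L else s$seg_len
  }, integer(1))
  pos <- vapply(signatures, function(s) s$start, integer(1))
  ord <- order(-seg_len, pos, seq_len(n))
  kept <- list()
  for (i in ord) {
    s <- signatures[[i]]
    dup <- FALSE
    for (k in kept) {
      if (signature_similarity(s, k, params)$candidate) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- s
  }
  # restore a stable reference-position order
  kept[order(vapply(kept, function(s) s$ref_name, character(1)),
             vapply(kept, function(s) s$start, integer(1)))]
}

#' Pair signatures across haplotypes and assign genotypes
#'
#' Builds a one-to-one matching between the two haplotypes' signatures,
#' greedily by ascending normalized distance (ties broken by ascending
#' reference position, then haplotype-1 input order). Every matched pair
#' becomes one homozygous candidate; every unmatched signature becomes a
#' heterozygous candidate. Coordinates and sequences of a merged pair are
#' taken from the haplotype-1 signature.
#'
#' @param hap1,hap2 Lists of [sv_signature()]s labelled haplotype 1 and 2.
#' @param params An [sv_params()] object.
#' @return List of [sv_candidate()]s sorted by (chromosome, position).
#' @export
pair_and_genotype <- function(hap1, hap2, params = sv_params()) {
  hap1 <- drop_bnd_mates(hap1)
  hap2 <- drop_bnd_mates(hap2)
  n1 <- length(hap1); n2 <- length(hap2)
  edges <- NULL
  if (n1 > 0L && n2 > 0L) {
    rows <- list()
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        sim <- signature_similarity(hap1[[i]], hap2[[j]], params)
        if (sim$candidate) {
          rows[[length(rows) + 1L]] <-
            c(i = i, j = j, d = sim$distance, pos = hap1[[i]]$start)
        }
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  matched1 <- logical(n1); matched2 <- logical(n2)
  cands <- list()
  if (!is.null(edges)) {
    ord <- order(edges[, "d"], edges[, "pos"], edges[, "i"], edges[, "j"])
    for (k in ord) {
      i <- edges[k, "i"]; j <- edges[k, "j"]
      if (matched1[i] || matched2[j]) next
      matched1[i] <- TRUE; matched2[j] <- TRUE
      cands[[length(cands) + 1L]] <- sv_candidate(
        hap1[[i]], "hom_alt", support = list(hap1[[i]], hap2[[j]])
      )
    }
  }
  for (i in which(!matched1)) {
    cands[[length(cands) + 1L]] <- sv_candidate(hap1[[i]], "het")
  }
  for (j in which(!matched2)) {
    cands[[length(cands) + 1L]] <- sv_candidate(hap2[[j]], "het")
  }
  sort_candidates(cands)
}

#' Convert signatures of a haploid assembly directly to candidates
#'
#' Haploid assemblies carry no second haplotype, so zygosity cannot be
#' estimated: every signature becomes a candidate with genotype `"unknown"`.
#'
#' @param signatures List of [sv_signature()]s.
#' @return List of [sv_candidate()]s sorted by (chromosome, position).
#' @export
signatures_to_candidates <- function(signatures) {
  sort_candidates(lapply(drop_bnd_mates(signatures),
                         sv_candidate, genotype = "unknown"))
}

sort_candidates <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  cands[order(vapply(cands, function(c) c$ref_name, character(1)),
              vapply(cands, function(c) c$start, integer(1)),
              vapply(cands, function(c) c$sv_type, character(1)))]
}
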