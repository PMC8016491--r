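# COLLECT: extract SV signatures per haplotype from discordant contig
# alignments. Two evidence sources are used: long gaps inside one alignment
# record (CIGAR I/D operations) and discordant placements/orientations
# between the split alignment segments of one contig.

#' Construct an SV signature
#'
#' One piece of evidence for a structural variant from one haplotype, before
#' cross-haplotype pairing. Intervals are 0-based half-open on the reference;
#' insertions are anchored at a point (`start == end`).
#'
#' @param sv_type One of `"INS"`, `"DEL"`, `"INV"`, `"DUP_TANDEM"`,
#'   `"DUP_INT"`, `"BND"`.
#' @param ref_name,start,end Reference locus of the variant.
#' @param sv_length Variant length in bp (0 for breakends).
#' @param alt_seq Inserted bases in reference orientation (INS and the
#'   interspersed-duplication copy); empty otherwise.
#' @param src_ref,src_start,src_end Origin of the duplicated sequence for
#'   interspersed duplications; `NA` otherwise.
#' @param adj Breakend adjacency (see [bnd_adjacency()]), or `NULL`.
#' @param haplotype,origin,query_name,seg_len Provenance: haplotype label,
#'   evidence origin (`"intra"` or `"inter"`), source contig, and the query
#'   span of the shortest supporting alignment segment (used to pick
#'   deduplication representatives).
#' @return An object of class `sv_signature`.
#' @export
sv_signature <- function(sv_type, ref_name, start, end, sv_length,
                         alt_seq = "", src_ref = NA_character_,
                         src_start = NA_integer_, src_end = NA_integer_,
                         adj = NULL, haplotype = NA_integer_,
                         origin = "intra", query_name = NA_character_,
                         seg_len = NA_integer_) {
  stopifnot(sv_type %in% c("INS", "DEL", "INV", "DUP_TANDEM", "DUP_INT", "BND"))
  structure(list(
    sv_type = sv_type, ref_name = ref_name,
    start = as.integer(start), end = as.integer(end),
    sv_length = as.integer(sv_length), alt_seq = alt_seq,
    src_ref = src_ref, src_start = as.integer(src_start),
    src_end = as.integer(src_end), adj = adj,
    haplotype = as.integer(haplotype), origin = origin,
    query_name = query_name, seg_len = as.integer(seg_len)
  ), class = "sv_signature")
}

#' Construct a breakend adjacency
#'
#' One novel adjacency between two genomic loci, oriented. `side` is the side
#' of the base that is joined: `"right"` means the sequence continues past the
#' right edge of the base into the partner locus, `"left"` the mirror case.
#'
#' @param local_ref,local_pos,local_side Breakend locus of the record
#'   (`*_pos` is a 0-based base position).
#' @param mate_ref,mate_pos,mate_side The partner breakend.
#' @param canonical `TRUE` for the lexicographically first breakend of the
#'   adjacency; each adjacency has exactly one canonical side.
#' @return A list of class `bnd_adjacency`.
#' @export
bnd_adjacency <- function(local_ref, local_pos, local_side,
                          mate_ref, mate_pos, mate_side, canonical = TRUE) {
  stopifnot(local_side %in% c("left", "right"),
            mate_side %in% c("left", "right"))
  structure(list(
    local_ref = local_ref, local_pos = as.integer(local_pos),
    local_side = local_side,
    mate_ref = mate_ref, mate_pos = as.integer(mate_pos),
    mate_side = mate_side, canonical = isTRUE(canonical)
  ), class = "bnd_adjacency")
}

#' Extract signatures from gaps within a single alignment
#'
#' Walks the CIGAR of one segment and emits one deletion signature per `D`
#' operation and one insertion signature per `I` operation of at least
#' `min_sv_size` bp. Inserted bases are taken from the stored record sequence,
#' which SAM keeps in reference orientation, so no re-orientation is needed.
#'
#' @param segment An [alignment_segment()].
#' @param params An [sv_params()] object.
#' @return List of `sv_signature` objects.
#' @export
extract_intra_signatures <- function(segment, params = sv_params()) {
  sigs <- list()
  r <- segment$ref_start
  q <- 0L  # cursor into the stored sequence
  have_seq <- !is.na(segment$seq)
  span <- segment$query_end - segment$query_start
  for (k in seq_along(segment$ops)) {
    op <- segment$ops[k]
    len <- segment$lengths[k]
    if (op %in% c("M", "=", "X")) {
      r <- r + len; q <- q + len
    } else if (op == "S") {
      q <- q + len
    } else if (op == "I") {
      if (len >= params$min_sv_size) {
        alt <- if (have_seq) substr(segment$seq, q + 1L, q + len) else ""
        if (!have_seq) {
          warning("insertion without stored sequence in ", segment$query_name,
                  "; pairing will fall back to length comparison")
        }
        sigs[[length(sigs) + 1L]] <- sv_signature(
          "INS", segment$ref_name, r, r, len, alt_seq = alt,
          haplotype = segment$haplotype, origin = "intra",
          query_name = segment$query_name, seg_len = span
        )
      }
      q <- q + len
    } else if (op == "D") {
      if (len >= params$min_sv_size) {
        sigs[[length(sigs) + 1L]] <- sv_signature(
          "DEL", segment$ref_name, r, r + len, len,
          haplotype = segment$haplotype, origin = "intra",
          query_name = segment$query_name, seg_len = span
        )
      }
      r <- r + len
    }
    # H consumes neither cursor
  }
  sigs
}

# Breakend of a segment at its query-end side (where the contig continues
# into the next segment).
breakend_tail <- function(seg) {
  if (seg$strand == "+") {
    list(ref = seg$ref_name, pos = seg$ref_end - 1L, side = "right")
  } else {
    list(ref = seg$ref_name, pos = seg$ref_start, side = "left")
  }
}

# Breakend of a segment at its query-start side.
breakend_head <- function(seg) {
  if (seg$strand == "+") {
    list(ref = seg$ref_name, pos = seg$ref_start, side = "left")
  } else {
    list(ref = seg$ref_name, pos = seg$ref_end - 1L, side = "right")
  }
}

breakend_before <- function(b1, b2) {
  if (b1$ref != b2$ref) return(b1$ref < b2$ref)
  if (b1$pos != b2$pos) return(b1$pos < b2$pos)
  TRUE
}

# Reciprocal pair of BND signatures for the novel adjacency joining the tail
# of `a` to the head of `b` (in contig order).
bnd_pair <- function(a, b, seg_len) {
  ba <- breakend_tail(a)
  bb <- breakend_head(b)
  a_first <- breakend_before(ba, bb)
  mk <- function(loc, mate, canonical) {
    sv_signature(
      "BND", loc$ref, loc$pos, loc$pos, 0L,
      adj = bnd_adjacency(loc$ref, loc$pos, loc$side,
                          mate$ref, mate$pos, mate$side,
                          canonical = canonical),
      haplotype = a$haplotype, origin = "inter",
      query_name = a$query_name, seg_len = seg_len
    )
  }
  list(mk(ba, bb, a_first), mk(bb, ba, !a_first))
}

# Trim a small query overlap between consecutive segments symmetrically
# (midpoint convention). Returns list(a, b) or NULL when the overlap exceeds
# the tolerance.
trim_query_overlap <- function(a, b, q_tol) {
  o <- a$query_end - b$query_start
  if (o <= 0L) return(list(a = a, b = b))
  if (o > q_tol) return(NULL)
  da <- o %/% 2L
  db <- o - da
  a$query_end <- a$query_end - da
  if (a$strand == "+") a$ref_end <- a$ref_end - da else a$ref_start <- a$ref_start + da
  b$query_start <- b$query_start + db
  if (b$strand == "+") b$ref_start <- b$ref_start + db else b$ref_end <- b$ref_end - db
  list(a = a, b = b)
}

#' Classify the discordancy between two consecutive alignment segments
#'
#' Given two split-alignment segments of one contig, sorted by their position
#' on the contig, decides which structural variant (if any) the junction
#' between them encodes: a reference gap is a deletion, a contig gap an
#' insertion, both together a replacement (one of each), a reference overlap
#' a tandem duplication, an orientation switch or a long-range/interchromosomal
#' jump a reciprocal breakend pair. Concordant junctions yield nothing.
#'
#' @param a,b [alignment_segment()]s of the same contig with
#'   `a$query_start <= b$query_start`.
#' @param params An [sv_params()] object.
#' @param contig_seq Full forward-strand contig sequence, used to fill the
#'   inserted bases of insertion signatures; `NA` to fall back to empty
#'   sequences.
#' @return List of `sv_signature` objects (possibly empty).
#' @export
classify_segment_pair <- function(a, b, params = sv_params(),
                                  contig_seq = NA_character_) {
  stopifnot(a$query_name == b$query_name, a$query_start <= b$query_start)
  seg_len <- min(a$query_end - a$query_start, b$query_end - b$query_start)

  tr <- trim_query_overlap(a, b, params$query_gap_tolerance)
  if (is.null(tr)) return(list())
  a <- tr$a; b <- tr$b
  q_gap <- b$query_start - a$query_end

  # Different chromosomes: always a novel adjacency.
  if (a$ref_name != b$ref_name) return(bnd_pair(a, b, seg_len))
  # Orientation switch on one chromosome: breakends unless a surrounding
  # triple explains it as an inversion (the caller suppresses those pairs).
  if (a$strand != b$strand) return(bnd_pair(a, b, seg_len))

  fwd <- a$strand == "+"
  r_gap <- if (fwd) b$ref_start - a$ref_end else a$ref_start - b$ref_end
  if (abs(r_gap) > params$max_sv_size) return(bnd_pair(a, b, seg_len))

  sigs <- list()
  hap <- a$haplotype
  qn <- a$query_name
  # the insertion is anchored at the reference-left flank's end so that the
  # locus is invariant under reverse-complementing the contig
  ins_anchor <- if (fwd) a$ref_end else b$ref_end

  del_here <- r_gap >= params$min_sv_size &&
    (q_gap <= params$query_gap_tolerance || q_gap >= params$min_sv_size)
  ins_here <- q_gap >= params$min_sv_size &&
    (abs(r_gap) <= params$reference_gap_tolerance ||
       r_gap >= params$min_sv_size)

  if (del_here) {
    iv <- if (fwd) c(a$ref_end, b$ref_start) else c(b$ref_end, a$ref_start)
    sigs[[length(sigs) + 1L]] <- sv_signature(
      "DEL", a$ref_name, iv[1L], iv[2L], r_gap,
      haplotype = hap, origin = "inter", query_name = qn, seg_len = seg_len
    )
  }
  if (ins_here) {
    alt <- ""
    if (!is.na(contig_seq)) {
      alt <- substr(contig_seq, a$query_end + 1L, b$query_start)
      if (!fwd) alt <- revcomp(alt)
    } else {
      warning("insertion between split segments of ", qn,
              " without contig sequence; pairing will fall back to lengths")
    }
    sigs[[length(sigs) + 1L]] <- sv_signature(
      "INS", a$ref_name, ins_anchor, ins_anchor, q_gap, alt_seq = alt,
      haplotype = hap, origin = "inter", query_name = qn, seg_len = seg_len
    )
  }
  if (!del_here && !ins_here &&
      r_gap <= -params$min_sv_size &&
      q_gap <= params$query_gap_tolerance) {
    iv <- if (fwd) c(b$ref_start, a$ref_end) else c(a$ref_start, b$ref_end)
    sigs[[length(sigs) + 1L]] <- sv_signature(
      "DUP_TANDEM", a$ref_name, iv[1L], iv[2L], -r_gap,
      haplotype = hap, origin = "inter", query_name = qn, seg_len = seg_len
    )
  }
  sigs
}

# Forward-orientation triple geometry check. A and C must be "+" strand.
# Returns an sv_signature or NULL. `alt_fun(qs, qe, rc)` retrieves contig
# bases for the interspersed-duplication copy.
check_triple_forward <- function(A, B, C, params, alt_fun) {
  if (A$strand != "+" || C$strand != "+") return(NULL)
  if (A$ref_name != C$ref_name) return(NULL)
  q_tol <- params$query_gap_tolerance
  g1 <- B$query_start - A$query_end
  g2 <- C$query_start - B$query_end
  if (abs(g1) > q_tol || abs(g2) > q_tol) return(NULL)
  tol <- params$reference_gap_tolerance
  span_b <- B$query_end - B$query_start

  # (a) inverted middle segment filling the A..C reference gap
  if (B$strand == "-" && B$ref_name == A$ref_name &&
      abs(B$ref_start - A$ref_end) <= tol &&
      abs(C$ref_start - B$ref_end) <= tol &&
      B$ref_end - B$ref_start >= params$min_sv_size) {
    return(sv_signature(
      "INV", B$ref_name, B$ref_start, B$ref_end, B$ref_end - B$ref_start,
      haplotype = A$haplotype, origin = "inter", query_name = A$query_name,
      seg_len = min(A$query_end - A$query_start, span_b,
                    C$query_end - C$query_start)
    ))
  }

  # (b) collinear flanks with a distant middle segment: an interspersed
  # duplication whose copy was inserted at the A/C junction
  distant <- B$ref_name != A$ref_name ||
    B$ref_end <= A$ref_end - tol || B$ref_start >= C$ref_start + tol
  if (abs(C$ref_start - A$ref_end) <= tol && distant &&
      span_b >= params$min_sv_size) {
    alt <- alt_fun(B$query_start, B$query_end, B$strand == "-")
    return(sv_signature(
      "DUP_INT", A$ref_name, A$ref_end, A$ref_end, span_b, alt_seq = alt,
      src_ref = B$ref_name, src_start = B$ref_start, src_end = B$ref_end,
      haplotype = A$haplotype, origin = "inter", query_name = A$query_name,
      seg_len = min(A$query_end - A$query_start, span_b,
                    C$query_end - C$query_start)
    ))
  }
  NULL
}

#' Detect inversions and interspersed duplications from segment triples
#'
#' Scans consecutive triples (A, B, C) of the query-sorted split-alignment
#' segments of one contig. A middle segment on the opposite strand that fills
#' the reference gap between collinear flanks is an inversion; a middle
#' segment mapping to a distant locus between collinear, near-adjacent flanks
#' is an interspersed duplication inserted at the flank junction. Triples on
#' contigs aligned in reverse orientation are handled by mirroring the triple
#' onto the reverse-complemented contig.
#'
#' @param segments Query-sorted list of [alignment_segment()]s of one contig.
#' @param params An [sv_params()] object.
#' @param contig_seq Full forward-strand contig sequence or `NA`.
#' @return A list with `signatures` (list of `sv_signature`) and
#'   `consumed` (integer vector: index `i` means the pair of segments
#'   `(i, i+1)` is explained by a triple and must not be re-classified).
#' @export
analyze_segment_triples <- function(segments, params = sv_params(),
                                    contig_seq = NA_character_) {
  n <- length(segments)
  sigs <- list()
  consumed <- integer(0)
  if (n < 3L) return(list(signatures = sigs, consumed = consumed))

  alt_fun <- function(qs, qe, rc) {
    if (is.na(contig_seq)) return("")
    alt <- substr(contig_seq, qs + 1L, qe)
    if (rc) revcomp(alt) else alt
  }
  for (i in seq_len(n - 2L)) {
    A <- segments[[i]]; B <- segments[[i + 1L]]; C <- segments[[i + 2L]]
    if (A$strand == "+" && C$strand == "+") {
      hit <- check_triple_forward(A, B, C, params, alt_fun)
    } else if (A$strand == "-" && C$strand == "-") {
      # mirror onto the reverse-complemented contig; reference coordinates
      # (and therefore the resulting signature) are orientation-invariant,
      # but the copy sequence must be taken from the original B segment
      alt_fun_flipped <- function(qs, qe, rc) {
        alt_fun(B$query_start, B$query_end, B$strand == "-")
      }
      hit <- check_triple_forward(flip_segment(C), flip_segment(B),
                                  flip_segment(A), params, alt_fun_flipped)
      if (!is.null(hit)) {
        hit$haplotype <- A$haplotype
        hit$query_name <- A$query_name
      }
    } else {
      hit <- NULL
    }
    if (!is.null(hit)) {
      sigs[[length(sigs) + 1L]] <- hit
      consumed <- c(consumed, i, i + 1L)
    }
  }
  list(signatures = sigs, consumed = unique(consumed))
}

# Full forward-strand contig sequence, reconstructed from any record that
# stores the complete query (typically the soft-clipped primary alignment).
contig_forward_sequence <- function(segments) {
  for (seg in segments) {
    if (!is.na(seg$seq) && nchar(seg$seq) == seg$query_length) {
      return(if (seg$strand == "+") seg$seq else revcomp(seg$seq))
    }
  }
  NA_character_
}

#' Collect SV signatures from a stream of alignment segments
#'
#' Groups segments by contig, sorts each group along the contig and extracts
#' all intra-alignment (CIGAR gap) and inter-alignment (split segment)
#' signatures. Segment pairs explained by a surrounding triple (inversions,
#' interspersed duplications) are not re-classified.
#'
#' @param segments List of [alignment_segment()]s (any order).
#' @param params An [sv_params()] object.
#' @return List of `sv_signature` objects with haplotype labels propagated
#'   from the segments.
#' @export
collect_signatures <- function(segments, params = sv_params()) {
  if (length(segments) == 0L) return(list())
  qnames <- vapply(segments, function(s) s$query_name, character(1))
  out <- list()
  for (qn in unique(qnames)) {
    group <- segments[qnames == qn]
    ord <- order(vapply(group, function(s) s$query_start, integer(1)))
    group <- group[ord]
    contig_seq <- contig_forward_sequence(group)

    for (seg in group) {
      out <- c(out, extract_intra_signatures(seg, params))
    }
    tri <- analyze_segment_triples(group, params, contig_seq)
    out <- c(out, tri$signatures)
    if (length(group) >= 2L) {
      for (i in seq_len(length(group) - 1L)) {
        if (i %in% tri$consumed) next
        out <- c(out, classify_segment_pair(group[[i]], group[[i + 1L]],
                                            params, contig_seq))
      }
    }
  }
  out
}

#' Tabulate signatures or candidates
#'
#' @param x List of `sv_signature` or `sv_candidate` objects.
#' @return A `data.frame` with one row per element (adjacency and sequence
#'   detail columns flattened).
#' @export
sv_table <- function(x) {
  if (length(x) == 0L) {
    return(data.frame(sv_type = character(0), ref_name = character(0),
                      start = integer(0), end = integer(0),
                      sv_length = integer(0)))
  }
  grab <- function(f, mode) vapply(x, function(s) {
    v <- s[[f]]
    if (is.null(v)) v <- NA
    as(v, mode)
  }, vector(mode, 1))
  df <- data.frame(
    sv_type = grab("sv_type", "character"),
    ref_name = grab("ref_name", "character"),
    start = grab("start", "integer"),
    end = grab("end", "integer"),
    sv_length = grab("sv_length", "integer"),
    haplotype = grab("haplotype", "integer"),
    stringsAsFactors = FALSE
  )
  if (!is.null(x[[1L]]$genotype)) df$genotype <- grab("genotype", "character")
  df
}
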