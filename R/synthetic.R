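# Synthetic benchmarking genomes: a random reference, two haplotypes with
# implanted SVs of all six classes and controlled zygosity, the corresponding
# ideal gapped/split SAM alignments (constructed analytically, no aligner),
# and a truth-based evaluator.

#' Generate a random reference genome
#'
#' @param n_chroms Number of chromosomes (named `chr1` ... `chrN`).
#' @param chrom_length Length of each chromosome in bp.
#' @param seed Integer seed; the output is deterministic for a given seed.
#' @return A [Biostrings::DNAStringSet] with uniform base composition.
#' @export
generate_reference <- function(n_chroms = 2L, chrom_length = 250000L,
                               seed = 1L) {
  stopifnot(chrom_length > 0L, n_chroms >= 1L)
  set.seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  Biostrings::DNAStringSet(seqs)
}

#' Specify which SVs to implant
#'
#' @param sv_type Vector of SV classes (`"DEL"`, `"INS"`, `"INV"`,
#'   `"DUP_TANDEM"`, `"DUP_INT"`, `"BND"`).
#' @param count Events per class.
#' @param min_length,max_length Length range per class in bp (ignored for
#'   BND, which is a point adjacency).
#' @param prop_hom Fraction of events implanted homozygously; the rest are
#'   split evenly between the two haplotypes.
#' @return A `data.frame` consumed by [implant_svs()].
#' @export
sv_spec <- function(sv_type, count, min_length = 50L, max_length = 5000L,
                    prop_hom = 0.5) {
  data.frame(sv_type = sv_type, count = as.integer(count),
             min_length = as.integer(min_length),
             max_length = as.integer(max_length),
             prop_hom = prop_hom, stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Place event windows on the chromosomes: each event requests one or two
# windows (span + guard on both sides); windows never overlap. Entries of
# `fixed_chrom` that are not NA pin a window to a chromosome (used to put the
# two flanks of a translocation adjacency on different chromosomes).
place_windows <- function(chrom_lengths, widths, guard, fixed_chrom = NULL) {
  n_chrom <- length(chrom_lengths)
  if (is.null(fixed_chrom)) fixed_chrom <- rep(NA_integer_, length(widths))
  free <- which(is.na(fixed_chrom))
  assign_chrom <- fixed_chrom
  assign_chrom[free] <- sample(rep(seq_len(n_chrom), length.out = length(free)))
  starts <- integer(length(widths))
  for (ch in seq_len(n_chrom)) {
    idx <- which(assign_chrom == ch)
    if (!length(idx)) next
    idx <- sample(idx)  # random order along the chromosome
    w <- widths[idx] + 2L * guard
    usable <- chrom_lengths[ch] - 2L * guard
    slack <- usable - sum(w)
    if (slack < 0L) {
      stop("SV specification does not fit the genome: need ",
           sum(w), " bp on a ", chrom_lengths[ch], " bp chromosome")
    }
    gaps <- as.vector(stats::rmultinom(1L, slack, rep(1, length(w) + 1L)))
    pos <- guard + cumsum(gaps[seq_along(w)] + c(0L, w[-length(w)])) + guard
    starts[idx] <- as.integer(pos)
  }
  data.frame(chrom = assign_chrom, start = starts, width = widths)
}

#' Implant structural variants into two haplotypes
#'
#' Builds two haplotype genomes from a reference by applying each event to
#' both haplotypes (homozygous) or to exactly one (heterozygous). Deletions
#' remove the span, insertions add random bases, inversions
#' reverse-complement the span, tandem duplications append one extra copy in
#' place, interspersed duplications copy a distant source span to a new
#' anchor, and translocation breakends record a novel adjacency between two
#' chromosomes (realized later as a fusion contig by [emit_alignments()]).
#' Event loci are separated by at least `guard` bp. An optional per-haplotype
#' substitution rate adds allele divergence to stress cross-haplotype
#' pairing.
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @param spec A [sv_spec()] data frame.
#' @param seed Integer seed.
#' @param guard Minimum distance between implanted loci, bp.
#' @param mutation_rate Per-base substitution probability applied
#'   independently to each haplotype after implantation (so the expected
#'   between-haplotype divergence is about twice this rate).
#' @param bnd_flank Flank length in bp reserved on each side of a
#'   translocation adjacency (the fusion contig emitted by
#'   [emit_alignments()] covers these flanks).
#' @return List with `hap1`, `hap2` (named character vectors of haplotype
#'   chromosome sequences) and `truth` (a `data.frame` of truth records with
#'   0-based half-open reference coordinates).
#' @export
implant_svs <- function(reference, spec, seed = 1L, guard = 500L,
                        mutation_rate = 0, bnd_flank = 2000L) {
  set.seed(seed + 1L)
  ref <- as.character(reference)
  chrom_names <- names(ref)
  chrom_lengths <- nchar(ref)

  types <- rep(spec$sv_type, spec$count)
  if (any(types == "BND") && length(chrom_names) < 2L) {
    stop("translocation adjacencies require at least two chromosomes")
  }
  lens <- unlist(Map(function(t, c, lo, hi) {
    if (t == "BND") rep(0L, c)
    else lo + sample.int(hi - lo + 1L, c, replace = TRUE) - 1L
  }, spec$sv_type, spec$count, spec$min_length, spec$max_length))
  prop_hom <- rep(spec$prop_hom, spec$count)
  n <- length(types)
  if (n == 0L) {
    return(list(hap1 = ref, hap2 = ref,
                truth = empty_truth()))
  }
  zyg <- ifelse(stats::runif(n) < prop_hom, "hom",
                ifelse(stats::runif(n) < 0.5, "het_hap1", "het_hap2"))

  # window widths on the reference: INS and DUP_INT anchors occupy (almost)
  # no reference span; BND endpoints reserve the fusion-contig flank
  width_main <- ifelse(types %in% c("DEL", "INV", "DUP_TANDEM"), lens,
                       ifelse(types == "BND", bnd_flank, 1L))
  extra_types <- types %in% c("DUP_INT", "BND")
  width_extra <- ifelse(types == "DUP_INT", lens, bnd_flank)[extra_types]
  # pin the two flanks of each adjacency to different chromosomes
  is_bnd <- types == "BND"
  fixed_main <- rep(NA_integer_, n)
  fixed_main[is_bnd] <- rep_len(seq_along(chrom_names), sum(is_bnd))
  fixed_extra <- rep(NA_integer_, sum(extra_types))
  fixed_extra[types[extra_types] == "BND"] <-
    (fixed_main[is_bnd] %% length(chrom_names)) + 1L
  wins <- place_windows(chrom_lengths, c(width_main, width_extra), guard,
                        fixed_chrom = c(fixed_main, fixed_extra))
  main <- wins[seq_len(n), ]
  extra <- wins[-seq_len(n), , drop = FALSE]

  truth <- empty_truth()
  ei <- 0L
  for (i in seq_len(n)) {
    chrom <- chrom_names[main$chrom[i]]
    s <- main$start[i]
    rec <- data.frame(
      sv_type = types[i], ref_name = chrom, start = s, end = s,
      sv_length = lens[i], zygosity = zyg[i], alt_seq = "",
      src_ref = NA_character_, src_start = NA_integer_,
      src_end = NA_integer_, mate_ref = NA_character_,
      mate_pos = NA_integer_, stringsAsFactors = FALSE
    )
    if (types[i] %in% c("DEL", "INV", "DUP_TANDEM")) {
      rec$end <- s + lens[i]
    } else if (types[i] == "INS") {
      rec$alt_seq <- random_dna(lens[i])
    } else if (types[i] == "DUP_INT") {
      ei <- ei + 1L
      src_chrom <- chrom_names[extra$chrom[ei]]
      ss <- extra$start[ei]
      rec$src_ref <- src_chrom
      rec$src_start <- ss
      rec$src_end <- ss + lens[i]
      rec$alt_seq <- substr(ref[[src_chrom]], ss + 1L, ss + lens[i])
    } else if (types[i] == "BND") {
      ei <- ei + 1L
      # local flank covers [start, start + flank); the breakend is the last
      # flank base, joined on its right side to the left side of the mate
      rec$start <- s + bnd_flank - 1L
      rec$end <- rec$start
      rec$mate_ref <- chrom_names[extra$chrom[ei]]
      rec$mate_pos <- extra$start[ei]
    }
    truth <- rbind(truth, rec)
  }

  apply_events <- function(hap_id) {
    seqs <- ref
    carried <- truth$zygosity == "hom" |
      truth$zygosity == paste0("het_hap", hap_id)
    ev <- truth[carried & truth$sv_type != "BND", , drop = FALSE]
    for (chrom in chrom_names) {
      evc <- ev[ev$ref_name == chrom, , drop = FALSE]
      if (!nrow(evc)) next
      evc <- evc[order(-evc$start), , drop = FALSE]  # splice right to left
      x <- seqs[[chrom]]
      for (k in seq_len(nrow(evc))) {
        e <- evc[k, ]
        left <- substr(x, 1L, e$start)
        right <- substr(x, e$end + 1L, nchar(x))
        mid <- switch(e$sv_type,
          DEL = "",
          INS = e$alt_seq,
          INV = revcomp(substr(x, e$start + 1L, e$end)),
          DUP_TANDEM = paste0(substr(x, e$start + 1L, e$end),
                              substr(x, e$start + 1L, e$end)),
          DUP_INT = e$alt_seq  # inserted at the anchor (start == end)
        )
        x <- paste0(left, mid, right)
      }
      seqs[[chrom]] <- x
    }
    seqs
  }
  hap1 <- apply_events(1L)
  hap2 <- apply_events(2L)

  if (mutation_rate > 0) {
    mutate <- function(seqs) {
      vapply(seqs, function(x) {
        n_mut <- stats::rbinom(1L, nchar(x), mutation_rate)
        if (n_mut == 0L) return(x)
        pos <- sample.int(nchar(x), n_mut)
        chars <- strsplit(x, "", fixed = TRUE)[[1L]]
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        }
        paste(chars, collapse = "")
      }, character(1))
    }
    hap1 <- mutate(hap1)
    hap2 <- mutate(hap2)
  }

  list(hap1 = hap1, hap2 = hap2, truth = truth)
}

empty_truth <- function() {
  data.frame(sv_type = character(0), ref_name = character(0),
             start = integer(0), end = integer(0), sv_length = integer(0),
             zygosity = character(0), alt_seq = character(0),
             src_ref = character(0), src_start = integer(0),
             src_end = integer(0), mate_ref = character(0),
             mate_pos = integer(0), stringsAsFactors = FALSE)
}
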