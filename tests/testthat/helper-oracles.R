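# Independent oracles and fixture shortcuts used across the test files.

# Quadratic dynamic-programming Levenshtein distance, row-vectorized with the
# prefix-minimum unrolling of the horizontal (insertion) transitions.
lev_dp_oracle <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(A)
  n <- length(B)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n
  idx <- 0:n
  for (i in 1:m) {
    sub <- prev[1:n] + (A[i] != B)
    del <- prev[2:(n + 1)] + 1L
    full <- c(i, pmin(sub, del))
    prev <- cummin(full - idx) + idx
  }
  prev[n + 1L]
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Alignment segment with convenient defaults for geometry-only tests.
make_seg <- function(ref = "chr1", rs, re, qs, qe, strand = "+",
                     qn = "ctg1", qlen = max(qe, 2000L),
                     seq = NA_character_, hap = 1L,
                     ops = "M", lens = qe - qs) {
  alignment_segment(
    query_name = qn, ref_name = ref, ref_start = rs, ref_end = re,
    query_start = qs, query_end = qe, query_length = qlen,
    strand = strand, ops = ops, lengths = lens, seq = seq, haplotype = hap
  )
}

# Exhaustive maximum matching between two signature lists: returns the
# maximum number of cross-haplotype pairs under signature_similarity, found
# by enumerating all injective assignments. Only feasible for tiny inputs.
brute_force_max_pairs <- function(hap1, hap2, params = sv_params()) {
  n1 <- length(hap1)
  n2 <- length(hap2)
  ok <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      ok[i, j] <- signature_similarity(hap1[[i]], hap2[[j]], params)$candidate
    }
  }
  best <- 0L
  recurse <- function(i, used2, count) {
    if (i > n1) {
      best <<- max(best, count)
      return(invisible(NULL))
    }
    recurse(i + 1L, used2, count)  # leave i unmatched
    for (j in seq_len(n2)) {
      if (!used2[j] && ok[i, j]) {
        used2[j] <- TRUE
        recurse(i + 1L, used2, count + 1L)
        used2[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n2), 0L)
  best
}

# Random CIGAR with clips only at the ends and at least one M op.
random_cigar <- function() {
  n_inner <- sample(1:6, 1)
  inner_ops <- sample(c("M", "I", "D"), n_inner, replace = TRUE)
  inner_ops[sample(n_inner, 1)] <- "M"  # ensure an aligned op
  ops <- inner_ops
  lens <- sample(1:200, n_inner, replace = TRUE)
  if (stats::runif(1) < 0.6) {
    ops <- c(sample(c("S", "H"), 1), ops)
    lens <- c(sample(1:100, 1), lens)
  }
  if (stats::runif(1) < 0.6) {
    ops <- c(ops, sample(c("S", "H"), 1))
    lens <- c(lens, sample(1:100, 1))
  }
  list(ops = ops, lens = as.integer(lens))
}

# Parse a VCF breakend ALT string into its components.
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^([ACGTN]*)([][])([^:]+):([0-9]+)([][])([ACGTN]*)$", alt))[[1L]]
  stopifnot(length(m) == 7L, m[3] == m[6])
  t_before <- nzchar(m[2])
  list(
    t = if (t_before) m[2] else m[7],
    local_side = if (t_before) "right" else "left",
    mate_ref = m[4],
    mate_pos1 = as.integer(m[5]),
    mate_side = if (m[3] == "[") "left" else "right"
  )
}

# Standard mixed-class benchmark fixture shared by the integration tests.
standard_fixture_spec <- function() {
  rbind(
    sv_spec("DEL", 30), sv_spec("INS", 30), sv_spec("INV", 6),
    sv_spec("DUP_TANDEM", 6), sv_spec("DUP_INT", 4), sv_spec("BND", 4)
  )
}
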