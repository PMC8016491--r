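# COLLECT: intra-alignment gaps, split-segment pairs and triples.

test_that("CIGAR gaps below the size threshold produce no signatures", {
  seg <- make_seg(rs = 0, re = 100, qs = 0, qe = 100, qlen = 100,
                  ops = "M", lens = 100L, seq = random_dna_str(100))
  expect_length(extract_intra_signatures(seg), 0)
})

test_that("a long D operation becomes a deletion at the walked locus", {
  seg <- make_seg(rs = 1000, re = 1175, qs = 0, qe = 100, qlen = 100,
                  ops = c("M", "D", "M"), lens = c(50L, 75L, 50L),
                  seq = random_dna_str(100))
  sigs <- extract_intra_signatures(seg, sv_params(min_sv_size = 40))
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$sv_type, "DEL")
  expect_equal(sigs[[1]]$start, 1050)
  expect_equal(sigs[[1]]$end, 1125)
  expect_equal(sigs[[1]]$sv_length, 75)
})

test_that("sub-threshold gaps are filtered while long insertions are kept", {
  seq <- random_dna_str(170)
  seg <- make_seg(rs = 0, re = 140, qs = 0, qe = 170, qlen = 170,
                  ops = c("M", "I", "M", "D", "M"),
                  lens = c(50L, 60L, 50L, 30L, 10L), seq = seq)
  sigs <- extract_intra_signatures(seg, sv_params(min_sv_size = 40))
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$sv_type, "INS")
  expect_equal(sigs[[1]]$start, 50)
  expect_equal(sigs[[1]]$end, 50)
  # inserted bases are the stored-sequence slice after the first match
  expect_equal(sigs[[1]]$alt_seq, substr(seq, 51, 110))
})

test_that("an insertion op without stored sequence warns and degrades", {
  seg <- make_seg(rs = 0, re = 100, qs = 0, qe = 160, qlen = 160,
                  ops = c("M", "I", "M"), lens = c(50L, 60L, 50L))
  expect_warning(sigs <- extract_intra_signatures(seg), "without stored")
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$alt_seq, "")
  expect_equal(sigs[[1]]$sv_length, 60)
})

test_that("concordant split segments yield nothing", {
  a <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000)
  b <- make_seg(rs = 2000, re = 3000, qs = 1000, qe = 2000)
  expect_length(classify_segment_pair(a, b), 0)
})

test_that("a reference gap between split segments is a deletion", {
  a <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000)
  b <- make_seg(rs = 2500, re = 3000, qs = 1005, qe = 1505)
  sigs <- classify_segment_pair(a, b, sv_params(min_sv_size = 40,
                                                query_gap_tolerance = 50))
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$sv_type, "DEL")
  expect_equal(c(sigs[[1]]$start, sigs[[1]]$end), c(2000, 2500))
  expect_equal(sigs[[1]]$sv_length, 500)
})

test_that("a reference overlap between split segments is a tandem duplication", {
  a <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000)
  b <- make_seg(rs = 1700, re = 2600, qs = 1010, qe = 1910)
  sigs <- classify_segment_pair(a, b, sv_params(min_sv_size = 40))
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$sv_type, "DUP_TANDEM")
  expect_equal(c(sigs[[1]]$start, sigs[[1]]$end), c(1700, 2000))
  expect_equal(sigs[[1]]$sv_length, 300)
})

test_that("a query gap between split segments is an insertion with contig bases", {
  contig <- random_dna_str(2100)
  a <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000, qlen = 2100)
  b <- make_seg(rs = 2000, re = 3000, qs = 1100, qe = 2100, qlen = 2100)
  sigs <- classify_segment_pair(a, b, contig_seq = contig)
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$sv_type, "INS")
  expect_equal(sigs[[1]]$start, 2000)
  expect_equal(sigs[[1]]$alt_seq, substr(contig, 1001, 1100))
})

test_that("simultaneous reference and query gaps are a replacement (DEL + INS)", {
  a <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000, qlen = 2100)
  b <- make_seg(rs = 2200, re = 3000, qs = 1100, qe = 1900, qlen = 2100)
  sigs <- classify_segment_pair(a, b, contig_seq = random_dna_str(2100))
  types <- sort(vapply(sigs, function(s) s$sv_type, character(1)))
  expect_equal(types, c("DEL", "INS"))
})

test_that("an interchromosomal junction yields a reciprocal breakend pair", {
  a <- make_seg(ref = "chr1", rs = 1000, re = 2000, qs = 0, qe = 1000)
  b <- make_seg(ref = "chr5", rs = 500, re = 1400, qs = 1000, qe = 1900)
  sigs <- classify_segment_pair(a, b)
  expect_length(sigs, 2)
  expect_true(all(vapply(sigs, function(s) s$sv_type, character(1)) == "BND"))
  adj <- lapply(sigs, `[[`, "adj")
  # mates are mutual reciprocals
  expect_equal(adj[[1]]$local_pos, adj[[2]]$mate_pos)
  expect_equal(adj[[1]]$mate_pos, adj[[2]]$local_pos)
  expect_equal(adj[[1]]$local_side, adj[[2]]$mate_side)
  # exactly one canonical side per adjacency
  expect_equal(sum(vapply(adj, function(a) a$canonical, logical(1))), 1L)
  # geometry: tail of a (chr1:1999, right) joined to head of b (chr5:500, left)
  can <- adj[[which(vapply(adj, function(a) a$canonical, logical(1)))]]
  expect_equal(can$local_ref, "chr1")
  expect_equal(can$local_pos, 1999)
  expect_equal(can$local_side, "right")
  expect_equal(can$mate_ref, "chr5")
  expect_equal(can$mate_pos, 500)
  expect_equal(can$mate_side, "left")
})

test_that("pair classification is invariant under contig reverse-complement", {
  set.seed(21)
  scenarios <- list(
    list(rs2 = 2500, qs2 = 1005),  # deletion
    list(rs2 = 1700, qs2 = 1010),  # tandem duplication
    list(rs2 = 2010, qs2 = 1100)   # insertion
  )
  for (sc in scenarios) {
    qlen <- 2000L
    a <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000, qlen = qlen)
    b <- make_seg(rs = sc$rs2, re = sc$rs2 + 500L,
                  qs = sc$qs2, qe = sc$qs2 + 500L, qlen = qlen)
    # without a contig sequence the insertion scenario warns about the
    # length-comparison fallback; only the geometry matters here
    fwd <- suppressWarnings(classify_segment_pair(a, b))
    # mirror both segments onto the reverse-complemented contig and swap
    fa <- contigsv:::flip_segment(b)
    fb <- contigsv:::flip_segment(a)
    rev <- suppressWarnings(classify_segment_pair(fa, fb))
    key <- function(sigs) {
      df <- sv_table(sigs)
      df[order(df$sv_type, df$start), c("sv_type", "start", "end", "sv_length")]
    }
    expect_equal(key(fwd), key(rev), ignore_attr = TRUE)
  }
})

test_that("an inverted middle segment between collinear flanks is an inversion", {
  A <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000, qlen = 2000)
  B <- make_seg(rs = 2000, re = 2500, qs = 1000, qe = 1500, strand = "-",
                qlen = 2000)
  C <- make_seg(rs = 2500, re = 3000, qs = 1500, qe = 2000, qlen = 2000)
  res <- analyze_segment_triples(list(A, B, C))
  expect_length(res$signatures, 1)
  s <- res$signatures[[1]]
  expect_equal(s$sv_type, "INV")
  expect_equal(c(s$start, s$end, s$sv_length), c(2000, 2500, 500))
  expect_setequal(res$consumed, c(1L, 2L))
})

test_that("a distant middle segment between adjacent flanks is an interspersed duplication", {
  A <- make_seg(ref = "chr1", rs = 1000, re = 2000, qs = 0, qe = 1000,
                qlen = 2600)
  B <- make_seg(ref = "chr7", rs = 9000, re = 9600, qs = 1000, qe = 1600,
                qlen = 2600)
  C <- make_seg(ref = "chr1", rs = 2000, re = 3000, qs = 1600, qe = 2600,
                qlen = 2600)
  contig <- random_dna_str(2600)
  res <- analyze_segment_triples(list(A, B, C), contig_seq = contig)
  expect_length(res$signatures, 1)
  s <- res$signatures[[1]]
  expect_equal(s$sv_type, "DUP_INT")
  expect_equal(s$start, 2000)
  expect_equal(s$sv_length, 600)
  expect_equal(c(s$src_ref, s$src_start, s$src_end),
               c("chr7", "9000", "9600"))
  expect_equal(s$alt_seq, substr(contig, 1001, 1600))
})

test_that("collinear triples are concordant", {
  A <- make_seg(rs = 1000, re = 2000, qs = 0, qe = 1000, qlen = 3000)
  B <- make_seg(rs = 2000, re = 2500, qs = 1000, qe = 1500, qlen = 3000)
  C <- make_seg(rs = 2500, re = 3000, qs = 1500, qe = 2000, qlen = 3000)
  res <- analyze_segment_triples(list(A, B, C))
  expect_length(res$signatures, 0)
  expect_length(res$consumed, 0)
})

test_that("collect combines intra and inter evidence per contig", {
  expect_length(collect_signatures(list()), 0)

  seg <- make_seg(rs = 0, re = 1100, qs = 0, qe = 1000, qlen = 1000,
                  ops = c("M", "D", "M"), lens = c(500L, 100L, 500L),
                  seq = random_dna_str(1000))
  sigs <- collect_signatures(list(seg))
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$sv_type, "DEL")

  # a contig with one implanted inversion plus an 80 bp gapped deletion
  ref <- generate_reference(1, 30000, seed = 9)
  spec <- rbind(sv_spec("INV", 1, 500, 500, prop_hom = 1),
                sv_spec("DEL", 1, 80, 80, prop_hom = 1))
  imp <- implant_svs(ref, spec, seed = 9)
  path <- tempfile(fileext = ".sam")
  writeLines(emit_alignments(imp$hap1, imp$truth, ref, 1, style = "gapped"),
             path)
  sigs <- collect_signatures(read_alignments(path, 1L))
  types <- sort(vapply(sigs, function(s) s$sv_type, character(1)))
  expect_equal(types, c("DEL", "INV"))
  # exact loci and lengths against the truth table
  tab <- sv_table(sigs)
  truth <- imp$truth[order(imp$truth$sv_type), ]
  tab <- tab[order(tab$sv_type), ]
  expect_equal(tab$start, truth$start)
  expect_equal(tab$sv_length, truth$sv_length)
})

test_that("signature intervals stay within the reference bounds", {
  ref <- generate_reference(2, 40000, seed = 13)
  spec <- rbind(sv_spec("DEL", 3, 100, 800), sv_spec("INS", 3, 100, 800),
                sv_spec("INV", 2, 200, 800), sv_spec("DUP_TANDEM", 2, 200, 800))
  imp <- implant_svs(ref, spec, seed = 13)
  path <- tempfile(fileext = ".sam")
  writeLines(emit_alignments(imp$hap1, imp$truth, ref, 1, style = "split"),
             path)
  sigs <- collect_signatures(read_alignments(path, 1L))
  lens <- setNames(Biostrings::width(ref), names(ref))
  for (s in sigs) {
    expect_gte(s$start, 0)
    expect_lte(s$end, lens[[s$ref_name]])
  }
})
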