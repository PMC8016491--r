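# Synthetic genome generation, implantation bookkeeping, alignment emission
# and the truth-based evaluator.

test_that("reference generation is deterministic with uniform composition", {
  a <- generate_reference(1, 1000, seed = 7)
  b <- generate_reference(1, 1000, seed = 7)
  expect_identical(as.character(a), as.character(b))

  two <- generate_reference(2, 50000, seed = 3)
  expect_equal(unname(Biostrings::width(two)), c(50000, 50000))
  expect_equal(names(two), c("chr1", "chr2"))

  big <- generate_reference(1, 100000, seed = 1)
  freq <- Biostrings::alphabetFrequency(big[[1]])[c("A", "C", "G", "T")]
  expect_true(all(abs(freq / 100000 - 0.25) < 0.05))
})

test_that("implantation bookkeeping preserves sequence lengths", {
  ref <- generate_reference(1, 10000, seed = 17)

  imp <- implant_svs(ref, sv_spec("DEL", 0)[0, ], seed = 17)
  expect_identical(imp$hap1, as.character(ref))
  expect_equal(nrow(imp$truth), 0)

  imp <- implant_svs(ref, sv_spec("DEL", 1, 100, 100, prop_hom = 1), seed = 17)
  expect_equal(nchar(imp$hap1[["chr1"]]), 9900)
  expect_equal(nchar(imp$hap2[["chr1"]]), 9900)

  imp <- implant_svs(ref, sv_spec("INS", 8, 60, 60, prop_hom = 0), seed = 17,
                     guard = 200L)
  n1 <- sum(imp$truth$zygosity == "het_hap1")
  n2 <- sum(imp$truth$zygosity == "het_hap2")
  expect_equal(nchar(imp$hap1[["chr1"]]), 10000 + 60 * n1)
  expect_equal(nchar(imp$hap2[["chr1"]]), 10000 + 60 * n2)

  # inversions and tandem duplications change length by 0 and +len
  imp <- implant_svs(ref, rbind(sv_spec("INV", 1, 300, 300, prop_hom = 1),
                                sv_spec("DUP_TANDEM", 1, 200, 200, prop_hom = 1)),
                     seed = 18)
  expect_equal(nchar(imp$hap1[["chr1"]]), 10200)
})

test_that("homozygous events hit both haplotypes at identical loci", {
  ref <- generate_reference(1, 20000, seed = 19)
  imp <- implant_svs(ref, sv_spec("DEL", 3, 100, 200, prop_hom = 1), seed = 19)
  expect_true(all(imp$truth$zygosity == "hom"))
  expect_identical(imp$hap1, imp$hap2)
})

test_that("an infeasible specification is a fatal configuration error", {
  ref <- generate_reference(1, 5000, seed = 23)
  expect_error(implant_svs(ref, sv_spec("DEL", 10, 2000, 3000), seed = 23),
               "does not fit")
})

test_that("a no-SV genome emits one perfect match record per contig", {
  ref <- generate_reference(2, 8000, seed = 29)
  imp <- implant_svs(ref, sv_spec("DEL", 0)[0, ], seed = 29)
  lines <- emit_alignments(imp$hap1, imp$truth, ref, 1)
  body <- grep("^[^@]", lines, value = TRUE)
  expect_length(body, 2)
  cig <- vapply(strsplit(body, "\t"), `[`, character(1), 6L)
  expect_equal(cig, c("8000M", "8000M"))
})

test_that("a gapped deletion is encoded as an M-D-M CIGAR", {
  ref <- generate_reference(1, 10000, seed = 31)
  imp <- implant_svs(ref, sv_spec("DEL", 1, 75, 75, prop_hom = 1), seed = 31)
  for (hap in 1:2) {
    seqs <- if (hap == 1) imp$hap1 else imp$hap2
    lines <- emit_alignments(seqs, imp$truth, ref, hap, style = "gapped")
    body <- grep("^[^@]", lines, value = TRUE)
    expect_length(body, 1)
    cig <- strsplit(body, "\t")[[1]][6]
    expect_match(cig, "^[0-9]+M75D[0-9]+M$")
  }
})

test_that("a heterozygous inversion splits only the carrier haplotype", {
  ref <- generate_reference(1, 20000, seed = 37)
  imp <- implant_svs(ref, sv_spec("INV", 1, 500, 500, prop_hom = 0), seed = 37)
  carrier <- as.integer(sub("het_hap", "", imp$truth$zygosity[1]))
  other <- 3L - carrier
  seqs <- list(imp$hap1, imp$hap2)
  lines_c <- emit_alignments(seqs[[carrier]], imp$truth, ref, carrier,
                             style = "split")
  lines_o <- emit_alignments(seqs[[other]], imp$truth, ref, other,
                             style = "split")
  body_c <- grep("^[^@]", lines_c, value = TRUE)
  body_o <- grep("^[^@]", lines_o, value = TRUE)
  expect_length(body_c, 3)
  expect_length(body_o, 1)
  flags <- as.integer(vapply(strsplit(body_c, "\t"), `[`, character(1), 2L))
  expect_equal(sum(bitwAnd(flags, 16L) > 0L), 1L)  # one reverse-strand segment
})

test_that("emitted alignments reconstruct the haplotype exactly (CIGAR-apply oracle)", {
  ref <- generate_reference(1, 30000, seed = 41)
  spec <- rbind(sv_spec("DEL", 2, 100, 400, prop_hom = 1),
                sv_spec("INS", 2, 100, 400, prop_hom = 1))
  imp <- implant_svs(ref, spec, seed = 41)
  path <- tempfile(fileext = ".sam")
  writeLines(emit_alignments(imp$hap1, imp$truth, ref, 1, style = "gapped"),
             path)
  segs <- read_alignments(path, 1L)
  expect_length(segs, 1)
  s <- segs[[1]]
  # walk the CIGAR: M stretches must equal the reference, and the stored
  # sequence must be the haplotype chromosome
  expect_equal(s$seq, imp$hap1[["chr1"]])
  refc <- as.character(ref[[1]])
  r <- s$ref_start
  q <- 0L
  for (k in seq_along(s$ops)) {
    op <- s$ops[k]
    len <- s$lengths[k]
    if (op == "M") {
      expect_equal(substr(s$seq, q + 1, q + len), substr(refc, r + 1, r + len))
      r <- r + len
      q <- q + len
    } else if (op == "D") {
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
  }
  expect_equal(r, s$ref_end)
})

test_that("contig cutting produces multiple round-trippable contigs", {
  ref <- generate_reference(1, 60000, seed = 43)
  spec <- sv_spec("DEL", 4, 100, 300, prop_hom = 1)
  imp <- implant_svs(ref, spec, seed = 43)
  path <- tempfile(fileext = ".sam")
  writeLines(emit_alignments(imp$hap1, imp$truth, ref, 1, style = "gapped",
                             contig_length = 15000), path)
  segs <- read_alignments(path, 1L)
  expect_gt(length(unique(vapply(segs, function(s) s$query_name,
                                 character(1)))), 1)
  sigs <- collect_signatures(read_alignments(path, 1L))
  ev <- evaluate_calls(signatures_to_candidates(sigs), imp$truth)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
})

test_that("the evaluator computes the closed-form metrics", {
  ref <- generate_reference(1, 50000, seed = 47)
  imp <- implant_svs(ref, sv_spec("DEL", 10, 100, 300, prop_hom = 1),
                     seed = 47)
  truth <- imp$truth
  mk_call <- function(row, genotype = "hom_alt") {
    sv_candidate(sv_signature(row$sv_type, row$ref_name, row$start, row$end,
                              row$sv_length), genotype)
  }
  calls <- lapply(seq_len(nrow(truth)), function(i) mk_call(truth[i, ]))

  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$f1, 1.0)
  expect_equal(ev$gt_concordance, 1.0)

  ev <- evaluate_calls(list(), truth)
  expect_equal(ev$recall, 0)
  expect_equal(ev$precision, 0)
  expect_true(ev$zero_denominator)

  # 8 of 10 truth events called plus 1 spurious call
  spurious <- sv_candidate(
    sv_signature("DEL", "chr1", 49000, 49100, 100), "het")
  ev <- evaluate_calls(c(calls[1:8], list(spurious)), truth)
  expect_equal(ev$precision, 8 / 9)
  expect_equal(ev$recall, 8 / 10)
  expect_equal(ev$f1, 2 * (8 / 9) * (8 / 10) / ((8 / 9) + (8 / 10)))
})
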