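# Truth-based evaluation of SV calls: a simple position+length matcher in the
# spirit of standard SV benchmarking, with genotype concordance among true
# positives.

# Canonical unordered endpoint representation of an adjacency.
adjacency_endpoints <- function(ref1, pos1, side1, ref2, pos2, side2) {
  if (ref1 < ref2 || (ref1 == ref2 && pos1 <= pos2)) {
    list(r1 = ref1, p1 = pos1, s1 = side1, r2 = ref2, p2 = pos2, s2 = side2)
  } else {
    list(r1 = ref2, p1 = pos2, s1 = side2, r2 = ref1, p2 = pos1, s2 = side1)
  }
}

match_one <- function(call, tr, position_tolerance, length_tolerance_fraction) {
  if (call$sv_type != tr$sv_type) return(FALSE)
  if (call$sv_type == "BND") {
    a <- call$adj
    if (is.null(a)) return(FALSE)
    ce <- adjacency_endpoints(a$local_ref, a$local_pos, a$local_side,
                              a$mate_ref, a$mate_pos, a$mate_side)
    te <- adjacency_endpoints(tr$ref_name, tr$start, "right",
                              tr$mate_ref, tr$mate_pos, "left")
    return(ce$r1 == te$r1 && ce$r2 == te$r2 &&
             ce$s1 == te$s1 && ce$s2 == te$s2 &&
             abs(ce$p1 - te$p1) <= position_tolerance &&
             abs(ce$p2 - te$p2) <= position_tolerance)
  }
  if (call$ref_name != tr$ref_name) return(FALSE)
  if (abs(call$start - tr$start) > position_tolerance) return(FALSE)
  denom <- max(call$sv_length, tr$sv_length, 1L)
  abs(call$sv_length - tr$sv_length) / denom <= length_tolerance_fraction
}

#' Score SV calls against a truth set
#'
#' Greedy one-to-one matching of calls to truth records: a call matches a
#' truth record of the same type on the same chromosome when their positions
#' differ by at most `position_tolerance` bp and their lengths agree within
#' `length_tolerance_fraction` (relative to the longer). Breakends are matched
#' by both adjacency endpoints and orientations. Genotype concordance is
#' computed among true positives with an estimated genotype (`hom_alt`
#' against homozygous truth, `het` against either heterozygous truth label).
#'
#' @param calls List of [sv_candidate()]s.
#' @param truth Truth `data.frame` from [implant_svs()].
#' @param position_tolerance Maximum breakpoint offset in bp.
#' @param length_tolerance_fraction Maximum relative length difference.
#' @return List with counts (`tp`, `fp`, `fn`), `precision`, `recall`, `f1`,
#'   `gt_concordance` (`NA` when no true positive carries a genotype), and
#'   `zero_denominator` flagging empty call or truth sets.
#' @export
evaluate_calls <- function(calls, truth, position_tolerance = 10L,
                           length_tolerance_fraction = 0.3) {
  n_calls <- length(calls)
  n_truth <- if (is.null(truth)) 0L else nrow(truth)
  matched_truth <- rep(FALSE, n_truth)
  tp <- 0L
  gt_total <- 0L
  gt_correct <- 0L
  for (call in calls) {
    hit <- 0L
    best <- Inf
    for (t in which(!matched_truth)) {
      tr <- truth[t, ]
      if (match_one(call, tr, position_tolerance,
                    length_tolerance_fraction)) {
        d <- abs(call$start - tr$start)
        if (d < best) { best <- d; hit <- t }
      }
    }
    if (hit > 0L) {
      matched_truth[hit] <- TRUE
      tp <- tp + 1L
      if (!is.null(call$genotype) && call$genotype != "unknown") {
        gt_total <- gt_total + 1L
        zyg <- truth$zygosity[hit]
        ok <- (call$genotype == "hom_alt" && zyg == "hom") ||
          (call$genotype == "het" && zyg %in% c("het_hap1", "het_hap2"))
        if (ok) gt_correct <- gt_correct + 1L
      }
    }
  }
  fp <- n_calls - tp
  fn <- n_truth - tp
  precision <- if (n_calls > 0L) tp / n_calls else 0
  recall <- if (n_truth > 0L) tp / n_truth else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    gt_concordance = if (gt_total > 0L) gt_correct / gt_total else NA_real_,
    n_calls = n_calls, n_truth = n_truth,
    zero_denominator = n_calls == 0L || n_truth == 0L
  )
}
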