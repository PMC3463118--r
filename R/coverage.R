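# Optimal Query Coverage (OQC) and Filter By Similarity (FBS): selection of
# the primary alignment set along the query and of similar secondaries.

#' OQC parameters
#'
#' @param BP Breakpoint penalty in score units, charged once per split
#'   between consecutive primary alignments, multiplied by the genomic
#'   distance penalty (GDP).
#' @param maxGDP Cap on the GDP factor; alignments on different reference
#'   sequences always incur `maxGDP`.
#' @param enabled When `FALSE`, OQC is bypassed and all alignments are
#'   reported (see [report_all_mode()]).
#' @return An object of class `oqc_params`.
#' @export
oqc_params <- function(BP = 5, maxGDP = 5, enabled = TRUE) {
  if (BP < 0 || maxGDP < 0) stop("BP and maxGDP must be >= 0")
  structure(list(BP = BP, maxGDP = maxGDP, enabled = isTRUE(enabled)),
            class = "oqc_params")
}

#' FBS parameters
#'
#' @param minOverlapFrac Minimum reciprocal query-interval overlap fraction
#'   with a primary alignment.
#' @param minScoreFrac Minimum score as a fraction of that primary's score.
#' @param enabled When `FALSE`, no secondaries are reported.
#' @return An object of class `fbs_params`.
#' @export
fbs_params <- function(minOverlapFrac = 0.9, minScoreFrac = 0.9,
                       enabled = TRUE) {
  if (minOverlapFrac <= 0 || minOverlapFrac > 1 ||
      minScoreFrac <= 0 || minScoreFrac > 1)
    stop("FBS fractions must be in (0, 1]")
  structure(list(minOverlapFrac = minOverlapFrac,
                 minScoreFrac = minScoreFrac, enabled = isTRUE(enabled)),
            class = "fbs_params")
}

#' Genomic distance penalty factor between two alignments
#'
#' `GDP = min(maxGDP, log10(max(1, refGap)))` where `refGap` is the
#' base-pair distance between the nearest reference endpoints of the two
#' alignments (0 when they touch or overlap). Alignments on different
#' reference sequences always incur `maxGDP`. The split penalty charged to
#' the coverage objective is `BP * GDP`.
#'
#' @param a1,a2 One-row alignment data.frames (need `refName`, `rStart`,
#'   `rEnd`).
#' @param oqcParams An [oqc_params()] object.
#' @return The GDP factor (numeric).
#' @export
genomic_distance_penalty <- function(a1, a2, oqcParams = oqc_params()) {
  if (a1$refName != a2$refName) return(oqcParams$maxGDP)
  refGap <- max(a1$rStart, a2$rStart) - min(a1$rEnd, a2$rEnd)
  if (refGap <= 0) refGap <- 0
  min(oqcParams$maxGDP, log10(max(1, refGap)))
}

#' Score gain of appending an alignment to a coverage chain
#'
#' When the appended alignment overlaps its predecessor on the query (as at
#' homology-flanked breakpoints), the overlapping bases are credited once:
#' the gain is the appended alignment's score minus
#' `overlap * min(perBase(prev), perBase(next))`, the per-base score of the
#' weaker alignment prorated over the overlap. Zero overlap gives the full
#' score; full query containment is disallowed.
#'
#' @param prev,next_ One-row alignment data.frames with `qStart`, `qEnd`,
#'   `score`; `next_$qStart >= prev$qStart`.
#' @return Numeric gain, or `-Inf` when appending is disallowed.
#' @export
overlap_adjusted_gain <- function(prev, next_) {
  if (next_$qEnd <= prev$qEnd) return(-Inf)  # contained: no novel base
  ov <- max(0, prev$qEnd - next_$qStart)
  if (ov == 0) return(next_$score)
  perPrev <- prev$score / (prev$qEnd - prev$qStart)
  perNext <- next_$score / (next_$qEnd - next_$qStart)
  next_$score - ov * min(perPrev, perNext)
}

#' Optimal Query Coverage: select the primary alignment set
#'
#' Finds the subset of alignments that covers the query with the maximum
#' coverage score: the sum of overlap-adjusted scores minus a penalty
#' `BP * GDP` for each split between consecutive members. Uses the same
#' edge-free max-path DAG relaxation as fragment chaining, over alignments
#' presorted by query start; strand does not restrict chaining (an
#' inversion junction joins opposite-strand alignments) and cross-sequence
#' pairs chain at `maxGDP`.
#'
#' @param alignments Alignment data.frame for one query (both strands).
#' @param oqcParams An [oqc_params()] object.
#' @return An object of class `coverage_result`: list with `alignments`
#'   (all input rows, `isPrimary` set), `primaries` (the Optimal Coverage
#'   Set, ascending `qStart`), `secondaries` (empty until
#'   [filter_by_similarity()]), and `coverageScore`.
#' @export
optimal_query_coverage <- function(alignments, oqcParams = oqc_params()) {
  if (!oqcParams$enabled) return(report_all_mode(alignments))
  empty <- structure(list(alignments = alignments,
                          primaries = alignments[0, , drop = FALSE],
                          secondaries = alignments[0, , drop = FALSE],
                          coverageScore = 0),
                     class = "coverage_result")
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)
  o <- order(alignments$qStart, alignments$qEnd, alignments$refName,
             alignments$rStart, alignments$strand)
  aln <- alignments[o, , drop = FALSE]
  n <- nrow(aln)
  best <- as.numeric(aln$score)
  pred <- integer(n)
  len <- aln$qEnd - aln$qStart
  perBase <- aln$score / len
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (aln$qEnd[i] <= aln$qEnd[j]) next
      ov <- max(0, aln$qEnd[j] - aln$qStart[i])
      gain <- aln$score[i] -
        (if (ov > 0) ov * min(perBase[i], perBase[j]) else 0)
      gdp <- genomic_distance_penalty(aln[j, ], aln[i, ], oqcParams)
      cand <- best[j] + gain - oqcParams$BP * gdp
      if (cand > best[i] ||
          (cand == best[i] && pred[i] > 0L &&
           better_pred(aln, j, pred[i], i))) {
        best[i] <- cand
        pred[i] <- j
      }
    }
  }
  end <- which.max(best)
  sel <- integer(0)
  i <- end
  while (i != 0L) {
    sel <- c(i, sel)
    i <- pred[i]
  }
  aln$isPrimary <- FALSE
  aln$isPrimary[sel] <- TRUE
  structure(list(alignments = aln,
                 primaries = aln[sel, , drop = FALSE],
                 secondaries = aln[0, , drop = FALSE],
                 coverageScore = best[end]),
            class = "coverage_result")
}

# tie-break: prefer predecessor with smaller reference gap, then smaller
# query start, mirroring the fragment-chaining rule
better_pred <- function(aln, j, cur, i) {
  gap_j <- if (aln$refName[j] == aln$refName[i])
    max(0, aln$rStart[i] - aln$rEnd[j], aln$rStart[j] - aln$rEnd[i]) else Inf
  gap_c <- if (aln$refName[cur] == aln$refName[i])
    max(0, aln$rStart[i] - aln$rEnd[cur], aln$rStart[cur] - aln$rEnd[i]) else Inf
  if (gap_j != gap_c) return(gap_j < gap_c)
  if (aln$qStart[j] != aln$qStart[cur]) return(aln$qStart[j] < aln$qStart[cur])
  j < cur
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("coverage_result: ", nrow(x$primaries), " primary, ",
      nrow(x$secondaries), " secondary alignment(s); coverage score ",
      format(x$coverageScore), "\n", sep = "")
  invisible(x)
}

#' Filter By Similarity: identify secondary alignments
#'
#' A non-primary alignment becomes secondary iff, for some primary `p`, its
#' query interval overlaps `p`'s reciprocally by at least `minOverlapFrac`
#' (of both intervals) and its score is at least `minScoreFrac * p$score`.
#' Each secondary is tagged with its best-matching primary; all other
#' non-primary alignments are discarded from the output.
#'
#' @param coverageResult A `coverage_result` from
#'   [optimal_query_coverage()].
#' @param allAlignments Optional alignment data.frame to scan instead of
#'   the non-primaries stored in `coverageResult`.
#' @param fbsParams An [fbs_params()] object.
#' @return The `coverage_result` with `secondaries` populated (column
#'   `primaryOf` holds the matched primary's row position within
#'   `primaries`).
#' @export
filter_by_similarity <- function(coverageResult, allAlignments = NULL,
                                 fbsParams = fbs_params()) {
  stopifnot(inherits(coverageResult, "coverage_result"))
  prim <- coverageResult$primaries
  pool <- allAlignments %||% coverageResult$alignments
  if (!fbsParams$enabled || nrow(prim) == 0L || nrow(pool) == 0L) {
    return(coverageResult)
  }
  cand <- pool[!pool$isPrimary, , drop = FALSE]
  if (nrow(cand) == 0L) return(coverageResult)
  keep <- logical(nrow(cand))
  matched <- integer(nrow(cand))
  bestOv <- numeric(nrow(cand))
  for (p in seq_len(nrow(prim))) {
    ov <- pmin(cand$qEnd, prim$qEnd[p]) - pmax(cand$qStart, prim$qStart[p])
    ov <- pmax(ov, 0)
    fracA <- ov / (cand$qEnd - cand$qStart)
    fracP <- ov / (prim$qEnd[p] - prim$qStart[p])
    ok <- fracA >= fbsParams$minOverlapFrac &
      fracP >= fbsParams$minOverlapFrac &
      cand$score >= fbsParams$minScoreFrac * prim$score[p]
    recip <- pmin(fracA, fracP)
    upgrade <- ok & (!keep | recip > bestOv)
    matched[upgrade] <- p
    bestOv[upgrade] <- recip[upgrade]
    keep <- keep | ok
  }
  sec <- cand[keep, , drop = FALSE]
  if (nrow(sec)) {
    sec$isSecondary <- TRUE
    sec$primaryOf <- matched[keep]
  }
  coverageResult$secondaries <- sec
  coverageResult
}

#' Report-all mode: bypass OQC
#'
#' Returns every alignment unchanged; for SAM flag purposes the single
#' best-scoring alignment (ties broken by `refName` then `rStart`) is the
#' only primary and everything else is marked non-primary.
#'
#' @param alignments Alignment data.frame.
#' @return A `coverage_result` whose `alignments` carry the flags and whose
#'   `coverageScore` is the best single score.
#' @export
report_all_mode <- function(alignments) {
  empty <- structure(list(alignments = alignments,
                          primaries = alignments[0, , drop = FALSE],
                          secondaries = alignments[0, , drop = FALSE],
                          coverageScore = 0),
                     class = "coverage_result")
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)
  o <- order(-alignments$score, alignments$refName, alignments$rStart)
  bestRow <- o[1]
  alignments$isPrimary <- FALSE
  alignments$isPrimary[bestRow] <- TRUE
  sec <- alignments[-bestRow, , drop = FALSE]
  if (nrow(sec)) sec$isSecondary <- TRUE
  structure(list(alignments = alignments,
                 primaries = alignments[bestRow, , drop = FALSE],
                 secondaries = sec,
                 coverageScore = alignments$score[bestRow]),
            class = "coverage_result")
}
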