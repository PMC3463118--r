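# Fragment chaining: max-path DAG over qStart-sorted fragments with
# estimated affine-gap scoring, region partitioning and the minMatch filter.

#' Affine-gap scoring parameters
#'
#' Defaults are the conventional long-read settings Match = +1,
#' Mismatch = -3, GapOpen = -5, GapExtend = -2; a gap of length L costs
#' `gapOpen + gapExtend * L`. The same convention is used for chain score
#' estimation, DP fills, X-drop extensions and rescoring, so scores are
#' comparable across stages.
#'
#' @param match Reward per matching base (> 0).
#' @param mismatch Penalty per mismatching base (<= 0).
#' @param gapOpen Penalty for opening a gap (<= 0).
#' @param gapExtend Penalty per gap base (<= 0).
#' @return An object of class `ags_params`.
#' @export
ags_params <- function(match = 1L, mismatch = -3L, gapOpen = -5L,
                       gapExtend = -2L) {
  if (match <= 0) stop("match must be > 0")
  if (mismatch > 0 || gapOpen > 0 || gapExtend > 0)
    stop("mismatch, gapOpen and gapExtend must be <= 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend)),
            class = "ags_params")
}

#' Chaining parameters
#'
#' @param minMatch Minimum total non-overlapping query bases covered by
#'   seeds for a potential alignment to survive. Counted as the measure of
#'   the union of fragment query intervals, not the number of seed hits.
#' @param maxRegionGap Reference-distance threshold grouping fragments into
#'   one region; consecutive (rStart-sorted) fragments further apart start a
#'   new region. `NA` (the default) lets the pipeline derive
#'   `min(10 * queryLength, 50000)` per query.
#' @param bandWidth DP band half-width used later during completion.
#' @return An object of class `chain_params`.
#' @export
chain_params <- function(minMatch = 25L, maxRegionGap = NA,
                         bandWidth = 15L) {
  if (!is.na(maxRegionGap) && maxRegionGap <= 0)
    stop("maxRegionGap must be > 0")
  if (minMatch < 1) stop("minMatch must be >= 1")
  structure(list(minMatch = as.integer(minMatch),
                 maxRegionGap = as.integer(maxRegionGap),
                 bandWidth = as.integer(bandWidth)),
            class = "chain_params")
}

#' Partition fragments of one strand into reference regions
#'
#' Fragments are sorted by `rStart`; a new group starts whenever the
#' reference gap to the previous fragment exceeds `maxRegionGap` or a
#' sequence boundary is crossed. Groups are disjoint and cover all
#' fragments.
#'
#' @param fragments Fragment data.frame (one strand).
#' @param maxRegionGap Gap threshold in bases.
#' @param refOffsets Optional cumulative sequence start offsets (from a
#'   `seed_index`) used to detect boundary crossings.
#' @return A list of fragment data.frames.
#' @export
partition_regions <- function(fragments, maxRegionGap, refOffsets = NULL) {
  if (nrow(fragments) == 0L) return(list())
  o <- order(fragments$rStart, fragments$rEnd)
  fragments <- fragments[o, , drop = FALSE]
  gap <- c(0L, fragments$rStart[-1] - fragments$rEnd[-nrow(fragments)])
  newGroup <- gap > maxRegionGap
  if (!is.null(refOffsets)) {
    seqId <- findInterval(fragments$rStart, refOffsets)
    newGroup <- newGroup | c(FALSE, diff(seqId) != 0L)
  }
  grp <- cumsum(c(TRUE, newGroup[-1]))
  lapply(split(seq_len(nrow(fragments)), grp),
         function(i) fragments[i, , drop = FALSE])
}

#' Estimated score of one fragment succeeding another in a chain
#'
#' The difference between the two fragments' diagonals is scored as a single
#' indel (`gapOpen + gapExtend * d`, zero if on the same diagonal); bases of
#' the later fragment overlapping the earlier one on query or reference are
#' counted once by trimming them from the later fragment's match reward.
#' Any unmatched middle between the fragments (`min(qGap, rGap)` bases when
#' both gaps are positive) is charged at the mismatch rate: that is the
#' lower bound of what the DP fill between the fragments can score on
#' non-homologous sequence, and without it two fragments far apart on both
#' query and reference but on similar diagonals would chain for free. The
#' edge is disallowed (`-Inf`) when the later fragment adds no novel bases
#' on query or reference, or precedes the earlier one on the reference.
#'
#' @param f1,f2 Single-fragment data.frame rows (lists with `qStart`,
#'   `qEnd`, `rStart`, `rEnd`, `diagonal`); `f2$qStart >= f1$qStart`.
#' @param ags An [ags_params()] object.
#' @return The edge score adjustment (indel term minus trimmed reward),
#'   excluding f2's own node reward, or `-Inf` if disallowed.
#' @export
chain_score_edge <- function(f1, f2, ags = ags_params()) {
  if (f2$qEnd <= f1$qEnd || f2$rStart < f1$rStart || f2$rEnd <= f1$rEnd)
    return(-Inf)
  d <- abs(f2$diagonal - f1$diagonal)
  indel <- if (d == 0) 0 else ags$gapOpen + ags$gapExtend * d
  trim <- max(0L, f1$qEnd - f2$qStart, f1$rEnd - f2$rStart)
  if (f2$qEnd - f2$qStart - trim <= 0L) return(-Inf)
  bridge <- max(0L, min(f2$qStart - f1$qEnd, f2$rStart - f1$rEnd))
  indel - ags$match * trim + ags$mismatch * bridge
}

# Vectorized edge scores from all fragments in `fr` rows `js` to row `i`.
chain_edges_to <- function(fr, js, i, ags) {
  q2s <- fr$qStart[i]; q2e <- fr$qEnd[i]
  r2s <- fr$rStart[i]; r2e <- fr$rEnd[i]; d2 <- fr$diagonal[i]
  allowed <- fr$qEnd[js] < q2e & fr$rStart[js] <= r2s & fr$rEnd[js] < r2e
  d <- abs(d2 - fr$diagonal[js])
  indel <- ifelse(d == 0, 0, ags$gapOpen + ags$gapExtend * d)
  trim <- pmax(0L, fr$qEnd[js] - q2s, fr$rEnd[js] - r2s)
  bridge <- pmax(0L, pmin(q2s - fr$qEnd[js], r2s - fr$rEnd[js]))
  edge <- indel - ags$match * trim + ags$mismatch * bridge
  edge[!allowed | (q2e - q2s - trim) <= 0L] <- -Inf
  edge
}

#' Find the maximum-estimated-score fragment chain in a region
#'
#' Nodes are fragments sorted by `qStart`; each carries reward
#' `match * length` and edges are scored by [chain_score_edge()]. The DAG is
#' relaxed in one pass over all ordered pairs (O(n^2) time, O(n) space)
#' without materializing edges, keeping a best-score and back-pointer per
#' node. Ties prefer the predecessor with the smaller reference gap, then
#' the smaller `qStart`, so output is deterministic.
#'
#' @param group Nonempty fragment data.frame (one region, one strand).
#' @param ags An [ags_params()] object.
#' @return A list with `fragments` (the chain, ascending in both query and
#'   reference) and `estimatedScore`.
#' @export
chain_fragments <- function(group, ags = ags_params()) {
  stopifnot(nrow(group) >= 1L)
  o <- order(group$qStart, group$rStart)
  fr <- group[o, , drop = FALSE]
  n <- nrow(fr)
  reward <- ags$match * (fr$qEnd - fr$qStart)
  best <- as.numeric(reward)
  pred <- integer(n)
  for (i in seq_len(n)[-1]) {
    js <- seq_len(i - 1L)
    cand <- best[js] + reward[i] + chain_edges_to(fr, js, i, ags)
    m <- max(cand)
    if (m > best[i]) {
      ties <- js[cand == m]
      if (length(ties) > 1L) {
        refGap <- fr$rStart[i] - fr$rEnd[ties]
        ties <- ties[order(refGap, fr$qStart[ties], ties)]
      }
      best[i] <- m
      pred[i] <- ties[1L]
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  i <- end
  while (i != 0L) {
    chain <- c(i, chain)
    i <- pred[i]
  }
  list(fragments = fr[chain, , drop = FALSE], estimatedScore = best[end])
}

#' Repeatedly chain uncovered portions of the query within a region
#'
#' After the best chain is found, remaining fragments that still lie (at
#' least partly) in an uncovered portion of the query seed another run of
#' the chain algorithm, until no fragment covers any uncovered query base.
#' Fragments straddling a covered region boundary stay available: junctions
#' frequently carry a base or two of coincidental micro-homology, and
#' discarding a fragment for sharing a few query bases with an earlier
#' chain would silently drop one side of a split alignment.
#'
#' @param group Fragment data.frame for one region.
#' @param ags An [ags_params()] object.
#' @param chainParams A [chain_params()] object (reserved for future use in
#'   selection; the minMatch filter is applied separately).
#' @return A list of potential alignments (each with `fragments`,
#'   `estimatedScore`, `qStart`, `qEnd`), ordered by estimated score,
#'   descending.
#' @export
iterate_uncovered <- function(group, ags = ags_params(),
                              chainParams = chain_params()) {
  out <- list()
  remaining <- group
  hullS <- integer(0)
  hullE <- integer(0)
  while (nrow(remaining) > 0L) {
    ch <- chain_fragments(remaining, ags)
    qs <- min(ch$fragments$qStart)
    qe <- max(ch$fragments$qEnd)
    out[[length(out) + 1L]] <- list(fragments = ch$fragments,
                                    estimatedScore = ch$estimatedScore,
                                    qStart = qs, qEnd = qe)
    hullS <- c(hullS, qs)
    hullE <- c(hullE, qe)
    # merged union of chain hulls
    o <- order(hullS)
    ms <- hullS[o][1]; me <- hullE[o][1]
    us <- integer(0); ue <- integer(0)
    for (h in seq_along(o)[-1]) {
      if (hullS[o][h] > me) {
        us <- c(us, ms); ue <- c(ue, me)
        ms <- hullS[o][h]; me <- hullE[o][h]
      } else me <- max(me, hullE[o][h])
    }
    us <- c(us, ms); ue <- c(ue, me)
    fullyCovered <- vapply(seq_len(nrow(remaining)), function(i) {
      any(remaining$qStart[i] >= us & remaining$qEnd[i] <= ue)
    }, logical(1))
    remaining <- remaining[!fullyCovered, , drop = FALSE]
  }
  out[order(vapply(out, `[[`, numeric(1), "estimatedScore"),
            decreasing = TRUE)]
}

#' minMatch filter on a potential alignment
#'
#' Computes the seed-base count as the measure of the union of the chain's
#' fragment query intervals; the potential alignment is kept iff this count
#' is at least `minMatch` (boundary inclusive). A single k-base seed
#' therefore survives `minMatch = k` ("one seed hit").
#'
#' @param pa A potential alignment from [iterate_uncovered()] or
#'   [chain_fragments()].
#' @param minMatch Threshold in bases.
#' @return `TRUE` to keep, `FALSE` to drop; the computed `seedBases` is
#'   attached as an attribute.
#' @export
filter_minmatch <- function(pa, minMatch) {
  seedBases <- interval_union_length(pa$fragments$qStart, pa$fragments$qEnd)
  structure(seedBases >= minMatch, seedBases = seedBases)
}
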