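# Alignment completion: banded affine-gap fills between fragments, X-drop
# extensions at both ends, CIGAR/score assembly, and the full-SW oracle.

#' Dynamic-programming parameters
#'
#' @param bandWidth Half-width of the DP band around the guiding diagonal
#'   for inter-fragment fills. Extensions use
#'   `bandWidth * extensionBandFactor` because their endpoints are unknown.
#' @param X X-dropoff threshold (positive score units): an extension stops
#'   once the score of the current row falls more than `X` below the best
#'   score seen for a shorter extension.
#' @param extensionBandFactor Band multiplier applied during extensions.
#' @return An object of class `dp_params`.
#' @export
dp_params <- function(bandWidth = 15L, X = 25, extensionBandFactor = 2L) {
  if (bandWidth < 1) stop("bandWidth must be >= 1")
  if (X <= 0) stop("X must be > 0")
  structure(list(bandWidth = as.integer(bandWidth), X = X,
                 extensionBandFactor = as.integer(extensionBandFactor)),
            class = "dp_params")
}

#' Banded global affine-gap alignment of two segments
#'
#' Aligns a query segment against a reference segment with both endpoints
#' pinned (as between two exact-match fragments), restricted to DP cells
#' within `bandWidth` of the segment-pair diagonal. If the corridor cannot
#' contain any complete path (length difference exceeding the band), the
#' band is widened once to cover the endpoint diagonal and the result is
#' flagged. With `bandWidth >= max(nchar(query), nchar(ref))` the result
#' equals unbanded global affine alignment.
#'
#' @param querySeg,refSeg Nonempty segment strings.
#' @param ags An [ags_params()] object.
#' @param bandWidth Band half-width.
#' @return List with `score`, `cigar` (M/I/D; I consumes query, D consumes
#'   reference) and `widened`.
#' @export
banded_affine_fill <- function(querySeg, refSeg, ags = ags_params(),
                               bandWidth = 15L) {
  if (!nzchar(querySeg) || !nzchar(refSeg))
    stop("banded_affine_fill requires nonempty segments")
  global_affine_cpp(toupper(querySeg), toupper(refSeg), ags$match,
                    ags$mismatch, ags$gapOpen, ags$gapExtend,
                    as.integer(bandWidth))
}

#' X-drop extension from an anchor
#'
#' Extends an alignment from an anchor position forward or backward with
#' banded affine-gap DP (band `bandWidth * extensionBandFactor`), stopping
#' once a row's best score drops more than `X` below the best score seen,
#' and returning the extension that achieved the best score. Extending into
#' identical sequence reaches the end with score `match * length`.
#'
#' @param query,ref Full query and reference strings (or windows; offsets
#'   are interpreted within them).
#' @param anchorQ,anchorR 0-based positions abutting a fragment end: the
#'   extension covers `[anchorQ, ...)` forward or `[..., anchorQ)` backward.
#' @param direction `"forward"` or `"backward"`.
#' @param ags An [ags_params()] object.
#' @param dpParams A [dp_params()] object.
#' @return List with `score` (0 for an empty extension), `qExtent`,
#'   `rExtent` and `cigar` (always written left-to-right on the forward
#'   sequences).
#' @export
xdrop_extend <- function(query, ref, anchorQ, anchorR,
                         direction = c("forward", "backward"),
                         ags = ags_params(), dpParams = dp_params()) {
  direction <- match.arg(direction)
  query <- toupper(query); ref <- toupper(ref)
  band <- dpParams$bandWidth * dpParams$extensionBandFactor
  if (direction == "forward") {
    a <- substr(query, anchorQ + 1L, nchar(query))
    b <- substr(ref, anchorR + 1L, nchar(ref))
  } else {
    a <- reverse_string(substr(query, 1L, anchorQ))
    b <- reverse_string(substr(ref, 1L, anchorR))
  }
  if (!nzchar(a) || !nzchar(b))
    return(list(score = 0L, qExtent = 0L, rExtent = 0L, cigar = ""))
  res <- xdrop_extend_cpp(a, b, ags$match, ags$mismatch, ags$gapOpen,
                          ags$gapExtend, as.integer(band), dpParams$X)
  cig <- res$cigar
  if (direction == "backward") cig <- reverse_cigar(cig)
  list(score = res$score, qExtent = res$qExt, rExtent = res$rExt,
       cigar = cig)
}

reverse_string <- function(s) {
  if (!nzchar(s)) return(s)
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Exact local affine-gap alignment (full Smith-Waterman oracle)
#'
#' Unbanded quadratic DP used as the accuracy benchmark for the heuristic
#' pipeline; no banding or X-dropoff, so the returned score is the true
#' optimal local alignment score.
#'
#' @param query,ref Nonempty sequences.
#' @param ags An [ags_params()] object.
#' @return List with `score` and, when positive, 0-based half-open spans
#'   `qStart`, `qEnd`, `rStart`, `rEnd` and `cigar`; score 0 means the empty
#'   alignment.
#' @export
full_sw_oracle <- function(query, ref, ags = ags_params()) {
  stopifnot(nzchar(query), nzchar(ref))
  sw_local_cpp(toupper(query), toupper(ref), ags$match, ags$mismatch,
               ags$gapOpen, ags$gapExtend)
}

# Trim overlaps between successive chained fragments: later fragments lose
# their leading overlap on query or reference so every base is counted once.
trim_chain_overlaps <- function(fr) {
  if (nrow(fr) <= 1L) return(fr)
  for (i in seq_len(nrow(fr))[-1]) {
    trim <- max(0L, fr$qEnd[i - 1L] - fr$qStart[i],
                fr$rEnd[i - 1L] - fr$rStart[i])
    if (trim > 0L) {
      fr$qStart[i] <- fr$qStart[i] + trim
      fr$rStart[i] <- fr$rStart[i] + trim
    }
  }
  fr[fr$qEnd > fr$qStart & fr$rEnd > fr$rStart, , drop = FALSE]
}

#' Complete a potential alignment into a full alignment
#'
#' Concatenates backward X-drop extension + first fragment + banded
#' inter-fragment fills + ... + forward X-drop extension into one CIGAR,
#' scoring every part under the single affine-gap convention. Fragment
#' bases are emitted as matches without re-verification (they are exact by
#' construction). Extensions never cross a reference sequence boundary.
#'
#' @param pa Potential alignment (list with `fragments` in concatenated
#'   reference coordinates and query coordinates of the *oriented* query).
#' @param index The `seed_index`.
#' @param query The oriented query sequence (reverse-complemented for
#'   minus-strand potential alignments).
#' @param strand `"+"` or `"-"`.
#' @param qname Query name.
#' @param ags An [ags_params()] object.
#' @param dpParams A [dp_params()] object.
#' @return One-row alignment data.frame (forward-query coordinates `qStart`,
#'   `qEnd`; per-sequence reference coordinates; CIGAR in the orientation of
#'   the SAM SEQ field; exact AGS `score`), or `NULL` if a DP fill failed.
#' @export
complete_alignment <- function(pa, index, query, strand = "+",
                               qname = "query", ags = ags_params(),
                               dpParams = dp_params()) {
  fr <- trim_chain_overlaps(pa$fragments)
  if (nrow(fr) == 0L) return(NULL)
  QL <- nchar(query)
  si <- findInterval(fr$rStart[1], index$refOffsets)
  seqStart <- index$refOffsets[si]
  seqEnd <- seqStart + index$refLengths[si]
  band <- dpParams$bandWidth
  extBand <- band * dpParams$extensionBandFactor
  margin <- extBand + 8L

  score <- 0
  runs <- character(0)
  # backward extension
  qLeft <- fr$qStart[1]
  winStart <- max(seqStart, fr$rStart[1] - (qLeft + margin))
  back <- xdrop_extend(substr(query, 1L, qLeft),
                       ref_window(index, winStart, fr$rStart[1] - winStart),
                       anchorQ = qLeft, anchorR = fr$rStart[1] - winStart,
                       direction = "backward", ags = ags, dpParams = dpParams)
  qS <- fr$qStart[1] - back$qExtent
  rS <- fr$rStart[1] - back$rExtent
  score <- score + back$score
  runs <- c(runs, back$cigar)
  # fragments and fills
  for (i in seq_len(nrow(fr))) {
    if (i > 1L) {
      qGap <- fr$qStart[i] - fr$qEnd[i - 1L]
      rGap <- fr$rStart[i] - fr$rEnd[i - 1L]
      if (qGap > 0L && rGap > 0L) {
        fill <- banded_affine_fill(
          substr(query, fr$qEnd[i - 1L] + 1L, fr$qStart[i]),
          ref_window(index, fr$rEnd[i - 1L], rGap),
          ags = ags, bandWidth = band)
        score <- score + fill$score
        runs <- c(runs, fill$cigar)
      } else if (qGap > 0L) {
        score <- score + ags$gapOpen + ags$gapExtend * qGap
        runs <- c(runs, paste0(qGap, "I"))
      } else if (rGap > 0L) {
        score <- score + ags$gapOpen + ags$gapExtend * rGap
        runs <- c(runs, paste0(rGap, "D"))
      }
    }
    len <- fr$qEnd[i] - fr$qStart[i]
    score <- score + ags$match * len
    runs <- c(runs, paste0(len, "M"))
  }
  # forward extension
  nfr <- nrow(fr)
  qRight <- QL - fr$qEnd[nfr]
  winLen <- min(seqEnd, fr$rEnd[nfr] + qRight + margin) - fr$rEnd[nfr]
  fwd <- xdrop_extend(substr(query, fr$qEnd[nfr] + 1L, QL),
                      ref_window(index, fr$rEnd[nfr], winLen),
                      anchorQ = 0L, anchorR = 0L,
                      direction = "forward", ags = ags, dpParams = dpParams)
  qE <- fr$qEnd[nfr] + fwd$qExtent
  rE <- fr$rEnd[nfr] + fwd$rExtent
  score <- score + fwd$score
  runs <- c(runs, fwd$cigar)

  cigar <- cat_cigars(runs)
  # oriented -> forward query coordinates
  if (strand == "+") {
    qStartF <- qS; qEndF <- qE
  } else {
    qStartF <- QL - qE; qEndF <- QL - qS
  }
  data.frame(qname = qname, strand = strand,
             refName = index$refNames[si],
             rStart = rS - seqStart, rEnd = rE - seqStart,
             qStart = qStartF, qEnd = qEndF, queryLength = QL,
             cigar = cigar, score = score,
             isPrimary = FALSE, isSecondary = FALSE,
             stringsAsFactors = FALSE)
}

#' Recompute an alignment's affine-gap score from its CIGAR
#'
#' Walks the CIGAR against the aligned slices of the (oriented) query and
#' the reference; used to enforce CIGAR/score self-consistency on every
#' emitted alignment.
#'
#' @param aln One-row alignment data.frame as from [complete_alignment()].
#' @param query The forward query sequence.
#' @param index The `seed_index`.
#' @param ags An [ags_params()] object.
#' @return The recomputed integer score.
#' @export
rescore_alignment <- function(aln, query, index, ags = ags_params()) {
  oriented <- if (aln$strand == "+") query else revcomp(query)
  QL <- nchar(oriented)
  qs <- if (aln$strand == "+") aln$qStart else QL - aln$qEnd
  qe <- if (aln$strand == "+") aln$qEnd else QL - aln$qStart
  si <- match(aln$refName, index$refNames)
  gStart <- index$refOffsets[si] + aln$rStart
  res <- rescore_cigar_cpp(
    toupper(substr(oriented, qs + 1L, qe)),
    ref_window(index, gStart, aln$rEnd - aln$rStart),
    aln$cigar, ags$match, ags$mismatch, ags$gapOpen, ags$gapExtend)
  if (res$qConsumed != qe - qs || res$rConsumed != aln$rEnd - aln$rStart)
    stop("CIGAR does not span the recorded query/reference intervals")
  res$score
}
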