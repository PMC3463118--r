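# End-to-end alignment pipeline: seeding -> chaining -> completion ->
# coverage selection, per query.

#' Bundle of pipeline options
#'
#' @param ags [ags_params()].
#' @param chain [chain_params()]. `maxRegionGap = NA` (the default) derives
#'   the region threshold per query as `min(10 * queryLength, 50000)` bases.
#' @param dp [dp_params()].
#' @param oqc [oqc_params()].
#' @param fbs [fbs_params()].
#' @param reportAll When `TRUE`, OQC/FBS are bypassed and all completed
#'   alignments are reported.
#' @return An object of class `align_opts`.
#' @export
align_opts <- function(ags = ags_params(), chain = chain_params(maxRegionGap = NA),
                       dp = dp_params(), oqc = oqc_params(),
                       fbs = fbs_params(), reportAll = FALSE) {
  structure(list(ags = ags, chain = chain, dp = dp, oqc = oqc, fbs = fbs,
                 reportAll = isTRUE(reportAll)),
            class = "align_opts")
}

empty_alignments <- function() {
  data.frame(qname = character(0), strand = character(0),
             refName = character(0), rStart = integer(0), rEnd = integer(0),
             qStart = integer(0), qEnd = integer(0), queryLength = integer(0),
             cigar = character(0), score = numeric(0),
             isPrimary = logical(0), isSecondary = logical(0),
             stringsAsFactors = FALSE)
}

# all completed alignments of one oriented fragment set
complete_strand <- function(frags, index, oriented, strand, qname, opts,
                            maxRegionGap, counts) {
  out <- list()
  if (nrow(frags) > 0L) {
    groups <- partition_regions(frags, maxRegionGap, index$refOffsets)
    for (g in groups) {
      pas <- iterate_uncovered(g, opts$ags, opts$chain)
      counts$potential <- counts$potential + length(pas)
      for (pa in pas) {
        if (!filter_minmatch(pa, opts$chain$minMatch)) next
        counts$kept <- counts$kept + 1L
        aln <- complete_alignment(pa, index, oriented, strand = strand,
                                  qname = qname, ags = opts$ags,
                                  dpParams = opts$dp)
        if (!is.null(aln)) out[[length(out) + 1L]] <- aln
      }
    }
  }
  out
}

#' Align a single query through the full pipeline
#'
#' Seeds the query on both strands, chains fragments per reference region,
#' completes surviving potential alignments with banded DP, deduplicates,
#' and runs OQC and FBS (or report-all).
#'
#' @param index A `seed_index`.
#' @param query Query sequence (forward orientation as read from input).
#' @param qname Query name.
#' @param opts An [align_opts()] bundle.
#' @return A `coverage_result`; its `alignments` hold every completed
#'   alignment, `primaries`/`secondaries` the reportable set. Stage counts
#'   (seeds, fragments, potential alignments, completed) are attached as
#'   attribute `counts`.
#' @export
align_query <- function(index, query, qname = "query", opts = align_opts()) {
  query <- toupper(query)
  QL <- nchar(query)
  maxRegionGap <- opts$chain$maxRegionGap
  if (is.na(maxRegionGap)) maxRegionGap <- min(10L * QL, 50000L)
  counts <- new.env()
  counts$potential <- 0L
  counts$kept <- 0L

  seeds_p <- collect_seed_matches(index, query)
  seeds_m <- collect_seed_matches(index, revcomp(query))
  frags_p <- build_fragments(seeds_p, index$params$k)
  frags_m <- build_fragments(seeds_m, index$params$k)
  alns <- c(
    complete_strand(frags_p, index, query, "+", qname, opts,
                    maxRegionGap, counts),
    complete_strand(frags_m, index, revcomp(query), "-", qname, opts,
                    maxRegionGap, counts)
  )
  aln <- if (length(alns)) do.call(rbind, alns) else empty_alignments()
  if (nrow(aln) > 1L) {
    dup <- duplicated(aln[, c("strand", "qStart", "qEnd", "refName",
                              "rStart", "cigar")])
    aln <- aln[!dup, , drop = FALSE]
  }
  res <- if (opts$reportAll || !opts$oqc$enabled) {
    report_all_mode(aln)
  } else {
    filter_by_similarity(optimal_query_coverage(aln, opts$oqc),
                         fbsParams = opts$fbs)
  }
  attr(res, "counts") <- c(seeds = nrow(seeds_p) + nrow(seeds_m),
                           fragments = nrow(frags_p) + nrow(frags_m),
                           potential = counts$potential,
                           kept = counts$kept,
                           completed = nrow(aln))
  res
}

#' Alignments a query reports (primaries plus FBS secondaries)
#'
#' @param result A `coverage_result`.
#' @param includeSecondaries Include FBS secondaries.
#' @return Alignment data.frame.
#' @export
reported_alignments <- function(result, includeSecondaries = TRUE) {
  out <- result$primaries
  if (includeSecondaries && nrow(result$secondaries)) {
    sec <- result$secondaries
    sec$primaryOf <- NULL
    out <- rbind(out, sec)
  }
  out
}

#' Align a query file against an index and write SAM
#'
#' Streams FASTA/FASTQ queries through the pipeline and writes a SAM file
#' with strand, primary/secondary flags and soft clips. Deterministic for
#' fixed parameters and index.
#'
#' @param index A `seed_index` or path to an `SSIX` index file.
#' @param queryPath FASTA or FASTQ file of queries (gzip accepted).
#' @param outSam Output SAM path.
#' @param opts An [align_opts()] bundle.
#' @param includeSecondaries Write FBS secondaries (flag 256).
#' @param verbose Emit a per-stage summary via `message()`.
#' @return Invisibly, a per-query summary data.frame of stage counts.
#' @export
align_file <- function(index, queryPath, outSam, opts = align_opts(),
                       includeSecondaries = TRUE, verbose = FALSE) {
  if (is.character(index)) index <- read_index(index)
  queries <- read_queries(queryPath)
  alnList <- vector("list", nrow(queries))
  stats <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    res <- align_query(index, queries$seq[i], qname = queries$name[i],
                       opts = opts)
    alnList[[i]] <- reported_alignments(res, includeSecondaries)
    stats[[i]] <- attr(res, "counts")
  }
  aln <- do.call(rbind, c(alnList, list(empty_alignments())))
  mapped <- unique(aln$qname)
  write_sam(aln, index, queries, outSam)
  summary <- data.frame(qname = queries$name,
                        do.call(rbind, stats),
                        mapped = queries$name %in% mapped)
  if (verbose) {
    message(sprintf(
      "aligned %d queries: %d mapped; %d seeds, %d fragments, %d potential, %d completed",
      nrow(queries), sum(summary$mapped), sum(summary$seeds),
      sum(summary$fragments), sum(summary$potential), sum(summary$completed)))
  }
  invisible(summary)
}
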