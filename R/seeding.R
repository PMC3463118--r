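# Seed collation (heap merge) and coalescing into exact-match fragments.

#' Collect seed matches of a query against the index
#'
#' Enumerates every query k-mer, fetches its pre-sorted reference hit list,
#' and emits the seed stream sorted by (diagonal, query offset). The
#' collation is a QL-way merge of the per-position ROA slices through a
#' binary heap (at most one live entry per query position), not a
#' concatenate-and-sort; the two are equivalent and the heap merge bounds
#' the sorting cost by N log QL.
#'
#' @param index A `seed_index`.
#' @param query Query sequence (single string); case-insensitive. K-mers
#'   containing ambiguous bases emit nothing.
#' @return A data.frame with columns `qo`, `ro` (0-based offsets of seed
#'   starts on query and concatenated reference) and `diagonal` (`ro - qo`),
#'   sorted by (diagonal, qo), with attribute `peakHeap` giving the maximum
#'   number of live heap entries.
#' @export
collect_seed_matches <- function(index, query) {
  stopifnot(inherits(index, "seed_index"), is.character(query),
            length(query) == 1L)
  query <- toupper(query)
  if (nchar(query) < index$params$k) {
    out <- data.frame(qo = integer(0), ro = integer(0), diagonal = integer(0))
    attr(out, "peakHeap") <- 0L
    return(out)
  }
  res <- collect_seeds_cpp(index$keys, index$roaStarts, index$roa,
                           index$params$k, query)
  out <- data.frame(qo = res$qo, ro = res$ro, diagonal = res$ro - res$qo)
  attr(out, "peakHeap") <- res$peakHeap
  out
}

#' Coalesce sorted seeds into maximal exact-match fragments
#'
#' Seeds on the same diagonal whose query spans overlap or abut
#' (`next.qo <= prev.qo + k`) merge into one fragment; every fragment is an
#' exact match between query and reference because merged seed spans cover
#' it contiguously.
#'
#' @param seeds Seed data.frame sorted by (diagonal, qo), as produced by
#'   [collect_seed_matches()]. Unsorted input is a usage error.
#' @param k Seed length used to generate the seeds.
#' @return A data.frame of fragments with 0-based half-open spans `qStart`,
#'   `qEnd`, `rStart`, `rEnd`, plus `diagonal` and `seedCount`.
#' @export
build_fragments <- function(seeds, k) {
  stopifnot(is.data.frame(seeds))
  if (nrow(seeds) == 0L) {
    return(data.frame(qStart = integer(0), qEnd = integer(0),
                      rStart = integer(0), rEnd = integer(0),
                      diagonal = integer(0), seedCount = integer(0)))
  }
  d <- seeds$ro - seeds$qo
  key <- d * 2^32 + seeds$qo
  if (is.unsorted(key)) stop("seeds must be sorted by (diagonal, qo)")
  fr <- build_fragments_cpp(seeds$qo, seeds$ro, as.integer(k))
  fr$diagonal <- fr$rStart - fr$qStart
  fr
}

#' Seed a query on both strands
#'
#' Runs [collect_seed_matches()] and [build_fragments()] on the query and on
#' its reverse complement. Minus-strand fragments are expressed in the
#' coordinates of the reverse-complemented query against the forward
#' reference; downstream stages report them SAM-style (forward reference,
#' reverse-complemented query sequence).
#'
#' @param index A `seed_index`.
#' @param query Query sequence.
#' @return A list with elements `plus` and `minus`, each a fragment
#'   data.frame with a `strand` column.
#' @export
seed_query_both_strands <- function(index, query) {
  k <- index$params$k
  fwd <- build_fragments(collect_seed_matches(index, query), k)
  rev <- build_fragments(collect_seed_matches(index, revcomp(query)), k)
  if (nrow(fwd)) fwd$strand <- "+" else fwd$strand <- character(0)
  if (nrow(rev)) rev$strand <- "-" else rev$strand <- character(0)
  list(plus = fwd, minus = rev)
}
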