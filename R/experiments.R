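# Seeded end-to-end evaluation experiments on synthetic genomes: single-best
# accuracy vs the full-SW oracle, simple-SV breakpoint detection,
# repeat-insertion detection with and without secondaries, and CGR contigs.

# align a batch of simulated reads, returning the reported alignments
align_reads <- function(index, reads, opts, includeSecondaries = TRUE) {
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res <- align_query(index, reads$seq[i], qname = reads$name[i],
                       opts = opts)
    out[[i]] <- reported_alignments(res, includeSecondaries)
  }
  do.call(rbind, c(out, list(empty_alignments())))
}

#' Single-best alignment accuracy against the full-SW oracle
#'
#' Samples error-bearing reads from a random synthetic genome, aligns them
#' through the full pipeline, and compares each query's Coverage Score
#' against the optimal local alignment score at the known source locus
#' computed by the exact (unbanded) Smith-Waterman oracle. A query counts
#' as accurate when it produces at least one primary alignment and its
#' Coverage Score is at least the oracle score; queries whose Coverage
#' Score exceeds the oracle score found an equally or more viable placement
#' elsewhere and are not errors.
#'
#' @param refLength Synthetic genome length.
#' @param nReads Number of reads.
#' @param readLength Read length.
#' @param errorRate,indelFrac Read error profile.
#' @param minMatch minMatch threshold for this read length.
#' @param pad Reference padding around the source locus for the oracle.
#' @param seed Integer seed for genome, reads and any sampling.
#' @return List with `pct` (percent accurate), `n`, and a per-read detail
#'   data.frame.
#' @export
accuracy_experiment <- function(refLength = 1e6, nReads = 1000L,
                                readLength = 100L, errorRate = 0.02,
                                indelFrac = 0.1, minMatch = 20L,
                                pad = 60L, seed = 1L) {
  ref <- make_synthetic_reference(refLength, names = "chr1", rngSeed = seed)
  index <- build_index(ref)
  coverage <- nReads * readLength / refLength
  reads <- sample_reads(c(chr1 = ref[["chr1"]]),
                        read_sim_params(readLength = readLength,
                                        coverage = coverage,
                                        errorRate = errorRate,
                                        indelFrac = indelFrac,
                                        rngSeed = seed + 1L))
  opts <- align_opts(chain = chain_params(minMatch = minMatch,
                                          maxRegionGap = NA))
  ags <- opts$ags
  ok <- logical(nrow(reads))
  cs <- numeric(nrow(reads))
  oracle <- numeric(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res <- align_query(index, reads$seq[i], reads$name[i], opts)
    cs[i] <- if (nrow(res$primaries)) res$coverageScore else NA_real_
    lo <- max(0L, reads$start[i] - pad)
    hi <- min(refLength, reads$start[i] + readLength + pad)
    window <- substr(ref[["chr1"]], lo + 1L, hi)
    q <- if (reads$strand[i] == "-") revcomp(reads$seq[i]) else reads$seq[i]
    oracle[i] <- full_sw_oracle(q, window, ags)$score
    ok[i] <- !is.na(cs[i]) && cs[i] >= oracle[i]
  }
  list(pct = 100 * mean(ok), n = nrow(reads),
       details = data.frame(name = reads$name, coverageScore = cs,
                            oracleScore = oracle, ok = ok))
}

#' Simple-SV breakpoint detection experiment
#'
#' Simulates deletions, tandem duplications, inversions and distant-locus
#' insertions on a random synthetic genome, builds breakpoint-spanning
#' contigs, samples error-bearing reads, aligns them, and verifies truth
#' junctions from split alignments within the given tolerance.
#'
#' @param refLength Synthetic genome length.
#' @param nPerType Events per type.
#' @param lengthRange Event length range.
#' @param readLength,coverage,errorRate,indelFrac Read simulation settings.
#' @param minMatch minMatch threshold.
#' @param tolerance Breakpoint tolerance in bases.
#' @param seed Integer seed.
#' @return The [verify_breakpoints()] report, plus `events`, `truth` and
#'   the read count `nReads`.
#' @export
sv_detection_experiment <- function(refLength = 1e6, nPerType = 25L,
                                    lengthRange = c(100L, 10000L),
                                    readLength = 500L, coverage = 5,
                                    errorRate = 0.02, indelFrac = 0.1,
                                    minMatch = 25L, tolerance = 5L,
                                    seed = 1L) {
  ref <- make_synthetic_reference(refLength, names = "chr1", rngSeed = seed)
  events <- simulate_sv_events(ref, nPerType = nPerType,
                               lengthRange = lengthRange,
                               rngSeed = seed + 1L)
  sim <- apply_sv_events(ref, events)
  reads <- sample_reads(sim$contigs,
                        read_sim_params(readLength = readLength,
                                        coverage = coverage,
                                        errorRate = errorRate,
                                        indelFrac = indelFrac,
                                        rngSeed = seed + 2L))
  index <- build_index(ref)
  opts <- align_opts(chain = chain_params(minMatch = minMatch,
                                          maxRegionGap = NA))
  aln <- align_reads(index, reads, opts, includeSecondaries = FALSE)
  rep <- verify_breakpoints(aln, sim$truth, readTruth = reads,
                            tolerance = tolerance)
  c(rep, list(events = events, truth = sim$truth, nReads = nrow(reads)))
}

#' Repeat-element insertion detection with and without secondaries
#'
#' Plants a repeat family whose youngest members are identical (a recently
#' expanded subfamily), simulates insertions whose donors are those
#' identical elements, and measures the fraction of insertion junctions
#' verified using primary alignments alone versus primaries plus FBS
#' secondaries. Because the donor locus is ambiguous among identical
#' copies, the Optimal Coverage Set tends to place the element-side
#' alignment at one arbitrary (distance-favoured) copy, while the
#' similarity filter recovers the true donor as a secondary.
#'
#' @param refLength Synthetic genome length.
#' @param nCopies,nIdentical,copyLength,divergence Repeat family layout.
#' @param nInsertions Number of insertion events (donors drawn from the
#'   identical copies).
#' @param readLength,coverage,errorRate,indelFrac Read simulation settings.
#' @param minMatch minMatch threshold.
#' @param tolerance Breakpoint tolerance in bases.
#' @param seed Integer seed.
#' @return List with `pctPrimary`, `pctWithSecondaries` (junction
#'   verification rates) and the two full reports.
#' @export
alu_experiment <- function(refLength = 1e6, nCopies = 30L, nIdentical = 6L,
                           copyLength = 300L, divergence = 0.05,
                           nInsertions = 30L, readLength = 500L,
                           coverage = 5, errorRate = 0.02, indelFrac = 0.1,
                           minMatch = 25L, tolerance = 5L, seed = 1L) {
  ref <- make_synthetic_reference(
    refLength, names = "chr1",
    repeatFamily = list(n = nCopies, length = copyLength,
                        divergence = divergence, nIdentical = nIdentical),
    rngSeed = seed)
  repDf <- attr(ref, "repeats")
  donors <- repDf[repDf$identical, , drop = FALSE]
  events <- simulate_sv_events(
    ref, nPerType = nInsertions, types = "insertion_from_distant_locus",
    lengthRange = c(copyLength, copyLength), donorPool = donors,
    rngSeed = seed + 1L)
  sim <- apply_sv_events(ref, events)
  reads <- sample_reads(sim$contigs,
                        read_sim_params(readLength = readLength,
                                        coverage = coverage,
                                        errorRate = errorRate,
                                        indelFrac = indelFrac,
                                        rngSeed = seed + 2L))
  index <- build_index(ref)
  opts <- align_opts(chain = chain_params(minMatch = minMatch,
                                          maxRegionGap = NA))
  aln <- align_reads(index, reads, opts, includeSecondaries = TRUE)
  repPrim <- verify_breakpoints(aln, sim$truth, readTruth = reads,
                                tolerance = tolerance,
                                includeSecondaries = FALSE)
  repSec <- verify_breakpoints(aln, sim$truth, readTruth = reads,
                               tolerance = tolerance,
                               includeSecondaries = TRUE)
  list(pctPrimary = repPrim$pctJunctionsVerified,
       pctWithSecondaries = repSec$pctJunctionsVerified,
       primaryReport = repPrim, secondaryReport = repSec,
       truth = sim$truth, nReads = nrow(reads))
}

#' Chromothripsis contig detection experiment
#'
#' Simulates chromosome-shattering contigs, impresses an error profile on
#' each contig, aligns the contigs directly as long reads, and verifies
#' the shattering junctions from the Optimal Coverage Set.
#'
#' @param refLength Synthetic genome length.
#' @param nContigs Number of shattered contigs.
#' @param regionLength Total shattered length per contig.
#' @param numLoci Loci contributing fragments per contig (1 or 2).
#' @param errorRate,indelFrac Contig error profile (e.g. 1%/10% for
#'   assembled contigs, 4%/90% for single-molecule long reads).
#' @param minMatch minMatch threshold.
#' @param tolerance Breakpoint tolerance in bases.
#' @param seed Integer seed.
#' @return The [verify_breakpoints()] report plus `nJunctions`.
#' @export
cgr_experiment <- function(refLength = 1e6, nContigs = 10L,
                           regionLength = 30000L, numLoci = 1L,
                           errorRate = 0.01, indelFrac = 0.1,
                           minMatch = 25L, tolerance = 5L, seed = 1L) {
  ref <- make_synthetic_reference(refLength, names = "chr1", rngSeed = seed)
  contigs <- character(0)
  truth <- list()
  for (i in seq_len(nContigs)) {
    cg <- apply_cgr(ref, cgr_spec(regionLength = regionLength,
                                  numLoci = numLoci,
                                  rngSeed = seed + 10L + i),
                    contigName = sprintf("cgr%03d", i))
    contigs <- c(contigs, cg$contig)
    truth[[i]] <- cg$truth
  }
  truth <- do.call(rbind, truth)
  index <- build_index(ref)
  with_seed(seed + 999L, {
    errored <- vapply(contigs, apply_read_errors, character(1),
                      errorRate = errorRate, indelFrac = indelFrac)
  })
  reads <- data.frame(name = names(contigs), seq = unname(errored),
                      stringsAsFactors = FALSE)
  opts <- align_opts(chain = chain_params(minMatch = minMatch,
                                          maxRegionGap = NA))
  aln <- align_reads(index, reads, opts, includeSecondaries = FALSE)
  rep <- verify_breakpoints(aln, truth, tolerance = tolerance)
  c(rep, list(nJunctions = nrow(truth)))
}
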