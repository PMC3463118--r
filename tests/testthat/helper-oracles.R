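# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes the dumbest correct route (enumeration, full
# unbanded DP, an external alignment implementation) so that it shares no
# code path with the implementation it checks.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate, indelFrac = 0) {
  splitmap:::apply_read_errors(seq, rate, indelFrac)
}

rc <- function(seq) splitmap:::revcomp(seq)

# Biostrings pairwiseAlignment as the external affine-gap DP oracle; its
# gap convention (gapOpening + gapExtension * L) matches the package's.
bs_score <- function(a, b, type, ags = ags_params()) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = ags$match,
                                                mismatch = ags$mismatch,
                                                baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = type, substitutionMatrix = m,
    gapOpening = -ags$gapOpen, gapExtension = -ags$gapExtend)))
}

# exhaustive chain oracle: enumerate every qStart-ordered fragment chain
chain_oracle <- function(group, ags = ags_params()) {
  o <- order(group$qStart, group$rStart)
  fr <- group[o, , drop = FALSE]
  n <- nrow(fr)
  reward <- ags$match * (fr$qEnd - fr$qStart)
  best <- -Inf
  extend <- function(last, score) {
    best <<- max(best, score)
    if (last < n) {
      for (j in (last + 1L):n) {
        e <- chain_score_edge(fr[last, ], fr[j, ], ags)
        if (is.finite(e)) extend(j, score + reward[j] + e)
      }
    }
  }
  for (i in seq_len(n)) extend(i, reward[i])
  best
}

# exhaustive OQC oracle: score every qStart-ordered alignment subset
oqc_oracle <- function(aln, oqc = oqc_params()) {
  o <- order(aln$qStart, aln$qEnd, aln$refName, aln$rStart, aln$strand)
  a <- aln[o, , drop = FALSE]
  n <- nrow(a)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    sc <- a$score[idx[1]]
    ok <- TRUE
    if (length(idx) > 1L) {
      for (t in 2:length(idx)) {
        g <- overlap_adjusted_gain(a[idx[t - 1L], ], a[idx[t], ])
        if (!is.finite(g)) { ok <- FALSE; break }
        sc <- sc + g - oqc$BP *
          genomic_distance_penalty(a[idx[t - 1L], ], a[idx[t], ], oqc)
      }
    }
    if (ok && sc > best) best <- sc
  }
  best
}

# full anchored-extension DP (no band, no X-drop), best cell anywhere
xdrop_oracle <- function(a, b, ags = ags_params()) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) return(0)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  NEG <- -1e9
  H <- matrix(NEG, la + 1L, lb + 1L)
  E <- matrix(NEG, la + 1L, lb + 1L)
  FF <- matrix(NEG, la + 1L, lb + 1L)
  H[1, 1] <- 0
  go <- ags$gapOpen; ge <- ags$gapExtend
  for (j in 2:(lb + 1L)) {
    E[1, j] <- max(H[1, j - 1] + go + ge, E[1, j - 1] + ge)
    H[1, j] <- E[1, j]
  }
  for (i in 2:(la + 1L)) {
    FF[i, 1] <- max(H[i - 1, 1] + go + ge, FF[i - 1, 1] + ge)
    H[i, 1] <- FF[i, 1]
    for (j in 2:(lb + 1L)) {
      E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
      FF[i, j] <- max(H[i - 1, j] + go + ge, FF[i - 1, j] + ge)
      s <- if (A[i - 1] == B[j - 1]) ags$match else ags$mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], FF[i, j])
    }
  }
  max(max(H), 0)
}

# naive posting oracle: all occurrences of kmer in seq (overlapping)
naive_occurrences <- function(seq, kmer) {
  n <- nchar(seq); k <- nchar(kmer)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  which(substring(seq, starts, starts + k - 1L) == kmer) - 1L
}

# random fragment group on plausible geometry for chaining tests
random_fragment_group <- function(n, qRange = 200L, rBase = 1000L) {
  qStart <- sample.int(qRange, n, replace = TRUE) - 1L
  len <- sample(8:40, n, replace = TRUE)
  rStart <- rBase + sample.int(qRange * 3L, n, replace = TRUE) - 1L
  data.frame(qStart = qStart, qEnd = qStart + len,
             rStart = rStart, rEnd = rStart + len,
             diagonal = rStart - qStart, seedCount = 1L)
}

# random alignment set for OQC tests
random_alignment_set <- function(n, nRef = 2L) {
  qStart <- sample.int(400L, n, replace = TRUE) - 1L
  len <- sample(30:200, n, replace = TRUE)
  rStart <- sample.int(100000L, n, replace = TRUE)
  data.frame(qname = "q", strand = sample(c("+", "-"), n, replace = TRUE),
             refName = sample(paste0("chr", seq_len(nRef)), n, replace = TRUE),
             rStart = rStart, rEnd = rStart + len,
             qStart = qStart, qEnd = qStart + len, queryLength = 600L,
             cigar = paste0(len, "M"), score = sample(20:200, n, TRUE),
             isPrimary = FALSE, isSecondary = FALSE,
             stringsAsFactors = FALSE)
}

small_index <- function(seqs, k = 11L, ...) {
  build_index(seqs, index_params(k = k, ...))
}

default_opts <- function(minMatch = 25L) {
  align_opts(chain = chain_params(minMatch = minMatch, maxRegionGap = NA))
}
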