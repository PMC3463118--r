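aln_row <- function(qs, qe, score, rs = 1000L, refName = "chr1",
                    strand = "+") {
  data.frame(qname = "q", strand = strand, refName = refName,
             rStart = rs, rEnd = rs + (qe - qs), qStart = qs, qEnd = qe,
             queryLength = 1000L, cigar = paste0(qe - qs, "M"),
             score = score, isPrimary = FALSE, isSecondary = FALSE,
             stringsAsFactors = FALSE)
}

test_that("genomic distance penalty is log10 of the gap, floored and capped", {
  p <- oqc_params(BP = 5, maxGDP = 5)
  a <- aln_row(0, 100, 100, rs = 1000)
  b <- aln_row(100, 200, 100, rs = 2100)  # gap 1000
  expect_identical(genomic_distance_penalty(a, b, p), 3)
  # adjacent or overlapping on the reference -> 0
  expect_identical(genomic_distance_penalty(a, aln_row(100, 200, 100, 1100), p), 0)
  expect_identical(genomic_distance_penalty(a, aln_row(100, 200, 100, 1050), p), 0)
  # different sequences always incur maxGDP
  expect_identical(
    genomic_distance_penalty(a, aln_row(100, 200, 100, 1000, "chr2"), p), 5)
  # monotone non-decreasing in the gap, capped at maxGDP
  gaps <- c(0, 1, 5, 10, 100, 1e4, 1e6, 1e8)
  gdp <- vapply(gaps, function(g)
    genomic_distance_penalty(a, aln_row(100, 200, 100, 1100 + g), p),
    numeric(1))
  expect_false(is.unsorted(gdp))
  expect_true(all(gdp <= 5))
})

test_that("overlap-adjusted gain prorates the weaker alignment over the overlap", {
  a <- aln_row(0, 100, 100)
  expect_identical(overlap_adjusted_gain(a, aln_row(100, 200, 80)), 80)
  # 10-base overlap, both at per-base 1.0
  expect_identical(overlap_adjusted_gain(a, aln_row(90, 190, 100)), 90)
  # weaker per-base rate is the one credited
  expect_identical(overlap_adjusted_gain(a, aln_row(90, 190, 50)), 45)
  # containment disallowed
  expect_identical(overlap_adjusted_gain(a, aln_row(10, 90, 50)), -Inf)
})

test_that("OQC selects the optimal coverage set on canonical configurations", {
  one <- aln_row(0, 300, 280)
  r1 <- optimal_query_coverage(one)
  expect_identical(nrow(r1$primaries), 1L)
  expect_identical(r1$coverageScore, 280)
  # two strong query-disjoint alignments plus weaker overlapping ones:
  # the strong pair is primary
  aln <- rbind(aln_row(0, 500, 480, rs = 1000),
               aln_row(500, 1000, 470, rs = 8000),
               aln_row(100, 400, 120, rs = 50000),
               aln_row(550, 900, 110, rs = 70000))
  r2 <- optimal_query_coverage(aln)
  expect_identical(sort(r2$primaries$score), c(470, 480))
  expect_identical(r2$coverageScore, oqc_oracle(aln))
  expect_identical(nrow(optimal_query_coverage(aln[0, ])$primaries), 0L)
})

test_that("OQC equals brute-force enumeration on random instances", {
  set.seed(51)
  for (rep in 1:80) {
    aln <- random_alignment_set(sample(2:8, 1))
    r <- optimal_query_coverage(aln)
    expect_equal(r$coverageScore, oqc_oracle(aln))
    expect_false(is.unsorted(r$primaries$qStart))
  }
})

test_that("raising the breakpoint penalty never fragments the coverage set more", {
  set.seed(52)
  for (rep in 1:15) {
    aln <- random_alignment_set(6)
    sizes <- vapply(c(0, 2, 5, 10, 25, 100), function(bp) {
      nrow(optimal_query_coverage(aln, oqc_params(BP = bp))$primaries)
    }, numeric(1))
    expect_false(is.unsorted(rev(sizes)))
  }
})

test_that("FBS keeps only near-duplicates of a primary", {
  prim <- aln_row(0, 300, 290, rs = 1000)
  dup <- aln_row(0, 300, 290, rs = 50000)       # exact duplicate elsewhere
  weak <- aln_row(0, 300, 100, rs = 60000)      # fails the score fraction
  partial <- aln_row(270, 570, 20, rs = 70000)  # 10% overlap, weak
  res <- optimal_query_coverage(rbind(prim, dup, weak, partial))
  res <- filter_by_similarity(res)
  expect_identical(nrow(res$secondaries), 1L)
  expect_equal(res$secondaries$rStart, 50000)
  # direct threshold scan oracle over a random pool
  set.seed(53)
  pool <- random_alignment_set(12)
  pool$qStart <- sample(c(0L, 5L, 200L), 12, replace = TRUE)
  pool$qEnd <- pool$qStart + 100L
  r2 <- filter_by_similarity(optimal_query_coverage(pool))
  p <- r2$primaries
  expected <- vapply(seq_len(nrow(r2$alignments)), function(i) {
    a <- r2$alignments[i, ]
    if (a$isPrimary) return(FALSE)
    any(vapply(seq_len(nrow(p)), function(j) {
      ov <- max(0, min(a$qEnd, p$qEnd[j]) - max(a$qStart, p$qStart[j]))
      ov / (a$qEnd - a$qStart) >= 0.9 &&
        ov / (p$qEnd[j] - p$qStart[j]) >= 0.9 &&
        a$score >= 0.9 * p$score[j]
    }, logical(1)))
  }, logical(1))
  got <- paste(r2$alignments$qStart, r2$alignments$rStart)[expected]
  expect_setequal(paste(r2$secondaries$qStart, r2$secondaries$rStart), got)
})

test_that("report-all mode passes everything through with one primary", {
  aln <- rbind(aln_row(0, 100, 90, rs = 1000),
               aln_row(0, 100, 95, rs = 9000),
               aln_row(200, 300, 95, rs = 3000))
  r <- report_all_mode(aln)
  expect_identical(nrow(r$alignments), 3L)
  expect_identical(sum(r$alignments$isPrimary), 1L)
  # best-score tie broken by (refName, rStart)
  expect_equal(r$primaries$rStart, 3000)
  expect_identical(nrow(report_all_mode(aln[0, ])$alignments), 0L)
})

test_that("primary coverage overlaps only pairwise at junctions on pipeline output", {
  set.seed(54)
  ref <- rand_dna(30000)
  idx <- small_index(c(chr = ref), k = 11)
  for (rep in 1:10) {
    s <- sample(1000:20000, 2)
    q <- paste0(mutate_seq(substr(ref, s[1], s[1] + 299), 0.02),
                mutate_seq(substr(ref, s[2], s[2] + 299), 0.02))
    res <- align_query(idx, q, opts = default_opts())
    p <- res$primaries
    expect_gte(nrow(p), 1L)
    cover <- integer(600)
    for (i in seq_len(nrow(p)))
      cover[(p$qStart[i] + 1):p$qEnd[i]] <- cover[(p$qStart[i] + 1):p$qEnd[i]] + 1L
    expect_lte(max(cover), 2L)
  }
})
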