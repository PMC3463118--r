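test_that("synthetic references are reproducible and honor requested layout", {
  r1 <- make_synthetic_reference(c(2000, 1000), rngSeed = 3)
  r2 <- make_synthetic_reference(c(2000, 1000), rngSeed = 3)
  expect_identical(r1, r2)
  expect_identical(nchar(unname(unclass(r1))), c(2000L, 1000L))
  expect_identical(names(r1), c("chr1", "chr2"))
  r3 <- make_synthetic_reference(c(2000, 1000), rngSeed = 4)
  expect_false(identical(r1[[1]], r3[[1]]))
})

test_that("planted repeat families have the configured identity structure", {
  ref <- make_synthetic_reference(
    60000, repeatFamily = list(n = 8, length = 300, divergence = 0.05,
                               nIdentical = 3), rngSeed = 5)
  rep <- attr(ref, "repeats")
  expect_identical(nrow(rep), 8L)
  copies <- substring(ref[[1]], rep$start + 1, rep$end)
  # identical subfamily members are exact duplicates
  expect_identical(copies[1], copies[2])
  expect_identical(copies[2], copies[3])
  # diverged copies sit in a mid-90s pairwise identity band
  pid <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  for (i in 4:8) {
    p <- pid(copies[1], copies[i])
    expect_gt(p, 0.85)
    expect_lt(p, 0.99)
  }
})

test_that("SV contig arithmetic matches the event definitions", {
  set.seed(71)
  ref <- c(chr1 = rand_dna(60000), chr2 = rand_dna(30000))
  ev <- data.frame(
    eventId = c("e1", "e2", "e3", "e4", "e5"),
    type = c("deletion", "inversion", "insertion_from_distant_locus",
             "tandem_duplication", "inversion"),
    refName = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    start = c(1000L, 5000L, 9000L, 12000L, 20000L),
    length = c(300L, 300L, 300L, 200L, 4000L),
    donorName = c(NA, NA, "chr2", NA, NA),
    donorStart = c(NA, NA, 7000L, NA, NA), stringsAsFactors = FALSE)
  sim <- apply_sv_events(ref, ev, flank = 500L)
  len <- nchar(sim$contigs)
  tr <- sim$truth
  # deletion: contig 2*flank, one junction at offset 500
  expect_identical(unname(len[1]), 1000L)
  expect_identical(tr$offset[tr$eventId == "e1"], 500L)
  expect_identical(tr$pos1[tr$eventId == "e1"], 1000L)
  expect_identical(tr$pos2[tr$eventId == "e1"], 1300L)
  # small inversion: length preserved, junctions at 500 and 800
  expect_identical(unname(len[2]), 1300L)
  expect_identical(tr$offset[tr$eventId == "e2"], c(500L, 800L))
  # insertion: junction sides on two different sequences
  e3 <- tr[tr$eventId == "e3", ]
  expect_identical(nrow(e3), 2L)
  expect_setequal(unique(c(e3$ref1, e3$ref2)), c("chr1", "chr2"))
  # small tandem duplication: contig 2*flank + 2*L
  expect_identical(unname(len[4]), 1400L)
  # large inversion: left-breakpoint contig only, 2*flank
  expect_identical(unname(len[5]), 1000L)
  expect_identical(sum(tr$eventId == "e5"), 1L)
  # overlapping events are rejected
  bad <- ev[c(1, 1), ]
  bad$eventId <- c("x1", "x2"); bad$start <- c(1000L, 1100L)
  expect_error(apply_sv_events(ref, bad), "overlap")
})

test_that("event simulation respects spacing, lengths and donor distance", {
  ref <- make_synthetic_reference(500000, rngSeed = 8)
  ev <- simulate_sv_events(ref, nPerType = 5, lengthRange = c(100, 5000),
                           rngSeed = 9)
  expect_identical(nrow(ev), 20L)
  expect_true(all(ev$length >= 100 & ev$length <= 5000))
  ins <- ev[ev$type == "insertion_from_distant_locus", ]
  expect_true(all(abs(ins$donorStart - ins$start) >= 100000 |
                    ins$donorName != ins$refName))
  expect_silent(apply_sv_events(ref, ev))
})

test_that("CGR contigs conserve sequence and junction counts", {
  ref <- make_synthetic_reference(100000, rngSeed = 10)
  cg <- apply_cgr(ref, cgr_spec(regionLength = 10000, rngSeed = 11))
  blocks <- cg$blocks
  expect_identical(nchar(cg$contig[[1]]), sum(blocks$end - blocks$start))
  # junction count: one per consecutive non-reference-adjacent pair
  adj <- vapply(seq_len(nrow(blocks) - 1), function(i) {
    a <- blocks[i, ]; b <- blocks[i + 1, ]
    a$refName == b$refName && a$strand == b$strand &&
      ((a$strand == "+" && b$start == a$end) ||
       (a$strand == "-" && b$end == a$start))
  }, logical(1))
  expect_identical(nrow(cg$truth), sum(!adj))
  expect_false(is.unsorted(cg$truth$offset, strictly = TRUE))
  # reproducible
  cg2 <- apply_cgr(ref, cgr_spec(regionLength = 10000, rngSeed = 11))
  expect_identical(cg$contig, cg2$contig)
})

test_that("CGR fragment fates match the configured fractions", {
  ref <- make_synthetic_reference(200000, rngSeed = 12)
  fates <- character(0)
  for (s in 1:40) {
    cg <- apply_cgr(ref, cgr_spec(regionLength = 6000, rngSeed = 100 + s))
    fates <- c(fates, attr(cg$blocks, "fate"))
  }
  n <- length(fates)
  pDel <- mean(fates == "deleted")
  # within 3 binomial sigma of the configured 30%
  expect_lt(abs(pDel - 0.30), 3 * sqrt(0.3 * 0.7 / n))
  pInv <- mean(fates == "inverted")
  expect_lt(abs(pInv - 0.50), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("read sampling matches the coverage and error model", {
  set.seed(72)
  contig <- c(ctg = rand_dna(5000))
  # error-free reads are exact substrings (or reverse complements)
  r0 <- sample_reads(contig, read_sim_params(readLength = 200, coverage = 2,
                                             errorRate = 0, rngSeed = 1))
  expect_identical(nrow(r0), 50L)
  for (i in seq_len(nrow(r0))) {
    src <- substr(contig[[1]], r0$start[i] + 1, r0$start[i] + 200)
    expect_identical(r0$seq[i], if (r0$strand[i] == "-") rc(src) else src)
  }
  # pure-substitution profile: empirical rate within 3 sigma of errorRate
  big <- c(ctg = rand_dna(50000))
  r1 <- sample_reads(big, read_sim_params(readLength = 500, coverage = 4,
                                          errorRate = 0.03, indelFrac = 0,
                                          rngSeed = 2))
  nSub <- 0L; nBase <- 0L
  for (i in seq_len(nrow(r1))) {
    src <- substr(big[[1]], r1$start[i] + 1, r1$start[i] + 500)
    if (r1$strand[i] == "-") src <- rc(src)
    nSub <- nSub + sum(strsplit(r1$seq[i], "")[[1]] != strsplit(src, "")[[1]])
    nBase <- nBase + 500L
  }
  pSub <- nSub / nBase
  expect_lt(abs(pSub - 0.03), 3 * sqrt(0.03 * 0.97 / nBase))
  # indel-dominated profile shifts read lengths
  r2 <- sample_reads(big, read_sim_params(readLength = 500, coverage = 1,
                                          errorRate = 0.04, indelFrac = 0.9,
                                          rngSeed = 3))
  expect_gt(mean(nchar(r2$seq) != 500), 0.5)
})

test_that("breakpoint verification honors the inclusive tolerance", {
  truth <- data.frame(contig = "ctg", offset = 500,
                      ref1 = "chr1", pos1 = 1000L, orient1 = "+",
                      ref2 = "chr1", pos2 = 3000L, orient2 = "-",
                      stringsAsFactors = FALSE)
  mk <- function(shift) {
    rbind(
      data.frame(qname = "r1", strand = "+", refName = "chr1",
                 rStart = 500L, rEnd = 1000L + shift, qStart = 0L,
                 qEnd = 500L, queryLength = 1000L, cigar = "500M",
                 score = 500, isPrimary = TRUE, isSecondary = FALSE),
      data.frame(qname = "r1", strand = "+", refName = "chr1",
                 rStart = 3000L, rEnd = 3500L, qStart = 500L, qEnd = 1000L,
                 queryLength = 1000L, cigar = "500M", score = 500,
                 isPrimary = TRUE, isSecondary = FALSE))
  }
  expect_true(verify_breakpoints(mk(0L), truth)$junctions$verified)
  expect_true(verify_breakpoints(mk(5L), truth)$junctions$verified)
  expect_false(verify_breakpoints(mk(6L), truth)$junctions$verified)
  # opposite-strand read: same junction seen through swapped breakends
  swapped <- mk(0L)
  swapped$strand <- "-"
  swapped$rStart <- c(3000L, 500L); swapped$rEnd <- c(3500L, 1000L)
  expect_true(verify_breakpoints(swapped, truth)$junctions$verified)
  # wrong orientation fails
  flip <- mk(0L)
  flip$strand <- c("-", "+")
  expect_false(verify_breakpoints(flip, truth)$junctions$verified)
  # contig-name cross-check against read truth
  rt <- data.frame(name = "r1", contig = "other", start = 0,
                   sourceLength = 1000)
  expect_error(verify_breakpoints(mk(0L), truth, readTruth = rt), "contig")
})
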