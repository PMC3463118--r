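test_that("banded global fill scores and gap conventions are exact", {
  r <- banded_affine_fill("ACGT", "ACGT")
  expect_identical(r$score, 4L)
  expect_identical(r$cigar, "4M")
  r2 <- banded_affine_fill("ACGT", "AGGT")
  expect_identical(r2$score, 0L)  # 3 matches - 3
  expect_identical(r2$cigar, "4M")
  # one-base gap costs gapOpen + gapExtend
  r3 <- banded_affine_fill("ACGT", "ACT")
  expect_identical(r3$score, -4L)  # 3 - (5 + 2)
  runs <- splitmap:::cigar_runs(r3$cigar)
  gapOps <- runs[runs$op != "M", ]
  expect_identical(sum(gapOps$len), 1L)
  expect_error(banded_affine_fill("", "ACGT"), "nonempty")
})

test_that("banded fill with a covering band equals the external global DP oracle", {
  set.seed(41)
  for (rep in 1:40) {
    la <- sample(5:120, 1)
    a <- rand_dna(la)
    b <- if (rep %% 2) mutate_seq(a, 0.15, 0.3) else rand_dna(sample(5:120, 1))
    got <- banded_affine_fill(a, b, bandWidth = max(nchar(a), nchar(b)))
    expect_equal(got$score, bs_score(a, b, "global"))
    # CIGAR must rescore to the same value
    re <- splitmap:::rescore_cigar_cpp(a, b, got$cigar, 1L, -3L, -5L, -2L)
    expect_identical(re$score, as.numeric(got$score))
    expect_identical(re$qConsumed, as.numeric(nchar(a)))
    expect_identical(re$rConsumed, as.numeric(nchar(b)))
  }
})

test_that("a narrow band is widened once when the length difference exceeds it", {
  a <- rand_dna(50)
  b <- paste0(substr(a, 1, 25), rand_dna(40), substr(a, 26, 50))
  r <- banded_affine_fill(a, b, bandWidth = 5)
  expect_true(r$widened)
  expect_identical(splitmap:::cigar_qlen(r$cigar), 50L)
  expect_identical(splitmap:::cigar_rlen(r$cigar), 90L)
})

test_that("x-drop extension walks identical sequence to the end and stops at noise", {
  s <- rand_dna(30)
  r <- xdrop_extend(s, s, 0, 0, "forward")
  expect_identical(r$score, 30L)
  expect_identical(r$qExtent, 30L)
  expect_identical(r$cigar, "30M")
  # 5 matching bases then pure mismatch: returns the peak, extent 5
  q <- paste0("AAAAA", strrep("C", 20))
  ref <- paste0("AAAAA", strrep("G", 20))
  r2 <- xdrop_extend(q, ref, 0, 0, "forward")
  expect_identical(r2$score, 5L)
  expect_identical(r2$qExtent, 5L)
  # backward extension mirrors forward on reversed input
  r3 <- xdrop_extend(rc(s), rc(s), nchar(s), nchar(s), "backward")
  expect_identical(r3$score, 30L)
})

test_that("x-drop with a huge X equals the unrestricted extension oracle", {
  set.seed(42)
  for (rep in 1:25) {
    la <- sample(10:120, 1)
    a <- rand_dna(la)
    b <- if (rep %% 2) mutate_seq(a, 0.2, 0.3) else rand_dna(sample(10:120, 1))
    got <- xdrop_extend(a, b, 0, 0, "forward",
                        dpParams = dp_params(bandWidth = 100, X = 1e6))
    expect_equal(got$score, xdrop_oracle(a, b))
  }
})

test_that("the full-SW oracle finds exact local alignments", {
  r <- full_sw_oracle("ACGT", "TTACGTTT")
  expect_identical(r$score, 4L)
  expect_identical(c(r$rStart, r$rEnd), c(2L, 6L))
  # disjoint alphabets: empty local alignment, score floor 0
  r2 <- full_sw_oracle("AAAA", "GGGG")
  expect_identical(r2$score, 0L)
  expect_identical(r2$cigar, "")
  set.seed(43)
  for (rep in 1:25) {
    a <- rand_dna(sample(20:100, 1))
    b <- if (rep %% 2) paste0(rand_dna(10), mutate_seq(a, 0.1, 0.2),
                              rand_dna(10)) else rand_dna(sample(20:100, 1))
    expect_equal(full_sw_oracle(a, b)$score, bs_score(a, b, "local"))
  }
})

test_that("completed alignments assemble fragments, fills and extensions exactly", {
  set.seed(44)
  ref <- rand_dna(6000)
  idx <- small_index(c(chr = ref), k = 11)
  # perfect full-length query: single all-M alignment at full score
  q <- substr(ref, 2001, 2400)
  res <- align_query(idx, q, opts = default_opts())
  expect_identical(nrow(res$primaries), 1L)
  expect_identical(res$primaries$cigar, "400M")
  expect_identical(res$primaries$score, 400)
  # 3-base reference insertion: spanned by a 3D op, score down by 5 + 2*3
  qdel <- paste0(substr(ref, 3001, 3200), substr(ref, 3204, 3400))
  res2 <- align_query(idx, qdel, opts = default_opts())
  expect_identical(nrow(res2$primaries), 1L)
  expect_match(res2$primaries$cigar, "3D")
  expect_identical(res2$primaries$score, 397 - 11)
})

test_that("reported scores equal CIGAR rescoring on simulated error reads", {
  set.seed(45)
  ref <- rand_dna(20000)
  idx <- small_index(c(chr = ref), k = 11)
  reads <- sample_reads(c(chr = ref),
                        read_sim_params(readLength = 150, coverage = 0.5,
                                        errorRate = 0.02, indelFrac = 0.2,
                                        rngSeed = 9))
  checked <- 0L
  for (i in seq_len(nrow(reads))) {
    res <- align_query(idx, reads$seq[i], reads$name[i], default_opts())
    aln <- res$alignments
    for (j in seq_len(nrow(aln))) {
      expect_identical(rescore_alignment(aln[j, ], reads$seq[i], idx),
                       aln$score[j])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("the heuristic pipeline never beats the full-SW oracle", {
  set.seed(46)
  ref <- rand_dna(10000)
  idx <- small_index(c(chr = ref), k = 11)
  for (rep in 1:20) {
    s <- sample(1000:8000, 1)
    q <- mutate_seq(substr(ref, s, s + 199), 0.05, 0.2)
    res <- align_query(idx, q, opts = default_opts())
    if (nrow(res$primaries) == 0) next
    oracle <- full_sw_oracle(q, ref)
    expect_lte(max(res$alignments$score), oracle$score)
  }
})
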