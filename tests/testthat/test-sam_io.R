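test_that("FASTA and FASTQ queries round-trip through the readers", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">q1 description", "ACGTACGT", ">q2", "TTTTGGGG"), fa)
  qs <- read_queries(fa)
  expect_identical(qs$name, c("q1", "q2"))
  expect_identical(qs$seq, c("ACGTACGT", "TTTTGGGG"))
  expect_true(all(is.na(qs$qual)))
  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTAC", "+", "IIIIII", "@r2", "GGGTTT", "+", "FFFFFF"),
             fq)
  qf <- read_queries(fq)
  expect_identical(qf$seq, c("ACGTAC", "GGGTTT"))
  expect_identical(qf$qual, c("IIIIII", "FFFFFF"))
  expect_error(suppressWarnings(read_queries(tempfile())))
})

test_that("SAM records carry correct flags, coordinates, clips and scores", {
  set.seed(61)
  ref <- c(chrA = rand_dna(3000), chrB = rand_dna(2000))
  idx <- small_index(ref, k = 11)
  fq <- tempfile(fileext = ".fq")
  reads <- data.frame(
    name = c("plus", "minus", "nohit"),
    seq = c(substr(ref["chrB"], 501, 800),
            rc(paste0(rand_dna(50), substr(ref["chrA"], 1001, 1250))),
            strrep("N", 80)),
    qual = c(strrep("I", 300), strrep("I", 300), strrep("I", 80)))
  write_fastq(reads, fq)
  sam <- tempfile(fileext = ".sam")
  align_file(idx, fq, sam, default_opts())
  lines <- readLines(sam)
  expect_identical(sum(startsWith(lines, "@SQ")), 2L)
  body <- lines[!startsWith(lines, "@")]
  recs <- strsplit(body, "\t")
  byName <- setNames(recs, vapply(recs, `[`, "", 1))
  # plus-strand perfect alignment: POS is 1-based on its own sequence
  expect_identical(byName$plus[2], "0")
  expect_identical(byName$plus[3], "chrB")
  expect_identical(byName$plus[4], "501")
  expect_identical(byName$plus[6], "300M")
  expect_identical(byName$plus[12], "AS:i:300")
  # minus-strand: flag 16, SEQ is the reverse complement, clip on the
  # correct end
  expect_identical(byName$minus[2], "16")
  expect_identical(byName$minus[10], rc(reads$seq[2]))
  # soft clip covers the non-reference prefix (the x-drop extension may
  # claim a couple of chance-matching bases from it)
  mruns <- splitmap:::cigar_runs(byName$minus[6])
  expect_identical(mruns$op[1], "S")
  expect_gte(mruns$len[1], 45L)
  expect_identical(sum(mruns$len[mruns$op %in% c("S", "M", "I")]), 300L)
  # all-N query: unmapped flag 4
  expect_identical(byName$nohit[2], "4")
  expect_identical(byName$nohit[3], "*")
  # CIGAR length must equal SEQ length on every mapped record
  for (r in recs) {
    if (r[6] == "*") next
    runs <- splitmap:::cigar_runs(r[6])
    expect_identical(sum(runs$len[runs$op %in% c("M", "I", "S")]),
                     nchar(r[10]))
  }
})

test_that("our SAM is accepted by an external validator and round-trips", {
  set.seed(62)
  ref <- c(chr1 = rand_dna(8000))
  idx <- small_index(ref, k = 11)
  contig <- paste0(substr(ref, 1001, 1500), substr(ref, 4001, 4500))
  reads <- sample_reads(c(ctg = contig),
                        read_sim_params(readLength = 200, coverage = 3,
                                        errorRate = 0.01, rngSeed = 4))
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  sam <- tempfile(fileext = ".sam")
  align_file(idx, fq, sam, default_opts())
  # external parser/validator
  bam <- suppressWarnings(Rsamtools::asBam(sam, tempfile(),
                                           overwrite = TRUE,
                                           indexDestination = FALSE))
  expect_true(file.exists(bam))
  # round-trip: spans and scores recovered exactly
  back <- parse_sam(sam)
  back <- back[!is.na(back$rStart), ]
  expect_gt(nrow(back), 0)
  for (i in seq_len(nrow(reads))) {
    res <- align_query(idx, reads$seq[i], reads$name[i], default_opts())
    rep <- reported_alignments(res)
    got <- back[back$qname == reads$name[i], , drop = FALSE]
    expect_identical(nrow(got), nrow(rep))
    if (nrow(rep)) {
      o1 <- order(rep$qStart, rep$rStart)
      o2 <- order(got$qStart, got$rStart)
      for (col in c("qStart", "qEnd", "rStart", "rEnd", "strand", "cigar")) {
        expect_identical(got[[col]][o2], rep[[col]][o1])
      }
      expect_identical(got$score[o2], rep$score[o1])
    }
  }
})

test_that("alignment of a file is deterministic across reruns", {
  set.seed(63)
  ref <- c(chr1 = rand_dna(5000))
  idx <- small_index(ref, k = 11)
  reads <- sample_reads(c(chr1 = ref[[1]]),
                        read_sim_params(readLength = 120, coverage = 0.5,
                                        errorRate = 0.02, rngSeed = 8))
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  align_file(idx, fq, s1, default_opts())
  align_file(idx, fq, s2, default_opts())
  expect_identical(readLines(s1), readLines(s2))
})
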