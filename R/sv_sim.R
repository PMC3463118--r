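# Structural-variant / chromothripsis simulator, read sampler with
# configurable error profiles, and the within-tolerance breakpoint
# verification metric.

#' Generate a random synthetic reference genome
#'
#' Sequences are i.i.d. draws with a GC bias, reproducible from the seed.
#' Optionally a family of repeat elements is planted (copies of one
#' consensus, overwriting slices of the host sequence at non-overlapping
#' positions) to emulate interspersed repeats such as Alu elements: older
#' copies carry substitutions at the given divergence, while `nIdentical`
#' copies are exact — modelling a young, recently expanded subfamily whose
#' members are indistinguishable, which is what makes repeat-insertion
#' breakpoints ambiguous for an aligner.
#'
#' @param lengths Integer vector of sequence lengths.
#' @param names Sequence names (default `chr1..chrN`).
#' @param gc GC fraction.
#' @param repeatFamily Optional list with `n` (copies), `length`,
#'   `divergence` (per-base substitution rate of diverged copies from the
#'   consensus) and `nIdentical`.
#' @param rngSeed Integer seed.
#' @return A named character vector of sequences; planted repeat locations
#'   (a data.frame with `refName`, `start`, `end`, `copy`, `identical`) are
#'   attached as attribute `repeats`.
#' @export
make_synthetic_reference <- function(lengths, names = NULL, gc = 0.5,
                                     repeatFamily = NULL, rngSeed = 1L) {
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  with_seed(rngSeed, {
    seqs <- vapply(lengths, random_dna, character(1), gc = gc)
    names(seqs) <- names
    repDf <- NULL
    if (!is.null(repeatFamily)) {
      rf <- repeatFamily
      nIdent <- rf$nIdentical %||% 0L
      consensus <- random_dna(rf$length, gc = gc)
      # place copies in the first (host) sequence, non-overlapping, away
      # from the edges
      margin <- 2000L
      hostLen <- lengths[1]
      slots <- place_nonoverlapping(rf$n, rf$length, hostLen, margin,
                                    spacing = rf$length)
      rows <- vector("list", rf$n)
      host <- seqs[[1]]
      for (i in seq_len(rf$n)) {
        ident <- i <= nIdent
        copy <- if (ident) consensus else mutate_subs(consensus, rf$divergence)
        substr(host, slots[i] + 1L, slots[i] + rf$length) <- copy
        rows[[i]] <- data.frame(refName = names[1], start = slots[i],
                                end = slots[i] + rf$length, copy = i,
                                identical = ident)
      }
      seqs[[1]] <- host
      repDf <- do.call(rbind, rows)
    }
    structure(seqs, repeats = repDf)
  })
}

# sample n non-overlapping starts of width-`width` intervals in [margin,
# total - margin - width], at least `spacing` apart
place_nonoverlapping <- function(n, width, total, margin, spacing = 0L) {
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place non-overlapping intervals")
    s <- sample.int(total - 2L * margin - width, 1L) + margin
    if (all(abs(s - starts) >= width + spacing)) starts <- c(starts, s)
  }
  starts
}

mutate_subs <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a random set of simple SV events
#'
#' Draws non-overlapping deletion, tandem-duplication, inversion and
#' distant-locus-insertion events with log-uniform lengths in
#' `lengthRange`, keeping `flank` clearance from sequence ends and between
#' events. Insertion donor loci are at least 100 kb from the recipient (or
#' on another sequence); when `donorPool` is given (e.g. planted repeat
#' copies), donors are drawn from it instead.
#'
#' @param reference Named character vector of reference sequences.
#' @param nPerType Number of events of each type.
#' @param types Event types to simulate.
#' @param lengthRange Event length range in bases.
#' @param flank Flanking clearance (and later contig flank) in bases.
#' @param donorPool Optional data.frame with `refName`, `start`, `end`
#'   rows; insertion donors are sampled from it (lengths capped to the
#'   pool interval).
#' @param rngSeed Integer seed.
#' @return Data.frame of events: `eventId`, `type`, `refName`, `start`,
#'   `length`, `donorName`, `donorStart` (0-based).
#' @export
simulate_sv_events <- function(reference, nPerType = 25L,
                               types = c("deletion", "tandem_duplication",
                                         "inversion",
                                         "insertion_from_distant_locus"),
                               lengthRange = c(100L, 10000L), flank = 500L,
                               donorPool = NULL, rngSeed = 1L) {
  refLengths <- nchar(reference)
  refNames <- names(reference)
  with_seed(rngSeed, {
    events <- list()
    used <- data.frame(refName = character(0), start = numeric(0),
                       end = numeric(0))
    reserve <- function(refName, start, end) {
      used <<- rbind(used, data.frame(refName = refName, start = start,
                                      end = end))
    }
    clashes <- function(refName, start, end) {
      sel <- used$refName == refName
      any(sel & start < used$end + flank & end > used$start - flank)
    }
    eid <- 0L
    for (type in types) {
      for (i in seq_len(nPerType)) {
        eid <- eid + 1L
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 2000L)
            stop("could not place ", nPerType, " non-overlapping ", type,
                 " events of length ", lengthRange[1], "-", lengthRange[2],
                 " on this reference; reduce nPerType or lengthRange")
          L <- round(exp(runif(1, log(lengthRange[1]), log(lengthRange[2]))))
          ri <- sample.int(length(reference), 1L,
                           prob = as.numeric(refLengths))
          span <- if (type == "insertion_from_distant_locus") flank else L
          lo <- flank
          hi <- refLengths[ri] - flank - span
          if (hi <= lo) next
          s <- sample.int(hi - lo, 1L) + lo
          if (clashes(refNames[ri], s, s + span)) next
          donorName <- NA_character_; donorStart <- NA_integer_
          if (type == "insertion_from_distant_locus") {
            if (!is.null(donorPool)) {
              d <- donorPool[sample.int(nrow(donorPool), 1L), ]
              donorName <- d$refName
              donorStart <- d$start
              L <- min(L, d$end - d$start)
            } else {
              ok <- FALSE
              for (t in 1:200) {
                di <- sample.int(length(reference), 1L)
                dhi <- refLengths[di] - flank - L
                if (dhi <= flank) next
                ds <- sample.int(dhi - flank, 1L) + flank
                distant <- refNames[di] != refNames[ri] ||
                  abs(ds - s) >= 100000L
                if (distant && !clashes(refNames[di], ds, ds + L)) {
                  donorName <- refNames[di]; donorStart <- ds; ok <- TRUE
                  break
                }
              }
              if (!ok) next
              reserve(donorName, donorStart, donorStart + L)
            }
          }
          reserve(refNames[ri], s, s + span)
          events[[eid]] <- data.frame(
            eventId = sprintf("ev%04d", eid), type = type,
            refName = refNames[ri], start = s, length = L,
            donorName = donorName, donorStart = donorStart,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
    do.call(rbind, events)
  })
}

# Build a contig from reference blocks and record the junctions between
# consecutive blocks that are not reference-adjacent.
build_contig <- function(reference, blocks, contigName) {
  parts <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    s <- substr(reference[[blocks$refName[i]]], blocks$start[i] + 1L,
                blocks$end[i])
    parts[i] <- if (blocks$strand[i] == "-") revcomp(s) else s
  }
  lens <- blocks$end - blocks$start
  offs <- cumsum(lens)
  jn <- list()
  for (i in seq_len(nrow(blocks) - 1L)) {
    a <- blocks[i, ]; b <- blocks[i + 1L, ]
    adjacent <- a$refName == b$refName && a$strand == b$strand &&
      ((a$strand == "+" && b$start == a$end) ||
       (a$strand == "-" && b$end == a$start))
    if (adjacent) next
    side1 <- if (a$strand == "+") c(a$refName, a$end, "+")
             else c(a$refName, a$start, "-")
    side2 <- if (b$strand == "+") c(b$refName, b$start, "-")
             else c(b$refName, b$end, "+")
    jn[[length(jn) + 1L]] <- data.frame(
      contig = contigName, offset = offs[i],
      ref1 = side1[1], pos1 = as.integer(side1[2]), orient1 = side1[3],
      ref2 = side2[1], pos2 = as.integer(side2[2]), orient2 = side2[3],
      stringsAsFactors = FALSE)
  }
  list(seq = paste(parts, collapse = ""),
       junctions = if (length(jn)) do.call(rbind, jn) else NULL)
}

sv_event_blocks <- function(ev, flank) {
  s <- ev$start; L <- ev$length; e <- s + L; R <- ev$refName
  blk <- function(refName, start, end, strand = "+")
    data.frame(refName = refName, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  small <- L <= flank
  switch(ev$type,
    deletion = rbind(blk(R, s - flank, s), blk(R, e, e + flank)),
    tandem_duplication = if (small)
      rbind(blk(R, s - flank, e), blk(R, s, e + flank))
    else rbind(blk(R, e - flank, e), blk(R, s, s + flank)),
    inversion = if (small)
      rbind(blk(R, s - flank, s), blk(R, s, e, "-"), blk(R, e, e + flank))
    else rbind(blk(R, s - flank, s), blk(R, e - flank, e, "-")),
    insertion_from_distant_locus = {
      d <- ev$donorName; ds <- ev$donorStart
      if (small)
        rbind(blk(R, s - flank, s), blk(d, ds, ds + L), blk(R, s, s + flank))
      else rbind(blk(R, s - flank, s), blk(d, ds, ds + flank))
    },
    stop("unknown event type: ", ev$type))
}

#' Build breakpoint-spanning contigs for simulated SV events
#'
#' Each event of rearranged length at most `flank` yields a single contig
#' spanning the whole event with `flank` bases on each side; larger events
#' yield a contig for the left breakpoint only, with `flank` flanking
#' bases. Every junction between reference-non-adjacent blocks is recorded
#' as truth: the two sides carry the reference coordinate adjacent to the
#' junction and an orientation (`+` if the joined segment lies left of the
#' coordinate on the reference, `-` if right).
#'
#' @param reference Named character vector of sequences.
#' @param events Event data.frame from [simulate_sv_events()]. Events must
#'   not overlap.
#' @param flank Flank size in bases.
#' @return List with `contigs` (named character vector) and `truth`
#'   (junction data.frame with `contig`, `offset`, `ref1`, `pos1`,
#'   `orient1`, `ref2`, `pos2`, `orient2`, `eventId`, `type`).
#' @export
apply_sv_events <- function(reference, events, flank = 500L) {
  check_no_overlap(events)
  contigs <- character(0)
  truth <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    blocks <- sv_event_blocks(ev, flank)
    if (any(blocks$start < 0) ||
        any(blocks$end > nchar(reference[blocks$refName])))
      stop("event ", ev$eventId, " does not fit within its sequence")
    nm <- paste0(ev$eventId, "_", ev$type)
    bc <- build_contig(reference, blocks, nm)
    contigs[nm] <- bc$seq
    if (!is.null(bc$junctions)) {
      bc$junctions$eventId <- ev$eventId
      bc$junctions$type <- ev$type
      truth[[length(truth) + 1L]] <- bc$junctions
    }
  }
  list(contigs = contigs, truth = do.call(rbind, truth))
}

check_no_overlap <- function(events) {
  ivs <- events[events$type != "insertion_from_distant_locus", ]
  if (nrow(ivs) < 2L) return(invisible(TRUE))
  for (nm in unique(ivs$refName)) {
    x <- ivs[ivs$refName == nm, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1L && any(x$start[-1] < (x$start + x$length)[-nrow(x)]))
      stop("events overlap on ", nm)
  }
  invisible(TRUE)
}

#' Chromothripsis (CGR) contig specification
#'
#' @param regionLength Total shattered region length (split across
#'   `numLoci` loci).
#' @param meanFragLen,minFragLen Fragment length law: approximately
#'   exponential with this mean, floored at the minimum.
#' @param fracDeleted,fracDuplicated,fracInverted Fragment fate
#'   probabilities (remainder is retained unmodified).
#' @param numLoci 1 or 2 genomic locations contributing fragments.
#' @param rngSeed Integer seed.
#' @return An object of class `cgr_spec`.
#' @export
cgr_spec <- function(regionLength = 30000L, meanFragLen = 300L,
                     minFragLen = 50L, fracDeleted = 0.30,
                     fracDuplicated = 0.10, fracInverted = 0.50,
                     numLoci = 1L, rngSeed = 1L) {
  if (fracDeleted < 0 || fracDuplicated < 0 || fracInverted < 0 ||
      fracDeleted + fracDuplicated + fracInverted > 1)
    stop("fragment fate fractions must be in [0,1] and sum to at most 1")
  if (!numLoci %in% c(1L, 2L)) stop("numLoci must be 1 or 2")
  structure(list(regionLength = as.integer(regionLength),
                 meanFragLen = as.integer(meanFragLen),
                 minFragLen = as.integer(minFragLen),
                 fracDeleted = fracDeleted, fracDuplicated = fracDuplicated,
                 fracInverted = fracInverted, numLoci = as.integer(numLoci),
                 rngSeed = as.integer(rngSeed)),
            class = "cgr_spec")
}

#' Simulate a chromosome-shattering (chromothripsis) contig
#'
#' Partitions the selected region(s) into fragments with approximately
#' exponential lengths (floored at the minimum), deletes / duplicates /
#' inverts fragments according to the configured fractions, randomly
#' shuffles the retained fragments and ligates them into a single contig.
#' Every junction between reference-non-adjacent fragments is recorded as
#' truth.
#'
#' @param reference Named character vector of sequences.
#' @param spec A [cgr_spec()].
#' @param contigName Name for the resulting contig.
#' @return List with `contig` (single-element named character vector),
#'   `truth` (junction data.frame), and `blocks` (the shuffled fragment
#'   table).
#' @export
apply_cgr <- function(reference, spec = cgr_spec(), contigName = "cgr1") {
  with_seed(spec$rngSeed, {
    perLocus <- spec$regionLength %/% spec$numLoci
    regions <- list()
    for (l in seq_len(spec$numLoci)) {
      ri <- sample.int(length(reference), 1L,
                       prob = as.numeric(nchar(reference)))
      hi <- nchar(reference[ri]) - perLocus - 1000L
      if (hi <= 1000L) stop("reference too short for CGR region")
      s <- sample.int(hi - 1000L, 1L) + 1000L
      regions[[l]] <- list(refName = names(reference)[ri], start = s,
                           end = s + perLocus)
    }
    frags <- list()
    for (rg in regions) {
      pos <- rg$start
      while (pos < rg$end) {
        len <- max(spec$minFragLen,
                   as.integer(round(rexp(1, 1 / spec$meanFragLen))))
        if (pos + len > rg$end) len <- rg$end - pos
        if (len < spec$minFragLen && length(frags)) {
          # merge the short remainder into the previous fragment
          frags[[length(frags)]]$end <- rg$end
          break
        }
        frags[[length(frags) + 1L]] <- list(refName = rg$refName,
                                            start = pos, end = pos + len)
        pos <- pos + len
      }
    }
    fate <- sample(c("deleted", "duplicated", "inverted", "retained"),
                   length(frags), replace = TRUE,
                   prob = c(spec$fracDeleted, spec$fracDuplicated,
                            spec$fracInverted,
                            1 - spec$fracDeleted - spec$fracDuplicated -
                              spec$fracInverted))
    blocks <- list()
    for (i in seq_along(frags)) {
      f <- frags[[i]]
      if (fate[i] == "deleted") next
      strand <- if (fate[i] == "inverted") "-" else "+"
      reps <- if (fate[i] == "duplicated") 2L else 1L
      for (r in seq_len(reps)) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          refName = f$refName, start = f$start, end = f$end,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    blocks <- do.call(rbind, blocks)
    blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
    attr(blocks, "fate") <- fate
    bc <- build_contig(reference, blocks, contigName)
    truth <- bc$junctions
    if (!is.null(truth)) {
      truth$eventId <- contigName
      truth$type <- "cgr"
    }
    list(contig = setNames(bc$seq, contigName), truth = truth,
         blocks = blocks)
  })
}

#' Read-sampling parameters
#'
#' @param readLength Read length in bases.
#' @param coverage Target mean coverage of each contig.
#' @param errorRate Per-base error probability.
#' @param indelFrac Fraction of errors that are 1-bp indels (insertions and
#'   deletions equiprobable); the rest are random substitutions.
#' @param rngSeed Integer seed.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(readLength = 500L, coverage = 5,
                            errorRate = 0.02, indelFrac = 0.1,
                            rngSeed = 1L) {
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0,1)")
  if (indelFrac < 0 || indelFrac > 1) stop("indelFrac must be in [0,1]")
  structure(list(readLength = as.integer(readLength), coverage = coverage,
                 errorRate = errorRate, indelFrac = indelFrac,
                 rngSeed = as.integer(rngSeed)),
            class = "read_sim_params")
}

apply_read_errors <- function(seq, errorRate, indelFrac) {
  if (errorRate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  err <- which(runif(length(ch)) < errorRate)
  if (length(err) == 0L) return(seq)
  for (i in err) {
    if (runif(1) < indelFrac) {
      if (runif(1) < 0.5) ch[i] <- ""                      # deletion
      else ch[i] <- paste0(ch[i], sample(c("A", "C", "G", "T"), 1L))  # insertion
    } else {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Sample error-bearing reads from contigs
#'
#' Reads are drawn uniformly from both strands of each contig to the target
#' coverage (`round(coverage * contigLength / readLength)` reads per
#' contig). Each base is independently errored at `errorRate`; an error is
#' a 1-bp indel with probability `indelFrac`, otherwise a random
#' substitution.
#'
#' @param contigs Named character vector of contig sequences.
#' @param params A [read_sim_params()].
#' @return A data.frame with `name`, `seq`, `qual` and per-read truth
#'   columns `contig`, `start` (0-based source offset), `strand`,
#'   `sourceLength` (error-free source span).
#' @export
sample_reads <- function(contigs, params = read_sim_params()) {
  with_seed(params$rngSeed, {
    rows <- list()
    for (ci in seq_along(contigs)) {
      len <- nchar(contigs[ci])
      if (params$readLength > len)
        stop("readLength exceeds contig length for ", names(contigs)[ci])
      n <- round(params$coverage * len / params$readLength)
      if (n == 0L) next
      starts <- sample.int(len - params$readLength + 1L, n,
                           replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)
      for (i in seq_len(n)) {
        src <- substr(contigs[ci], starts[i] + 1L,
                      starts[i] + params$readLength)
        if (strands[i] == "-") src <- revcomp(src)
        seq <- apply_read_errors(src, params$errorRate, params$indelFrac)
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s_r%04d", names(contigs)[ci], i),
          seq = seq, qual = strrep("I", nchar(seq)),
          contig = names(contigs)[ci], start = starts[i],
          strand = strands[i], sourceLength = params$readLength,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(rows, list(NULL)))
    rownames(out) <- NULL
    out
  })
}

#' Write reads as FASTQ / contigs as FASTA
#'
#' @param reads Data.frame from [sample_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  writeLines(as.vector(rbind(paste0("@", reads$name), reads$seq, "+",
                             reads$qual)), path)
  invisible(path)
}

#' @rdname write_fastq
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# breakend of the query-left alignment facing the junction
observed_breakends <- function(a, b) {
  endA <- if (a$strand == "+") c(a$refName, a$rEnd, "+")
          else c(a$refName, a$rStart, "-")
  startB <- if (b$strand == "+") c(b$refName, b$rStart, "-")
            else c(b$refName, b$rEnd, "+")
  list(endA = endA, startB = startB)
}

side_match <- function(ref, pos, orient, tref, tpos, torient, tol) {
  ref == tref & orient == torient & abs(pos - tpos) <= tol
}

#' Verify SV breakpoints from split alignments
#'
#' A query verifies a junction iff it has two alignments (primaries, or
#' primaries plus FBS secondaries when `includeSecondaries = TRUE`) that
#' are adjacent on the query (gap or overlap at most `maxJunctionSlack`)
#' and whose junction-facing reference ends both fall within `tolerance`
#' bases (inclusive) of the two truth sides, with matching orientations.
#' Matching is orientation-symmetric, so reads sampled from either strand
#' verify the same junction.
#'
#' @param alignments Alignment data.frame (e.g. from
#'   [reported_alignments()] or [parse_sam()]) or a SAM file path.
#' @param truth Junction truth data.frame from [apply_sv_events()] /
#'   [apply_cgr()].
#' @param readTruth Optional per-read truth from [sample_reads()]; when
#'   given, the per-query rate is computed over junction-spanning reads
#'   (junction at least `minOverhang` bases from both read ends) and
#'   contig names are cross-checked against `truth`.
#' @param tolerance Breakpoint tolerance in bases (inclusive).
#' @param includeSecondaries Use secondary alignments as well as primaries.
#' @param maxJunctionSlack Maximum query-coordinate gap/overlap between the
#'   paired alignments at the junction.
#' @param minOverhang Minimum read overhang on each side for a read to
#'   count as spanning a junction.
#' @return List with `junctions` (truth plus `verified`, `nSupport`),
#'   `queries` (per-query verification table), `pctJunctionsVerified` and
#'   `pctQueriesVerified`.
#' @export
verify_breakpoints <- function(alignments, truth, readTruth = NULL,
                               tolerance = 5L, includeSecondaries = FALSE,
                               maxJunctionSlack = 30L, minOverhang = 25L) {
  if (is.character(alignments)) alignments <- parse_sam(alignments)
  if (!is.null(readTruth)) {
    if (!all(readTruth$contig %in% truth$contig))
      stop("read truth names contigs absent from the junction truth")
  }
  aln <- alignments[!is.na(alignments$rStart), , drop = FALSE]
  if (!includeSecondaries) aln <- aln[aln$isPrimary, , drop = FALSE]
  nj <- nrow(truth)
  support <- integer(nj)
  qnames <- unique(aln$qname)
  qrows <- split(seq_len(nrow(aln)), aln$qname)
  queryHit <- setNames(rep(FALSE, length(qnames)), qnames)
  queryJn <- setNames(vector("list", length(qnames)), qnames)
  for (qn in qnames) {
    rows <- aln[qrows[[qn]], , drop = FALSE]
    if (nrow(rows) < 2L) next
    rows <- rows[order(rows$qStart, rows$qEnd), , drop = FALSE]
    hits <- integer(0)
    for (i in seq_len(nrow(rows) - 1L)) {
      for (j in seq(i + 1L, nrow(rows))) {
        gap <- rows$qStart[j] - rows$qEnd[i]
        if (abs(gap) > maxJunctionSlack) next
        ob <- observed_breakends(rows[i, ], rows[j, ])
        pA <- as.integer(ob$endA[2]); pB <- as.integer(ob$startB[2])
        m <- (side_match(ob$endA[1], pA, ob$endA[3],
                         truth$ref1, truth$pos1, truth$orient1, tolerance) &
              side_match(ob$startB[1], pB, ob$startB[3],
                         truth$ref2, truth$pos2, truth$orient2, tolerance)) |
             (side_match(ob$endA[1], pA, ob$endA[3],
                         truth$ref2, truth$pos2, truth$orient2, tolerance) &
              side_match(ob$startB[1], pB, ob$startB[3],
                         truth$ref1, truth$pos1, truth$orient1, tolerance))
        hits <- union(hits, which(m))
      }
    }
    if (length(hits)) {
      queryHit[qn] <- TRUE
      queryJn[[qn]] <- hits
      support[hits] <- support[hits] + 1L
    }
  }
  junctions <- truth
  junctions$nSupport <- support
  junctions$verified <- support > 0L
  if (!is.null(readTruth)) {
    spans <- vapply(seq_len(nrow(readTruth)), function(i) {
      js <- which(truth$contig == readTruth$contig[i])
      any(truth$offset[js] >= readTruth$start[i] + minOverhang &
          truth$offset[js] <= readTruth$start[i] +
            readTruth$sourceLength[i] - minOverhang)
    }, logical(1))
    spanning <- readTruth$name[spans]
    verified <- spanning %in% names(queryHit)[queryHit]
    queries <- data.frame(qname = spanning, verified = verified,
                          stringsAsFactors = FALSE)
    pctQ <- if (length(spanning)) 100 * mean(verified) else NA_real_
  } else {
    queries <- data.frame(qname = qnames, verified = unname(queryHit),
                          stringsAsFactors = FALSE)
    pctQ <- if (length(qnames)) 100 * mean(queryHit) else NA_real_
  }
  list(junctions = junctions, queries = queries,
       pctJunctionsVerified = if (nj) 100 * mean(junctions$verified)
                              else NA_real_,
       pctQueriesVerified = pctQ)
}
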