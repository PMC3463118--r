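# Query readers (FASTA/FASTQ) and a SAM writer/parser with correct strand,
# primary/secondary and soft-clip conventions.

#' Read queries from FASTA or FASTQ
#'
#' Format is detected from the first non-empty character (`>` FASTA, `@`
#' FASTQ); gzip input is accepted. Duplicate names are allowed but flagged
#' with a warning.
#'
#' @param path Input file.
#' @return A data.frame with `name`, `seq` and `qual` (`NA` for FASTA).
#' @export
read_queries <- function(path) {
  con <- gzfile(path, "rt")
  first <- ""
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1L, 1L); break }
  }
  close(con)
  if (first == ">") {
    x <- Biostrings::readDNAStringSet(path)
    out <- data.frame(name = sub("\\s.*$", "", names(x)),
                      seq = as.character(x), qual = NA_character_,
                      stringsAsFactors = FALSE)
  } else if (first == "@") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- data.frame(name = sub("\\s.*$", "", names(x)),
                      seq = as.character(x),
                      qual = as.character(S4Vectors::mcols(x)$qualities),
                      stringsAsFactors = FALSE)
  } else {
    stop("cannot detect query format (expected FASTA or FASTQ): ", path)
  }
  if (anyDuplicated(out$name))
    warning("duplicate query names in ", path)
  rownames(out) <- NULL
  if (any(!nzchar(out$seq))) stop("empty query sequence in ", path)
  out
}

sam_flag <- function(strand, primary, mapped = TRUE) {
  f <- 0L
  if (!mapped) return(4L)
  if (strand == "-") f <- f + 16L
  if (!primary) f <- f + 256L
  f
}

# add soft clips for the uncovered oriented-query ends
clip_cigar <- function(aln) {
  QL <- aln$queryLength
  lead <- if (aln$strand == "+") aln$qStart else QL - aln$qEnd
  trail <- QL - cigar_qlen(aln$cigar) - lead
  cat_cigars(if (lead > 0L) paste0(lead, "S") else "",
             aln$cigar,
             if (trail > 0L) paste0(trail, "S") else "")
}

#' Write alignments as SAM
#'
#' Emits `@HD`, one `@SQ` per reference sequence and `@PG`, then one record
#' per alignment: FLAG bit 16 for minus strand (SEQ reverse-complemented),
#' bit 256 for every non-primary record, POS 1-based, CIGAR with soft clips
#' covering the uncovered query ends, the affine-gap score in tag `AS:i`,
#' and MAPQ 255 (unavailable; no mapping-quality model is defined). Queries
#' without alignments are emitted unmapped (FLAG 4). Secondary records
#' carry the full SEQ so downstream clustering tools can use them.
#'
#' @param alignments Alignment data.frame (flags set by the coverage
#'   stage).
#' @param index The `seed_index` (reference metadata for the header).
#' @param queries Query data.frame from [read_queries()] (sequence and
#'   quality source; queries absent from `alignments` become unmapped
#'   records).
#' @param path Output file or connection.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, index, queries, path) {
  unknown <- setdiff(alignments$refName, index$refNames)
  if (length(unknown))
    stop("alignment references unknown sequence: ", unknown[1])
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", index$refNames, "\tLN:", index$refLengths),
           paste0("@PG\tID:splitmap\tPN:splitmap\tVN:",
                  as.character(utils::packageVersion("splitmap"))))
  qseq <- setNames(queries$seq, queries$name)
  qqual <- setNames(queries$qual, queries$name)
  recs <- character(0)
  if (nrow(alignments)) {
    recs <- vapply(seq_len(nrow(alignments)), function(i) {
      a <- alignments[i, ]
      seq <- qseq[[a$qname]]
      qual <- qqual[[a$qname]]
      if (a$strand == "-") {
        seq <- revcomp(seq)
        if (!is.na(qual)) qual <- reverse_string(qual)
      }
      paste(a$qname, sam_flag(a$strand, a$isPrimary), a$refName,
            a$rStart + 1L, 255L, clip_cigar(a), "*", 0L, 0L,
            seq, if (is.na(qual)) "*" else qual,
            paste0("AS:i:", as.integer(a$score)),
            sep = "\t")
    }, character(1))
  }
  unmapped <- setdiff(queries$name, alignments$qname)
  if (length(unmapped)) {
    um <- vapply(unmapped, function(nm) {
      paste(nm, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, qseq[[nm]],
            if (is.na(qqual[[nm]])) "*" else qqual[[nm]],
            sep = "\t")
    }, character(1))
    recs <- c(recs, um)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Parse a SAM file back into an alignment data.frame
#'
#' Minimal reader for the records this package writes: recovers strand,
#' primary/secondary status, query/reference spans (forward-query
#' coordinates, from POS, CIGAR and soft clips) and the `AS` score.
#'
#' @param path SAM file.
#' @return Alignment data.frame (unmapped records get `NA` coordinates).
#' @export
parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    flag <- as.integer(p[2])
    if (bitwAnd(flag, 4L) > 0L) {
      return(data.frame(qname = p[1], strand = NA_character_,
                        refName = NA_character_, rStart = NA_integer_,
                        rEnd = NA_integer_, qStart = NA_integer_,
                        qEnd = NA_integer_, queryLength = nchar(p[10]),
                        cigar = NA_character_, score = NA_real_,
                        isPrimary = FALSE, isSecondary = FALSE,
                        stringsAsFactors = FALSE))
    }
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    primary <- bitwAnd(flag, 256L) == 0L
    cigar <- p[6]
    runs <- cigar_runs(cigar)
    QL <- sum(runs$len[runs$op %in% c("M", "=", "X", "I", "S")])
    lead <- if (runs$op[1] == "S") runs$len[1] else 0L
    trail <- if (runs$op[nrow(runs)] == "S") runs$len[nrow(runs)] else 0L
    qsO <- lead
    qeO <- QL - trail
    qStart <- if (strand == "+") qsO else QL - qeO
    qEnd <- if (strand == "+") qeO else QL - qsO
    rStart <- as.integer(p[4]) - 1L
    rEnd <- rStart + sum(runs$len[runs$op %in% c("M", "=", "X", "D")])
    asTag <- grep("^AS:i:", p[-(1:11)], value = TRUE)
    core <- runs[runs$op != "S", , drop = FALSE]
    data.frame(qname = p[1], strand = strand, refName = p[3],
               rStart = rStart, rEnd = rEnd, qStart = qStart, qEnd = qEnd,
               queryLength = QL, cigar = runs_to_cigar(core),
               score = if (length(asTag)) as.numeric(sub("^AS:i:", "", asTag[1]))
                       else NA_real_,
               isPrimary = primary, isSecondary = !primary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
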