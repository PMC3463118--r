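# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# CIGAR helpers ---------------------------------------------------------

cigar_runs <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) {
    return(data.frame(len = integer(0), op = character(0)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

runs_to_cigar <- function(runs) {
  if (nrow(runs) == 0L) return("")
  keep <- runs$len > 0L
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0L) return("")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, runs$op[-1] != runs$op[-nrow(runs)]))
  lens <- tapply(runs$len, grp, sum)
  ops <- runs$op[!duplicated(grp)]
  paste0(as.integer(lens), ops, collapse = "")
}

cat_cigars <- function(...) {
  parts <- Filter(nzchar, unlist(list(...)))
  if (length(parts) == 0L) return("")
  runs_to_cigar(do.call(rbind, lapply(parts, cigar_runs)))
}

cigar_qlen <- function(cigar) {
  r <- cigar_runs(cigar)
  sum(r$len[r$op %in% c("M", "=", "X", "I", "S")])
}

cigar_rlen <- function(cigar) {
  r <- cigar_runs(cigar)
  sum(r$len[r$op %in% c("M", "=", "X", "D")])
}

reverse_cigar <- function(cigar) {
  r <- cigar_runs(cigar)
  runs_to_cigar(r[rev(seq_len(nrow(r))), , drop = FALSE])
}

# Total length of the union of half-open intervals [starts, ends).
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L
  curS <- starts[1]; curE <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > curE) {
      tot <- tot + (curE - curS)
      curS <- starts[i]; curE <- ends[i]
    } else if (ends[i] > curE) curE <- ends[i]
  }
  tot + (curE - curS)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
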