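# k-mer hash index over a 2-bit-packed reference: construction, persistence
# and lookup.

#' Index construction parameters
#'
#' @param k Seed length in bases. Must be between 8 and 15 so that 2-bit
#'   packed keys fit in 30 bits; mammalian-scale practice is a "15/1" index
#'   (k = 15, skip = 1).
#' @param skip Distance in bases between successive indexed seed start
#'   positions within each reference sequence (1 = maximally overlapping
#'   seeds, k = non-overlapping).
#' @param maxHits Maximum retained reference hits per k-mer. K-mers occurring
#'   more often are dropped entirely, or down-sampled to `maxHits` when
#'   `sampling = TRUE`. The default 650 retains over 99.99% of distinct
#'   15-mers of a mammalian genome while bounding work on repeats.
#' @param sampling When `TRUE`, over-represented k-mers are uniformly
#'   down-sampled (without replacement) to `maxHits` hits instead of being
#'   excluded.
#' @param rngSeed Integer seed driving the down-sampling draws, so that two
#'   builds with identical inputs produce identical indexes.
#' @return An object of class `index_params`.
#' @export
index_params <- function(k = 15L, skip = 1L, maxHits = 650L,
                         sampling = FALSE, rngSeed = 1L) {
  k <- as.integer(k); skip <- as.integer(skip); maxHits <- as.integer(maxHits)
  if (is.na(k) || k < 8L || k > 15L) stop("k must be in 8..15")
  if (is.na(skip) || skip < 1L || skip > k) stop("skip must be in 1..k")
  if (is.na(maxHits) || maxHits < 1L) stop("maxHits must be >= 1")
  structure(list(k = k, skip = skip, maxHits = maxHits,
                 sampling = isTRUE(sampling), rngSeed = as.integer(rngSeed)),
            class = "index_params")
}

#' Encode a k-mer as a 2-bit-packed hash key
#'
#' Bases are encoded A=0, C=1, G=2, T=3 with the first base in the most
#' significant position, case-insensitively. Any non-ACGT character makes the
#' k-mer ambiguous and yields `NA` (the AMBIGUOUS sentinel); ambiguous k-mers
#' are never indexed or looked up.
#'
#' @param kmer A single k-base string.
#' @param k Expected seed length; defaults to `nchar(kmer)`.
#' @return Integer key in `[0, 4^k)`, or `NA_integer_` if ambiguous.
#' @examples
#' encode_kmer("ACGT")  # 27
#' @export
encode_kmer <- function(kmer, k = nchar(kmer)) {
  if (length(kmer) != 1L || !is.character(kmer)) stop("kmer must be a single string")
  if (nchar(kmer) != k) stop("kmer has length ", nchar(kmer), ", expected ", k)
  if (k > 15L) stop("k must be <= 15")
  code <- encode_kmer_cpp(kmer)
  if (code < 0L) NA_integer_ else code
}

normalize_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else if (is.character(reference)) {
    seqs <- reference
  } else {
    stop("reference must be a DNAStringSet, named character vector or FASTA path")
  }
  if (length(seqs) == 0L || any(!nzchar(seqs))) stop("empty reference sequence")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  toupper(seqs)
}

#' Build the k-mer index of a reference
#'
#' Records, for every seed start position `p` in `{0, skip, 2*skip, ...}`
#' of each reference sequence (with `p + k <= length` and no ambiguous base
#' in the k-mer), the concatenated-space offset of `p` under the k-mer's
#' hash key. Hit lists are stored ascending in one Reference Offset Array
#' (ROA); keys whose hit count exceeds `maxHits` are dropped, or uniformly
#' down-sampled to exactly `maxHits` when `params$sampling` is on.
#'
#' @param reference A `DNAStringSet`, a named character vector of sequences,
#'   or a path to a (optionally gzipped) FASTA file. Sequences are
#'   uppercased; multi-sequence references are concatenated into one offset
#'   space with per-sequence boundaries recorded (seeds never span a
#'   boundary). Only the forward strand is indexed; minus-strand alignment
#'   is done by aligning the reverse-complemented query.
#' @param params An [index_params()] object.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(reference, params = index_params()) {
  stopifnot(inherits(params, "index_params"))
  seqs <- normalize_reference(reference)
  posting <- build_posting_cpp(unname(seqs), params$k, params$skip)
  keys <- posting$keys
  starts <- posting$starts
  roa <- posting$roa
  counts <- diff(starts)
  over <- which(counts > params$maxHits)
  if (length(over)) {
    keep <- rep(TRUE, length(roa))
    if (params$sampling) {
      with_seed(params$rngSeed, {
        for (i in over) {
          idx <- (starts[i] + 1L):starts[i + 1L]
          drop <- idx[-sort(sample.int(length(idx), params$maxHits))]
          keep[drop] <- FALSE
        }
      })
      counts[over] <- params$maxHits
    } else {
      for (i in over) keep[(starts[i] + 1L):starts[i + 1L]] <- FALSE
      counts[over] <- 0L
    }
    roa <- roa[keep]
    nonempty <- counts > 0L
    keys <- keys[nonempty]
    starts <- c(0L, cumsum(counts[nonempty]))
  }
  refLengths <- nchar(seqs)
  refOffsets <- c(0L, cumsum(refLengths))[seq_along(seqs)]
  concat <- paste(seqs, collapse = "")
  rawSeq <- charToRaw(concat)
  ambigPos <- which(!(rawSeq %in% charToRaw("ACGT")))
  structure(list(
    params = params,
    refNames = names(seqs),
    refLengths = unname(refLengths),
    refOffsets = unname(refOffsets),
    totalLen = sum(refLengths),
    packedRef = pack_ref_cpp(concat),
    ambigPos = as.integer(ambigPos),
    keys = keys, roaStarts = starts, roa = roa,
    refSeq = restore_ambiguous(concat, ambigPos)
  ), class = "seed_index")
}

# The packed representation cannot carry non-ACGT letters; the cached
# concatenated sequence keeps them as N at the recorded positions.
restore_ambiguous <- function(concat, ambigPos) {
  if (length(ambigPos) == 0L) return(concat)
  r <- charToRaw(concat)
  r[ambigPos] <- charToRaw("N")
  rawToChar(r)
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: k=", x$params$k, " skip=", x$params$skip,
      " maxHits=", x$params$maxHits,
      if (x$params$sampling) " (sampling)" else "",
      "\n  ", length(x$refNames), " sequence(s), ", x$totalLen, " bp, ",
      length(x$keys), " distinct keys, ", length(x$roa), " stored hits\n",
      sep = "")
  invisible(x)
}

#' Look up the reference hit list of a k-mer
#'
#' @param index A `seed_index`.
#' @param key A k-base string or an integer hash key. Ambiguous k-mers are a
#'   usage error.
#' @return Ascending integer vector of reference offsets (concatenated
#'   0-based coordinate space); empty if the k-mer is absent or was excluded
#'   by `maxHits`.
#' @export
lookup <- function(index, key) {
  stopifnot(inherits(index, "seed_index"))
  if (is.character(key)) key <- encode_kmer(key, index$params$k)
  key <- as.integer(key)
  if (is.na(key)) stop("cannot look up an ambiguous k-mer")
  i <- findInterval(key, index$keys)
  if (i > 0L && index$keys[i] == key) {
    index$roa[(index$roaStarts[i] + 1L):index$roaStarts[i + 1L]]
  } else {
    integer(0)
  }
}

# Extract [start, start+len) of the concatenated reference (0-based start).
ref_window <- function(index, start, len) {
  substr(index$refSeq, start + 1L, start + len)
}

# index file layout: magic "SSIX", little-endian, versioned ----------------

INDEX_MAGIC <- charToRaw("SSIX")
INDEX_VERSION <- 1L

write_chunk_int <- function(con, x) {
  writeBin(length(x), con, size = 4L, endian = "little")
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

read_checked <- function(con, what, n, size = NA_integer_) {
  x <- if (identical(what, "raw")) readBin(con, "raw", n = n)
  else readBin(con, what, n = n, size = size, endian = "little")
  if (length(x) != n) stop("corrupt index file: truncated")
  x
}

read_chunk_int <- function(con) {
  n <- read_checked(con, "integer", 1L, 4L)
  if (n < 0L) stop("corrupt index file: negative length")
  read_checked(con, "integer", n, 4L)
}

#' Persist an index to a binary file
#'
#' The file is a single self-describing little-endian binary with magic
#' bytes `SSIX`, a format version and all build parameters, so that an index
#' can never be silently reused with mismatched parameters.
#'
#' @param index A `seed_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "seed_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(INDEX_MAGIC, con)
  p <- index$params
  writeBin(as.integer(c(INDEX_VERSION, p$k, p$skip, p$maxHits,
                        as.integer(p$sampling), p$rngSeed,
                        length(index$refNames))),
           con, size = 4L, endian = "little")
  for (nm in index$refNames) {
    nb <- charToRaw(nm)
    writeBin(length(nb), con, size = 4L, endian = "little")
    writeBin(nb, con)
  }
  write_chunk_int(con, index$refLengths)
  writeBin(as.integer(index$totalLen), con, size = 4L, endian = "little")
  write_chunk_int(con, index$ambigPos)
  write_chunk_int(con, index$keys)
  write_chunk_int(con, index$roaStarts)
  write_chunk_int(con, index$roa)
  writeBin(length(index$packedRef), con, size = 4L, endian = "little")
  writeBin(index$packedRef, con)
  invisible(path)
}

#' Read an index written by [write_index()]
#'
#' @param path Path to an `SSIX` index file.
#' @return A `seed_index` equal field-for-field to the one written.
#' @export
read_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_checked(con, "raw", 4L)
  if (!identical(magic, INDEX_MAGIC)) stop("not an SSIX index file (bad magic)")
  hdr <- read_checked(con, "integer", 7L, 4L)
  if (hdr[1] != INDEX_VERSION) stop("unsupported index format version ", hdr[1])
  params <- index_params(k = hdr[2], skip = hdr[3], maxHits = hdr[4],
                         sampling = hdr[5] == 1L, rngSeed = hdr[6])
  nref <- hdr[7]
  refNames <- character(nref)
  for (i in seq_len(nref)) {
    nb <- read_checked(con, "integer", 1L, 4L)
    refNames[i] <- rawToChar(read_checked(con, "raw", nb))
  }
  refLengths <- read_chunk_int(con)
  totalLen <- read_checked(con, "integer", 1L, 4L)
  ambigPos <- read_chunk_int(con)
  keys <- read_chunk_int(con)
  roaStarts <- read_chunk_int(con)
  roa <- read_chunk_int(con)
  npacked <- read_checked(con, "integer", 1L, 4L)
  packedRef <- read_checked(con, "raw", npacked)
  concat <- unpack_ref_cpp(packedRef, totalLen)
  structure(list(
    params = params, refNames = refNames, refLengths = refLengths,
    refOffsets = c(0L, cumsum(refLengths))[seq_len(nref)],
    totalLen = totalLen, packedRef = packedRef, ambigPos = ambigPos,
    keys = keys, roaStarts = roaStarts, roa = roa,
    refSeq = restore_ambiguous(concat, ambigPos)
  ), class = "seed_index")
}
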