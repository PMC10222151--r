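# Sparse k-mer counting core and relative-frequency genomic signatures.
#
# Words over {A,C,G,T} are integer-encoded base-4 (A=0 < C=1 < G=2 < T=3,
# i.e. lexicographic order) with a vectorized rolling window. The sparse
# (code, count) representation is mandatory at large k: a dense table at
# k = 14 would hold 4^14 ~ 2.7e8 cells per genome.

.BASE_CODE <- local({
  m <- rep(NA_real_, 256)
  m[utf8ToInt("A")] <- 0; m[utf8ToInt("C")] <- 1
  m[utf8ToInt("G")] <- 2; m[utf8ToInt("T")] <- 3
  m
})

# Integer codes of all valid k-windows of one contig, plus the skipped count.
.encode_windows <- function(contig, k) {
  b <- .BASE_CODE[utf8ToInt(contig)]
  n <- length(b)
  if (n < k) return(list(codes = numeric(0), skipped = 0L))
  nw <- n - k + 1L
  bad <- is.na(b)
  if (any(bad)) {
    cs <- c(0, cumsum(bad))
    valid <- (cs[(k + 1L):(n + 1L)] - cs[1:nw]) == 0
    b[bad] <- 0
  } else {
    valid <- rep(TRUE, nw)
  }
  codes <- numeric(nw)
  p <- 1
  for (j in k:1) {            # codes stay exact: 4^k <= 2^28 << 2^53
    codes <- codes + b[j:(j + nw - 1L)] * p
    p <- p * 4
  }
  list(codes = codes[valid], skipped = sum(!valid))
}

.revcomp <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Count k-mers in a genome
#'
#' Slides a window of width `k` over every contig independently (no window
#' spans a contig junction) and counts occurrences of each word over
#' \{A,C,G,T\}. Windows containing any other character are excluded and
#' tallied in `skipped_windows`. With `strand_mode = "both"` the reverse
#' complement of every contig is counted as well.
#'
#' @param record A [seq_record()] (or a plain character vector of contigs).
#' @param k Word length, integer >= 1.
#' @param strand_mode `"forward"` (count the deposited strand only, the
#'   default) or `"both"`.
#' @return An object of class `kmer_counts`: list with `k`, `codes` (sorted
#'   integer word codes present), `counts`, `total`, `skipped_windows`.
#' @export
count_kmers <- function(record, k, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single integer >= 1")
  contigs <- if (inherits(record, "seq_record")) record$contigs
             else toupper(as.character(record))
  if (strand_mode == "both")
    contigs <- c(contigs, vapply(contigs, .revcomp, character(1),
                                 USE.NAMES = FALSE))
  codes <- vector("list", length(contigs))
  skipped <- 0L
  for (i in seq_along(contigs)) {
    enc <- .encode_windows(contigs[[i]], as.integer(k))
    codes[[i]] <- enc$codes
    skipped <- skipped + enc$skipped
  }
  codes <- sort(unlist(codes, use.names = FALSE))
  r <- rle(codes)
  structure(
    list(k = as.integer(k), codes = r$values, counts = as.numeric(r$lengths),
         total = length(codes), skipped_windows = as.integer(skipped)),
    class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts> k=%d, %d distinct words, total %d (%d skipped windows)\n",
              x$k, length(x$codes), x$total, x$skipped_windows))
  invisible(x)
}

#' Decode integer word codes back to k-mer strings
#'
#' @param codes Numeric vector of base-4 word codes.
#' @param k Word length.
#' @return Character vector of words.
#' @export
decode_kmer <- function(codes, k) {
  out <- character(length(codes))
  letters4 <- c("A", "C", "G", "T")
  for (i in seq_along(codes)) {
    c0 <- codes[[i]]
    w <- character(k)
    for (j in k:1) {
      w[[j]] <- letters4[(c0 %% 4) + 1]
      c0 <- c0 %/% 4
    }
    out[[i]] <- paste(w, collapse = "")
  }
  out
}

#' Relative-frequency genomic signature
#'
#' Normalizes k-mer counts to the dense signature vector f_w(X) = X_w / S,
#' S = sum of all counts, in the fixed lexicographic word order (A < C < G
#' < T). Only defined for k small enough that a dense 4^k vector is sensible.
#'
#' @param counts A [count_kmers()] result with `total > 0` and `k <= 10`.
#' @return Object of class `kmer_signature`: list with `k` and `freq`
#'   (numeric of length 4^k summing to 1).
#' @export
signature <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (counts$total == 0)
    stop("no countable k-mers (zero-total counts)")
  if (counts$k > 10)
    stop("dense signatures limited to k <= 10 (4^k entries); use the sparse counts directly")
  freq <- numeric(4^counts$k)
  freq[counts$codes + 1] <- counts$counts / counts$total
  structure(list(k = counts$k, freq = freq), class = "kmer_signature")
}

#' @export
print.kmer_signature <- function(x, ...) {
  cat(sprintf("<kmer_signature> k=%d, %d non-zero of %d entries\n",
              x$k, sum(x$freq > 0), length(x$freq)))
  invisible(x)
}

#' Euclidean distance between two genomic signatures (k4freq)
#'
#' Eu(X, Y) = sqrt( sum_w (f_w(X) - f_w(Y))^2 ) over all 4^k words. With
#' k = 4 this is the tetramer-frequency distance used for phage/plasmid to
#' host comparison.
#'
#' @param sigX,sigY [signature()] objects with equal `k`.
#' @return Non-negative numeric distance (at most sqrt(2)).
#' @export
k4freq_distance <- function(sigX, sigY) {
  stopifnot(inherits(sigX, "kmer_signature"), inherits(sigY, "kmer_signature"))
  if (sigX$k != sigY$k)
    stop(sprintf("signature k mismatch: %d vs %d", sigX$k, sigY$k))
  sqrt(sum((sigX$freq - sigY$freq)^2))
}
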