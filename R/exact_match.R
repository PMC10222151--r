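# Exact long-k-mer match similarity SIM and distance DSW ("k14exact").

#' Exact k-mer match similarity SIM
#'
#' Let X be the input with the smaller k-mer total S (ties break to the
#' first argument) and Y the other. SIM(X, Y) = sum over words w present in
#' Y of X_w / S_X: the occurrence-weighted fraction of X's k-mers whose word
#' appears at least once in Y. SIM = 1 when X's sequence is contained in Y
#' (e.g. an integrated prophage); SIM = 0 when the genomes share no k-word.
#'
#' @param countsA,countsB [count_kmers()] results at the same `k`, both with
#'   `total > 0`.
#' @return SIM in \[0, 1\].
#' @export
sim <- function(countsA, countsB) {
  stopifnot(inherits(countsA, "kmer_counts"), inherits(countsB, "kmer_counts"))
  if (countsA$k != countsB$k)
    stop(sprintf("k mismatch: %d vs %d", countsA$k, countsB$k))
  if (countsA$total == 0 || countsB$total == 0)
    stop("no countable k-mers (zero-total counts)")
  if (countsA$total <= countsB$total) {
    x <- countsA; y <- countsB
  } else {
    x <- countsB; y <- countsA
  }
  shared <- x$codes %in% y$codes
  sum(x$counts[shared]) / x$total
}

#' Exact k-mer match distance DSW (k14exact)
#'
#' DSW = 1 - SIM, normalized to \[0, 1\]. DSW = 0 means the smaller genome is
#' inserted into the larger one; DSW = 1 means the genomes share no
#' oligonucleotide of length k. The recommended k for bacterial-scale
#' genomes is 14, at which unrelated random genomes share under 2% of words
#' (see [expected_random_match_rate()]).
#'
#' @inheritParams sim
#' @return DSW in \[0, 1\].
#' @export
dsw_distance <- function(countsA, countsB) {
  1 - sim(countsA, countsB)
}

#' Expected random k-mer match rate
#'
#' Probability that a fixed k-word occurs at least once in an i.i.d. uniform
#' random genome of the given length: 1 - (1 - 4^-k)^max(L - k + 1, 0).
#' This is the expected SIM between unrelated random genomes and the
#' rationale for choosing k = 14, where a ~5 Mb bacterial genome gives a
#' rate below 2%.
#'
#' @param k Word length, integer >= 1.
#' @param genome_length Genome length L in nucleotides, >= 0.
#' @return Match probability in \[0, 1\].
#' @export
expected_random_match_rate <- function(k, genome_length) {
  if (!is.numeric(k) || any(k < 1) || any(k != round(k)))
    stop("k must be integer >= 1")
  if (!is.numeric(genome_length) || any(genome_length < 0))
    stop("genome_length must be >= 0")
  nw <- pmax(genome_length - k + 1, 0)
  -expm1(nw * log1p(-4^(-k)))
}

#' Smallest k meeting a random-match-rate bound
#'
#' Scans k upward until [expected_random_match_rate()] for a genome of the
#' given length drops below `max_rate`.
#'
#' @param genome_length Target (larger) genome length in nt.
#' @param max_rate Acceptable random-match probability (default 0.02).
#' @return The smallest qualifying k.
#' @export
choose_k <- function(genome_length, max_rate = 0.02) {
  stopifnot(genome_length >= 0, max_rate > 0, max_rate < 1)
  for (k in 1:32) {
    if (expected_random_match_rate(k, genome_length) < max_rate) return(k)
  }
  stop("no k <= 32 meets the requested rate")
}
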