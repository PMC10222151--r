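# Independent brute-force oracles (string slicing / direct summation) and
# small fixture builders. These deliberately avoid the package's
# integer-encoded counting path.

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# k-mer occurrence table of one sequence by plain string slicing; windows
# containing non-ACGT characters are dropped.
naive_kmer_table <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  words <- substring(s, 1:(n - k + 1), k:n)
  words <- words[!grepl("[^ACGT]", words)]
  tab <- table(words)
  setNames(as.integer(tab), names(tab))
}

naive_sim <- function(sa, sb, k) {
  ta <- naive_kmer_table(sa, k)
  tb <- naive_kmer_table(sb, k)
  if (sum(ta) <= sum(tb)) { x <- ta; y <- tb } else { x <- tb; y <- ta }
  sum(x[names(x) %in% names(y)]) / sum(x)
}

# Direct-summation Euclidean distance over the union of observed words
# (words absent from both contribute zero).
naive_euclid <- function(sa, sb, k) {
  ta <- naive_kmer_table(sa, k)
  tb <- naive_kmer_table(sb, k)
  fa <- ta / sum(ta)
  fb <- tb / sum(tb)
  words <- union(names(fa), names(fb))
  tot <- 0
  for (w in words) {
    d <- (if (w %in% names(fa)) fa[[w]] else 0) -
         (if (w %in% names(fb)) fb[[w]] else 0)
    tot <- tot + d * d
  }
  sqrt(tot)
}

# AUC as the Mann-Whitney concordance probability by brute-force pair
# counting (positive class = lysogenic = small distances).
naive_auc <- function(distances, labels) {
  pos <- distances[labels == "lysogenic"]
  neg <- distances[labels == "lytic"]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p < q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

rec <- function(id, s, role = "host") seq_record(id, s, role)

coll <- function(...) seq_collection(list(...))
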