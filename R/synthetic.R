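# Synthetic genomes with the compositional structure the distance methods
# assume: host "genera" with distinct base composition, ameliorated
# (lysogenic-like) phages drawn from the host model, compositionally
# divergent (lytic-like) phages, prophage insertions, and genome pairs
# sharing no k-word.

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate a small reference panel: three host genera spread over
#' the realistic bacterial GC range (32-68%), twenty 200 kb genomes per
#' genus, 50 kb phages, and equal numbers of ameliorated (lysogenic-like)
#' and divergent (lytic-like) phages. `composition_divergence` is the mixing
#' weight pulling a lytic-like phage's base composition away from its host
#' group toward a foreign composition (0 = indistinguishable from
#' lysogenic-like, 1 = fully foreign).
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_groups Number of host groups (>= 1).
#' @param genomes_per_group Host genomes per group.
#' @param genome_length Host genome length, nt.
#' @param phage_length Phage genome length, nt.
#' @param markov_order 0 (i.i.d. bases) or 1 (first-order chain).
#' @param composition_divergence Mixing weight in \[0, 1\] for lytic-like
#'   phages.
#' @param n_lysogenic,n_lytic Phage counts per class.
#' @param host_divergence Per-base substitution rate separating each strain
#'   from its group's ancestral backbone (default 0.02, typical congeneric
#'   strain divergence).
#' @param shared_fraction Fraction of a lysogenic-like phage genome copied
#'   verbatim from its group's ancestral backbone (default 0.10), emulating
#'   the prophage-derived DNA temperate phages share with their host clade.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_groups = 3L, genomes_per_group = 20L,
                             genome_length = 200000L, phage_length = 50000L,
                             markov_order = 0L, composition_divergence = 0.5,
                             n_lysogenic = 50L, n_lytic = 50L,
                             host_divergence = 0.02, shared_fraction = 0.10) {
  stopifnot(n_groups >= 1, genomes_per_group >= 1,
            genome_length >= 1, phage_length >= 1,
            markov_order %in% c(0L, 1L),
            composition_divergence >= 0, composition_divergence <= 1,
            n_lysogenic >= 0, n_lytic >= 0,
            host_divergence >= 0, host_divergence < 1,
            shared_fraction >= 0, shared_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

.BASES <- c("A", "C", "G", "T")

# Base probabilities for a group: GC content on an evenly spaced ladder over
# [0.32, 0.68] plus small seeded jitter, with mild AT/GC strand skews.
.group_compositions <- function(n_groups) {
  gc <- if (n_groups == 1) 0.5 else
    seq(0.32, 0.68, length.out = n_groups)
  gc <- pmin(0.75, pmax(0.25, gc + stats::runif(n_groups, -0.02, 0.02)))
  lapply(seq_len(n_groups), function(g) {
    at_skew <- stats::runif(1, 0.45, 0.55)
    gc_skew <- stats::runif(1, 0.45, 0.55)
    c((1 - gc[g]) * at_skew, gc[g] * gc_skew,
      gc[g] * (1 - gc_skew), (1 - gc[g]) * (1 - at_skew))
  })
}

# One random genome string from an order-0 or order-1 base model.
.random_genome <- function(length, probs, markov_order = 0L, trans = NULL) {
  if (markov_order == 0L) {
    return(paste(sample(.BASES, length, replace = TRUE, prob = probs),
                 collapse = ""))
  }
  b <- integer(length)
  b[1] <- sample.int(4L, 1L, prob = probs)
  u <- stats::runif(length)
  cum <- t(apply(trans, 1, cumsum))
  for (i in 2:length)
    b[i] <- findInterval(u[i], cum[b[i - 1], ], left.open = TRUE) + 1L
  paste(.BASES[b], collapse = "")
}

# Order-1 transition matrix whose stationary flavour follows `probs`, with
# modest persistence so local composition patchiness resembles real genomes.
.trans_from_probs <- function(probs, persistence = 0.2) {
  t0 <- matrix(rep(probs, each = 4), nrow = 4)
  diag(t0) <- diag(t0) + persistence
  t0 / rowSums(t0)
}

# Substitute bases at the given per-base rate (each hit becomes one of the
# three other bases uniformly).
.mutate_genome <- function(genome, rate) {
  if (rate <= 0) return(genome)
  b <- strsplit(genome, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  if (length(hit)) {
    repl <- vapply(b[hit], function(cur)
      sample(setdiff(.BASES, cur), 1L), character(1), USE.NAMES = FALSE)
    b[hit] <- repl
  }
  paste(b, collapse = "")
}

#' Generate synthetic host groups
#'
#' Each group emulates a bacterial genus: one ancestral backbone genome is
#' drawn from the group's base-composition model (see [synthetic_config()])
#' and every strain is that backbone with independent substitutions at rate
#' `host_divergence`, so strains of a group share both composition and most
#' of their exact sequence — as congeneric reference strains do. Output is
#' fully determined by `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` ([seq_collection()]), `groups` (named
#'   character vector id -> group label), `compositions` (per-group base
#'   probabilities), `ancestors` (per-group backbone sequences).
#' @export
make_host_groups <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  comps <- .group_compositions(config$n_groups)
  names(comps) <- sprintf("group%d", seq_len(config$n_groups))
  recs <- list()
  groups <- character(0)
  ancestors <- character(config$n_groups)
  for (g in seq_len(config$n_groups)) {
    trans <- if (config$markov_order == 1L) .trans_from_probs(comps[[g]])
    ancestors[[g]] <- .random_genome(config$genome_length, comps[[g]],
                                     config$markov_order, trans)
    for (i in seq_len(config$genomes_per_group)) {
      id <- sprintf("host_g%d_%02d", g, i)
      recs[[id]] <- seq_record(
        id, .mutate_genome(ancestors[[g]], config$host_divergence), "host")
      groups[[id]] <- names(comps)[[g]]
    }
  }
  names(ancestors) <- names(comps)
  list(records = seq_collection(recs), groups = groups, compositions = comps,
       ancestors = ancestors)
}

#' Generate synthetic phages with planted lifestyles
#'
#' Lysogenic-like ("ameliorated") phages are drawn from their host group's
#' composition model and additionally carry a contiguous segment copied from
#' the group's ancestral backbone (`shared_fraction` of the phage length),
#' emulating the prophage-derived DNA that temperate phages share with their
#' host clade — the signal exact long-word matching responds to. Lytic-like
#' phages are purely compositional, drawn from a mixture pulled toward a
#' foreign composition with weight `composition_divergence`. Phages cycle
#' over host groups. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param hosts Result of [make_host_groups()] under the same config.
#' @return List with `records` ([seq_collection()]), `truth` (`data.frame`
#'   of `element_id`, `host_group`, `lifestyle`).
#' @export
make_phages <- function(config, hosts) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1000L)
  comps <- hosts$compositions
  n_g <- length(comps)
  truth <- data.frame(element_id = character(0), host_group = character(0),
                      lifestyle = character(0), stringsAsFactors = FALSE)
  recs <- list()
  mk <- function(idx, lifestyle) {
    g <- ((idx - 1L) %% n_g) + 1L
    p <- comps[[g]]
    if (lifestyle == "lytic") {
      gcf <- stats::runif(1, 0.25, 0.75)
      foreign <- c((1 - gcf) / 2, gcf / 2, gcf / 2, (1 - gcf) / 2)
      p <- (1 - config$composition_divergence) * p +
        config$composition_divergence * foreign
    }
    trans <- if (config$markov_order == 1L) .trans_from_probs(p)
    gseq <- .random_genome(config$phage_length, p, config$markov_order, trans)
    if (lifestyle == "lysogenic" && config$shared_fraction > 0) {
      seg_len <- min(round(config$shared_fraction * config$phage_length),
                     nchar(hosts$ancestors[[g]]))
      if (seg_len >= 1) {
        from <- sample.int(nchar(hosts$ancestors[[g]]) - seg_len + 1L, 1L)
        seg <- substr(hosts$ancestors[[g]], from, from + seg_len - 1L)
        at <- sample.int(config$phage_length - seg_len + 1L, 1L)
        gseq <- paste0(substr(gseq, 1, at - 1L), seg,
                       substr(gseq, at + seg_len, config$phage_length))
      }
    }
    id <- sprintf("phage_%s_%03d", substr(lifestyle, 1, 3), idx)
    recs[[id]] <<- seq_record(id, gseq, "phage")
    truth <<- rbind(truth, data.frame(
      element_id = id, host_group = names(comps)[[g]], lifestyle = lifestyle,
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(config$n_lysogenic)) mk(i, "lysogenic")
  for (i in seq_len(config$n_lytic)) mk(i, "lytic")
  list(records = seq_collection(recs), truth = truth)
}

#' Insert a phage genome into a host genome
#'
#' Splices the (concatenated) phage sequence into one contig of the host at
#' the given 0-based position, emulating an integrated prophage: the DSW
#' distance between phage and modified host is 0 for any k up to the phage
#' length. Pure function; inputs are not modified.
#'
#' @param host,phage [seq_record()]s.
#' @param position Insertion offset in \[0, contig length\] (0 = prefix).
#' @param contig Index of the host contig receiving the insertion.
#' @return A new [seq_record()] with id `<host>_lysogen`.
#' @export
insert_prophage <- function(host, phage, position, contig = 1L) {
  stopifnot(inherits(host, "seq_record"), inherits(phage, "seq_record"))
  if (contig < 1L || contig > length(host$contigs))
    stop("contig index out of range")
  target <- host$contigs[[contig]]
  if (position < 0 || position > nchar(target))
    stop(sprintf("position %d out of range [0, %d]", position, nchar(target)))
  ins <- paste(phage$contigs, collapse = "")
  new_contigs <- host$contigs
  new_contigs[[contig]] <- paste0(substr(target, 1, position), ins,
                                  substr(target, position + 1, nchar(target)))
  seq_record(paste0(host$id, "_lysogen"), new_contigs, host$role)
}

#' Construct two genomes sharing no k-word
#'
#' Builds one genome over \{A, C\} and one over \{G, T\}: every k-word of the
#' first contains only A/C and every k-word of the second only G/T, so the
#' two word sets are disjoint for any k >= 1 and DSW = 1. The disjointness
#' is re-verified by brute-force intersection of the counted word sets.
#'
#' @param k Word length the pair is checked at.
#' @param lengths Two genome lengths in nt (each >= k).
#' @param seed Integer seed.
#' @return List of two [seq_record()]s (`disjointA`, `disjointB`).
#' @export
make_disjoint_pair <- function(k, lengths = c(10000L, 10000L), seed = 1L) {
  stopifnot(k >= 1, length(lengths) == 2, all(lengths >= k))
  set.seed(seed)
  a <- paste(sample(c("A", "C"), lengths[[1]], replace = TRUE), collapse = "")
  b <- paste(sample(c("G", "T"), lengths[[2]], replace = TRUE), collapse = "")
  ra <- seq_record("disjointA", a, "host")
  rb <- seq_record("disjointB", b, "host")
  shared <- intersect(count_kmers(ra, k)$codes, count_kmers(rb, k)$codes)
  if (length(shared))
    stop("disjoint construction failed verification")  # unreachable by design
  list(disjointA = ra, disjointB = rb)
}

#' Write synthetic fixtures to disk
#'
#' Generates hosts and phages under `config` and writes per-role FASTA files
#' plus a truth TSV (`element_id`, `role`, `host_group`, `lifestyle`).
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of written paths.
#' @export
write_synthetic_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hosts <- make_host_groups(config)
  phages <- make_phages(config, hosts)
  p_hosts <- file.path(dir, "hosts.fasta")
  p_phages <- file.path(dir, "phages.fasta")
  p_truth <- file.path(dir, "truth.tsv")
  write_fasta(hosts$records, p_hosts)
  write_fasta(phages$records, p_phages)
  truth <- rbind(
    data.frame(element_id = names(hosts$groups), role = "host",
               host_group = unname(hosts$groups), lifestyle = NA_character_,
               stringsAsFactors = FALSE),
    cbind(phages$truth[, "element_id", drop = FALSE], role = "phage",
          phages$truth[, c("host_group", "lifestyle")]))
  write.table(truth, p_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(hosts = p_hosts, phages = p_phages, truth = p_truth))
}
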