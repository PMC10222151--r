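# Scaled-down configs keep the generator tests fast; the full-size defaults
# are exercised by the acceptance suite.
small_cfg <- function(seed = 3, ...) {
  synthetic_config(seed = seed, n_groups = 3, genomes_per_group = 4,
                   genome_length = 30000, phage_length = 8000,
                   n_lysogenic = 6, n_lytic = 6, ...)
}

test_that("generators are pure functions of the seed", {
  cfg <- small_cfg()
  h1 <- make_host_groups(cfg)
  h2 <- make_host_groups(cfg)
  expect_identical(h1$records, h2$records)
  expect_identical(h1$ancestors, h2$ancestors)
  p1 <- make_phages(cfg, h1)
  p2 <- make_phages(cfg, h2)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$truth, p2$truth)
  h3 <- make_host_groups(small_cfg(seed = 4))
  expect_false(identical(h1$records[[1]]$contigs, h3$records[[1]]$contigs))
})

test_that("host groups are compositionally separated and internally coherent", {
  hosts <- make_host_groups(small_cfg())
  mat <- signature_matrix(hosts$records, 4)
  sigs <- lapply(rownames(mat), function(id)
    structure(list(k = 4L, freq = mat[id, ]), class = "kmer_signature"))
  names(sigs) <- rownames(mat)
  ids <- names(hosts$groups)
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    d <- k4freq_distance(sigs[[ids[i]]], sigs[[ids[j]]])
    if (hosts$groups[[ids[i]]] == hosts$groups[[ids[j]]])
      within <- c(within, d) else between <- c(between, d)
  }
  expect_lt(mean(within), mean(between))
  expect_lt(max(within), min(between))   # clean group structure at this scale
})

test_that("planted lifestyles order phage-to-group distances as intended", {
  cfg <- small_cfg()
  hosts <- make_host_groups(cfg)
  phages <- make_phages(cfg, hosts)
  expect_equal(nrow(phages$truth), 12L)
  expect_setequal(unique(phages$truth$lifestyle), c("lysogenic", "lytic"))
  eg <- setNames(phages$truth$host_group, phages$truth$element_id)
  for (method in c("k4freq", "k14exact")) {
    gd <- group_mean_table(phages$records, hosts$records, hosts$groups, eg,
                           method)
    lifestyle <- phages$truth$lifestyle[match(gd$element_id,
                                              phages$truth$element_id)]
    expect_lt(mean(gd$mean[lifestyle == "lysogenic"]),
              mean(gd$mean[lifestyle == "lytic"]))
  }
})

test_that("with zero divergence and no shared DNA the classes are exchangeable", {
  cfg <- small_cfg(seed = 5, composition_divergence = 0,
                   shared_fraction = 0)
  hosts <- make_host_groups(cfg)
  phages <- make_phages(cfg, hosts)
  eg <- setNames(phages$truth$host_group, phages$truth$element_id)
  gd <- group_mean_table(phages$records, hosts$records, hosts$groups, eg,
                         "k4freq")
  roc <- roc_threshold(gd$mean, phages$truth$lifestyle[
    match(gd$element_id, phages$truth$element_id)])
  expect_lt(abs(roc$auc - 0.5), 0.35)   # labels uninformative by construction
})

test_that("prophage insertion is a pure splice with DSW 0 at any position", {
  set.seed(131)
  host <- rec("h", random_dna(30000))
  phage <- rec("p", random_dna(2000), "phage")
  before <- host$contigs
  for (pos in c(0, 12345, 30000)) {
    lys <- insert_prophage(host, phage, pos)
    expect_equal(lys$length, 32000L)
    expect_equal(dsw_distance(count_kmers(phage, 14), count_kmers(lys, 14)), 0)
    expect_identical(host$contigs, before)   # input untouched
  }
  expect_error(insert_prophage(host, phage, 30001), "out of range")
  expect_error(insert_prophage(host, phage, -1), "out of range")
})

test_that("disjoint pairs share no k-word, verified independently", {
  pair <- make_disjoint_pair(6, c(2000, 3000), seed = 132)
  wa <- names(naive_kmer_table(pair$disjointA$contigs, 6))
  wb <- names(naive_kmer_table(pair$disjointB$contigs, 6))
  expect_length(intersect(wa, wb), 0L)
  expect_equal(dsw_distance(count_kmers(pair$disjointA, 6),
                            count_kmers(pair$disjointB, 6)), 1)
  expect_identical(make_disjoint_pair(6, c(2000, 3000), seed = 132), pair)
})

test_that("fixture writer produces loadable FASTA plus a consistent truth table", {
  dir <- file.path(tempdir(), "fixtures")
  cfg <- small_cfg(seed = 6)
  paths <- write_synthetic_fixtures(cfg, dir)
  hosts <- read_fasta(paths$hosts, "host", "per-record")
  phages <- read_fasta(paths$phages, "phage", "per-record")
  truth <- read.delim(paths$truth)
  expect_equal(length(hosts), 12L)
  expect_equal(length(phages), 12L)
  expect_setequal(truth$element_id, c(names(hosts), names(phages)))
  expect_equal(sum(truth$role == "phage"), 12L)
  regen <- make_host_groups(cfg)
  expect_equal(hosts[[1]]$contigs, regen$records[[1]]$contigs)
})
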