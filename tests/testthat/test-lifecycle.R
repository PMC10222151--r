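test_that("group mean distances match a direct recomputation", {
  set.seed(101)
  hosts <- coll(rec("h1", random_dna(4000)), rec("h2", random_dna(4000)),
                rec("h3", random_dna(4000)))
  phage <- rec("p1", random_dna(1200), "phage")
  gd <- group_mean_distance(phage, hosts, "k4freq", host_group = "g")
  expect_equal(gd$n_hosts, 3L)
  ps <- signature(count_kmers(phage, 4))
  d <- vapply(hosts, function(h)
    k4freq_distance(ps, signature(count_kmers(h, 4))), numeric(1))
  expect_equal(gd$mean, mean(d))
  expect_equal(gd$sd, sd(d))

  single <- group_mean_distance(phage, hosts[1], "k4freq")
  expect_equal(single$mean, unname(d[1]))
  expect_equal(single$sd, 0)
  expect_error(group_mean_distance(phage, hosts[0], "k4freq"), "empty")

  # bulk table agrees with per-element calls
  phages <- coll(rec("pa", random_dna(1000), "phage"),
                 rec("pb", random_dna(1000), "phage"))
  groups <- setNames(c("g1", "g1", "g2"), names(hosts))
  eg <- c(pa = "g1", pb = "g2")
  bulk <- group_mean_table(phages, hosts, groups, eg, "k4freq")
  expect_equal(bulk$mean[bulk$element_id == "pa"],
               group_mean_distance(phages$pa, hosts[c("h1", "h2")], "k4freq")$mean)
  expect_equal(bulk$mean[bulk$element_id == "pb"],
               group_mean_distance(phages$pb, hosts["h3"], "k4freq")$mean)
})

test_that("distance_table enumerates all pairs with method defaults", {
  set.seed(102)
  q <- coll(rec("q1", random_dna(600), "phage"), rec("q2", random_dna(600), "phage"))
  h <- coll(rec("h1", random_dna(900)), rec("h2", random_dna(900)),
            rec("h3", random_dna(900)))
  tab <- distance_table(q, h, "k4freq")
  expect_equal(nrow(tab), 6L)
  expect_equal(unique(tab$k), 4L)
  tab14 <- distance_table(q, h, "k14exact", k = 5)
  expect_equal(unique(tab14$k), 5L)
  expect_true(all(tab14$distance >= 0 & tab14$distance <= 1))
})

test_that("ROC finds the perfect separator and its AUC matches pair counting", {
  r <- roc_threshold(c(0.01, 0.02, 0.04, 0.05),
                     c("lysogenic", "lysogenic", "lytic", "lytic"))
  expect_equal(r$auc, 1)
  expect_equal(r$best_threshold, 0.03)
  expect_equal(unname(r$best_point), c(0, 1))

  # interleaved identical multisets: no separability
  r2 <- roc_threshold(c(1, 2, 3, 4, 1, 2, 3, 4),
                      rep(c("lysogenic", "lytic"), each = 4))
  expect_equal(r2$auc, 0.5)

  set.seed(111)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    d <- round(runif(n), 2)           # ties likely
    lab <- sample(c("lysogenic", "lytic"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    r3 <- roc_threshold(d, lab)
    expect_equal(r3$auc, naive_auc(d, lab), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(112)
  d <- c(rnorm(20, 1), rnorm(20, 1.6))
  lab <- rep(c("lysogenic", "lytic"), each = 20)
  r <- roc_threshold(d, lab)
  pr <- pROC::roc(response = lab, predictor = d,
                  levels = c("lytic", "lysogenic"), direction = ">",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  r_t <- roc_threshold(exp(3 * d), lab)
  expect_equal(r_t$auc, r$auc, tolerance = 1e-12)
  expect_error(roc_threshold(d, rep("lytic", 40)), "ROC undefined")
})

test_that("classification honours the boundary convention and is monotone", {
  gd <- data.frame(element_id = c("a", "b", "c"), host_group = "g",
                   method = "k4freq", mean = c(0.019, 0.030, 0.026))
  calls <- classify_lifecycle(gd, 0.026)
  expect_equal(calls$call, c("lysogenic", "lytic", "lysogenic"))
  # monotone: increasing distance never flips lytic -> lysogenic
  ds <- seq(0, 0.1, by = 0.005)
  cc <- classify_lifecycle(data.frame(element_id = as.character(seq_along(ds)),
                                      method = "k4freq", mean = ds), 0.026)$call
  expect_false(any(cc[-length(cc)] == "lytic" & cc[-1] == "lysogenic"))
  expect_warning(classify_lifecycle(gd, 0.955), "k14exact-scale")
  gd14 <- transform(gd, method = "k14exact", mean = mean + 0.9)
  expect_warning(classify_lifecycle(gd14, 0.026), "k4freq-scale")
  expect_error(classify_lifecycle(gd, -1), "positive")
})

test_that("reactivity ranking sorts, breaks ties by id and flags the lysogenic area", {
  gd <- data.frame(element_id = c("A", "B", "C", "D"), host_group = "g",
                   method = "k4freq", mean = c(0.03, 0.01, 0.02, 0.02))
  rk <- reactivity_rank(gd, threshold = 0.026,
                        interactions = c(A = 1, B = 9, C = 4, D = 3))
  expect_equal(rk$element_id, c("B", "C", "D", "A"))
  expect_equal(rk$rank, 1:4)
  expect_equal(rk$below_threshold, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(rk$interactions, c(9, 4, 3, 1))
  gd$method <- c("k4freq", "k4freq", "k14exact", "k14exact")
  expect_error(reactivity_rank(gd), "mixed methods")
})

test_that("association screening covers every element x cluster and flags transfer", {
  set.seed(121)
  mutate <- function(s, rate = 0.02) {
    b <- strsplit(s, "")[[1]]
    hit <- which(runif(length(b)) < rate)
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(b, collapse = "")
  }
  hostsA <- lapply(1:3, function(i)
    rec(sprintf("a%d", i), random_dna(6000, probs = c(0.4, 0.1, 0.1, 0.4))))
  baseB <- random_dna(6000, probs = c(0.1, 0.4, 0.4, 0.1))
  hostsB <- list(rec("b1", baseB), rec("b2", mutate(baseB)),
                 rec("b3", mutate(baseB)))
  hosts <- seq_collection(c(hostsA, hostsB))
  clusters <- list(clA = paste0("a", 1:3), clB = paste0("b", 1:3))
  # e1, e3 ameliorated to their own clusters; e2 is annotated to clA but is a
  # verbatim chunk of the clB strain backbone (horizontal-transfer candidate)
  e1 <- rec("e1", random_dna(1500, probs = c(0.4, 0.1, 0.1, 0.4)), "plasmid")
  e2 <- rec("e2", substr(baseB, 1000, 2499), "plasmid")
  e3 <- rec("e3", random_dna(1500, probs = c(0.1, 0.4, 0.4, 0.1)), "plasmid")
  elements <- seq_collection(list(e1, e2, e3))
  assoc <- data.frame(element_id = c("e1", "e2", "e3"), role = "plasmid",
                      host_group = c("clA", "clA", "clB"))
  scr <- association_screen(elements, clusters, hosts, "k14exact", k = 8,
                            associations = assoc)
  expect_equal(nrow(scr), 6L)
  expect_equal(sum(scr$associated), 3L)
  # e2 undercuts clB's own associated mean (b1 carries it verbatim, DSW 0)
  d_e2_B <- scr$mean[scr$element_id == "e2" & scr$host_group == "clB"]
  expect_lt(d_e2_B, scr$mean[scr$element_id == "e3" & scr$host_group == "clB"])
  expect_true(scr$transfer_flag[scr$element_id == "e2" & scr$host_group == "clB"])
  expect_false(any(scr$transfer_flag[scr$associated]))
  # group-by oracle: recompute one cell directly
  direct <- group_mean_distance(e1, hosts[clusters$clA], "k14exact", k = 8)
  expect_equal(scr$mean[scr$element_id == "e1" & scr$host_group == "clA"],
               direct$mean)
  expect_error(association_screen(elements, clusters, hosts, "k4freq",
                                  associations = transform(assoc, host_group = "clZ")),
               "unknown cluster")
})
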