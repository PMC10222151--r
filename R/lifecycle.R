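# Phage/plasmid-to-host-group distances, ROC threshold learning,
# lytic/lysogenic classification, reactivity ranking and association
# screening.

.method_k <- function(method, k) {
  if (!is.null(k)) return(as.integer(k))
  switch(method, k4freq = 4L, k14exact = 14L)
}

# Count each genome once at the required k; returns a named list of
# kmer_counts (k14exact) or kmer_signature (k4freq).
.profiles <- function(records, method, k, strand_mode = "forward") {
  lapply(records, function(r) {
    cnt <- count_kmers(r, k, strand_mode)
    if (cnt$total == 0)
      stop(sprintf("genome '%s' has no countable %d-mers", r$id, k))
    if (method == "k4freq") signature(cnt) else cnt
  })
}

.pair_distance <- function(pa, pb, method) {
  if (method == "k4freq") k4freq_distance(pa, pb) else dsw_distance(pa, pb)
}

#' Pairwise genomic distance table
#'
#' Computes the chosen distance between every query and every target genome.
#' Each genome is profiled once (counts or signatures) and reused across
#' pairs.
#'
#' @param queries,targets [seq_collection()]s.
#' @param method `"k4freq"` (signature Euclidean) or `"k14exact"` (DSW).
#' @param k Word length; defaults to 4 for k4freq and 14 for k14exact.
#' @param strand_mode Passed to [count_kmers()].
#' @return `data.frame` with columns `query_id`, `target_id`, `method`, `k`,
#'   `distance`.
#' @export
distance_table <- function(queries, targets,
                           method = c("k4freq", "k14exact"),
                           k = NULL, strand_mode = "forward") {
  method <- match.arg(method)
  k <- .method_k(method, k)
  pq <- .profiles(queries, method, k, strand_mode)
  pt <- .profiles(targets, method, k, strand_mode)
  out <- expand.grid(target_id = names(targets), query_id = names(queries),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("query_id", "target_id")]
  out$method <- method
  out$k <- k
  out$distance <- mapply(
    function(q, t) .pair_distance(pq[[q]], pt[[t]], method),
    out$query_id, out$target_id, USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean distance of one element to a host group
#'
#' Computes the chosen distance from a phage or plasmid to every genome of a
#' host group and summarizes it as mean, sample standard deviation (n - 1
#' denominator; 0 for a single host) and group size.
#'
#' @param element A [seq_record()] (phage or plasmid).
#' @param hosts Non-empty [seq_collection()] of the group's host genomes.
#' @param method `"k4freq"` or `"k14exact"`.
#' @param k Word length (method default when `NULL`).
#' @param host_group Group label recorded in the result.
#' @param strand_mode Passed to [count_kmers()].
#' @return One-row `data.frame`: `element_id`, `host_group`, `method`, `k`,
#'   `mean`, `sd`, `n_hosts`.
#' @export
group_mean_distance <- function(element, hosts,
                                method = c("k4freq", "k14exact"),
                                k = NULL, host_group = NA_character_,
                                strand_mode = "forward") {
  method <- match.arg(method)
  if (length(hosts) == 0L) stop("empty host group")
  k <- .method_k(method, k)
  tab <- distance_table(seq_collection(list(element)), hosts, method, k,
                        strand_mode)
  d <- tab$distance
  data.frame(element_id = element$id, host_group = host_group,
             method = method, k = k, mean = mean(d),
             sd = if (length(d) > 1) sd(d) else 0,
             n_hosts = length(d), stringsAsFactors = FALSE)
}

#' Mean distances of many elements to their annotated host groups
#'
#' Bulk companion to [group_mean_distance()]: profiles every genome exactly
#' once, computes all element-to-host distances, and summarizes each element
#' against the host group it is annotated to.
#'
#' @param elements [seq_collection()] of phages/plasmids.
#' @param hosts [seq_collection()] of host genomes.
#' @param groups Named character vector mapping host id -> group label.
#' @param element_groups Named character vector mapping element id -> the
#'   host group to summarize it against.
#' @param method,k,strand_mode See [distance_table()].
#' @return `data.frame` with one row per element: `element_id`,
#'   `host_group`, `method`, `k`, `mean`, `sd`, `n_hosts`.
#' @export
group_mean_table <- function(elements, hosts, groups, element_groups,
                             method = c("k4freq", "k14exact"), k = NULL,
                             strand_mode = "forward") {
  method <- match.arg(method)
  k <- .method_k(method, k)
  stopifnot(all(names(elements) %in% names(element_groups)),
            all(element_groups[names(elements)] %in% groups))
  tab <- distance_table(elements, hosts, method, k, strand_mode)
  tab$group <- unname(groups[tab$target_id])
  rows <- lapply(names(elements), function(eid) {
    grp <- unname(element_groups[[eid]])
    d <- tab$distance[tab$query_id == eid & tab$group == grp]
    data.frame(element_id = eid, host_group = grp, method = method, k = k,
               mean = mean(d), sd = if (length(d) > 1) sd(d) else 0,
               n_hosts = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ROC threshold for separating lysogenic and lytic phages
#'
#' The positive class is lysogenic and an element is predicted lysogenic
#' when its distance is at or below the threshold (lysogenic phages sit
#' closer to their hosts). Candidate thresholds are the midpoints between
#' consecutive sorted unique distances plus sentinels below the minimum and
#' above the maximum. AUC is the trapezoid area under the (FPR, TPR) curve;
#' the best threshold is the candidate whose ROC point is closest (Euclidean)
#' to the ideal classifier at (0, 1), ties resolved to the smallest
#' threshold. The midpoint of the two class means is also reported for
#' comparison.
#'
#' @param distances Numeric vector of element-to-host-group mean distances.
#' @param labels Character/factor vector of `"lysogenic"` / `"lytic"`, same
#'   length; both classes must be present.
#' @return Object of class `roc_result`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `best_threshold`, `best_point`, `class_mean_midpoint`.
#' @export
roc_threshold <- function(distances, labels) {
  labels <- as.character(labels)
  stopifnot(length(distances) == length(labels))
  if (!all(labels %in% c("lysogenic", "lytic")))
    stop("labels must be 'lysogenic' or 'lytic'")
  pos <- labels == "lysogenic"
  if (!any(pos) || all(pos)) stop("ROC undefined: both classes must be present")
  u <- sort(unique(distances))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  delta <- max(diff(range(u)), abs(u[1]), 1) * 1e-6
  thr <- c(u[1] - delta, mids, u[length(u)] + delta)
  tpr <- vapply(thr, function(t) mean(distances[pos] <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(distances[!pos] <= t), numeric(1))
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  d01 <- sqrt(fpr^2 + (1 - tpr)^2)
  best <- which(d01 == min(d01))
  best <- best[which.min(thr[best])]
  structure(
    list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
         best_threshold = thr[[best]],
         best_point = c(fpr = fpr[[best]], tpr = tpr[[best]]),
         class_mean_midpoint =
           (mean(distances[pos]) + mean(distances[!pos])) / 2),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f; best threshold %.6g at (FPR %.3f, TPR %.3f); class-mean midpoint %.6g\n",
              x$auc, x$best_threshold, x$best_point[["fpr"]],
              x$best_point[["tpr"]], x$class_mean_midpoint))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A [roc_threshold()] result.
#' @param ... Passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  o <- order(x$fpr, x$tpr)
  plot(x$fpr[o], x$tpr[o], type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::points(x$best_point[["fpr"]], x$best_point[["tpr"]], pch = 19)
  invisible(x)
}

#' Classify elements as lytic or lysogenic from mean distances
#'
#' An element is called lysogenic when its mean distance to the host group is
#' at or below the threshold (the boundary itself goes to lysogenic), lytic
#' otherwise. Thresholds are method-specific: k4freq thresholds live well
#' below 0.5 while k14exact (DSW) thresholds live near 1; a mismatch between
#' the two scales triggers a warning.
#'
#' @param gd `data.frame` of group distances as produced by
#'   [group_mean_distance()] (columns `element_id`, `host_group`, `method`,
#'   `mean`).
#' @param threshold Positive distance threshold on the method's scale.
#' @return `gd` with added columns `threshold` and `call`.
#' @export
classify_lifecycle <- function(gd, threshold) {
  stopifnot(is.data.frame(gd), all(c("element_id", "method", "mean") %in% names(gd)))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  m <- unique(gd$method)
  if (length(m) == 1L) {
    if (m == "k4freq" && threshold > 0.5)
      warning("threshold > 0.5 looks like a k14exact-scale threshold applied to k4freq distances")
    if (m == "k14exact" && threshold <= 0.5)
      warning("threshold <= 0.5 looks like a k4freq-scale threshold applied to k14exact distances")
  }
  gd$threshold <- threshold
  gd$call <- ifelse(gd$mean <= threshold, "lysogenic", "lytic")
  gd
}

#' Rank elements by predicted reactivity
#'
#' Sorts elements of one host group ascending by mean distance (shorter
#' distance = predicted broader lytic reactivity), ties broken by element id.
#' When a threshold is supplied, elements at or below it are flagged as
#' falling in the "lysogenic area"; observed interaction counts can be
#' joined for comparison.
#'
#' @param gd `data.frame` of group distances (one host group, one method).
#' @param threshold Optional distance threshold for the below-threshold flag.
#' @param interactions Optional named numeric vector of observed interaction
#'   counts per element id.
#' @return `gd` sorted with added `rank` and (optionally) `below_threshold`
#'   and `interactions` columns.
#' @export
reactivity_rank <- function(gd, threshold = NULL, interactions = NULL) {
  stopifnot(is.data.frame(gd), all(c("element_id", "method", "mean") %in% names(gd)))
  if (length(unique(gd$method)) > 1L)
    stop("mixed methods in ranking input; rank one method at a time")
  if ("host_group" %in% names(gd) && length(unique(gd$host_group)) > 1L)
    stop("mixed host groups in ranking input")
  gd <- gd[order(gd$mean, gd$element_id), , drop = FALSE]
  gd$rank <- seq_len(nrow(gd))
  if (!is.null(threshold)) gd$below_threshold <- gd$mean <= threshold
  if (!is.null(interactions))
    gd$interactions <- unname(interactions[gd$element_id])
  rownames(gd) <- NULL
  gd
}

#' Screen elements against every host cluster
#'
#' Computes a [group_mean_distance()] row for every element x cluster pair,
#' marks each element's annotated cluster (from the association table, when
#' given), and flags candidate horizontal transfer: an element whose
#' distance to a non-associated cluster falls below that cluster's mean over
#' its own associated elements.
#'
#' @param elements [seq_collection()] of phages/plasmids.
#' @param clusters A [cluster_hosts()] result or a named list of host-id
#'   vectors.
#' @param hosts [seq_collection()] covering all cluster members.
#' @param method,k,strand_mode Distance parameters (see [distance_table()]).
#' @param associations Optional association `data.frame`
#'   ([read_associations()]); `host_group` values must be cluster names.
#' @return `data.frame` with one row per element x cluster: the
#'   [group_mean_distance()] columns plus `associated` and `transfer_flag`.
#' @export
association_screen <- function(elements, clusters, hosts,
                               method = c("k4freq", "k14exact"), k = NULL,
                               strand_mode = "forward", associations = NULL) {
  method <- match.arg(method)
  k <- .method_k(method, k)
  members <- if (inherits(clusters, "host_clustering")) clusters$clusters
             else clusters
  stopifnot(length(members) >= 1)
  missing_hosts <- setdiff(unlist(members), names(hosts))
  if (length(missing_hosts))
    stop(sprintf("cluster member(s) absent from host collection: %s",
                 paste(missing_hosts, collapse = ", ")))
  anno <- setNames(rep(NA_character_, length(elements)), names(elements))
  if (!is.null(associations)) {
    hit <- associations$element_id %in% names(elements)
    bad <- setdiff(associations$host_group[hit], names(members))
    if (length(bad))
      stop(sprintf("element annotated to unknown cluster '%s'", bad[[1]]))
    anno[associations$element_id[hit]] <- associations$host_group[hit]
  }
  tab <- distance_table(elements, hosts, method, k, strand_mode)
  rows <- vector("list", length(elements) * length(members))
  i <- 0L
  for (eid in names(elements)) {
    for (cl in names(members)) {
      d <- tab$distance[tab$query_id == eid & tab$target_id %in% members[[cl]]]
      i <- i + 1L
      rows[[i]] <- data.frame(
        element_id = eid, host_group = cl, method = method, k = k,
        mean = mean(d), sd = if (length(d) > 1) sd(d) else 0,
        n_hosts = length(d), associated = !is.na(anno[[eid]]) && anno[[eid]] == cl,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # per-cluster mean over its own associated elements; transfer candidates
  # are non-associated elements undercutting that mean
  out$transfer_flag <- FALSE
  if (any(out$associated)) {
    assoc_mean <- tapply(out$mean[out$associated],
                         out$host_group[out$associated], mean)
    ref <- unname(assoc_mean[out$host_group])
    out$transfer_flag <- !out$associated & !is.na(ref) & out$mean < ref
  }
  rownames(out) <- NULL
  out
}
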