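# Host-genome grouping: hexamer signature matrix, PCA projection, DBSCAN.

#' Signature matrix for a genome collection
#'
#' One dense relative-frequency signature row per genome, fixed lexicographic
#' column order, rows summing to 1. The default k = 6 (hexamers) is the
#' resolution used to group bacterial host genomes.
#'
#' @param records A [seq_collection()].
#' @param k Word length (default 6).
#' @param strand_mode Passed to [count_kmers()].
#' @return Numeric matrix, rownames = genome ids, 4^k columns.
#' @export
signature_matrix <- function(records, k = 6, strand_mode = "forward") {
  mat <- matrix(0, nrow = length(records), ncol = 4^k,
                dimnames = list(names(records), NULL))
  for (i in seq_along(records)) {
    cnt <- count_kmers(records[[i]], k, strand_mode)
    if (cnt$total == 0)
      stop(sprintf("genome '%s' has no countable %d-mers", records[[i]]$id, k))
    mat[i, ] <- signature(cnt)$freq
  }
  mat
}

# Classic DBSCAN on a point matrix. Returns integer labels: 0 = noise,
# 1..n = clusters in order of discovery. Points are visited in row order, so
# callers wanting order-independence must sort rows first.
.dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)   # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!core[i]) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(labels[j]) && labels[j] != 0L) next
      expand <- is.na(labels[j]) && core[j]
      labels[j] <- cl
      if (expand) queue <- c(queue, setdiff(nb[[j]], which(!is.na(labels) & labels != 0L)))
    }
  }
  labels
}

#' Cluster host genomes by signature
#'
#' Mean-centres the signature matrix, projects it onto the leading principal
#' components (no column scaling; component signs fixed so each component's
#' largest-magnitude loading is positive), and groups the projected genomes
#' with DBSCAN. Genomes in no dense region are flagged as noise and are
#' typically removed before downstream distance work ([drop_noise()]).
#'
#' Rows are sorted by id before clustering so the partition does not depend
#' on input order. `eps` is a radius in the projection's coordinate system;
#' with `rescale = TRUE` the projection is scaled to unit total variance
#' first, making a given `eps` comparable across datasets.
#'
#' @param mat Signature matrix from [signature_matrix()] (rownames = ids).
#' @param eps DBSCAN neighbourhood radius (default 0.50).
#' @param min_pts DBSCAN minimum neighbourhood size (default 10).
#' @param n_components Number of principal components to project onto
#'   (default 2).
#' @param rescale Scale the projection to unit total variance before
#'   clustering (default `FALSE`).
#' @return Object of class `host_clustering`: list with `labels` (named
#'   integer vector, 0 = noise), `clusters` (list of member-id vectors,
#'   decreasing size), `noise` (ids), `projection`, `explained_variance`,
#'   `eps`, `min_pts`, `n_components`.
#' @export
cluster_hosts <- function(mat, eps = 0.50, min_pts = 10, n_components = 2,
                          rescale = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1)
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  n_components <- min(n_components, nrow(mat), ncol(mat))
  pca <- prcomp(mat, center = TRUE, scale. = FALSE)
  k_av <- min(n_components, ncol(pca$x))
  proj <- pca$x[, seq_len(k_av), drop = FALSE]
  for (j in seq_len(ncol(proj))) {        # sign convention for reproducibility
    ld <- pca$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) proj[, j] <- -proj[, j]
  }
  if (rescale) {
    tv <- sum(apply(proj, 2, stats::var))
    if (tv > 0) proj <- proj / sqrt(tv)
  }
  if (nrow(mat) < min_pts) {
    warning(sprintf("fewer genomes (%d) than min_pts (%d): all flagged as noise",
                    nrow(mat), min_pts))
    labels <- rep(0L, nrow(mat))
  } else {
    labels <- .dbscan(proj, eps, min_pts)
  }
  names(labels) <- rownames(mat)
  ids_by_cl <- split(names(labels), labels)
  noise <- unname(ids_by_cl[["0"]] %||% character(0))
  clusters <- ids_by_cl[names(ids_by_cl) != "0"]
  clusters <- clusters[order(-vapply(clusters, length, integer(1)),
                             vapply(clusters, function(m) m[[1]], character(1)))]
  names(clusters) <- if (length(clusters))
    sprintf("cluster%d", seq_along(clusters)) else character(0)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  structure(
    list(labels = labels, clusters = clusters, noise = noise,
         projection = proj,
         explained_variance = ev[seq_len(k_av)],
         eps = eps, min_pts = min_pts, n_components = k_av),
    class = "host_clustering")
}

#' @export
print.host_clustering <- function(x, ...) {
  cat(sprintf("<host_clustering> %d cluster(s), %d noise genome(s) of %d (eps=%g, min_pts=%d)\n",
              length(x$clusters), length(x$noise), length(x$labels),
              x$eps, x$min_pts))
  for (nm in names(x$clusters))
    cat(sprintf("  %s: %d members\n", nm, length(x$clusters[[nm]])))
  invisible(x)
}

#' Remove noise genomes flagged by clustering
#'
#' @param report A [cluster_hosts()] result computed from `records`.
#' @param records The [seq_collection()] that was clustered.
#' @return List with `records` (collection restricted to cluster members)
#'   and `noise` (the removed ids, for logging).
#' @export
drop_noise <- function(report, records) {
  stopifnot(inherits(report, "host_clustering"))
  keep <- setdiff(names(records), report$noise)
  if (!length(keep)) warning("all genomes flagged as noise; empty collection returned")
  list(records = records[keep], noise = report$noise)
}

#' Serialize a clustering report to JSON
#'
#' @param report A [cluster_hosts()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering_json <- function(report, path) {
  jsonlite::write_json(
    list(eps = report$eps, min_pts = report$min_pts,
         n_components = report$n_components,
         explained_variance = report$explained_variance,
         clusters = lapply(report$clusters, as.list),
         noise = as.list(report$noise)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
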