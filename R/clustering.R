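# Expression-profile clustering: correlation distance, UPGMA, seeded k-means
# with correlation distance, and the robust intersection of the two
# partitions. Profiles are time courses of signed log2 fold change; shape
# (not amplitude) drives similarity, hence the correlation metric and the
# row standardization used by k-means.

#' Correlation distance between two profiles
#'
#' 1 - Pearson correlation; 0 for identical shapes, 2 for perfectly
#' anticorrelated ones.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return distance in \[0, 2\].
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    isc_stop("profiles must have equal length >= 3", "isc_param_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    isc_stop("zero-variance (flat) profile has no correlation distance",
             "isc_degenerate_profile")
  1 - stats::cor(x, y)
}

# All-pairs correlation-distance matrix for the rows of a profile matrix.
correlation_distance_matrix <- function(mat) {
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    isc_stop(paste0("flat profile(s): ",
                    paste(utils::head(rownames(mat)[sds == 0], 5), collapse = ", ")),
             "isc_degenerate_profile")
  d <- 1 - stats::cor(t(mat))
  d[d < 0] <- 0   # clip numerical noise
  diag(d) <- 0
  d
}

#' UPGMA (average linkage) clustering of a distance matrix
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal.
#' @return an `hclust` tree (merge heights are the UPGMA average distances).
#' @export
upgma_cluster <- function(distance_matrix) {
  if (!is.matrix(distance_matrix) ||
      nrow(distance_matrix) != ncol(distance_matrix) ||
      max(abs(distance_matrix - t(distance_matrix))) > 1e-8 ||
      any(abs(diag(distance_matrix)) > 1e-12))
    isc_stop("distance matrix must be symmetric with zero diagonal",
             "isc_validation_error")
  stats::hclust(stats::as.dist(distance_matrix), method = "average")
}

#' Build the profile matrix for clustering
#'
#' Rows are genes whose maximal absolute fold change exceeds
#' `cluster_fc_threshold`; entries are signed log2 of the per-time fold
#' change, sign carrying the direction of regulation.
#'
#' @param results `differential_result`.
#' @param config `analysis_config`.
#' @param statuses statuses eligible for clustering; by default the
#'   up-regulated set (UP and ISP), matching the published procedure of
#'   clustering the induced genes.
#' @return numeric matrix, genes x times, with gene ids as row names.
#' @export
profile_matrix <- function(results, config = analysis_config(),
                           statuses = c("UP", "ISP")) {
  times <- attr(results, "times")
  keep <- results$max_abs_fc > config$cluster_fc_threshold &
    results$status %in% statuses
  tl <- function(t) format(t, trim = TRUE)
  m <- sapply(times, function(t) {
    fc <- results[[paste0("fc_", tl(t), "h")]][keep]
    sign(fc) * log2(abs(fc))
  })
  rownames(m) <- results$gene_id[keep]
  colnames(m) <- paste0(times, "h")
  m
}

# Standardize rows to zero mean / unit variance: on these, squared Euclidean
# distance is proportional to correlation distance.
standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0))
    isc_stop("flat profile cannot be standardized", "isc_degenerate_profile")
  (mat - mu) / sds
}

#' Seeded k-means on profiles with correlation distance
#'
#' Lloyd iterations on row-standardized profiles: assignment minimizes
#' correlation distance to the centroid; the update is the standardized mean
#' of the member profiles (the profile minimizing summed correlation
#' distance, up to standardization). The best of `restarts` random starts by
#' total within-cluster distance is returned; results are deterministic for a
#' given seed.
#'
#' @param mat profile matrix (genes x times).
#' @param k number of classes, k <= nrow(mat).
#' @param seed RNG seed.
#' @param restarts random restarts. Default 50.
#' @return integer vector of cluster labels (1..k), named by gene id.
#' @export
kmeans_profiles <- function(mat, k, seed = 1L, restarts = 50L) {
  n <- nrow(mat)
  if (k > n) isc_stop("k must not exceed the number of profiles", "isc_param_error")
  z <- standardize_rows(mat)
  with_seed(seed, {
    best <- NULL
    best_obj <- Inf
    for (r in seq_len(restarts)) {
      centers <- z[sample.int(n, k), , drop = FALSE]
      labels <- integer(n)
      for (iter in 1:100) {
        # correlation distance = ||z_i - c_j||^2 / (2 (p-1)) on standardized rows
        d2 <- outer(rowSums(z^2), rowSums(centers^2), `+`) - 2 * z %*% t(centers)
        new_labels <- max.col(-d2, ties.method = "first")
        if (identical(new_labels, labels)) break
        labels <- new_labels
        for (j in seq_len(k)) {
          if (!any(labels == j)) next   # empty classes keep their centroid
          cm <- colMeans(z[labels == j, , drop = FALSE])
          s <- stats::sd(cm)
          centers[j, ] <- if (s > 0) (cm - mean(cm)) / s else cm
        }
      }
      d2 <- outer(rowSums(z^2), rowSums(centers^2), `+`) - 2 * z %*% t(centers)
      obj <- sum(d2[cbind(seq_len(n), labels)])
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- labels
      }
    }
    names(best) <- rownames(mat)
    best
  })
}

# Mean silhouette width for a labeling given a precomputed distance matrix.
mean_silhouette <- function(d, labels) {
  n <- length(labels)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { sil[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(sil)
}

#' Cut an UPGMA tree at the silhouette-optimal number of classes
#'
#' @param tree `hclust` tree.
#' @param d distance matrix the tree was built from.
#' @param k_range candidate class counts. Default 2..15.
#' @return integer labels.
#' @export
cut_by_silhouette <- function(tree, d, k_range = 2:15) {
  k_range <- k_range[k_range <= nrow(d)]
  scores <- vapply(k_range, function(k) mean_silhouette(d, stats::cutree(tree, k)),
                   numeric(1))
  stats::cutree(tree, k_range[which.max(scores)])
}

#' Robust clusters by intersecting two partitions
#'
#' Genes sharing both a class in partition one and a class in partition two
#' form a cell; cells with at least `min_size` members become robust
#' clusters (labeled by decreasing size), the rest are unclassified.
#'
#' @param hier_labels,kmeans_labels label vectors over the same genes, named
#'   by gene id (names of the first vector are used).
#' @param min_size minimum robust-cluster size. Default 10.
#' @return object of class `robust_clustering`: list with `clusters` (named
#'   list of gene-id vectors) and `unclassified` (gene ids).
#' @export
robust_intersection <- function(hier_labels, kmeans_labels, min_size = 10L) {
  if (length(hier_labels) != length(kmeans_labels))
    isc_stop("label vectors must have equal length", "isc_validation_error")
  ids <- names(hier_labels)
  if (is.null(ids)) ids <- as.character(seq_along(hier_labels))
  cell <- paste(hier_labels, kmeans_labels, sep = "|")
  sizes <- sort(table(cell), decreasing = TRUE)
  robust_cells <- names(sizes)[sizes >= min_size]
  clusters <- list()
  for (i in seq_along(robust_cells))
    clusters[[paste0("C", i)]] <- ids[cell == robust_cells[i]]
  unclassified <- ids[!(cell %in% robust_cells)]
  structure(list(clusters = clusters, unclassified = unclassified),
            class = "robust_clustering")
}

#' @export
print.robust_clustering <- function(x, ...) {
  cat("robust_clustering:", length(x$clusters), "clusters,",
      length(x$unclassified), "unclassified\n")
  for (nm in names(x$clusters))
    cat(" ", nm, ":", length(x$clusters[[nm]]), "genes\n")
  invisible(x)
}

#' Cluster centroid profiles
#'
#' @param clustering `robust_clustering`.
#' @param mat profile matrix the clustering was computed on.
#' @return data.frame: cluster, time column means (`profile_*`), the profile
#'   centered on its median level (`centered_*`), and per-time standard
#'   deviations (`sd_*`).
#' @export
cluster_centroids <- function(clustering, mat) {
  rows <- lapply(names(clustering$clusters), function(nm) {
    sub <- mat[clustering$clusters[[nm]], , drop = FALSE]
    prof <- colMeans(sub)
    sds <- apply(sub, 2, stats::sd)
    out <- data.frame(cluster = nm, n = nrow(sub))
    for (j in seq_along(prof)) {
      out[[paste0("profile_", colnames(mat)[j])]] <- prof[j]
      out[[paste0("centered_", colnames(mat)[j])]] <- prof[j] - stats::median(prof)
      out[[paste0("sd_", colnames(mat)[j])]] <- sds[j]
    }
    out
  })
  do.call(rbind, rows)
}

#' Full robust-clustering pipeline for a profile matrix
#'
#' UPGMA on the correlation-distance matrix (cut at the silhouette-optimal
#' class count), independent k-means with `config$kmeans_k` classes, and the
#' intersection of the two partitions.
#'
#' @param mat profile matrix from [profile_matrix()].
#' @param config `analysis_config`.
#' @return list with `clustering` (`robust_clustering`), `centroids`,
#'   `hier_labels`, `kmeans_labels`.
#' @export
cluster_profiles <- function(mat, config = analysis_config()) {
  d <- correlation_distance_matrix(mat)
  tree <- upgma_cluster(d)
  hier <- cut_by_silhouette(tree, d)
  km <- kmeans_profiles(mat, k = config$kmeans_k,
                        seed = derive_seed(config$rng_seed, 101L),
                        restarts = config$kmeans_restarts)
  clustering <- robust_intersection(hier, km, min_size = config$min_cluster_size)
  list(clustering = clustering,
       centroids = cluster_centroids(clustering, mat),
       hier_labels = hier,
       kmeans_labels = km)
}
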