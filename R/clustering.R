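# Clustering of validated stabilizing mutations on the nine-column feature
# table, to split the library into independent experimental accumulation
# tracks. k-means on standardized features, with the number of clusters
# chosen by mean silhouette when not fixed by the user.

#' Standardize a feature table for clustering
#'
#' z-scores each numeric feature column (columns with zero spread map to 0),
#' passes the binary entropy flag through unscaled, and multiplies the three
#' CA coordinate columns jointly by `coordinate_weight` after scaling so the
#' spatial contribution to the distance can be tuned (0 removes geography
#' entirely).
#'
#' @param table feature table from [feature_table()].
#' @param coordinate_weight multiplier for the scaled coordinate columns
#'   (default 1).
#' @return numeric matrix (rows named by mutation) with attribute `scaling`
#'   (per-column center/spread used).
#' @export
standardize_features <- function(table, coordinate_weight = 1) {
  if (nrow(table) < 2) stopf("need at least 2 mutations to standardize")
  cols <- c("delta_tm", "hbond", "hydrophobic", "entropy", "ca_x", "ca_y", "ca_z")
  stopifnot(all(cols %in% names(table)))
  x <- as.matrix(table[, cols])
  center <- colMeans(x)
  spread <- apply(x, 2, stats::sd)
  center["entropy"] <- 0
  spread["entropy"] <- 1
  z <- sweep(x, 2, center)
  safe_spread <- ifelse(spread > 0, spread, 1)
  z <- sweep(z, 2, safe_spread, "/")
  z[, spread == 0] <- 0
  z[, "entropy"] <- x[, "entropy"]
  z[, c("ca_x", "ca_y", "ca_z")] <- z[, c("ca_x", "ca_y", "ca_z")] * coordinate_weight
  rownames(z) <- table$mutation
  attr(z, "scaling") <- data.frame(column = cols, center = center, spread = spread,
                                   row.names = NULL)
  z
}

mean_silhouette <- function(labels, x) {
  k <- length(unique(labels))
  n <- length(labels)
  if (k < 2 || k > n - 1) return(NA_real_)
  mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
}

#' Cluster stabilizing mutations
#'
#' k-means (20 restarts) on the standardized feature matrix. With
#' `k = "auto"` the number of clusters maximizing the mean silhouette width
#' over `k_range` is chosen, ties broken toward fewer clusters (fewer parallel
#' experimental tracks). Deterministic for a fixed seed.
#'
#' @param table feature table from [feature_table()] (>= 2 rows).
#' @param k number of clusters, or `"auto"` (default).
#' @param k_range candidate k values tried when `k = "auto"`; default
#'   `2:min(8, n - 1)`.
#' @param seed integer seed for the k-means restarts.
#' @param coordinate_weight passed to [standardize_features()].
#' @return an object of class `cluster_assignment`: `labels` (named integer
#'   vector, values `0..k-1`), `k`, `clusters` (member list per label),
#'   `silhouette` (mean width; `NA` when undefined), `scaling`, and the input
#'   `table`.
#' @export
cluster_mutations <- function(table, k = "auto", k_range = NULL, seed = 0,
                              coordinate_weight = 1) {
  n <- nrow(table)
  if (n < 2) stopf("need at least 2 mutations to cluster")
  x <- standardize_features(table, coordinate_weight)
  fit_k <- function(kk) {
    if (kk == 1) {
      list(cluster = rep(1L, n))
    } else if (kk == n) {
      list(cluster = seq_len(n))
    } else {
      with_seed(seed, stats::kmeans(x, centers = kk, nstart = 20, iter.max = 100))
    }
  }
  if (identical(k, "auto")) {
    if (is.null(k_range)) k_range <- seq(2, min(8, n - 1))
    k_range <- k_range[k_range >= 2 & k_range <= n - 1]
    if (length(k_range) == 0) stopf("no admissible k for n = %d", n)
    sils <- vapply(k_range, function(kk) mean_silhouette(fit_k(kk)$cluster, x),
                   numeric(1))
    k <- k_range[which.max(sils)]  # which.max takes the first (smallest) tie
  } else {
    if (!is_count(k) || k < 1 || k > n) stopf("k must be an integer in [1, %d]", n)
  }
  fit <- fit_k(k)
  labels <- as.integer(fit$cluster) - 1L
  names(labels) <- table$mutation
  structure(list(
    labels = labels, k = as.integer(k),
    clusters = split(names(labels), labels),
    silhouette = mean_silhouette(fit$cluster, x),
    scaling = attr(x, "scaling"),
    table = table
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, n = %d, mean silhouette = %s\n",
              x$k, length(x$labels),
              ifelse(is.na(x$silhouette), "undefined", sprintf("%.3f", x$silhouette))))
  invisible(x)
}

#' Per-cluster summary
#'
#' One row per cluster with its size, mean melting-temperature improvement,
#' and centroid CA position; the `members` column lists the cluster's
#' mutations sorted by delta-Tm descending, the order in which the greedy
#' accumulation stage will consider them.
#'
#' @param assignment a [cluster_mutations()] result.
#' @return data frame `cluster`, `size`, `mean_delta_tm`, `centroid_x/y/z`,
#'   `members` (semicolon-joined, delta-Tm descending).
#' @export
cluster_report <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  tab <- assignment$table
  out <- lapply(sort(unique(assignment$labels)), function(lb) {
    members <- names(assignment$labels)[assignment$labels == lb]
    sub <- tab[match(members, tab$mutation), ]
    sub <- sub[order(-sub$delta_tm), ]
    data.frame(cluster = lb, size = nrow(sub),
               mean_delta_tm = mean(sub$delta_tm),
               centroid_x = mean(sub$ca_x), centroid_y = mean(sub$ca_y),
               centroid_z = mean(sub$ca_z),
               members = paste(sub$mutation, collapse = ";"))
  })
  do.call(rbind, out)
}

#' Write/read cluster assignments
#'
#' @param assignment a [cluster_mutations()] result.
#' @param path CSV path (`mutation,cluster`).
#' @export
write_clusters <- function(assignment, path) {
  utils::write.csv(data.frame(mutation = names(assignment$labels),
                              cluster = unname(assignment$labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mutation", "cluster") %in% names(out)))
    stopf("cluster CSV must have columns mutation, cluster")
  out
}
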