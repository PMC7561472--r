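#' High/low N/C YAP threshold by 1-D k-means
#'
#' Standardises the values, runs k-means with k = 2 (10 restarts, fixed
#' seed, best inertia kept), and reports the threshold as the midpoint — on
#' the original scale — between the maximum of the low cluster and the
#' minimum of the high cluster. A cell is labelled `high` when its value is
#' strictly above the threshold. The classification is invariant under
#' affine rescaling of the inputs.
#'
#' @param values numeric vector of N/C ratios (>= 4 finite values).
#' @param nstart k-means restarts (default 10).
#' @param seed seed for the k-means restarts (default 1).
#' @return list with `threshold`, `labels` (factor low/high aligned to
#'   `values`, `NA` where the input was not finite) and the k-means fit.
#' @export
yap_threshold <- function(values, nstart = 10L, seed = 1L) {
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) < 4L) stop("need at least 4 finite values")
  if (stats::sd(v) == 0) stop("all values identical: no bimodality to threshold")
  z <- as.numeric(scale(v))
  km <- withr::with_seed(seed, stats::kmeans(z, centers = 2L, nstart = nstart))
  low <- which.min(km$centers) # ties broken toward the lowest centroid
  thr <- (max(v[km$cluster == low]) + min(v[km$cluster != low])) / 2
  labels <- rep(NA_character_, length(values))
  labels[ok] <- ifelse(values[ok] > thr, "high", "low")
  list(threshold = thr,
       labels = factor(labels, levels = c("low", "high")),
       kmeans = km)
}

# Adaptive merge-height-gap cut of a Ward dendrogram: among k in 2..6 whose
# clusters all reach min_size, pick the k with the largest relative drop in
# merge height; deterministic fallback to k = 3 when no candidate qualifies.
dynamic_cut <- function(hc, n, min_size, k_range = 2:6) {
  heights <- sort(hc$height, decreasing = TRUE) # H1 >= H2 >= ...
  k_range <- k_range[k_range <= n - 1L]
  scores <- vapply(k_range, function(k) {
    hk <- heights[k]
    if (hk <= 0) return(Inf)
    heights[k - 1] / hk
  }, numeric(1))
  ord <- k_range[order(scores, decreasing = TRUE)]
  for (k in ord) {
    sizes <- tabulate(stats::cutree(hc, k = k))
    if (min(sizes) >= min_size) return(k)
  }
  3L
}

#' Hierarchical clustering of blastomere records
#'
#' Z-scores the chosen variables, builds the Euclidean distance matrix,
#' clusters with Ward's method, and picks the number of clusters with an
#' adaptive tree cut (largest relative merge-height gap subject to a
#' minimum cluster size, fallback k = 3). Clusters are named from their
#' centroids on the original scale: lowest N/C YAP *and* lowest exposed
#' proportion is `inside-like`; the highest N/C YAP among the rest is
#' `outside-like`; remaining clusters are `undefined` (these carry the
#' highest exposed proportion at intermediate YAP). If no cluster is lowest
#' in both variables the naming is ambiguous: names stay unset with a
#' warning rather than guessing.
#'
#' @param records data.frame of blastomere records.
#' @param variables columns to cluster on (default `nc_yap` and
#'   `prop_exposed`, the two variables the inside/outside states separate
#'   on).
#' @param k optional fixed cluster count (bypasses the adaptive cut).
#' @param min_size minimum cluster size for the adaptive cut (default
#'   `max(3, 5%)` of the records).
#' @return object of class `cluster_model`: `labels` (integer cluster ids),
#'   `names` (cluster id to state name, possibly `NA`), `state` (per-record
#'   state factor), `k`, `linkage`, `centroids` (original scale), `scaling`
#'   (per-variable mean/sd), `silhouette` (mean, when the cluster package is
#'   available) and the `hclust` tree.
#' @export
hier_cluster <- function(records, variables = c("nc_yap", "prop_exposed"),
                         k = NULL, min_size = NULL) {
  stopifnot(all(variables %in% names(records)))
  X <- as.matrix(records[, variables, drop = FALSE])
  ok <- apply(is.finite(X), 1, all)
  if (!all(ok)) stop("non-finite values in clustering variables")
  n <- nrow(X)
  if (is.null(k) && n < 9L) stop("need at least 3 * k = 9 records")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) stop("constant clustering variable: ",
                          paste(variables[sdv == 0], collapse = ", "))
  Z <- scale(X, center = mu, scale = sdv)
  hc <- stats::hclust(stats::dist(Z, method = "euclidean"),
                      method = "ward.D2")
  if (is.null(min_size)) min_size <- max(3L, ceiling(0.05 * n))
  if (is.null(k)) k <- dynamic_cut(hc, n, min_size)
  labels <- stats::cutree(hc, k = k)

  centroids <- apply(X, 2, function(col) tapply(col, labels, mean))
  centroids <- matrix(centroids, nrow = k,
                      dimnames = list(NULL, variables))

  sil <- NA_real_
  if (requireNamespace("cluster", quietly = TRUE) && k > 1L) {
    sw <- cluster::silhouette(labels, stats::dist(Z))
    sil <- mean(sw[, "sil_width"])
  }

  nm <- name_clusters(centroids, variables)
  if (!is.na(sil) && sil < 0.15) {
    warning("weak cluster structure (mean silhouette < 0.15); names unset")
    nm <- rep(NA_character_, k)
  }

  state <- factor(nm[labels],
                  levels = c("inside-like", "outside-like", "undefined"))
  structure(list(labels = labels, names = nm, state = state, k = k,
                 linkage = "ward.D2 on z-scored Euclidean distances",
                 centroids = centroids,
                 scaling = list(mean = mu, sd = sdv),
                 silhouette = sil, hclust = hc),
            class = "cluster_model")
}

# Name clusters from centroid ordering in (nc_yap, prop_exposed)-like pairs:
# the first variable is the YAP axis, the second the exposure axis.
name_clusters <- function(centroids, variables) {
  k <- nrow(centroids)
  yap <- centroids[, 1]
  expo <- centroids[, 2]
  nm <- rep("undefined", k)
  lo <- which.min(yap)
  if (which.min(expo) != lo) {
    warning("ambiguous centroid ordering: no cluster is lowest in both ",
            variables[1], " and ", variables[2], "; names unset")
    return(rep(NA_character_, k))
  }
  nm[lo] <- "inside-like"
  rest <- setdiff(seq_len(k), lo)
  nm[rest[which.max(yap[rest])]] <- "outside-like"
  nm
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d (%s)\n", x$k, x$linkage))
  tab <- table(x$labels)
  for (i in seq_len(x$k)) {
    cat(sprintf("  cluster %d [%s]: n = %d, centroid (%s)\n", i,
                x$names[i] %||% "?", tab[as.character(i)],
                paste(sprintf("%.3f", x$centroids[i, ]), collapse = ", ")))
  }
  invisible(x)
}
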