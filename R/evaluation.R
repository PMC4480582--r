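#' k-means clustering baseline
#'
#' Squared-Euclidean k-means with many random restarts, keeping the restart
#' with the smallest within-cluster sum of squares (the protocol used by the
#' reference clustering comparison: 500 random starting points).
#'
#' @param data Numeric matrix or data frame (observations in rows).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param restarts Number of random restarts.
#' @param seed Optional integer seed; the best restart is then deterministic.
#' @return An object of class `unpbn_clustering` with fields `labels`,
#'   `k`, `method`, `objective` (total within-cluster SS) and `parameters`.
#' @export
cluster_kmeans <- function(data, k, restarts = 500, seed = NULL) {
  X <- as_data_matrix(data)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1) {
    km <- list(cluster = rep(1L, n),
               tot.withinss = sum(scale(X, scale = FALSE)^2))
  } else {
    km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100)
  }
  new_clustering(km$cluster, k, "kmeans", km$tot.withinss,
                 list(restarts = restarts, seed = seed))
}

#' Ward hierarchical clustering baseline
#'
#' Agglomerative clustering on Euclidean distances with Ward's
#' minimum-increase-of-within-cluster-variance linkage, cut at `k` clusters
#' (for `k = 2` this keeps the final two clusters of the dendrogram).
#'
#' @inheritParams cluster_kmeans
#' @return An `unpbn_clustering`; the fitted dendrogram is kept in
#'   `parameters$hclust`.
#' @export
cluster_ward <- function(data, k) {
  X <- as_data_matrix(data)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and n", call. = FALSE)
  hc <- hclust(dist(X), method = "ward.D2")
  labels <- cutree(hc, k)
  new_clustering(as.integer(labels), k, "hierarchical", NA_real_,
                 list(linkage = "ward.D2", hclust = hc))
}

new_clustering <- function(labels, k, method, objective, parameters) {
  labels <- as.integer(labels)
  if (any(tabulate(labels, nbins = k) == 0))
    stop("clustering produced an empty cluster", call. = FALSE)
  structure(list(labels = labels, k = as.integer(k), method = method,
                 objective = objective, parameters = parameters),
            class = "unpbn_clustering")
}

#' @export
print.unpbn_clustering <- function(x, ...) {
  cat(x$method, "clustering with k =", x$k, "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
tidy.unpbn_clustering <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$labels), cluster = x$labels)
}

#' Silhouette values and average silhouette width (ASW)
#'
#' For each observation, `sil(x_i) = (b_i - a_i) / max(a_i, b_i)` where `a_i`
#' is its mean Euclidean dissimilarity to the other members of its own
#' cluster and `b_i` the smallest mean dissimilarity to any other cluster.
#' Values lie in `[-1, 1]`; members of singleton clusters get 0 (Rousseeuw's
#' convention). With a single cluster the silhouette is undefined and an
#' error is signalled.
#'
#' @param data Numeric matrix or data frame.
#' @param labels Cluster labels (length `n`), or an `unpbn_clustering` /
#'   `unpbn_consensus` object.
#' @return `silhouette_values()`: numeric vector of length `n`;
#'   `average_silhouette_width()`: a scalar.
#' @export
silhouette_values <- function(data, labels) {
  X <- as_data_matrix(data)
  l <- extract_labels(labels)
  if (length(l) != nrow(X))
    stop("labels length does not match the data", call. = FALSE)
  if (length(unique(l)) < 2)
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  sil <- cluster::silhouette(as.integer(as.factor(l)), dist(X))
  as.numeric(sil[, "sil_width"])
}

#' @rdname silhouette_values
#' @export
average_silhouette_width <- function(data, labels) {
  mean(silhouette_values(data, labels))
}

extract_labels <- function(labels) {
  if (inherits(labels, "unpbn_clustering")) labels$labels
  else if (inherits(labels, "unpbn_consensus")) labels$labels
  else as.integer(as.factor(labels))
}

#' Select the number of clusters by maximal ASW
#'
#' Compares labelings produced by *one* method at several cluster counts and
#' returns the count with the largest average silhouette width. Silhouette
#' widths are not comparable between different clustering approaches, so
#' this comparison must stay within a single method. Exact ties are
#' reported, not silently broken.
#'
#' @param data Numeric matrix or data frame.
#' @param labelings Named list mapping each candidate `k` to its labels
#'   (names coercible to integer), e.g. `list("2" = ..., "3" = ...)`.
#' @return A tibble with columns `k`, `asw`, `is_best`; the attribute
#'   `k_best` holds the selected `k` (several values on a tie, with a
#'   message).
#' @export
asw_model_selection <- function(data, labelings) {
  if (length(labelings) < 2)
    stop("labelings for at least two values of k are required", call. = FALSE)
  ks <- as.integer(names(labelings))
  if (anyNA(ks)) stop("labelings must be named by k", call. = FALSE)
  asw <- vapply(labelings, function(l) average_silhouette_width(data, l),
                numeric(1))
  best <- which(asw == max(asw))
  if (length(best) > 1)
    message("ASW tie between k = ", paste(ks[best], collapse = ", "))
  out <- tibble::tibble(k = ks, asw = unname(asw),
                        is_best = seq_along(ks) %in% best)
  attr(out, "k_best") <- ks[best]
  out
}
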