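# Sum-of-squares decomposition in the original feature space.
# WSS_c = sum over cluster c of squared distance to the cluster centroid;
# TSS about the grand centroid; BSS = TSS - sum(WSS) (and equals the
# centroid decomposition exactly, by the law of total variance).
wss_stats <- function(x, labels) {
  x <- as.matrix(x)
  grand <- colMeans(x)
  tss <- sum(sweep(x, 2L, grand)^2)
  labs <- sort(unique(labels))
  per <- vapply(labs, function(l) {
    xi <- x[labels == l, , drop = FALSE]
    sum(sweep(xi, 2L, colMeans(xi))^2)
  }, numeric(1L))
  names(per) <- labs
  total <- sum(per)
  list(per_cluster_wss = per, total_wss = total, tss = tss,
       bss = tss - total,
       bss_ratio = if (tss > 0) (tss - total) / tss else NA_real_)
}

# run stats::kmeans defensively: retry a few fresh starts if an empty
# cluster persists, error only if it survives all retries
run_kmeans <- function(emb, k, n_restarts, iter_max = 300L) {
  for (attempt in 1:5) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(emb, centers = k, nstart = n_restarts,
                                     iter.max = iter_max)),
      error = function(e) e)
    if (!inherits(fit, "error") && length(unique(fit$cluster)) == k)
      return(fit)
  }
  if (inherits(fit, "error")) stop(conditionMessage(fit))
  stop("k-means produced an empty cluster in every restart (k = ", k, ")")
}

#' Cluster a spectral embedding by k-means
#'
#' Best-of-restarts k-means on the embedding coordinates; cluster-quality
#' sums of squares (WSS/BSS/TSS) are computed in the ORIGINAL feature
#' space supplied as `x`, not in embedding space, so they describe the
#' data actually clustered.
#'
#' With `polish = TRUE` (the default) the spectral labels additionally
#' seed one Lloyd k-means pass in the original feature space, so the
#' reported labels are a local optimum of the very WSS objective the
#' result is scored by; boundary points snap to their nearest cluster
#' centroid. `polish = FALSE` returns the classical embedding-space
#' assignment unchanged.
#'
#' @param embedding a `"spectral_embedding"`.
#' @param k number of clusters, `k <= n`.
#' @param x original feature matrix (rows must match the embedding).
#' @param n_restarts random k-means starts; the best (lowest embedding
#'   WSS) is kept.
#' @param polish refine the labels by a final Lloyd pass in the original
#'   feature space (kept only if it preserves all k clusters).
#' @param seed optional RNG seed for the restart stream.
#' @return `"clustering_result"`, see [spectral_cluster()].
#' @export
kmeans_cluster <- function(embedding, k, x, n_restarts = 25L, polish = TRUE,
                           seed = NULL) {
  stopifnot(inherits(embedding, "spectral_embedding"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(embedding$vectors))
    stop("x and embedding disagree on the number of rows")
  k <- as.integer(k)
  if (k < 1L || k > nrow(x)) stop("k must satisfy 1 <= k <= n")
  if (!is.null(seed)) set.seed(seed)
  if (k == nrow(x)) {
    labels <- as.character(seq_len(nrow(x)))
  } else if (k == 1L) {
    labels <- rep("1", nrow(x))
  } else {
    fit <- run_kmeans(embedding$vectors, k, n_restarts)
    labels <- as.character(fit$cluster)
    if (polish) {
      cent <- do.call(rbind, lapply(sort(unique(labels)), function(l)
        colMeans(x[labels == l, , drop = FALSE])))
      pol <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = cent, iter.max = 300L)),
        error = function(e) NULL)
      if (!is.null(pol) && length(unique(pol$cluster)) == k)
        labels <- as.character(pol$cluster)
    }
  }
  ids <- if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
  ss <- wss_stats(x, labels)
  structure(list(partition = partition(ids, labels), k = k,
                 per_cluster_wss = ss$per_cluster_wss,
                 total_wss = ss$total_wss, tss = ss$tss,
                 bss_ratio = ss$bss_ratio,
                 feature_space_ids = colnames(x),
                 embedding = embedding),
            class = "clustering_result")
}

#' Spectral clustering of rows of a feature matrix
#'
#' The package's estimator: build a k-nearest-neighbour graph over the
#' rows of `x` (Euclidean metric), form the chosen graph Laplacian, embed
#' the rows in the `k` smallest eigenvectors, and k-means the embedding.
#' Defaults follow standard practice for expression-profile clustering:
#' 3-nearest-neighbour weak (union-symmetrized) graph, symmetric
#' normalized Laplacian with row-normalized embedding, k-means best of 25
#' restarts. Quality sums of squares are reported in the original feature
#' space.
#'
#' @param x numeric matrix, rows = objects to cluster (typically TFs over
#'   the selected attributes).
#' @param k number of clusters (and embedding dimensions).
#' @param k_nn neighbours per node for the graph (default 3).
#' @param graph_mode `"weak"` or `"mutual"` symmetrization.
#' @param laplacian `"sym"`, `"rw"`, `"l"` or `"lw"` (see
#'   [build_laplacian()]).
#' @param weighting,sigma edge weighting, see [build_knn_graph()].
#' @param include_trivial keep the first (trivial) eigenvector in the
#'   embedding (default) or drop it and use the next `k`.
#' @param n_restarts k-means restarts.
#' @param polish final Lloyd refinement of the labels in the original
#'   feature space (see [kmeans_cluster()]); default on.
#' @param seed optional RNG seed (k-means initialization stream).
#' @return object of class `"clustering_result"` with fields `partition`
#'   (a [partition()]), `k`, `per_cluster_wss`, `total_wss`, `tss`,
#'   `bss_ratio`, `feature_space_ids`, `embedding`, `graph` and `call`.
#' @examples
#' sim <- generate_expression(synthetic_spec(seed = 7))
#' xs <- impute_missing(sim$expression)
#' fit <- spectral_cluster(xs, k = 4, seed = 7)
#' fit
#' adjusted_rand_index(fit$partition, sim$truth)
#' @export
spectral_cluster <- function(x, k, k_nn = 3L, graph_mode = c("weak", "mutual"),
                             laplacian = c("sym", "rw", "l", "lw"),
                             weighting = c("binary", "gaussian"), sigma = NULL,
                             include_trivial = TRUE, n_restarts = 25L,
                             polish = TRUE, seed = NULL) {
  graph_mode <- match.arg(graph_mode)
  laplacian <- match.arg(laplacian)
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains missing values; impute first")
  g <- build_knn_graph(x, k_nn = k_nn, mode = graph_mode,
                       weighting = weighting, sigma = sigma)
  lap <- build_laplacian(g, variant = laplacian)
  emb <- spectral_embed(lap, k = min(k, g$n - 1L),
                        include_trivial = include_trivial)
  res <- kmeans_cluster(emb, k, x, n_restarts = n_restarts, polish = polish,
                        seed = seed)
  res$graph <- g
  res$call <- match.call()
  res
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Spectral clustering: %d objects in %d clusters\n",
              length(x$partition$ids), x$k))
  cat(sprintf("  total WSS %.4g, TSS %.4g, BSS/TSS %.1f%%\n",
              x$total_wss, x$tss, 100 * x$bss_ratio))
  invisible(x)
}

#' @export
summary.clustering_result <- function(object, ...) {
  sizes <- table(object$partition$labels)
  tab <- data.frame(cluster = names(object$per_cluster_wss),
                    n = as.integer(sizes[names(object$per_cluster_wss)]),
                    wss = unname(object$per_cluster_wss))
  structure(list(k = object$k, table = tab, total_wss = object$total_wss,
                 tss = object$tss, bss_ratio = object$bss_ratio),
            class = "summary.clustering_result")
}

#' @export
print.summary.clustering_result <- function(x, ...) {
  cat(sprintf("Spectral clustering, k = %d; BSS/TSS = %.1f%%\n",
              x$k, 100 * x$bss_ratio))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("total WSS %.4g of TSS %.4g\n", x$total_wss, x$tss))
  invisible(x)
}

#' @export
plot.clustering_result <- function(x, dims = NULL, ...) {
  emb <- x$embedding$vectors
  if (is.null(dims))
    dims <- if (ncol(emb) >= 3L && x$embedding$include_trivial) 2:3
            else seq_len(min(2L, ncol(emb)))
  if (length(dims) == 1L) dims <- c(dims, dims)
  cl <- as.integer(factor(x$partition$labels))
  graphics::plot(emb[, dims[1L]], emb[, dims[2L]], col = cl, pch = 19,
                 xlab = paste("eigenvector", dims[1L]),
                 ylab = paste("eigenvector", dims[2L]),
                 main = sprintf("spectral embedding, k = %d", x$k), ...)
  invisible(x)
}

#' Cluster labels of a clustering result
#'
#' @param fit a `"clustering_result"`.
#' @return named character vector of labels (names = object ids).
#' @export
cluster_labels <- function(fit) {
  stopifnot(inherits(fit, "clustering_result"))
  fit$partition$labels
}
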