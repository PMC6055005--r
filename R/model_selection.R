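#' Total within-sum-of-squares curve over a range of cluster counts
#'
#' Runs the full spectral pipeline once per candidate k (the embedding is
#' recomputed with k eigenvectors each time) and records the total WSS in
#' the original feature space. The graph and Laplacian are shared across
#' k.
#'
#' @param x feature matrix (rows = objects).
#' @param k_min,k_max candidate range (defaults 2 and 90, capped at
#'   `nrow(x) - 1`).
#' @param seed RNG seed; each k draws from an independent substream so
#'   changing the range does not perturb other k's.
#' @inheritParams spectral_cluster
#' @return `"wss_curve"`: data.frame with columns `k`, `total_wss`,
#'   `bss_ratio`.
#' @export
wss_curve <- function(x, k_min = 2L, k_max = 90L, k_nn = 3L,
                      graph_mode = "weak", laplacian = "sym",
                      include_trivial = TRUE, n_restarts = 25L,
                      polish = TRUE, seed = NULL) {
  x <- as.matrix(x)
  k_max <- min(as.integer(k_max), nrow(x) - 1L)
  k_min <- as.integer(k_min)
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max < n")
  g <- build_knn_graph(x, k_nn = k_nn, mode = graph_mode)
  lap <- build_laplacian(g, variant = laplacian)
  ks <- k_min:k_max
  out <- lapply(seq_along(ks), function(i) {
    k <- ks[[i]]
    emb <- spectral_embed(lap, k = k, include_trivial = include_trivial)
    res <- kmeans_cluster(emb, k, x, n_restarts = n_restarts, polish = polish,
                          seed = if (is.null(seed)) NULL else seed + i)
    data.frame(k = k, total_wss = res$total_wss, bss_ratio = res$bss_ratio)
  })
  structure(do.call(rbind, out), class = c("wss_curve", "data.frame"))
}

#' @export
plot.wss_curve <- function(x, ...) {
  graphics::plot(x$k, x$total_wss, type = "b", pch = 19,
                 xlab = "number of clusters k", ylab = "total WSS", ...)
  invisible(x)
}

#' Select cluster counts at the major descents of a WSS curve
#'
#' The descent at k is `delta(k) = WSS(k-1) - WSS(k)`. A descent is
#' "major" when it exceeds the robust outlier bound
#' `median(delta) + c * MAD(delta)`; consecutive major descents form a
#' run, and each run is reported by its terminal k — the last cluster
#' count whose gain is still outlier-large, i.e. where the descent
#' completes and the curve flattens. Selected k are returned in ascending
#' order. A smooth (e.g. geometric) decay has no outlier descent and
#' yields an empty selection with a warning. Deterministic: the same
#' curve always gives the same answer.
#'
#' @param curve a `"wss_curve"` (or data.frame with columns `k`,
#'   `total_wss`), at least 3 points.
#' @param n_descents maximum number of k values returned.
#' @param c MAD multiplier of the descent-size rule.
#' @return integer vector of selected k (possibly empty).
#' @export
select_k <- function(curve, n_descents = 2L, c = 2) {
  if (nrow(curve) < 3L) stop("curve must contain at least 3 points")
  ord <- order(curve$k)
  ks <- curve$k[ord]
  wss <- curve$total_wss[ord]
  delta <- -diff(wss)                       # descent at ks[-1]
  dk <- ks[-1L]
  thr <- stats::median(delta) + c * stats::mad(delta)
  above <- delta > thr
  run_end <- above & !c(above[-1L], FALSE)   # last k of each major-descent run
  sel <- dk[run_end]
  if (!length(sel)) {
    warning("no descent exceeds the median + ", c, "*MAD rule; no k selected")
    return(integer(0))
  }
  utils::head(sort(sel), n_descents)
}

#' Stability of a spectral clustering over random k-means restarts
#'
#' Repeats the k-means stage `n_trials` times on a fixed graph and
#' embedding, varying only the initialization stream, and summarizes the
#' spread of the solutions: the coefficient of variation of the total WSS
#' (in percent) and the mean pairwise adjusted Rand index of the label
#' vectors.
#'
#' @inheritParams spectral_cluster
#' @param k number of clusters.
#' @param n_trials number of repeated runs (>= 2).
#' @param seed master seed; trial t uses `seed + t`.
#' @param n_restarts k-means restarts per trial; each trial keeps the best
#'   of its own restarts, so the report measures the spread of converged
#'   solutions, not of raw initializations.
#' @return `"stability_report"`: list with `n_trials`,
#'   `per_trial_total_wss`, `cv_percent`, `mean_pairwise_ari`, `k`.
#' @export
stability_trials <- function(x, k, n_trials = 500L, k_nn = 3L,
                             graph_mode = "weak", laplacian = "sym",
                             include_trivial = TRUE, n_restarts = 25L,
                             polish = TRUE, seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L) stop("n_trials must be at least 2")
  x <- as.matrix(x)
  g <- build_knn_graph(x, k_nn = k_nn, mode = graph_mode)
  lap <- build_laplacian(g, variant = laplacian)
  emb <- spectral_embed(lap, k = min(k, g$n - 1L),
                        include_trivial = include_trivial)
  wss <- numeric(n_trials)
  labs <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    res <- kmeans_cluster(emb, k, x, n_restarts = n_restarts, polish = polish,
                          seed = seed + t)
    wss[t] <- res$total_wss
    labs[[t]] <- res$partition$labels
  }
  mu <- mean(wss)
  cv <- if (mu == 0) 0 else 100 * stats::sd(wss) / mu
  pairs_ari <- numeric(choose(n_trials, 2))
  idx <- 0L
  for (i in seq_len(n_trials - 1L))
    for (j in (i + 1L):n_trials) {
      idx <- idx + 1L
      pairs_ari[idx] <- adjusted_rand_index(labs[[i]], labs[[j]])
    }
  structure(list(n_trials = n_trials, per_trial_total_wss = wss,
                 cv_percent = cv, mean_pairwise_ari = mean(pairs_ari),
                 k = k),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("Stability over %d trials (k = %d): ",
                     "CV of total WSS = %.3g%%, mean pairwise ARI = %.3f\n"),
              x$n_trials, x$k, x$cv_percent, x$mean_pairwise_ari))
  invisible(x)
}
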