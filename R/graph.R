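#' Build a k-nearest-neighbour similarity graph
#'
#' Directed kNN lists under the Euclidean metric, symmetrized by union
#' ("weak": an edge if either endpoint lists the other) or intersection
#' ("mutual": both must). Ties in neighbour ranking are broken by row
#' order. Weights are binary by default, or Gaussian
#' `w_ij = exp(-d_ij^2 / (2 sigma^2))` on retained edges.
#'
#' @param x numeric matrix, rows = objects, columns = features (typically
#'   the selected attributes).
#' @param k_nn neighbours per node; must be `< nrow(x)`.
#' @param mode `"weak"` (union, the default) or `"mutual"` (intersection).
#' @param weighting `"binary"` or `"gaussian"`.
#' @param sigma bandwidth for Gaussian weighting; defaults to the median
#'   retained-edge distance.
#' @return `"neighbor_graph"`: list with `n`, `k_nn`, `mode`, `adjacency`
#'   (symmetric binary, zero diagonal), `weights` (symmetric, support in
#'   the adjacency), `degrees` (row sums of weights) and `ids`.
#' @export
build_knn_graph <- function(x, k_nn = 3L, mode = c("weak", "mutual"),
                            weighting = c("binary", "gaussian"),
                            sigma = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  n <- nrow(x)
  k_nn <- as.integer(k_nn)
  if (k_nn < 1L) stop("k_nn must be positive")
  if (k_nn >= n) stop("k_nn must be smaller than the number of rows (", n, ")")
  d <- as.matrix(stats::dist(x))
  nbr <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])                 # stable: ties by row order
    idx <- seq_len(n)[-i][ord[seq_len(k_nn)]]
    nbr[i, idx] <- TRUE
  }
  a <- if (mode == "weak") nbr | t(nbr) else nbr & t(nbr)
  diag(a) <- FALSE
  adjacency <- a * 1
  if (weighting == "gaussian") {
    ed <- d[a]
    if (is.null(sigma)) sigma <- stats::median(ed)
    if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
    weights <- exp(-d^2 / (2 * sigma^2)) * adjacency
  } else {
    weights <- adjacency
  }
  ids <- rownames(x)
  if (!is.null(ids)) dimnames(adjacency) <- dimnames(weights) <- list(ids, ids)
  structure(list(n = n, k_nn = k_nn, mode = mode, adjacency = adjacency,
                 weights = weights, degrees = rowSums(weights), ids = ids),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("%s %dNN graph on %d nodes: %d undirected edges, components: %d\n",
              x$mode, x$k_nn, x$n, sum(x$adjacency) / 2,
              n_components(x$adjacency)))
  invisible(x)
}

# connected components of a symmetric adjacency by breadth-first search
n_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(a[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}

#' Build a graph Laplacian
#'
#' Variants: `"l"` the unnormalized Laplacian D - A on the binary
#' adjacency; `"lw"` the weighted Laplacian D - W; `"rw"` the random-walk
#' normalized Laplacian I - D^-1 W; `"sym"` (default) the symmetric
#' normalized Laplacian D^-1/2 (D - W) D^-1/2. Degrees are taken from the
#' matrix the variant operates on (A for `"l"`, W otherwise). Normalized
#' variants require every node to have positive degree.
#'
#' @param g a `"neighbor_graph"`.
#' @param variant one of `"sym"`, `"rw"`, `"l"`, `"lw"`.
#' @return `"laplacian"`: list with `matrix`, `variant`, `degrees`, `n`,
#'   `ids`.
#' @export
build_laplacian <- function(g, variant = c("sym", "rw", "l", "lw")) {
  stopifnot(inherits(g, "neighbor_graph"))
  variant <- match.arg(variant)
  w <- if (variant == "l") g$adjacency else g$weights
  deg <- rowSums(w)
  if (variant %in% c("rw", "sym") && any(deg == 0)) {
    iso <- which(deg == 0)
    stop("isolated node(s) incompatible with a normalized Laplacian: ",
         paste(if (is.null(g$ids)) iso else g$ids[iso], collapse = ", "))
  }
  lm <- switch(variant,
    l   = diag(deg) - w,
    lw  = diag(deg) - w,
    rw  = diag(g$n) - sweep(w, 1L, deg, `/`),
    sym = {
      dih <- 1 / sqrt(deg)
      diag(g$n) - (dih * w) %*% diag(dih)    # D^-1/2 (D - W) D^-1/2
    })
  if (!is.null(g$ids)) dimnames(lm) <- list(g$ids, g$ids)
  structure(list(matrix = lm, variant = variant, degrees = deg, n = g$n,
                 ids = g$ids), class = "laplacian")
}

#' Spectral embedding from a Laplacian
#'
#' Eigenvectors of the `k` smallest eigenvalues. By default the trivial
#' first eigenvector (eigenvalue ~0 on a connected graph) is included and,
#' for the symmetric normalized variant, embedding rows are normalized to
#' unit length (the standard normalized-spectral-clustering practice);
#' `include_trivial = FALSE` drops the first eigenvector and takes the
#' next `k`. Random-walk eigenvectors are computed from the symmetric
#' variant via u = D^-1/2 v, which shares its eigenvalues.
#'
#' @param lap a `"laplacian"`.
#' @param k number of embedding coordinates, `k < n`.
#' @param include_trivial include the first (smallest-eigenvalue)
#'   eigenvector.
#' @param row_normalize normalize embedding rows to unit length; default
#'   on for the `"sym"` variant, off otherwise.
#' @return `"spectral_embedding"`: `eigenvalues` (all n, ascending),
#'   `vectors` (n x k), `k`, `include_trivial`, `row_normalized`, `ids`.
#' @export
spectral_embed <- function(lap, k, include_trivial = TRUE,
                           row_normalize = identical(lap$variant, "sym")) {
  stopifnot(inherits(lap, "laplacian"))
  k <- as.integer(k)
  if (k < 1L || k >= lap$n) stop("k must satisfy 1 <= k < n")
  if (!include_trivial && k + 1L > lap$n)
    stop("k + 1 eigenvectors unavailable with include_trivial = FALSE")
  if (lap$variant == "rw") {
    # recover W from L_rw = I - D^-1 W, then form the symmetric equivalent
    w <- (diag(lap$n) - lap$matrix) * lap$degrees  # row-scale back: D (D^-1 W)
    dih <- 1 / sqrt(lap$degrees)
    m <- diag(lap$n) - (dih * w) %*% diag(dih)
    eig <- eigen(m, symmetric = TRUE)
    vecs <- dih * eig$vectors                     # u = D^-1/2 v
  } else {
    eig <- eigen(lap$matrix, symmetric = TRUE)
    vecs <- eig$vectors
  }
  values <- rev(eig$values)                       # ascending
  vecs <- vecs[, rev(seq_len(lap$n)), drop = FALSE]
  take <- if (include_trivial) seq_len(k) else seq_len(k) + 1L
  emb <- vecs[, take, drop = FALSE]
  if (row_normalize) {
    nrm <- sqrt(rowSums(emb^2))
    zero <- nrm < 1e-12
    if (any(zero))
      stop("all-zero embedding row(s) cannot be normalized: ",
           paste(if (is.null(lap$ids)) which(zero) else lap$ids[zero],
                 collapse = ", "))
    emb <- emb / nrm
  }
  rownames(emb) <- lap$ids
  structure(list(eigenvalues = values, vectors = emb, k = k,
                 include_trivial = include_trivial,
                 row_normalized = row_normalize, ids = lap$ids),
            class = "spectral_embedding")
}
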