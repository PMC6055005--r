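#' Specification of a synthetic expression benchmark
#'
#' Defines a TF-by-condition matrix with planted row clusters: informative
#' conditions carry cluster-specific centroids, noise conditions are pure
#' Gaussian, and duplicate blocks repeat one informative condition with
#' tiny jitter (within-block correlations > 0.9 by construction, so the
#' decorrelation step of attribute selection has something to do). Cluster
#' centroids sit on scaled coordinate axes of the informative subspace so
#' that every pair of centroids is exactly `separation` apart, making
#' `separation` (in units of `noise_sd`) the single difficulty knob.
#'
#' Defaults are the benchmark conditions used throughout the package's
#' validation: 120 TFs in 4 clusters at separation 6, unit noise, 5%
#' missing values.
#'
#' @param n_rows number of TFs.
#' @param n_clusters planted number of clusters.
#' @param n_informative_cols conditions carrying cluster signal (must be
#'   at least `n_clusters`).
#' @param n_noise_cols uninformative pure-noise conditions.
#' @param n_duplicate_blocks groups of near-identical columns; each block
#'   repeats one informative column `dup_block_size` times with jitter
#'   sd `noise_sd/100`.
#' @param dup_block_size copies per duplicate block.
#' @param separation pairwise distance between cluster centroids, in units
#'   of `noise_sd`.
#' @param noise_sd within-cluster standard deviation.
#' @param missing_rate fraction of entries masked `NA`, in \[0, 1).
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_rows = 120L, n_clusters = 4L,
                           n_informative_cols = 10L, n_noise_cols = 20L,
                           n_duplicate_blocks = 3L, dup_block_size = 3L,
                           separation = 6, noise_sd = 1,
                           missing_rate = 0.05, seed = 1L) {
  spec <- list(n_rows = as.integer(n_rows), n_clusters = as.integer(n_clusters),
               n_informative_cols = as.integer(n_informative_cols),
               n_noise_cols = as.integer(n_noise_cols),
               n_duplicate_blocks = as.integer(n_duplicate_blocks),
               dup_block_size = as.integer(dup_block_size),
               separation = separation, noise_sd = noise_sd,
               missing_rate = missing_rate, seed = as.integer(seed))
  if (spec$n_rows < 1L || spec$n_informative_cols < 1L)
    stop("n_rows and n_informative_cols must be positive")
  if (spec$n_clusters > spec$n_rows)
    stop("n_clusters cannot exceed n_rows")
  if (spec$n_clusters > spec$n_informative_cols)
    stop("need n_informative_cols >= n_clusters for axis-aligned centroids")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (spec$separation < 0) stop("separation must be >= 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$n_duplicate_blocks > spec$n_informative_cols)
    stop("cannot duplicate more blocks than informative columns")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with planted clusters
#'
#' Row i in planted cluster c gets, on the informative columns, the
#' cluster-c centroid plus Gaussian(0, `noise_sd`) noise; noise columns
#' are Gaussian(0, `noise_sd`); each duplicate block repeats one
#' informative column with jitter sd `noise_sd`/100; finally a fraction
#' `missing_rate` of entries is masked uniformly at random.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expression` (matrix, rows `tf001`..., columns
#'   `inf01`..., `dup01_1`..., `noise01`...) and `truth` (the planted
#'   `"partition"`, labels `"1"`..`"k"`).
#' @export
generate_expression <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_rows; k <- spec$n_clusters
  p_inf <- spec$n_informative_cols
  # centroids on scaled axes: |s*e_i - s*e_j| = s*sqrt(2) = separation*noise_sd
  scale_ <- spec$separation * spec$noise_sd / sqrt(2)
  centroids <- diag(k) * scale_                       # k x k, padded below
  centroids <- cbind(centroids, matrix(0, k, p_inf - k))
  labels <- rep_len(seq_len(k), n)                    # balanced clusters
  inf <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * p_inf, sd = spec$noise_sd), n, p_inf)
  colnames(inf) <- sprintf("inf%02d", seq_len(p_inf))
  dup <- NULL
  if (spec$n_duplicate_blocks > 0L) {
    src <- seq_len(spec$n_duplicate_blocks)           # first informative cols
    dup <- do.call(cbind, lapply(src, function(j) {
      block <- replicate(spec$dup_block_size,
                         inf[, j] + stats::rnorm(n, sd = spec$noise_sd / 100))
      colnames(block) <- sprintf("dup%02d_%d", j, seq_len(spec$dup_block_size))
      block
    }))
  }
  noise <- NULL
  if (spec$n_noise_cols > 0L) {
    noise <- matrix(stats::rnorm(n * spec$n_noise_cols, sd = spec$noise_sd),
                    n, spec$n_noise_cols)
    colnames(noise) <- sprintf("noise%02d", seq_len(spec$n_noise_cols))
  }
  x <- cbind(inf, dup, noise)
  rownames(x) <- sprintf("tf%03d", seq_len(n))
  if (spec$missing_rate > 0) {
    mask <- which(stats::runif(length(x)) < spec$missing_rate)
    x[mask] <- NA_real_
  }
  validate_expression(x)
  list(expression = x,
       truth = partition(rownames(x), as.character(labels)))
}

#' Generate an annotation catalog with planted enrichments
#'
#' Each planted cluster gets one signature functional category: target
#' genes of that cluster's TFs carry the signature with probability
#' `enrichment_strength` and every non-signature category at rate
#' `background_rate`. Each cluster likewise has one overrepresented TF
#' family (probability `family_bias`, other families uniform) and one
#' biased regulatory mode (cycled over activator/repressor/dual).
#' Evidence classes are sampled to mimic a realistically mixed catalog
#' (40% strong, 25% weak, 35% hypothetical); enrichment only uses
#' strong/weak TFs' targets, as for real regulons.
#'
#' @param truth planted `"partition"` of TFs.
#' @param n_targets_per_tf target genes per TF (genes are TF-specific, so
#'   regulons do not overlap).
#' @param n_categories number of functional categories (must be at least
#'   the number of clusters; the first `k` are the signatures).
#' @param enrichment_strength probability a cluster-c target gene carries
#'   cluster c's signature category; must exceed `background_rate`.
#' @param background_rate probability a gene carries any given
#'   non-signature category.
#' @param n_families number of TF families (>= number of clusters).
#' @param family_bias probability a TF is assigned its cluster's family.
#' @param mode_bias probability an interaction takes its cluster's
#'   preferred regulatory mode.
#' @param seed RNG seed.
#' @return list with `catalog` (an `"annotation_catalog"` whose
#'   gene-category scheme is named `"synthetic"`), and the planted truth:
#'   `signature_categories`, `signature_families`, `signature_modes`
#'   (each named by cluster label).
#' @export
generate_annotations <- function(truth, n_targets_per_tf = 5L,
                                 n_categories = 8L,
                                 enrichment_strength = 0.8,
                                 background_rate = 0.05,
                                 n_families = NULL, family_bias = 0.7,
                                 mode_bias = 0.7, seed = 1L) {
  stopifnot(inherits(truth, "partition"))
  k <- truth$k
  clusters <- sort(unique(unname(truth$labels)))
  if (n_categories < k) stop("n_categories must be >= number of clusters")
  if (enrichment_strength <= background_rate)
    stop("enrichment_strength must exceed background_rate")
  if (is.null(n_families)) n_families <- max(k, 4L)
  if (n_families < k) stop("n_families must be >= number of clusters")
  set.seed(seed)
  tfs <- truth$ids
  cats <- sprintf("cat%02d", seq_len(n_categories))
  fams <- sprintf("fam%02d", seq_len(n_families))
  sig_cat <- stats::setNames(cats[seq_len(k)], clusters)
  sig_fam <- stats::setNames(fams[seq_len(k)], clusters)
  sig_mode <- stats::setNames(REGULATORY_MODES[(seq_len(k) - 1L) %% 3L + 1L],
                              clusters)
  ev <- sample(EVIDENCE_CLASSES, length(tfs), replace = TRUE,
               prob = c(0.40, 0.25, 0.35))
  names(ev) <- tfs
  fam <- character(length(tfs)); names(fam) <- tfs
  rows <- vector("list", length(tfs))
  gene_cat <- vector("list", length(tfs))
  for (i in seq_along(tfs)) {
    cl <- unname(truth$labels[[tfs[i]]])
    fam[i] <- if (stats::runif(1) < family_bias) sig_fam[[cl]]
              else sample(setdiff(fams, sig_fam[[cl]]), 1L)
    genes <- sprintf("%s_g%02d", tfs[i], seq_len(n_targets_per_tf))
    pref <- sig_mode[[cl]]
    modes <- ifelse(stats::runif(n_targets_per_tf) < mode_bias, pref,
                    sample(REGULATORY_MODES, n_targets_per_tf, replace = TRUE))
    rows[[i]] <- data.frame(tf = tfs[i], gene = genes, mode = modes)
    carries_sig <- stats::runif(n_targets_per_tf) < enrichment_strength
    bg <- matrix(stats::runif(n_targets_per_tf * n_categories) < background_rate,
                 n_targets_per_tf, n_categories)
    bg[, match(sig_cat[[cl]], cats)] <- carries_sig
    hit <- which(bg, arr.ind = TRUE)
    gene_cat[[i]] <- if (nrow(hit))
      data.frame(gene = genes[hit[, 1L]], category = cats[hit[, 2L]])
    else NULL
  }
  catalog <- annotation_catalog(
    tf_targets = do.call(rbind, rows),
    tf_family = fam, tf_evidence = ev,
    gene_categories = list(synthetic = do.call(rbind, gene_cat)))
  list(catalog = catalog, signature_categories = sig_cat,
       signature_families = sig_fam, signature_modes = sig_mode)
}
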