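#' Principal component analysis of an expression matrix
#'
#' Thin wrapper around [stats::prcomp()] producing a `"pca_model"` with a
#' reproducible sign convention (the largest-magnitude coordinate of each
#' loading vector is positive, so results do not depend on the
#' eigen-solver's arbitrary signs). Rows are the objects (TFs), columns
#' the attributes (conditions); each principal component is a linear
#' combination of all conditions.
#'
#' @param x complete expression matrix (impute first; see
#'   [impute_missing()]), at least 2 rows and 2 columns.
#' @param center,scale. center (default on) and/or scale (default off)
#'   columns before decomposition.
#' @return `"pca_model"`: list with `col_means`, `col_scales`, `loadings`
#'   (conditions x components, orthonormal), `sdev` (component standard
#'   deviations, non-increasing), `scores` (rows x components) and `ids`.
#' @export
fit_pca <- function(x, center = TRUE, scale. = FALSE) {
  validate_expression(x)
  if (anyNA(x)) stop("expression matrix contains missing values; impute first")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 rows and 2 columns")
  if (scale.) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance column(s) with scale = TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(x, center = center, scale. = scale.)
  # sign convention: largest-|.| loading coordinate positive
  flip <- apply(pr$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pr$rotation <- sweep(pr$rotation, 2L, flip, `*`)
  pr$x <- sweep(pr$x, 2L, flip, `*`)
  structure(list(
    col_means = if (isTRUE(center) || is.numeric(center)) pr$center else rep(0, ncol(x)),
    col_scales = if (scale.) pr$scale else rep(1, ncol(x)),
    loadings = pr$rotation, sdev = pr$sdev, scores = pr$x,
    ids = rownames(x)), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cv <- cumulative_variance(x)
  cat(sprintf("PCA model: %d objects, %d attributes, %d components\n",
              nrow(x$scores), nrow(x$loadings), length(x$sdev)))
  m65 <- which(cv >= 0.65)[1L]
  cat(sprintf("  %d component(s) reach 65%% cumulative variance\n", m65))
  invisible(x)
}

#' Cumulative explained-variance ratios
#'
#' @param model a `"pca_model"`.
#' @return non-decreasing numeric vector in (0, 1\]; the last entry is 1
#'   at full rank.
#' @export
cumulative_variance <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  v <- model$sdev^2
  cumsum(v) / sum(v)
}

#' Components needed to reach a cumulative-variance goal
#'
#' @param model a `"pca_model"`.
#' @param goal cumulative explained-variance ratio in (0, 1].
#' @return smallest component count whose cumulative ratio >= `goal`.
#' @export
components_for_variance <- function(model, goal = 0.65) {
  stopifnot(goal > 0, goal <= 1)
  unname(which(cumulative_variance(model) >= goal - 1e-12)[1L])
}

#' Projections of original attributes over leading components
#'
#' Entry (j, i) is attribute j's loading on component i scaled by that
#' component's standard deviation — i.e. the covariance between attribute
#' j (centered/scaled as fitted) and the unit-variance score of component
#' i. Attributes with similar projection vectors carry redundant
#' information.
#'
#' @param model a `"pca_model"`.
#' @param m number of leading components, `1 <= m <=` available rank.
#' @return attributes x `m` matrix with attribute rownames.
#' @export
attribute_projections <- function(model, m) {
  stopifnot(inherits(model, "pca_model"))
  m <- as.integer(m)
  if (m < 1L || m > length(model$sdev))
    stop("m must lie between 1 and the number of available components (",
         length(model$sdev), ")")
  proj <- sweep(model$loadings[, seq_len(m), drop = FALSE], 2L,
                model$sdev[seq_len(m)], `*`)
  rownames(proj) <- rownames(model$loadings)
  proj
}

#' Select informative, decorrelated attributes
#'
#' Two-step rule over the projection matrix of
#' [attribute_projections()]. Step 1: candidates are the attributes whose
#' maximum absolute projection over the m components is at least
#' `tau_candidate`. Step 2 (decorrelation): candidates are visited in
#' descending order of that maximum (ties by column order) and admitted
#' iff the absolute Pearson correlation of their projection vector with
#' every already-admitted attribute is below `tau_decorrelate` — one
#' representative per block of correlated attributes, favouring the most
#' informative.
#'
#' @param projections attributes x m projection matrix (rownames
#'   required), from [attribute_projections()].
#' @param tau_candidate projection-magnitude threshold in (0, 1].
#' @param tau_decorrelate pairwise-correlation ceiling in (0, 1].
#' @return `"attribute_selection"`: list with `m`, the thresholds,
#'   `projection_matrix`, `candidate_ids`, `selected_ids`.
#' @export
select_attributes <- function(projections, tau_candidate = 0.15,
                              tau_decorrelate = 0.9) {
  if (is.null(rownames(projections))) stop("projections must have rownames")
  if (tau_candidate <= 0 || tau_candidate > 1 ||
      tau_decorrelate <= 0 || tau_decorrelate > 1)
    stop("thresholds must lie in (0, 1]")
  maxabs <- apply(abs(projections), 1L, max)
  cand <- which(maxabs >= tau_candidate)
  if (!length(cand))
    stop("no attribute reaches tau_candidate = ", tau_candidate,
         "; lower the threshold")
  ord <- cand[order(-maxabs[cand])]            # order() is stable: ties by input order
  selected <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (s in selected) {
      if (abs(proj_cor(projections[j, ], projections[s, ])) >= tau_decorrelate) {
        ok <- FALSE; break
      }
    }
    if (ok) selected <- c(selected, j)
  }
  selected <- selected[order(selected)]        # report in column order
  structure(list(m = ncol(projections),
                 tau_candidate = tau_candidate,
                 tau_decorrelate = tau_decorrelate,
                 projection_matrix = projections,
                 candidate_ids = rownames(projections)[sort(cand)],
                 selected_ids = rownames(projections)[selected]),
            class = "attribute_selection")
}

# Pearson correlation of two projection vectors; a zero-variance vector
# cannot witness a correlated block, so its correlation is defined as 0.
proj_cor <- function(u, v) {
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  stats::cor(u, v)
}

#' @export
print.attribute_selection <- function(x, ...) {
  cat(sprintf(paste0("Attribute selection over %d components: %d candidates",
                     " (max |projection| >= %g), %d selected",
                     " (pairwise |cor| < %g)\n"),
              x$m, length(x$candidate_ids), x$tau_candidate,
              length(x$selected_ids), x$tau_decorrelate))
  cat("  selected:", paste(x$selected_ids, collapse = ", "), "\n")
  invisible(x)
}
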