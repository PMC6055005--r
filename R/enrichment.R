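#' One-tailed Fisher exact test on a 2x2 table
#'
#' Upper-tail hypergeometric probability `P(X >= a)` with all margins
#' fixed: the chance of an overlap at least as large as the observed one.
#' Summation is done in log space (log-binomial coefficients combined by
#' log-sum-exp) so tables with counts in the thousands stay accurate.
#'
#' @param a in-cluster AND in-category count.
#' @param b in-cluster, not in-category.
#' @param c in-category, not in-cluster.
#' @param d neither.
#' @return the one-tailed p-value in (0, 1].
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all-zero contingency table")
  m1 <- a + b                                 # cluster margin
  m2 <- a + c                                 # category margin
  xs <- max(0L, m1 + m2 - n):min(m1, m2)      # support of X
  tail <- xs[xs >= a]
  if (!length(tail)) return(1)
  lp <- lchoose(m2, tail) + lchoose(n - m2, m1 - tail) - lchoose(n, m1)
  mx <- max(lp)
  p <- exp(mx + log(sum(exp(lp - mx))))
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-controlling adjusted p-values: order-preserving, never
#' smaller than the raw value, capped at 1, idempotent.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# assemble one enrichment row
enr_row <- function(cluster, scheme, category, a, b, c, d) {
  data.frame(cluster = as.character(cluster), scheme = scheme,
             category = category, a = a, b = b, c = c, d = d,
             p_raw = fisher_one_tailed(a, b, c, d),
             p_adj = NA_real_, significant = NA)
}

# finalize: BH within the table, flag significance, sort by p_adj
finish_enrichment <- function(rows, alpha) {
  if (!length(rows)) {
    out <- data.frame(cluster = character(0), scheme = character(0),
                      category = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
    return(structure(out, class = c("enrichment_result", "data.frame"),
                     alpha = alpha))
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$significant <- tab$p_adj < alpha
  tab <- tab[order(tab$p_adj, tab$p_raw, tab$cluster, tab$category), ]
  rownames(tab) <- NULL
  structure(tab, class = c("enrichment_result", "data.frame"), alpha = alpha)
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("Enrichment: %d tests, %d significant at adjusted p < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  if (nrow(x)) print.data.frame(utils::head(x, n), digits = 4, row.names = FALSE)
  invisible(x)
}

# target-gene set of a cluster: union of the targets of its
# experimentally characterized (strong/weak) TFs
cluster_target_sets <- function(p, catalog, include_hypothetical = FALSE) {
  tt <- catalog$tf_targets
  if (is.null(tt)) stop("catalog has no tf_targets table")
  keep_ev <- if (include_hypothetical) EVIDENCE_CLASSES else c("strong", "weak")
  ev <- catalog$tf_evidence
  lapply(split(p$ids, unname(p$labels)), function(tfs) {
    if (!is.null(ev))
      tfs <- tfs[tfs %in% names(ev)[ev %in% keep_ev]]
    unique(tt$gene[tt$tf %in% tfs])
  })
}

#' Enrichment of target-gene functional categories per cluster
#'
#' For each cluster, the target-gene set is the union of the targets of
#' its experimentally characterized TFs (evidence strong or weak; a gene
#' regulated by several cluster TFs counts once). Each category of the
#' chosen scheme is tested against the universe by a one-tailed Fisher
#' exact test; BH correction is applied across all (cluster, category)
#' tests of the scheme.
#'
#' @param p a `"partition"` of TFs.
#' @param catalog an `"annotation_catalog"` with `tf_targets` and the
#'   scheme present in `gene_categories`.
#' @param scheme name of the category scheme to test.
#' @param universe `"targets_union"` (default; the union of all clusters'
#'   target genes) or `"all_annotated"` (every gene of the scheme).
#' @param alpha significance threshold on the adjusted p-value.
#' @param include_hypothetical also count targets of hypothetical TFs.
#' @return an `"enrichment_result"` data.frame sorted by `p_adj`.
#'   Clusters with no annotated targets are untestable and absent.
#' @export
enrich_cluster_categories <- function(p, catalog, scheme,
                                      universe = c("targets_union", "all_annotated"),
                                      alpha = 0.045,
                                      include_hypothetical = FALSE) {
  stopifnot(inherits(p, "partition"), inherits(catalog, "annotation_catalog"))
  universe <- match.arg(universe)
  if (!scheme %in% names(catalog$gene_categories))
    stop("scheme not in catalog: ", scheme)
  gc <- catalog$gene_categories[[scheme]]
  sets <- cluster_target_sets(p, catalog, include_hypothetical)
  uni <- if (universe == "targets_union") unique(unlist(sets, use.names = FALSE))
         else unique(gc$gene)
  cat_members <- lapply(split(gc$gene, gc$category), function(g)
    intersect(unique(g), uni))
  rows <- list()
  for (cl in names(sets)) {
    gset <- intersect(sets[[cl]], uni)
    if (!length(gset)) next                   # untestable, reported absent
    for (cat_ in names(cat_members)) {
      memb <- cat_members[[cat_]]
      a <- length(intersect(gset, memb))
      b <- length(gset) - a
      c_ <- length(memb) - a
      d <- length(uni) - a - b - c_
      rows[[length(rows) + 1L]] <- enr_row(cl, scheme, cat_, a, b, c_, d)
    }
  }
  finish_enrichment(rows, alpha)
}

#' Enrichment of TF families per cluster
#'
#' Units are TFs, not genes: for every (cluster, family) pair, membership
#' of the cluster is tested against membership of the family among all
#' clustered TFs that carry a family annotation.
#'
#' @inheritParams enrich_cluster_categories
#' @return an `"enrichment_result"` with `scheme = "family"`.
#' @export
enrich_cluster_families <- function(p, catalog, alpha = 0.045) {
  stopifnot(inherits(p, "partition"), inherits(catalog, "annotation_catalog"))
  fam <- catalog$tf_family
  if (is.null(fam)) stop("catalog has no tf_family map")
  tfs <- intersect(p$ids, names(fam))
  if (!length(tfs)) stop("no clustered TF has a family annotation")
  labs <- p$labels[tfs]
  fams <- fam[tfs]
  rows <- list()
  for (cl in sort(unique(unname(labs)))) {
    in_cl <- labs == cl
    for (f in sort(unique(unname(fams)))) {
      in_f <- fams == f
      a <- sum(in_cl & in_f); b <- sum(in_cl & !in_f)
      c_ <- sum(!in_cl & in_f); d <- sum(!in_cl & !in_f)
      rows[[length(rows) + 1L]] <- enr_row(cl, "family", f, a, b, c_, d)
    }
  }
  finish_enrichment(rows, alpha)
}

#' Enrichment of regulatory modes per cluster
#'
#' Counting unit: the (TF, gene, mode) regulatory interaction. For each
#' cluster, every mode (activator / repressor / dual) is tested for
#' overrepresentation among the cluster's interactions relative to all
#' interactions of clustered TFs.
#'
#' @inheritParams enrich_cluster_categories
#' @return an `"enrichment_result"` with `scheme = "mode"`.
#' @export
enrich_regulatory_mode <- function(p, catalog, alpha = 0.045,
                                   include_hypothetical = FALSE) {
  stopifnot(inherits(p, "partition"), inherits(catalog, "annotation_catalog"))
  tt <- catalog$tf_targets
  if (is.null(tt)) stop("catalog has no tf_targets table")
  keep_ev <- if (include_hypothetical) EVIDENCE_CLASSES else c("strong", "weak")
  ev <- catalog$tf_evidence
  keep_tfs <- p$ids
  if (!is.null(ev)) keep_tfs <- keep_tfs[keep_tfs %in% names(ev)[ev %in% keep_ev]]
  tt <- tt[tt$tf %in% keep_tfs, , drop = FALSE]
  if (!nrow(tt)) stop("no interactions left after evidence filtering")
  cl_of <- p$labels[tt$tf]
  rows <- list()
  for (cl in sort(unique(unname(cl_of)))) {
    in_cl <- cl_of == cl
    for (mo in REGULATORY_MODES) {
      in_mo <- tt$mode == mo
      a <- sum(in_cl & in_mo); b <- sum(in_cl & !in_mo)
      c_ <- sum(!in_cl & in_mo); d <- sum(!in_cl & !in_mo)
      rows[[length(rows) + 1L]] <- enr_row(cl, "mode", mo, a, b, c_, d)
    }
  }
  finish_enrichment(rows, alpha)
}

#' Overlap enrichment between two partitions
#'
#' Tests every cluster-of-`p1` x cluster-of-`p2` pair for overlap by a
#' one-tailed Fisher exact test, BH-corrected across all pairs. At
#' `level = "tf"` the items themselves are compared; at
#' `level = "target_gene"` each cluster is first expanded to the union of
#' its experimentally characterized TFs' target genes.
#'
#' @param p1,p2 `"partition"` objects (e.g. this pipeline's clusters and
#'   an external module assignment).
#' @param catalog an `"annotation_catalog"`; required for
#'   `level = "target_gene"`.
#' @param level `"tf"` or `"target_gene"`.
#' @param alpha significance threshold on adjusted p-values.
#' @return an `"enrichment_result"`: `cluster` holds the `p1` label,
#'   `category` the `p2` label.
#' @export
compare_clusterings <- function(p1, p2, catalog = NULL,
                                level = c("tf", "target_gene"),
                                alpha = 0.045) {
  stopifnot(inherits(p1, "partition"), inherits(p2, "partition"))
  level <- match.arg(level)
  if (level == "tf") {
    sets1 <- split(p1$ids, unname(p1$labels))
    sets2 <- split(p2$ids, unname(p2$labels))
  } else {
    if (is.null(catalog)) stop("target_gene level needs an annotation catalog")
    sets1 <- cluster_target_sets(p1, catalog)
    sets2 <- cluster_target_sets(p2, catalog)
  }
  uni <- union(unlist(sets1, use.names = FALSE), unlist(sets2, use.names = FALSE))
  if (!length(intersect(unlist(sets1, use.names = FALSE),
                        unlist(sets2, use.names = FALSE))))
    stop("the two partitions cover disjoint item universes at this level")
  rows <- list()
  for (c1 in names(sets1)) {
    s1 <- sets1[[c1]]
    for (c2 in names(sets2)) {
      s2 <- sets2[[c2]]
      a <- length(intersect(s1, s2))
      b <- length(s1) - a
      c_ <- length(s2) - a
      d <- length(uni) - a - b - c_
      rows[[length(rows) + 1L]] <- enr_row(c1, paste0("overlap_", level), c2,
                                           a, b, c_, d)
    }
  }
  finish_enrichment(rows, alpha)
}
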