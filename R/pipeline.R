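#' Default pipeline configuration
#'
#' A fully resolved list of every tunable of the workflow, validated
#' before any stage runs. Defaults: center (not scale) before PCA, keep
#' enough components for 65% of variance, candidate threshold 0.15,
#' decorrelation ceiling 0.9, 3-nearest-neighbour weak graph, symmetric
#' normalized Laplacian, k scanned over 2..90 with descent-based
#' selection, 25 k-means restarts, 500 stability trials, enrichment at
#' adjusted p < 0.045 against the targets-union universe.
#'
#' @param ... overrides of the defaults (named).
#' @return `"pipeline_config"` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    impute = "row_mean",
    center = TRUE, scale = FALSE,
    m = NULL, variance_goal = 0.65,
    tau_candidate = 0.15, tau_decorrelate = 0.9,
    k_nn = 3L, graph_mode = "weak", laplacian = "sym",
    include_trivial = TRUE,
    k = NULL, k_min = 2L, k_max = 90L, n_descents = 2L,
    n_restarts = 25L, n_trials = 500L,
    schemes = NULL, universe = "targets_union", alpha = 0.045,
    compare_level = "target_gene",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$impute %in% c("row_mean", "zero"),
            cfg$tau_candidate > 0, cfg$tau_candidate <= 1,
            cfg$tau_decorrelate > 0, cfg$tau_decorrelate <= 1,
            cfg$variance_goal > 0, cfg$variance_goal <= 1,
            cfg$k_nn >= 1, cfg$k_min >= 1, cfg$k_max >= cfg$k_min,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_restarts >= 1, cfg$n_trials >= 2)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full clustering-and-enrichment pipeline
#'
#' Orchestrates impute -> PCA -> attribute selection -> WSS scan and k
#' selection (unless `config$k` fixes k) -> final spectral clustering ->
#' stability trials -> enrichment (categories per scheme, families,
#' regulatory modes, optional external-partition overlap), writing every
#' typed product plus a JSON run manifest into `out_dir`. The master seed
#' fans out to fixed per-stage offsets, so changing the trial count does
#' not perturb earlier stages; identical config and seed give identical
#' outputs.
#'
#' @param expression expression matrix or path to an expression TSV.
#' @param catalog optional `"annotation_catalog"` (or NULL to skip
#'   enrichment).
#' @param config a [pipeline_config()].
#' @param external optional second `"partition"` for overlap enrichment.
#' @param out_dir output directory (created); NULL runs in memory only.
#' @return (invisibly) list with `imputed`, `pca`, `cumulative_variance`,
#'   `selection`, `x_selected`, `curve`, `k_candidates`, `k`, `fit`,
#'   `stability`, `enrichment` (list of `"enrichment_result"`s),
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(expression, catalog = NULL,
                         config = pipeline_config(), external = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.character(expression)) expression <- read_expression(expression)
  validate_expression(expression)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  xs <- stage("impute", impute_missing(expression, config$impute))
  model <- stage("pca", fit_pca(xs, center = config$center, scale. = config$scale))
  cv <- cumulative_variance(model)
  m <- if (is.null(config$m)) components_for_variance(model, config$variance_goal)
       else as.integer(config$m)
  proj <- stage("projections", attribute_projections(model, m))
  sel <- stage("select", select_attributes(proj, config$tau_candidate,
                                           config$tau_decorrelate))
  x_sel <- xs[, sel$selected_ids, drop = FALSE]

  if (is.null(config$k)) {
    curve <- stage("wss_curve",
      wss_curve(x_sel, k_min = config$k_min, k_max = config$k_max,
                k_nn = config$k_nn, graph_mode = config$graph_mode,
                laplacian = config$laplacian,
                include_trivial = config$include_trivial,
                n_restarts = config$n_restarts, seed = config$seed + 1000L))
    k_candidates <- stage("select_k", select_k(curve, config$n_descents))
    k <- if (length(k_candidates)) max(k_candidates) else {
      warning("no major WSS descent; falling back to the largest-descent k")
      curve$k[which.max(-diff(curve$total_wss)) + 1L]
    }
  } else {
    curve <- NULL; k_candidates <- integer(0); k <- as.integer(config$k)
  }

  fit <- stage("cluster",
    spectral_cluster(x_sel, k = k, k_nn = config$k_nn,
                     graph_mode = config$graph_mode,
                     laplacian = config$laplacian,
                     include_trivial = config$include_trivial,
                     n_restarts = config$n_restarts,
                     seed = config$seed + 2000L))
  stab <- stage("stability",
    stability_trials(x_sel, k = k, n_trials = config$n_trials,
                     k_nn = config$k_nn, graph_mode = config$graph_mode,
                     laplacian = config$laplacian,
                     include_trivial = config$include_trivial,
                     seed = config$seed + 3000L))

  enr <- list(); comp <- NULL
  if (!is.null(catalog)) {
    schemes <- config$schemes
    if (is.null(schemes)) schemes <- names(catalog$gene_categories)
    for (sc in schemes)
      enr[[sc]] <- stage(paste0("enrich_", sc),
        enrich_cluster_categories(fit$partition, catalog, sc,
                                  universe = config$universe,
                                  alpha = config$alpha))
    if (!is.null(catalog$tf_family))
      enr[["family"]] <- stage("enrich_family",
        enrich_cluster_families(fit$partition, catalog, alpha = config$alpha))
    if (!is.null(catalog$tf_targets))
      enr[["mode"]] <- stage("enrich_mode",
        enrich_regulatory_mode(fit$partition, catalog, alpha = config$alpha))
    if (!is.null(external))
      comp <- stage("compare",
        compare_clusterings(fit$partition, external, catalog,
                            level = config$compare_level,
                            alpha = config$alpha))
  }

  out <- list(imputed = xs, pca = model, cumulative_variance = cv,
              selection = sel, x_selected = x_sel, curve = curve,
              k_candidates = k_candidates, k = k, fit = fit,
              stability = stab, enrichment = enr, comparison = comp)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tfclust")),
    r_version = as.character(getRversion()),
    config = Filter(Negate(is.null), unclass(config)), m = m, k = k,
    n_rows = nrow(expression), n_cols = ncol(expression),
    n_selected = length(sel$selected_ids),
    selected_ids = sel$selected_ids,
    bss_ratio = fit$bss_ratio,
    stability_cv_percent = stab$cv_percent,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_partition(fit$partition, fp("partition.tsv"))
    utils::write.table(
      data.frame(component = seq_along(cv), cumulative_variance = cv),
      fp("pca_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(attribute = sel$selected_ids),
      fp("selected_attributes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(curve))
      utils::write.table(curve, fp("wss_curve.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    writeLines(c("metric\tvalue",
                 sprintf("n_trials\t%d", stab$n_trials),
                 sprintf("cv_percent\t%.6g", stab$cv_percent),
                 sprintf("mean_pairwise_ari\t%.6g", stab$mean_pairwise_ari)),
               fp("stability.tsv"))
    for (nm in names(enr))
      write_results(enr[[nm]], fp(sprintf("enrichment_%s.tsv", nm)))
    if (!is.null(comp)) write_results(comp, fp("comparison.tsv"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$manifest <- manifest
  invisible(out)
}

#' Descriptive summary of a catalog and partition
#'
#' Counts TFs by evidence class, distinct regulated genes (strong/weak
#' evidence), the percentage of a supplied genome gene total they
#' represent (1 decimal), the number of regulatory interactions, and
#' per-cluster sizes.
#'
#' @param catalog an `"annotation_catalog"`.
#' @param p optional `"partition"` for per-cluster sizes.
#' @param genome_total optional total gene count of the genome.
#' @return `"catalog_summary"` list with `tfs_by_evidence`,
#'   `n_regulated_genes`, `pct_of_genome`, `n_interactions`,
#'   `cluster_sizes`.
#' @export
summarize_catalog <- function(catalog, p = NULL, genome_total = NULL) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  ev_tab <- if (!is.null(catalog$tf_evidence))
    table(factor(catalog$tf_evidence, EVIDENCE_CLASSES))
  else table(factor(character(0), EVIDENCE_CLASSES))
  n_genes <- 0L; n_inter <- 0L
  if (!is.null(catalog$tf_targets)) {
    tt <- catalog$tf_targets
    if (!is.null(catalog$tf_evidence)) {
      exp_tfs <- names(catalog$tf_evidence)[catalog$tf_evidence %in% c("strong", "weak")]
      tt <- tt[tt$tf %in% exp_tfs, , drop = FALSE]
    }
    n_genes <- length(unique(tt$gene))
    n_inter <- nrow(tt)
  }
  pct <- if (!is.null(genome_total) && genome_total > 0)
    round(100 * n_genes / genome_total, 1) else NA_real_
  sizes <- if (!is.null(p)) {
    s <- table(unname(p$labels))
    stats::setNames(as.integer(s), names(s))
  } else integer(0)
  structure(list(tfs_by_evidence = ev_tab, n_regulated_genes = n_genes,
                 pct_of_genome = pct, n_interactions = n_inter,
                 cluster_sizes = sizes),
            class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Catalog summary\n")
  ev <- x$tfs_by_evidence
  cat(sprintf("  TFs by evidence: %s\n",
              paste(sprintf("%s=%d", names(ev), ev), collapse = ", ")))
  cat(sprintf("  distinct regulated genes (strong/weak): %d", x$n_regulated_genes))
  if (!is.na(x$pct_of_genome)) cat(sprintf(" (%.1f%% of genome)", x$pct_of_genome))
  cat(sprintf("\n  regulatory interactions: %d\n", x$n_interactions))
  if (length(x$cluster_sizes))
    cat("  cluster sizes:",
        paste(sprintf("%s=%d", names(x$cluster_sizes), x$cluster_sizes),
              collapse = ", "), "\n")
  invisible(x)
}
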