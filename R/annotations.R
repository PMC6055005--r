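REGULATORY_MODES <- c("activator", "repressor", "dual")
EVIDENCE_CLASSES <- c("strong", "weak", "hypothetical")

#' Construct an annotation catalog
#'
#' Bundles the regulatory annotation a cluster characterization needs:
#' regulons (TF -> target genes with regulatory mode), TF families, TF
#' evidence classes, and per-scheme gene functional categories.
#'
#' @param tf_targets data.frame with columns `tf`, `gene`, `mode`; `mode`
#'   must be one of `activator`, `repressor`, `dual`.
#' @param tf_family named character vector, TF id -> family label.
#' @param tf_evidence named character vector, TF id -> one of `strong`,
#'   `weak`, `hypothetical`.
#' @param gene_categories named list of schemes (e.g. `KEGG`, `Supfam`,
#'   `Pfam`); each scheme a data.frame with columns `gene`, `category`.
#' @return object of class `"annotation_catalog"`.
#' @export
annotation_catalog <- function(tf_targets = NULL, tf_family = NULL,
                               tf_evidence = NULL, gene_categories = list()) {
  if (!is.null(tf_targets)) {
    tf_targets <- as.data.frame(tf_targets)
    need <- c("tf", "gene", "mode")
    if (!all(need %in% names(tf_targets)))
      stop("tf_targets needs columns tf, gene, mode")
    tf_targets <- tf_targets[need]
    for (j in need) tf_targets[[j]] <- as.character(tf_targets[[j]])
    bad <- !tf_targets$mode %in% REGULATORY_MODES
    if (any(bad))
      stop("unknown regulatory mode(s) in tf_targets row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), ": ",
           paste(unique(tf_targets$mode[bad]), collapse = ", "),
           " (allowed: ", paste(REGULATORY_MODES, collapse = ", "), ")")
    if (any(!nzchar(tf_targets$tf)) || any(!nzchar(tf_targets$gene)))
      stop("empty TF or gene identifier in tf_targets")
  }
  if (!is.null(tf_evidence)) {
    tf_evidence <- stats::setNames(as.character(tf_evidence), names(tf_evidence))
    bad <- !tf_evidence %in% EVIDENCE_CLASSES
    if (any(bad))
      stop("unknown evidence class(es): ",
           paste(unique(tf_evidence[bad]), collapse = ", "))
    if (is.null(names(tf_evidence)) || any(!nzchar(names(tf_evidence))))
      stop("tf_evidence must be named by TF id")
  }
  if (!is.null(tf_family)) {
    tf_family <- stats::setNames(as.character(tf_family), names(tf_family))
    if (is.null(names(tf_family)) || any(!nzchar(names(tf_family))))
      stop("tf_family must be named by TF id")
  }
  if (length(gene_categories)) {
    if (is.null(names(gene_categories)) || anyDuplicated(names(gene_categories)))
      stop("gene_categories schemes must have unique names")
    gene_categories <- lapply(gene_categories, function(sc) {
      sc <- as.data.frame(sc)
      if (!all(c("gene", "category") %in% names(sc)))
        stop("each gene_categories scheme needs columns gene, category")
      sc <- sc[c("gene", "category")]
      sc$gene <- as.character(sc$gene); sc$category <- as.character(sc$category)
      unique(sc)
    })
  }
  structure(list(tf_targets = tf_targets, tf_family = tf_family,
                 tf_evidence = tf_evidence, gene_categories = gene_categories),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("Annotation catalog\n")
  if (!is.null(x$tf_targets))
    cat(sprintf("  regulons: %d interactions, %d TFs, %d target genes\n",
                nrow(x$tf_targets), length(unique(x$tf_targets$tf)),
                length(unique(x$tf_targets$gene))))
  if (!is.null(x$tf_family))
    cat(sprintf("  families: %d TFs, %d families\n",
                length(x$tf_family), length(unique(x$tf_family))))
  if (!is.null(x$tf_evidence)) {
    ev <- table(factor(x$tf_evidence, EVIDENCE_CLASSES))
    cat(sprintf("  evidence: %s\n",
                paste(sprintf("%s=%d", names(ev), ev), collapse = ", ")))
  }
  for (sc in names(x$gene_categories))
    cat(sprintf("  scheme %s: %d gene-category assignments, %d categories\n",
                sc, nrow(x$gene_categories[[sc]]),
                length(unique(x$gene_categories[[sc]]$category))))
  invisible(x)
}

#' Parse a GMT gene-set file into a gene -> category table
#'
#' Standard GMT: one category per line, tab-separated: name, description,
#' then member genes.
#'
#' @param path GMT file path.
#' @return data.frame with columns `gene`, `category`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- lapply(lines, function(f) {
    if (length(f) < 3L)
      stop("GMT line needs name, description and at least one gene: ",
           paste(f, collapse = "\t"))
    data.frame(gene = f[-(1:2)], category = f[[1L]])
  })
  unique(do.call(rbind, out))
}

#' Read annotation tables into a catalog
#'
#' @param tf_targets_path 3-column TSV (tf, gene, mode) with header.
#' @param tf_family_path 2-column TSV (tf, family) with header.
#' @param tf_evidence_path 2-column TSV (tf, evidence) with header.
#' @param gene_category_paths named character vector of scheme -> file;
#'   each file either GMT (`.gmt`) or 2-column TSV (gene, category).
#' @return an `"annotation_catalog"`.
#' @export
read_annotations <- function(tf_targets_path = NULL, tf_family_path = NULL,
                             tf_evidence_path = NULL,
                             gene_category_paths = character()) {
  read2 <- function(p) utils::read.delim(p, header = TRUE, colClasses = "character")
  tt <- fam <- ev <- NULL
  if (!is.null(tf_targets_path)) {
    tt <- read2(tf_targets_path)
    names(tt)[1:3] <- c("tf", "gene", "mode")
  }
  if (!is.null(tf_family_path)) {
    t2 <- read2(tf_family_path); fam <- stats::setNames(t2[[2L]], t2[[1L]])
  }
  if (!is.null(tf_evidence_path)) {
    t2 <- read2(tf_evidence_path); ev <- stats::setNames(t2[[2L]], t2[[1L]])
  }
  gc <- lapply(gene_category_paths, function(p) {
    if (grepl("\\.gmt$", p, ignore.case = TRUE)) read_gmt(p)
    else { t2 <- read2(p); names(t2)[1:2] <- c("gene", "category"); t2[1:2] }
  })
  annotation_catalog(tf_targets = tt, tf_family = fam, tf_evidence = ev,
                     gene_categories = gc)
}

#' Write pipeline products to TSV
#'
#' Partitions go out as 2-column TSV (id, label); enrichment tables as TSV
#' with the fixed column order `cluster, scheme, category, a, b, c, d,
#' p_raw, p_adj, significant`. Dispatches on class.
#'
#' @param result a `"partition"` or `"enrichment_result"` table.
#' @param path output path.
#' @export
write_results <- function(result, path) UseMethod("write_results")

#' @export
write_results.partition <- function(result, path) write_partition(result, path)

#' @export
write_results.enrichment_result <- function(result, path) {
  cols <- c("cluster", "scheme", "category", "a", "b", "c", "d",
            "p_raw", "p_adj", "significant")
  utils::write.table(as.data.frame(result)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.default <- function(result, path) {
  stop("no writer for objects of class ", paste(class(result), collapse = "/"))
}
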