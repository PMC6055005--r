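#' Construct a partition of items into clusters
#'
#' @param ids ordered unique item identifiers.
#' @param labels one cluster label per item (coerced to character).
#' @return object of class `"partition"`: list with `ids`, `labels`
#'   (named by `ids`) and `k`, the number of distinct labels.
#' @export
partition <- function(ids, labels) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) != length(labels))
    stop("ids and labels must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate item identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids)) || any(!nzchar(labels)))
    stop("empty identifier or label in partition")
  structure(list(ids = ids, labels = stats::setNames(labels, ids),
                 k = length(unique(labels))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition of", length(x$ids), "items into", x$k, "clusters\n")
  print(table(cluster = x$labels), ...)
  invisible(x)
}

#' Read / write a partition as 2-column TSV (id, label)
#'
#' @param path TSV path with header `id<TAB>label`.
#' @return a `"partition"`.
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  partition(tab[[1L]], tab[[2L]])
}

#' @rdname read_partition
#' @param p a `"partition"` object.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  writeLines(c("id\tlabel", paste(p$ids, p$labels, sep = "\t")), path)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the pair-counting contingency table. 1 means identical up
#' to label renaming; the expected value under independent random
#' labelings is 0.
#'
#' @param a,b label vectors of equal length, or `"partition"` objects over
#'   the same ids (matched by id, not position).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "partition") && inherits(b, "partition")) {
    common <- intersect(a$ids, b$ids)
    if (!length(common)) stop("partitions share no item ids")
    a <- a$labels[common]; b <- b$labels[common]
  }
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)          # degenerate: both one cluster
  (sum_ij - expected) / (max_idx - expected)
}
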