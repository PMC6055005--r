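#' Validate an expression matrix
#'
#' An expression matrix is a base numeric matrix whose rownames are TF (or
#' gene) identifiers and whose colnames are condition labels. Log-ratio
#' values; `NA` marks missing measurements. Identifiers must be unique and
#' non-empty; validation rejects, it never repairs.
#'
#' @param x numeric matrix with rownames and colnames.
#' @return `x` invisibly, if valid.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix")
  rid <- rownames(x)
  cid <- colnames(x)
  if (is.null(rid) || is.null(cid))
    stop("expression matrix must carry rownames (TF ids) and colnames (condition labels)")
  if (any(!nzchar(rid)) || any(!nzchar(cid)))
    stop("empty identifier in expression matrix dimnames")
  if (anyDuplicated(rid))
    stop("duplicate row identifier(s): ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  if (anyDuplicated(cid))
    stop("duplicate column identifier(s): ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "))
  invisible(x)
}

#' Read a TF-by-condition expression matrix from TSV
#'
#' First row holds condition labels, first column row identifiers. Empty
#' cells and the token `NA` (case-insensitive) denote missing values; any
#' other non-numeric cell is a hard error reporting its coordinates.
#' Input order of rows and columns is preserved.
#'
#' @param path TSV file path.
#' @param synonyms optional 2-column TSV (alias, primary) applied to row
#'   identifiers at read time; identifiers are case-sensitive.
#' @param na_tokens tokens treated as missing (case-insensitive), besides
#'   the empty cell.
#' @return numeric matrix (rows = TFs, columns = conditions) with `NA` for
#'   missing entries.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, synonyms = NULL, na_tokens = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression TSV needs a header row and at least one data row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids))
    stop("duplicate column identifier(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(col_ids),
                 dimnames = list(row_ids, col_ids))
  na_tokens <- toupper(na_tokens)
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    length(cells) <- length(col_ids)           # ragged short rows -> NA-pad then check
    miss <- is.na(cells) | !nzchar(cells) | toupper(cells) %in% na_tokens
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   row_ids[i], col_ids[bad[1L]], cells[bad[1L]]))
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  if (!is.null(synonyms)) rownames(vals) <- apply_synonyms(rownames(vals), synonyms)
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Tab-separated with a mandatory header; missing values written as `NA`.
#' A [read_expression()] round-trip is lossless.
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  header <- paste(c("id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Apply a synonym table to identifiers
#'
#' @param ids character identifiers.
#' @param synonyms path to a 2-column TSV (alias, primary) with header, or
#'   a named character vector `c(alias = primary)`.
#' @return identifiers with aliases replaced by primary names (case-sensitive).
#' @export
apply_synonyms <- function(ids, synonyms) {
  if (is.character(synonyms) && length(synonyms) == 1L && file.exists(synonyms)) {
    tab <- utils::read.delim(synonyms, header = TRUE, colClasses = "character")
    map <- stats::setNames(tab[[2L]], tab[[1L]])
  } else if (!is.null(names(synonyms))) {
    map <- synonyms
  } else stop("synonyms must be a 2-column TSV path or a named character vector")
  hit <- ids %in% names(map)
  ids[hit] <- unname(map[ids[hit]])
  ids
}

#' Impute missing expression values
#'
#' @param x expression matrix, possibly with `NA` entries.
#' @param strategy `"row_mean"` replaces each missing entry by the mean of
#'   the observed values in its row; `"zero"` replaces by 0 (a log-ratio of
#'   0 is "no change"). Non-missing values are never altered.
#' @return complete expression matrix.
#' @export
impute_missing <- function(x, strategy = c("row_mean", "zero")) {
  strategy <- match.arg(strategy)
  validate_expression(x)
  if (!anyNA(x)) return(x)
  all_na <- rowSums(!is.na(x)) == 0L
  if (strategy == "row_mean" && any(all_na))
    stop("row(s) entirely missing, cannot impute row mean: ",
         paste(rownames(x)[all_na], collapse = ", "))
  miss <- is.na(x)
  if (strategy == "zero") {
    x[miss] <- 0
  } else {
    rm_ <- rowMeans(x, na.rm = TRUE)
    x[miss] <- rm_[row(x)[miss]]
  }
  x
}
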