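#' Packaged reference cluster table
#'
#' The published 12-cluster assignment of the 291 E. coli K-12 TFs, as
#' transcribed fixtures: per-cluster sizes and within-sum-of-squares, and
#' the membership list with evidence classes (strong / weak /
#' hypothetical) and synonyms. Transcription defects in the source table
#' are flagged, never guessed: one unnamed entry (described only as
#' "regulated by RcsB-BglJ"), two entries lost to extraction (placeholder
#' rows so the authoritative `n` column still governs sizes), and one TF
#' listed twice.
#'
#' @param what `"sizes"` (cluster, n, wss), `"membership"` (tf, synonym,
#'   cluster, evidence, flag) or `"partition"` (a [partition()] built
#'   from the membership rows whose per-cluster counts reproduce the
#'   published `n` column: placeholder rows for extraction losses are
#'   included, while the unnamed parenthetical entry is excluded — the
#'   published count shows it was not a separate table entry).
#' @return data.frame or `"partition"`, per `what`.
#' @export
reference_clusters <- function(what = c("sizes", "membership", "partition")) {
  what <- match.arg(what)
  path <- function(f) system.file("extdata", f, package = "tfclust",
                                  mustWork = TRUE)
  if (what == "sizes")
    return(utils::read.delim(path("table1_sizes.tsv"),
                             colClasses = c("character", "integer", "numeric")))
  memb <- utils::read.delim(path("table1_clusters.tsv"),
                            colClasses = "character", fill = TRUE)
  memb$flag[is.na(memb$flag)] <- ""
  memb$synonym[is.na(memb$synonym)] <- ""
  if (what == "membership") return(memb)
  keep <- !grepl("unnamed_in_source", memb$flag)
  partition(memb$tf[keep], memb$cluster[keep])
}
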