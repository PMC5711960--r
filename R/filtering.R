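#' Junction-spanning read-support filter
#'
#' Flags consensus fusions supported by at least `min_pairs` junction-
#' spanning read pairs in *each* caller's report. Fusions below the
#' threshold are not deleted: they keep `passed_support_filter = FALSE` and
#' remain in the table so that homology scoring can still cover them; use
#' [retained_fusions()] to subset to events passing all filters.
#'
#' Requiring the threshold from both callers is the conservative reading of
#' a two-caller consensus design in which each caller already imposed a
#' minimum-read rule at detection time.
#'
#' @param fusions Consensus-fusion data.frame.
#' @param min_pairs Minimum junction-spanning pairs per caller (default 3).
#' @return The same data.frame with `passed_support_filter` filled in.
#' @export
filter_read_support <- function(fusions, min_pairs = 3L) {
  assert_columns(fusions, c("junction_pairs_A", "junction_pairs_B"),
                 where = "consensus table")
  if (any(fusions$junction_pairs_A < 0 | fusions$junction_pairs_B < 0,
          na.rm = TRUE)) {
    abort("negative junction-pair counts")
  }
  fusions$passed_support_filter <-
    fusions$junction_pairs_A >= min_pairs & fusions$junction_pairs_B >= min_pairs
  fusions
}

#' Same-gene-family filter
#'
#' Flags fusions whose two partners share no gene-family identifier in an
#' HGNC-style family table. Partner pairs from the same family (e.g. two
#' histone paralogs) are likely alignment artifacts driven by sequence
#' similarity and get `passed_family_filter = FALSE`. Genes absent from the
#' table share nothing and therefore pass.
#'
#' @param fusions Consensus-fusion data.frame.
#' @param families A [gene_family_table()].
#' @return The same data.frame with `passed_family_filter` filled in.
#' @export
filter_gene_family <- function(fusions, families) {
  assert_columns(fusions, c("gene5", "gene3"), where = "consensus table")
  fusions$passed_family_filter <-
    if (nrow(fusions) == 0) logical(0) else
      !shares_family(families, fusions$gene5, fusions$gene3)
  fusions
}

#' Subset to fusions passing all applied filters
#'
#' Keeps rows whose filter flags are `TRUE`; a flag still `NA` (filter not
#' applied yet) does not remove a row.
#'
#' @param fusions Consensus-fusion data.frame.
#' @return The retained subset.
#' @export
retained_fusions <- function(fusions) {
  keep <- (is.na(fusions$passed_support_filter) | fusions$passed_support_filter) &
    (is.na(fusions$passed_family_filter) | fusions$passed_family_filter)
  out <- fusions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
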