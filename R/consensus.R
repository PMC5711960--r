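#' Orientation-aware intersection of two callers' calls for one sample
#'
#' A candidate fusion is validated when both callers report the same ordered
#' (5' gene, 3' gene) pair in the same sample, regardless of differences in
#' the exact breakpoint predictions. Order matters: `IGH-NSD2` and
#' `NSD2-IGH` are distinct fusions (reciprocal products of a translocation).
#' Coordinates and strands of the consensus record are taken from caller A's
#' (TopHat-style) prediction, which downstream homology scoring uses;
#' junction-pair counts are carried from both callers.
#'
#' @param calls_a,calls_b Normalized fusion-call tables (see
#'   [read_caller_report()]) for one sample each. Both callers' tables must
#'   carry the same single `sample_id`. Inputs are assumed collapsed to one
#'   row per ordered gene pair (the reader guarantees this).
#' @return A consensus-fusion data.frame with one row per shared ordered
#'   gene pair; filter flags, homology score and classification columns are
#'   initialized to `NA` and filled by later stages.
#' @export
#' @examples
#' a <- data.frame(sample_id = "s1", caller = "tophat",
#'                 gene5 = "IGHG1", chrom5 = "chr14", bp5 = 1000L, strand5 = "+",
#'                 gene3 = "NSD2", chrom3 = "chr4", bp3 = 5000L, strand3 = "+",
#'                 junction_pairs = 12L)
#' b <- a; b$caller <- "mapsplice"; b$bp5 <- 1012L; b$junction_pairs <- 5L
#' intersect_calls(a, b)
intersect_calls <- function(calls_a, calls_b) {
  for (tbl in list(calls_a, calls_b)) {
    assert_columns(tbl, setdiff(names(fusion_call_proto()), "caller"),
                   where = "fusion-call table")
    if (length(unique(tbl$sample_id)) > 1) {
      abort("intersect_calls: mixed sample_ids within one call list")
    }
  }
  if (nrow(calls_a) && nrow(calls_b) &&
      calls_a$sample_id[1] != calls_b$sample_id[1]) {
    abort("intersect_calls: the two call lists are from different samples")
  }
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) return(empty_consensus())

  key_a <- paste(calls_a$gene5, calls_a$gene3, sep = "\r")
  key_b <- paste(calls_b$gene5, calls_b$gene3, sep = "\r")
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    abort("intersect_calls: inputs must be collapsed to one row per ordered gene pair")
  }
  hit <- match(key_a, key_b)
  keep <- which(!is.na(hit))
  if (length(keep) == 0) return(empty_consensus())
  a <- calls_a[keep, , drop = FALSE]
  b <- calls_b[hit[keep], , drop = FALSE]

  data.frame(
    sample_id = a$sample_id,
    gene5 = a$gene5, gene3 = a$gene3,
    chrom5 = a$chrom5, bp5 = a$bp5, strand5 = a$strand5,
    chrom3 = a$chrom3, bp3 = a$bp3, strand3 = a$strand3,
    junction_pairs_A = a$junction_pairs,
    junction_pairs_B = b$junction_pairs,
    passed_support_filter = NA,
    passed_family_filter = NA,
    homology_escore = NA_real_,
    is_ig = NA, ig_class = NA_character_,
    is_recurrent = NA, is_same_chr_lt10Mb = NA,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Intersect both callers' reports across a cohort
#'
#' Applies [intersect_calls()] per sample over the union of sample ids seen
#' by either caller and concatenates the results. A sample present for one
#' caller only triggers a warning and is treated as having an empty report
#' for the missing caller (hence contributes no consensus fusions).
#'
#' @param calls_a,calls_b Normalized fusion-call tables covering any number
#'   of samples (rows carry `sample_id`).
#' @param metadata Optional sample metadata (see [read_sample_metadata()]);
#'   when given, metadata columns are joined onto the result and samples
#'   listed only in the metadata count as fusion-free rather than unknown.
#' @return A cohort-level consensus-fusion data.frame.
#' @export
intersect_cohort <- function(calls_a, calls_b, metadata = NULL) {
  ids_a <- unique(calls_a$sample_id)
  ids_b <- unique(calls_b$sample_id)
  one_sided <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(one_sided)) {
    warning(sprintf("sample(s) reported by one caller only (treated as empty for the other): %s",
                    paste(one_sided, collapse = ", ")), call. = FALSE)
  }
  ids <- union(ids_a, ids_b)
  parts <- lapply(ids, function(s) {
    a <- calls_a[calls_a$sample_id == s, , drop = FALSE]
    b <- calls_b[calls_b$sample_id == s, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) empty_consensus() else intersect_calls(a, b)
  })
  out <- do.call(rbind, c(list(empty_consensus()), parts))
  rownames(out) <- NULL
  if (!is.null(metadata)) {
    extra <- setdiff(names(metadata), "sample_id")
    out <- merge(out, metadata[, c("sample_id", extra), drop = FALSE],
                 by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  out
}
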