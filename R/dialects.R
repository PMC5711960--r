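#' Fusion-report dialect descriptions
#'
#' A dialect maps one caller's report columns onto the normalized fusion-call
#' schema and declares the source file's coordinate convention, so that
#' [read_caller_report()] can convert everything to the internal
#' representation (1-based breakpoints, one `junction_pairs` count).
#'
#' `dialect_tophat()` describes a TopHat-Fusion-style table: one column of
#' junction-spanning mate pairs ("spanning mate pairs where one end spans the
#' fusion"), 0-based breakpoints and `chr`-prefixed chromosome names.
#' `dialect_mapsplice()` describes a MapSplice-style table: junction support
#' split into `multiple_paired_read_count` and `unique_paired_read_count`
#' (summed into `junction_pairs` at read time), 1-based breakpoints and bare
#' chromosome names.
#'
#' @param columns Named character vector mapping normalized field names
#'   (`gene5`, `chrom5`, `bp5`, `strand5`, `gene3`, `chrom3`, `bp3`,
#'   `strand3`) to source column names.
#' @param count_columns Character vector of source columns whose row-wise sum
#'   gives `junction_pairs`.
#' @param coord_base Either `0` or `1`: the coordinate base of breakpoint
#'   columns in the source file. 0-based positions are shifted by +1 on read.
#' @param chrom_prefix Logical: whether the source file uses `chr`-prefixed
#'   chromosome names.
#'
#' @return An object of class `fusion_dialect`.
#' @export
#' @examples
#' d <- dialect_mapsplice()
#' d$count_columns
fusion_dialect <- function(columns, count_columns, coord_base = 1L,
                           chrom_prefix = TRUE) {
  needed <- c("gene5", "chrom5", "bp5", "strand5",
              "gene3", "chrom3", "bp3", "strand3")
  missing <- setdiff(needed, names(columns))
  if (length(missing)) {
    abort("dialect 'columns' must map field(s): %s",
          paste(missing, collapse = ", "))
  }
  if (!coord_base %in% c(0L, 1L)) abort("coord_base must be 0 or 1")
  if (length(count_columns) < 1) abort("at least one count column is required")
  structure(
    list(columns = columns[needed],
         count_columns = count_columns,
         coord_base = as.integer(coord_base),
         chrom_prefix = isTRUE(chrom_prefix)),
    class = "fusion_dialect"
  )
}

#' @rdname fusion_dialect
#' @export
dialect_tophat <- function() {
  fusion_dialect(
    columns = c(gene5 = "gene_1", chrom5 = "chromosome_1",
                bp5 = "breakpoint_1", strand5 = "strand_1",
                gene3 = "gene_2", chrom3 = "chromosome_2",
                bp3 = "breakpoint_2", strand3 = "strand_2"),
    count_columns = "spanning_mate_pairs",
    coord_base = 0L,
    chrom_prefix = TRUE
  )
}

#' @rdname fusion_dialect
#' @export
dialect_mapsplice <- function() {
  fusion_dialect(
    columns = c(gene5 = "gene_5p", chrom5 = "chrom_5p",
                bp5 = "pos_5p", strand5 = "strand_5p",
                gene3 = "gene_3p", chrom3 = "chrom_3p",
                bp3 = "pos_3p", strand3 = "strand_3p"),
    count_columns = c("multiple_paired_read_count",
                      "unique_paired_read_count"),
    coord_base = 1L,
    chrom_prefix = FALSE
  )
}

default_dialect <- function(caller) {
  switch(caller,
         tophat = dialect_tophat(),
         mapsplice = dialect_mapsplice(),
         abort("no built-in dialect for caller '%s'", caller))
}
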