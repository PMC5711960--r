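## Normalized schemas -------------------------------------------------------

fusion_call_proto <- function() {
  list(sample_id = character(), caller = character(),
       gene5 = character(), chrom5 = character(), bp5 = integer(),
       strand5 = character(),
       gene3 = character(), chrom3 = character(), bp3 = integer(),
       strand3 = character(),
       junction_pairs = integer())
}

consensus_proto <- function() {
  list(sample_id = character(),
       gene5 = character(), gene3 = character(),
       chrom5 = character(), bp5 = integer(), strand5 = character(),
       chrom3 = character(), bp3 = integer(), strand3 = character(),
       junction_pairs_A = integer(), junction_pairs_B = integer(),
       passed_support_filter = logical(), passed_family_filter = logical(),
       homology_escore = numeric(),
       is_ig = logical(), ig_class = character(),
       is_recurrent = logical(), is_same_chr_lt10Mb = logical())
}

#' Empty normalized fusion-call table
#' @return A zero-row data.frame with the normalized fusion-call columns.
#' @keywords internal
#' @export
empty_fusion_calls <- function() empty_df(fusion_call_proto())

#' Empty consensus-fusion table
#' @return A zero-row data.frame with the consensus-fusion columns.
#' @keywords internal
#' @export
empty_consensus <- function() empty_df(consensus_proto())

## Caller reports -----------------------------------------------------------

#' Read one caller's fusion report into the normalized schema
#'
#' Reads a TSV fusion report in either of the two supported dialects (or a
#' custom [fusion_dialect()]) and normalizes it: breakpoints are converted to
#' 1-based coordinates, chromosome names are harmonized to a single style,
#' the dialect's read-count column(s) are summed into `junction_pairs`, gene
#' aliases are resolved, rows without a parseable gene symbol are dropped
#' (with a message giving the count), and multiple rows for the same ordered
#' gene pair are collapsed to the row with maximal `junction_pairs`.
#'
#' Collapsing to gene-pair level reflects that downstream consensus calling
#' is defined on ordered gene pairs, not on individual breakpoints; keeping
#' the best-supported row prevents double counting.
#'
#' @param path Path to a TSV report. An empty file (header only or zero
#'   bytes) yields a zero-row table.
#' @param caller `"tophat"` or `"mapsplice"`; selects the default dialect and
#'   is recorded in the `caller` column.
#' @param sample_id Sample identifier recorded in every row.
#' @param dialect A [fusion_dialect()]; defaults to the caller's built-in one.
#' @param chrom_style `"chr"` (ensure `chr` prefix), `"plain"` (strip it) or
#'   `"asis"`. The internal convention used by the synthetic annotation is
#'   `"chr"`.
#' @param aliases Optional named character vector mapping alias symbols to
#'   canonical ones (e.g. `c(WHSC1 = "NSD2", MMSET = "NSD2")`).
#'
#' @return A data.frame with columns `sample_id, caller, gene5, chrom5, bp5,
#'   strand5, gene3, chrom3, bp3, strand3, junction_pairs`.
#' @export
read_caller_report <- function(path, caller = c("tophat", "mapsplice"),
                               sample_id, dialect = NULL,
                               chrom_style = c("chr", "plain", "asis"),
                               aliases = NULL) {
  caller <- match.arg(caller)
  chrom_style <- match.arg(chrom_style)
  dialect <- dialect %||% default_dialect(caller)
  if (!inherits(dialect, "fusion_dialect")) abort("'dialect' must be a fusion_dialect")
  if (!file.exists(path)) abort("report file not found: %s", path)
  if (missing(sample_id) || !nzchar(sample_id)) abort("'sample_id' is required")

  if (file.size(path) == 0) return(empty_fusion_calls())
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) return(empty_fusion_calls())

  assert_columns(raw, unname(c(dialect$columns, dialect$count_columns)),
                 where = sprintf("report '%s'", basename(path)))

  cols <- dialect$columns
  out <- data.frame(
    sample_id = sample_id,
    caller = caller,
    gene5 = as.character(raw[[cols[["gene5"]]]]),
    chrom5 = as.character(raw[[cols[["chrom5"]]]]),
    bp5 = as.integer(raw[[cols[["bp5"]]]]),
    strand5 = as.character(raw[[cols[["strand5"]]]]),
    gene3 = as.character(raw[[cols[["gene3"]]]]),
    chrom3 = as.character(raw[[cols[["chrom3"]]]]),
    bp3 = as.integer(raw[[cols[["bp3"]]]]),
    strand3 = as.character(raw[[cols[["strand3"]]]]),
    junction_pairs = as.integer(
      Reduce(`+`, lapply(dialect$count_columns, function(cc) raw[[cc]]))),
    stringsAsFactors = FALSE
  )

  bad <- is.na(out$gene5) | is.na(out$gene3) |
    !nzchar(trimws(out$gene5)) | !nzchar(trimws(out$gene3))
  if (any(bad)) {
    message(sprintf("read_caller_report: dropped %d row(s) with unparseable gene symbols",
                    sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  if (any(out$junction_pairs < 0, na.rm = TRUE)) {
    abort("negative junction-pair counts in '%s'", basename(path))
  }

  if (dialect$coord_base == 0L) {
    out$bp5 <- out$bp5 + 1L
    out$bp3 <- out$bp3 + 1L
  }
  out$chrom5 <- normalize_chrom_names(out$chrom5, chrom_style)
  out$chrom3 <- normalize_chrom_names(out$chrom3, chrom_style)
  if (!is.null(aliases)) {
    out$gene5 <- resolve_aliases(out$gene5, aliases)
    out$gene3 <- resolve_aliases(out$gene3, aliases)
  }

  collapse_gene_pairs(out)
}

#' Harmonize chromosome-name style
#'
#' @param x Character vector of chromosome names.
#' @param style `"chr"` to ensure a `chr` prefix, `"plain"` to strip it,
#'   `"asis"` to leave names untouched.
#' @return Character vector of normalized names.
#' @export
normalize_chrom_names <- function(x, style = c("chr", "plain", "asis")) {
  style <- match.arg(style)
  switch(style,
         asis = x,
         plain = sub("^chr", "", x),
         chr = ifelse(grepl("^chr", x), x, paste0("chr", x)))
}

resolve_aliases <- function(symbols, aliases) {
  hit <- symbols %in% names(aliases)
  symbols[hit] <- unname(aliases[symbols[hit]])
  symbols
}

# one row per (sample, ordered gene pair): keep the max-support row
collapse_gene_pairs <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  key <- paste(calls$sample_id, calls$gene5, calls$gene3, sep = "\r")
  ord <- order(key, -calls$junction_pairs)
  calls <- calls[ord, , drop = FALSE]
  calls <- calls[!duplicated(key[ord]), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

## Gene annotation ----------------------------------------------------------

#' Default exclusion list for immunoglobulin symbol classification
#'
#' Gene symbols that match the `IGH`/`IGK`/`IGL` prefix-plus-designator
#' pattern but are not immunoglobulin locus segments.
#' @return Character vector of excluded symbols.
#' @export
ig_symbol_exclusions <- function() {
  c("IGHMBP2", "IGLL1", "IGLL5", "IGLON5")
}

#' Classify gene symbols into immunoglobulin locus classes
#'
#' A symbol is assigned class `IGH`, `IGK` or `IGL` when it matches the
#' locus prefix followed by a segment or constant-region designator
#' (V/D/J/C segments; IGH constants M/G/A/E/D), and is not on the exclusion
#' list. Everything else is `"none"`. This prefix rule plus an explicit
#' exclusion list is auditable, unlike a hard-coded symbol list.
#'
#' @param symbols Character vector of gene symbols.
#' @param exclusions Symbols never classified as immunoglobulin.
#' @return Character vector over `{"IGH","IGK","IGL","none"}`.
#' @export
#' @examples
#' classify_ig_symbol(c("IGKC", "IGHG1", "IGHMBP2", "NSD2"))
classify_ig_symbol <- function(symbols, exclusions = ig_symbol_exclusions()) {
  cls <- rep("none", length(symbols))
  cls[grepl("^IGH[VDJCMGAE]", symbols)] <- "IGH"
  cls[grepl("^IGK[VJC]", symbols)] <- "IGK"
  cls[grepl("^IGL[VJC]", symbols)] <- "IGL"
  cls[symbols %in% exclusions] <- "none"
  cls
}

#' Read gene annotation from GTF/GFF
#'
#' Imports `gene` features and reduces them to one record per symbol (the
#' widest genomic span when a symbol appears several times), then assigns
#' immunoglobulin locus classes with [classify_ig_symbol()].
#'
#' @param path GTF/GFF file.
#' @param exclusions Passed to [classify_ig_symbol()].
#' @param aliases Optional named character vector mapping alias symbols to a
#'   canonical symbol before records are merged.
#' @return A data.frame with columns `symbol, chrom, start, end, strand,
#'   is_ig, ig_class`.
#' @export
read_gene_annotation <- function(path, exclusions = ig_symbol_exclusions(),
                                 aliases = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
  if (nrow(df) == 0) abort("no gene features found in '%s'", path)
  symbol <- if ("gene_name" %in% names(df) && !all(is.na(df$gene_name))) {
    ifelse(is.na(df$gene_name), df$gene_id, df$gene_name)
  } else if ("gene_id" %in% names(df)) df$gene_id else
    abort("no gene_name/gene_id attribute in '%s'", path)
  symbol <- as.character(symbol)
  if (!is.null(aliases)) symbol <- resolve_aliases(symbol, aliases)

  ann <- data.frame(symbol = symbol,
                    chrom = as.character(df$seqnames),
                    start = as.integer(df$start),
                    end = as.integer(df$end),
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$symbol)) {
    ann <- do.call(rbind, lapply(split(ann, ann$symbol), function(g) {
      g$start[1] <- min(g$start); g$end[1] <- max(g$end); g[1, , drop = FALSE]
    }))
  }
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  ann$ig_class <- classify_ig_symbol(ann$symbol, exclusions)
  ann$is_ig <- ann$ig_class != "none"
  rownames(ann) <- NULL
  ann[, c("symbol", "chrom", "start", "end", "strand", "is_ig", "ig_class")]
}

## Gene families ------------------------------------------------------------

#' Read an HGNC-style gene-family membership table
#'
#' Expects a TSV with a gene-symbol column and a family-identifier column.
#' Duplicated symbols contribute the union of their family ids; malformed
#' rows (missing symbol or family) are skipped with a message. Symbols
#' absent from the file map to the empty set on lookup.
#'
#' @param path TSV file.
#' @param symbol_col,family_col Source column names.
#' @return An object of class `gene_family_table`.
#' @export
read_gene_families <- function(path, symbol_col = "symbol",
                               family_col = "family_id") {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_columns(raw, c(symbol_col, family_col), where = "gene-family table")
  sym <- as.character(raw[[symbol_col]])
  fam <- as.character(raw[[family_col]])
  bad <- is.na(sym) | is.na(fam) | !nzchar(trimws(sym)) | !nzchar(trimws(fam))
  if (any(bad)) {
    message(sprintf("read_gene_families: skipped %d malformed row(s)", sum(bad)))
  }
  gene_family_table(sym[!bad], fam[!bad])
}

#' Build a gene-family table from vectors
#' @param symbols,families Parallel character vectors (one row per membership).
#' @return An object of class `gene_family_table`: a named list mapping each
#'   symbol to its set of family identifiers.
#' @export
gene_family_table <- function(symbols = character(), families = character()) {
  stopifnot(length(symbols) == length(families))
  tab <- lapply(split(families, symbols), function(x) sort(unique(x)))
  structure(tab, class = "gene_family_table")
}

#' Look up family identifiers for gene symbols
#' @param table A `gene_family_table`.
#' @param symbols Character vector of symbols.
#' @return A list of character vectors (empty for unknown symbols).
#' @export
family_ids <- function(table, symbols) {
  stopifnot(inherits(table, "gene_family_table"))
  out <- unclass(table)[symbols]
  out[vapply(out, is.null, logical(1))] <- list(character())
  names(out) <- symbols
  out
}

#' Do two genes share a family?
#' @param table A `gene_family_table`.
#' @param gene1,gene2 Parallel character vectors of symbols.
#' @return Logical vector; `FALSE` whenever either gene is absent.
#' @export
shares_family <- function(table, gene1, gene2) {
  f1 <- family_ids(table, gene1)
  f2 <- family_ids(table, gene2)
  mapply(function(a, b) length(intersect(a, b)) > 0, f1, f2,
         USE.NAMES = FALSE)
}

## Metadata and expression --------------------------------------------------

#' Read per-sample metadata
#'
#' Expects a TSV with mandatory columns `sample_id` and `population`
#' (`patient`/`cell_line`) and optional `light_chain` (`kappa`/`lambda`/
#' `unknown`), `ploidy_group` (`high_hyperdiploid`/`other`/`unknown`),
#' `fish_translocation` (logical: any of t(11;14), t(4;14), t(14;16)) and
#' `age` (years).
#'
#' @param path TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_columns(meta, c("sample_id", "population"), where = "sample metadata")
  badpop <- !meta$population %in% c("patient", "cell_line")
  if (any(badpop)) {
    abort("invalid population value(s): %s",
          paste(unique(meta$population[badpop]), collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicated sample_id in metadata")
  if ("fish_translocation" %in% names(meta)) {
    meta$fish_translocation <- as.logical(meta$fish_translocation)
  }
  if ("age" %in% names(meta)) meta$age <- as.numeric(meta$age)
  meta
}

#' Read a genes x samples log-expression matrix
#'
#' @param path TSV with gene symbols in the first column and one column per
#'   sample; values are log-scaled normalized expression.
#' @return A numeric matrix (genes in rows).
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("expression matrix contains non-finite values")
  m
}

## Normalized fusion table --------------------------------------------------

fusion_table_columns <- function() names(consensus_proto())

#' Write / read the normalized consensus-fusion table
#'
#' The table is written as TSV with a stable column order (sample, ordered
#' gene pair, caller-A coordinates, per-caller junction-pair counts, filter
#' flags, homology E-score, classification flags) and round-trips losslessly
#' through [read_fusion_table()].
#'
#' @param fusions A consensus-fusion data.frame (see [intersect_calls()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fusion_table <- function(fusions, path) {
  cols <- fusion_table_columns()
  for (cn in setdiff(cols, names(fusions))) {
    fusions[[cn]] <- rep(consensus_proto()[[cn]][NA_integer_], nrow(fusions))
  }
  ok <- tryCatch({
    write.table(fusions[, cols, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort("cannot write fusion table to '%s': %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' @rdname write_fusion_table
#' @return `read_fusion_table()` returns the consensus-fusion data.frame.
#' @export
read_fusion_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "NA")
  assert_columns(df, fusion_table_columns(), where = "fusion table")
  proto <- consensus_proto()
  if (nrow(df) == 0) return(empty_consensus())
  for (cn in names(proto)) {
    df[[cn]] <- switch(class(proto[[cn]]),
                       character = as.character(df[[cn]]),
                       integer = as.integer(df[[cn]]),
                       numeric = as.numeric(df[[cn]]),
                       logical = as.logical(df[[cn]]))
  }
  df
}
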