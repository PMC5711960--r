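#' Classify consensus fusions against the gene annotation
#'
#' Fills the classification flags of a consensus-fusion table:
#' `is_ig`/`ig_class` (does either partner lie in the immunoglobulin
#' heavy-chain, kappa or lambda locus, and which), and `is_same_chr_lt10Mb`
#' (are both partners on the same chromosome with a gap between their gene
#' spans below `max_gap` — the signature of read-through transcription or a
#' local rearrangement). The gap is measured between gene spans, 0 when the
#' spans overlap. When both partners are immunoglobulin genes the 5'
#' partner's class is recorded.
#'
#' Fusions whose partners are missing from the annotation keep `NA` flags
#' (classification deferred) and are counted in a message.
#'
#' @param fusions Consensus-fusion data.frame.
#' @param annotation Gene annotation from [read_gene_annotation()].
#' @param max_gap Read-through distance threshold in bases (default 10 Mb).
#' @return The data.frame with classification columns filled.
#' @export
classify_fusions <- function(fusions, annotation, max_gap = 1e7) {
  if (nrow(fusions) == 0) return(fusions)
  i5 <- match(fusions$gene5, annotation$symbol)
  i3 <- match(fusions$gene3, annotation$symbol)
  unresolved <- is.na(i5) | is.na(i3)
  if (any(unresolved)) {
    message(sprintf("classify_fusions: %d fusion(s) with unresolved gene symbols left unclassified",
                    sum(unresolved)))
  }
  cls5 <- annotation$ig_class[i5]
  cls3 <- annotation$ig_class[i3]
  fusions$is_ig <- cls5 != "none" | cls3 != "none"
  fusions$ig_class <- ifelse(cls5 != "none", cls5,
                             ifelse(cls3 != "none", cls3, "none"))
  same_chr <- annotation$chrom[i5] == annotation$chrom[i3]
  gap <- pmax(0, pmax(annotation$start[i5], annotation$start[i3]) -
                pmin(annotation$end[i5], annotation$end[i3]))
  fusions$is_same_chr_lt10Mb <- same_chr & gap < max_gap
  fusions$is_ig[unresolved] <- NA
  fusions$ig_class[unresolved] <- NA_character_
  fusions$is_same_chr_lt10Mb[unresolved] <- NA
  fusions
}

#' Unique ordered gene pairs and their recurrence
#'
#' Collapses a cohort fusion table to its distinct ordered (5' gene, 3'
#' gene) pairs, counting the number of distinct samples expressing each
#' pair. A pair observed in at least two samples of the population is
#' recurrent.
#'
#' @param cohort Cohort-level consensus-fusion data.frame (typically the
#'   retained, classified fusions of one population).
#' @param population Optional population to subset to (requires a
#'   `population` column, joined from metadata).
#' @return A data.frame with one row per ordered pair: `gene5`, `gene3`,
#'   `n_samples`, `recurrent`, plus `is_ig`, `ig_class` and
#'   `is_same_chr_lt10Mb` carried over when present.
#' @export
unique_pairs <- function(cohort, population = NULL) {
  if (!is.null(population)) {
    assert_columns(cohort, "population", where = "cohort table")
    cohort <- cohort[cohort$population %in% population, , drop = FALSE]
  }
  proto <- data.frame(gene5 = character(), gene3 = character(),
                      n_samples = integer(), recurrent = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(cohort) == 0) return(proto)
  key <- paste(cohort$gene5, cohort$gene3, sep = "\r")
  n_samples <- vapply(split(cohort$sample_id, key),
                      function(s) length(unique(s)), integer(1))
  first <- cohort[!duplicated(key), , drop = FALSE]
  first_key <- key[!duplicated(key)]
  out <- data.frame(gene5 = first$gene5, gene3 = first$gene3,
                    n_samples = as.integer(n_samples[first_key]),
                    recurrent = unname(n_samples[first_key]) >= 2L,
                    stringsAsFactors = FALSE)
  for (cn in c("is_ig", "ig_class", "is_same_chr_lt10Mb")) {
    if (cn %in% names(first)) out[[cn]] <- first[[cn]]
  }
  rownames(out) <- NULL
  out
}

#' Cohort landscape summary
#'
#' Computes the descriptive landscape statistics of a fusion cohort for one
#' population: total and unique fusion counts; the decomposition of unique
#' pairs into immunoglobulin fusions, recurrent non-immunoglobulin fusions
#' and the remaining "others" (with the share of others lying on the same
#' chromosome within 10 Mb); the share of samples carrying at least one
#' Ig/IGH/IGK/IGL fusion, overall and stratified by light-chain phenotype
#' when metadata provides it; per-sample fusion counts (fusion-free samples
#' included as zeros); per-gene involvement counts; and the split of
#' immunoglobulin fusions by locus class, computed both over unique pairs
#' and over total fusion events.
#'
#' The three unique-pair categories are exhaustive and disjoint: `Ig` takes
#' every pair with an immunoglobulin partner (recurrent or not), `recurrent
#' non-Ig` the remaining recurrent pairs, `others` the rest.
#'
#' @param cohort Retained, classified cohort fusion table.
#' @param metadata Sample metadata (defines the population's full sample
#'   list, hence the zero counts).
#' @param population `"patient"` or `"cell_line"`.
#' @return An object of class `landscape_summary` (a named list).
#' @export
summarize_landscape <- function(cohort, metadata, population = "patient") {
  assert_columns(metadata, c("sample_id", "population"), where = "metadata")
  samples <- metadata$sample_id[metadata$population == population]
  cohort <- cohort[cohort$sample_id %in% samples, , drop = FALSE]

  counts <- setNames(integer(length(samples)), samples)
  if (nrow(cohort)) {
    tab <- table(cohort$sample_id)
    counts[names(tab)] <- as.integer(tab)
  }

  up <- unique_pairs(cohort)
  n_unique <- nrow(up)
  pct <- function(x) if (n_unique == 0) 0 else 100 * sum(x, na.rm = TRUE) / n_unique
  ig <- !is.na(up$is_ig) & up$is_ig
  rec_non_ig <- up$recurrent & !ig
  other <- !ig & !up$recurrent
  pct_other_same_chr <- if (sum(other) == 0) NA_real_ else
    100 * sum(up$is_same_chr_lt10Mb[other], na.rm = TRUE) / sum(other)

  # share of samples with >=1 fusion of each Ig class, by light-chain stratum
  strata <- list(all = samples)
  if ("light_chain" %in% names(metadata)) {
    md <- metadata[metadata$population == population, , drop = FALSE]
    strata$kappa <- md$sample_id[md$light_chain %in% "kappa"]
    strata$lambda <- md$sample_id[md$light_chain %in% "lambda"]
  }
  ig_events <- cohort[!is.na(cohort$is_ig) & cohort$is_ig, , drop = FALSE]
  sample_pct <- sapply(strata, function(ss) {
    if (length(ss) == 0) return(c(Ig = NA, IGH = NA, IGK = NA, IGL = NA))
    with_class <- function(cls) {
      has <- unique(ig_events$sample_id[ig_events$ig_class == cls])
      100 * length(intersect(has, ss)) / length(ss)
    }
    c(Ig = 100 * length(intersect(unique(ig_events$sample_id), ss)) / length(ss),
      IGH = with_class("IGH"), IGK = with_class("IGK"), IGL = with_class("IGL"))
  })

  class_split <- function(x) {
    tab <- table(factor(x, levels = c("IGH", "IGK", "IGL")))
    if (sum(tab) == 0) setNames(rep(NA_real_, 3), names(tab)) else
      setNames(100 * as.vector(tab) / sum(tab), names(tab))
  }
  split_unique <- class_split(up$ig_class[ig])
  split_total <- class_split(ig_events$ig_class)

  genes <- c(cohort$gene5, cohort$gene3)
  partner <- c(cohort$gene3, cohort$gene5)
  samp <- c(cohort$sample_id, cohort$sample_id)
  per_gene <- if (length(genes)) {
    do.call(rbind, lapply(split(seq_along(genes), genes), function(idx) {
      data.frame(gene = genes[idx[1]],
                 n_fusions = length(idx),
                 n_partners = length(unique(partner[idx])),
                 n_samples = length(unique(samp[idx])),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(), n_fusions = integer(),
               n_partners = integer(), n_samples = integer())
  }
  per_gene <- per_gene[order(-per_gene$n_fusions, per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL

  structure(list(
    population = population,
    n_samples = length(samples),
    n_fusions_total = nrow(cohort),
    n_unique_pairs = n_unique,
    pct_ig_of_unique = pct(ig),
    pct_recurrent_of_unique = pct(up$recurrent),
    pct_recurrent_non_ig_of_unique = pct(rec_non_ig),
    pct_other_of_unique = pct(other),
    pct_other_same_chr_lt10Mb = pct_other_same_chr,
    pct_samples_with_ig_fusion = sample_pct,
    ig_class_split_unique = split_unique,
    ig_class_split_total = split_total,
    per_sample_counts = counts,
    per_gene_counts = per_gene
  ), class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("Fusion landscape (%s, %d samples)\n", x$population, x$n_samples))
  cat(sprintf("  fusions: %d total, %d unique pairs\n",
              x$n_fusions_total, x$n_unique_pairs))
  cat(sprintf("  unique-pair decomposition: Ig %.1f%% | recurrent non-Ig %.1f%% | others %.1f%% (same-chr<10Mb: %.1f%% of others)\n",
              x$pct_ig_of_unique, x$pct_recurrent_non_ig_of_unique,
              x$pct_other_of_unique, x$pct_other_same_chr_lt10Mb))
  cat(sprintf("  samples with >=1 Ig fusion: %.1f%%\n",
              x$pct_samples_with_ig_fusion["Ig", "all"]))
  cat(sprintf("  mean fusions per sample: %.2f\n", mean(x$per_sample_counts)))
  invisible(x)
}

#' Fusion frequency versus chromosome gene density
#'
#' Counts, per chromosome, the fusion partner genes it carries (each fusion
#' contributes its two partners' chromosomes, so an intra-chromosomal fusion
#' counts twice on its chromosome) and correlates that count with the
#' chromosome's gene density (genes per Mb). Chromosomes carrying special
#' structure (e.g. the immunoglobulin loci) can be excluded from the
#' correlation.
#'
#' @param cohort Retained cohort fusion table.
#' @param annotation Gene annotation ([read_gene_annotation()]).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#' @param exclude Chromosomes to drop before computing the correlation.
#' @return A list with `density` (per-chromosome data.frame: `chrom`,
#'   `length_mb`, `n_genes`, `genes_per_mb`, `fusion_gene_count`) and
#'   `correlation` (Pearson r over the non-excluded chromosomes).
#' @export
density_correlation <- function(cohort, annotation, chrom_lengths,
                                exclude = character()) {
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) abort("'chrom_lengths' must be a named vector")
  gene_tab <- table(factor(annotation$chrom, levels = chroms))
  fus_tab <- table(factor(c(cohort$chrom5, cohort$chrom3), levels = chroms))
  density <- data.frame(
    chrom = chroms,
    length_mb = as.numeric(chrom_lengths) / 1e6,
    n_genes = as.integer(gene_tab),
    genes_per_mb = as.integer(gene_tab) / (as.numeric(chrom_lengths) / 1e6),
    fusion_gene_count = as.integer(fus_tab),
    stringsAsFactors = FALSE
  )
  keep <- !density$chrom %in% exclude
  if (sum(keep) < 3) abort("fewer than 3 chromosomes left after exclusion")
  r <- cor(density$genes_per_mb[keep], density$fusion_gene_count[keep],
           method = "pearson")
  list(density = density, correlation = r)
}

#' Per-sample fusion counts and group summaries
#'
#' @param cohort Retained cohort fusion table.
#' @param metadata Sample metadata; defines the full sample list so that
#'   fusion-free samples contribute zero counts.
#' @param population Population to summarize.
#' @param groupby Optional metadata column for group means.
#' @param threshold Optional count threshold; the number of samples strictly
#'   above it is reported.
#' @return A list with `counts` (named per-sample vector), `group_means`
#'   (named vector, when `groupby` given) and `n_above_threshold`.
#' @export
per_sample_counts <- function(cohort, metadata, population = "patient",
                              groupby = NULL, threshold = NULL) {
  samples <- metadata$sample_id[metadata$population == population]
  counts <- setNames(integer(length(samples)), samples)
  inpop <- cohort[cohort$sample_id %in% samples, , drop = FALSE]
  if (nrow(inpop)) {
    tab <- table(inpop$sample_id)
    counts[names(tab)] <- as.integer(tab)
  }
  group_means <- NULL
  if (!is.null(groupby)) {
    if (!groupby %in% names(metadata)) {
      abort("unknown metadata field '%s'", groupby)
    }
    md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
    group_means <- tapply(counts, md[[groupby]], mean)
  }
  list(counts = counts,
       group_means = group_means,
       n_above_threshold = if (is.null(threshold)) NULL else
         sum(counts > threshold))
}
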