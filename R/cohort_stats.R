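permutation_result <- function(statistic_name, observed, n_permutations,
                               p_value, n_x, n_y) {
  structure(list(statistic_name = statistic_name, observed = observed,
                 n_permutations = as.integer(n_permutations),
                 p_value = p_value, n_x = n_x, n_y = n_y),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %.4g, p = %.4g (%d permutations; n = %d vs %d)\n",
              x$statistic_name, x$observed, x$p_value, x$n_permutations,
              x$n_x, x$n_y))
  invisible(x)
}

# two-sample KS statistic evaluated on a pooled sorted order; `ends` marks
# the last index of each tie group (the ECDF difference is only meaningful
# at distinct values)
ks_from_labels <- function(lab_sorted, nx, ny, ends) {
  d <- cumsum(ifelse(lab_sorted, 1 / nx, -1 / ny))
  max(abs(d[ends]))
}

#' Two-sample Kolmogorov-Smirnov permutation test
#'
#' Computes the two-sample KS statistic (maximal absolute difference of the
#' empirical CDFs, tie-aware) and an empirical p-value under `n_perm` random
#' relabelings of the pooled observations. The p-value uses the add-one
#' estimator `p = (1 + #(permuted >= observed)) / (1 + n_perm)`, so it is
#' never zero and is bounded below by `1/(n_perm + 1)`.
#'
#' @param x,y Numeric vectors (both non-empty), e.g. per-sample fusion
#'   counts of two populations.
#' @param n_perm Number of permutations (default 99999).
#' @param seed Optional integer seed; permutations are reproducible given a
#'   seed and do not disturb the caller's RNG stream.
#' @return A `permutation_result` with the observed statistic, permutation
#'   count, empirical p-value and group sizes.
#' @export
ks_permutation_test <- function(x, y, n_perm = 99999L, seed = NULL) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  ord <- order(pool)
  pool_sorted <- pool[ord]
  lab <- c(rep(TRUE, nx), rep(FALSE, ny))[ord]
  n <- nx + ny
  ends <- which(c(pool_sorted[-1] != pool_sorted[-n], TRUE))
  observed <- ks_from_labels(lab, nx, ny, ends)
  hits <- with_seed_or_not(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      ks_from_labels(lab[sample.int(n)], nx, ny, ends)
    }, numeric(1)) >= observed - 1e-12)
  })
  permutation_result("KS", observed, n_perm, (1 + hits) / (1 + n_perm), nx, ny)
}

#' Mean-difference permutation test
#'
#' Two-sided permutation test of the absolute difference of group means,
#' with the same add-one empirical p-value as [ks_permutation_test()]. Used
#' for subgroup burden contrasts: e.g. fusion counts of samples with versus
#' without an immunoglobulin fusion, IGH-fusion counts of FISH-translocated
#' versus other patients, or immunoglobulin-fusion counts of highly
#' hyperdiploid versus other patients.
#'
#' @inheritParams ks_permutation_test
#' @param n_perm Number of permutations (default 9999).
#' @return A `permutation_result`.
#' @export
mean_diff_permutation_test <- function(x, y, n_perm = 9999L, seed = NULL) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  total <- sum(pool)
  observed <- abs(mean(x) - mean(y))
  hits <- with_seed_or_not(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      s1 <- sum(pool[sample.int(nx + ny, nx)])
      abs(s1 / nx - (total - s1) / ny)
    }, numeric(1)) >= observed - 1e-12)
  })
  permutation_result("mean_difference", observed, n_perm,
                     (1 + hits) / (1 + n_perm), nx, ny)
}

#' Fusion burden versus a numeric covariate
#'
#' Spearman correlation between per-sample fusion counts and a numeric
#' covariate (e.g. age), with a two-sided permutation p-value on the
#' absolute correlation.
#'
#' @param counts Numeric vector of per-sample fusion counts.
#' @param covariate Numeric covariate, same length; missing values are
#'   dropped pairwise.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return A list with `rho`, `p_value`, `n`, and `undefined` (`TRUE` when
#'   the covariate or the counts are constant, in which case `rho` is `NA`).
#' @export
burden_vs_covariate <- function(counts, covariate, n_perm = 9999L,
                                seed = NULL) {
  stopifnot(length(counts) == length(covariate))
  ok <- is.finite(counts) & is.finite(covariate)
  counts <- counts[ok]; covariate <- covariate[ok]
  if (length(counts) < 3) abort("need the covariate for at least 3 samples")
  if (sd(covariate) == 0 || sd(counts) == 0) {
    warning("constant covariate or counts: correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(counts),
                undefined = TRUE))
  }
  rho <- cor(counts, covariate, method = "spearman")
  hits <- with_seed_or_not(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(counts, covariate[sample.int(length(covariate))],
              method = "spearman"))
    }, numeric(1)) >= abs(rho) - 1e-12)
  })
  list(rho = rho, p_value = (1 + hits) / (1 + n_perm), n = length(counts),
       undefined = FALSE)
}

#' Most recurrent fusion partner genes
#'
#' Ranks genes by the number of distinct samples in which they are involved
#' in a retained fusion (ties broken by total fusion count, then
#' alphabetically) and returns the top `n`.
#'
#' @param cohort Retained cohort fusion table.
#' @param n Number of genes to return (default 36).
#' @return Character vector of gene symbols.
#' @export
recurrent_partner_genes <- function(cohort, n = 36L) {
  genes <- c(cohort$gene5, cohort$gene3)
  samp <- c(cohort$sample_id, cohort$sample_id)
  if (length(genes) == 0) return(character())
  n_samples <- vapply(split(samp, genes), function(s) length(unique(s)),
                      integer(1))
  n_fusions <- vapply(split(genes, genes), length, integer(1))
  ord <- order(-n_samples, -n_fusions, names(n_samples))
  head(names(n_samples)[ord], n)
}

#' Fused-versus-unfused expression tests
#'
#' For each gene of interest, splits the expression matrix's samples into
#' those carrying at least one retained fusion involving the gene and the
#' rest, and runs a two-sided t-test on the log-normalized expression
#' values. P-values are adjusted for multiple testing across the testable
#' genes. Genes with fewer than `min_group` fused (or unfused) samples are
#' flagged untestable and excluded from the adjustment.
#'
#' @param cohort Retained cohort fusion table.
#' @param expr Genes x samples matrix of log-normalized expression
#'   ([read_expression_matrix()]).
#' @param genes Genes to test; defaults to the 36 most recurrent partner
#'   genes ([recurrent_partner_genes()]) intersected with the matrix rows.
#'   Supplying a gene absent from the matrix is an error.
#' @param alpha Adjusted-p significance cutoff (default 0.01).
#' @param method Multiple-testing adjustment, any [stats::p.adjust()] method
#'   (default Benjamini-Hochberg).
#' @param min_group Minimum group size for a gene to be testable.
#' @return A data.frame with one row per gene: group sizes and means,
#'   t statistic, raw and adjusted p, `significant`, `testable`.
#' @export
fused_expression_tests <- function(cohort, expr, genes = NULL, alpha = 0.01,
                                   method = "BH", min_group = 2L) {
  if (is.null(genes)) {
    genes <- intersect(recurrent_partner_genes(cohort, 36L), rownames(expr))
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort("gene(s) absent from the expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  samples <- colnames(expr)
  res <- do.call(rbind, lapply(genes, function(g) {
    fused <- intersect(samples,
                       unique(cohort$sample_id[cohort$gene5 == g |
                                                 cohort$gene3 == g]))
    unfused <- setdiff(samples, fused)
    testable <- length(fused) >= min_group && length(unfused) >= min_group
    if (testable) {
      tt <- t.test(expr[g, fused], expr[g, unfused], alternative = "two.sided")
      data.frame(gene = g, n_fused = length(fused), n_unfused = length(unfused),
                 mean_fused = unname(tt$estimate[1]),
                 mean_unfused = unname(tt$estimate[2]),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 testable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, n_fused = length(fused), n_unfused = length(unfused),
                 mean_fused = if (length(fused)) mean(expr[g, fused]) else NA_real_,
                 mean_unfused = if (length(unfused)) mean(expr[g, unfused]) else NA_real_,
                 t_statistic = NA_real_, p_value = NA_real_,
                 testable = FALSE, stringsAsFactors = FALSE)
    }
  }))
  res$p_adjusted <- NA_real_
  res$p_adjusted[res$testable] <- p.adjust(res$p_value[res$testable],
                                           method = method)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}
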