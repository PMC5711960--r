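## simulate_cohort() and its helpers ---------------------------------------

draw_burden <- function(n, mean, size) {
  1L + rnbinom(n, mu = mean - 1, size = size)
}

# a fresh (pool-free) Ig pair: random segment gene of the class, random
# non-Ig partner, random orientation
draw_fresh_ig_pair <- function(cls, nonig_symbols) {
  igg <- sample(ig_segment_genes()[[cls]], 1)
  partner <- sample(nonig_symbols, 1)
  if (runif(1) < 0.5) c(igg, partner) else c(partner, igg)
}

# a fresh non-Ig pair: same-chromosome with configured probability
draw_fresh_nonig_pair <- function(cfg, nonig_symbols, chrom_of, chrom_genes) {
  if (runif(1) < cfg$same_chr_fraction) {
    sizes <- vapply(chrom_genes, length, integer(1))
    chrom <- sample(names(chrom_genes)[sizes >= 2], 1,
                    prob = sizes[sizes >= 2])
    sample(chrom_genes[[chrom]], 2)
  } else {
    a <- sample(nonig_symbols, 1)
    b <- sample(nonig_symbols[chrom_of[nonig_symbols] != chrom_of[[a]]], 1)
    c(a, b)
  }
}

# compose one sample's true events (distinct ordered pairs, no same-family
# pair). The pool-versus-fresh split is decided per event *before* drawing,
# and a sample's pool pairs are drawn without replacement, so within-sample
# deduplication cannot shift the configured pool/fresh mixture.
sample_true_events <- function(sample_id, n_total, n_ig, phenotype, cfg,
                               pools, families, nonig_symbols, chrom_of,
                               chrom_genes) {
  if (n_total == 0) return(NULL)
  classes <- character(0)
  if (n_ig > 0) {
    classes <- ifelse(runif(n_ig) < cfg$ig_class_probs[["IGH"]], "IGH",
                      if (phenotype == "lambda") "IGL" else "IGK")
  }
  classes <- c(classes, rep("none", n_total - n_ig))

  pairs <- matrix(NA_character_, nrow = n_total, ncol = 2)
  seen <- character(0)
  # pool draws first, without replacement within the sample
  for (cls in unique(classes)) {
    at <- which(classes == cls)
    pool <- if (cls == "none") pools$nonig else pools$ig[[cls]]
    p_pool <- if (cls == "none") cfg$nonig_pool_fraction else
      1 - cfg$ig_fresh_fraction
    from_pool <- at[runif(length(at)) < p_pool]
    from_pool <- from_pool[seq_len(min(length(from_pool), nrow(pool)))]
    if (length(from_pool)) {
      rows <- sample.int(nrow(pool), length(from_pool), prob = pool$weight)
      pairs[from_pool, 1] <- pool$gene5[rows]
      pairs[from_pool, 2] <- pool$gene3[rows]
      seen <- c(seen, paste(pool$gene5[rows], pool$gene3[rows], sep = "\r"))
    }
  }
  # fresh draws for the rest, rejecting duplicates and same-family pairs
  for (i in which(is.na(pairs[, 1]))) {
    repeat {
      g <- if (classes[i] == "none") {
        draw_fresh_nonig_pair(cfg, nonig_symbols, chrom_of, chrom_genes)
      } else {
        draw_fresh_ig_pair(classes[i], nonig_symbols)
      }
      key <- paste(g[1], g[2], sep = "\r")
      if (key %in% seen) next
      if (shares_family(families, g[1], g[2])) next
      break
    }
    pairs[i, ] <- g
    seen <- c(seen, key)
  }
  data.frame(sample_id = sample_id,
             gene5 = pairs[, 1], gene3 = pairs[, 2],
             label = "true", ig_class = classes,
             homology_decoy = runif(n_total) < cfg$homology_decoy_frac,
             stringsAsFactors = FALSE)
}

# caller-specific false positives for one sample: pairs never shared with
# the other caller or with the sample's true/decoy events
sample_fp_events <- function(sample_id, n, label, taken, nonig_symbols) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      g <- sample(nonig_symbols, 2)
      key <- paste(g[1], g[2], sep = "\r")
      if (!key %in% taken) break
    }
    taken <- c(taken, key)
    rows[[i]] <- data.frame(sample_id = sample_id, gene5 = g[1], gene3 = g[2],
                            label = label, ig_class = "none",
                            homology_decoy = FALSE, stringsAsFactors = FALSE)
  }
  list(rows = if (n > 0) do.call(rbind, rows) else NULL, taken = taken)
}

sample_family_decoys <- function(sample_id, n, family_df, taken) {
  fams <- split(family_df$symbol, family_df$family_id)
  fams <- fams[vapply(fams, length, integer(1)) >= 2]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      members <- fams[[sample(length(fams), 1)]]
      g <- sample(members, 2)
      key <- paste(g[1], g[2], sep = "\r")
      if (!key %in% taken) break
    }
    taken <- c(taken, key)
    rows[[i]] <- data.frame(sample_id = sample_id, gene5 = g[1], gene3 = g[2],
                            label = "family_decoy", ig_class = "none",
                            homology_decoy = FALSE, stringsAsFactors = FALSE)
  }
  list(rows = if (n > 0) do.call(rbind, rows) else NULL, taken = taken)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# genomic breakpoint inside a gene, kept clear of contig edges
draw_breakpoint <- function(ann_row, chrom_lengths, margin) {
  lo <- max(ann_row$start, margin)
  hi <- min(ann_row$end, chrom_lengths[[ann_row$chrom]] - margin)
  as.integer(sample(lo:hi, 1))
}

# overwrite gene3's before-flank with a mutated copy of gene5's, so the two
# breakpoints share (flank_len - 2) of flank_len bases
plant_flank_homology <- function(genome, a5, bp5, a3, bp3, flank_len) {
  take <- function(ann, bp) {
    if (ann$strand == "+") {
      substring(genome[[ann$chrom]], bp - flank_len + 1, bp)
    } else {
      s <- substring(genome[[ann$chrom]], bp, bp + flank_len - 1)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
  }
  flank <- strsplit(take(a5, bp5), "")[[1]]
  mut <- sample(flank_len, 2)
  for (m in mut) flank[m] <- sample(setdiff(c("A", "C", "G", "T"), flank[m]), 1)
  flank <- paste(flank, collapse = "")
  if (a3$strand == "+") {
    substr(genome[[a3$chrom]], bp3 - flank_len + 1, bp3) <- flank
  } else {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(flank)))
    substr(genome[[a3$chrom]], bp3, bp3 + flank_len - 1) <- rc
  }
  genome
}

true_support <- function(n, cfg) {
  as.integer(3 + rnbinom(n, mu = cfg$support_mu, size = cfg$support_size))
}

#' Simulate a complete synthetic fusion cohort
#'
#' Generates, deterministically from the configuration (including its seed):
#' a toy genome and gene annotation, a gene-family table, both callers'
#' fusion reports for every sample, per-sample metadata, a patient
#' log-expression matrix, and a ground-truth table labelling every report
#' row as `true`, caller-specific false positive (`fp_a`/`fp_b`) or
#' `family_decoy`, with an additional flag for events whose breakpoint
#' flanks were rewritten to be homologous. True events appear in both
#' callers' reports (caller B with jittered breakpoints) with junction
#' support of at least 3 on each side; false positives appear in exactly one
#' caller's report.
#'
#' @param config A [sim_config()] (e.g. [study_preset()]).
#' @param dir Optional output directory; when given, all artifacts are
#'   written as plain-text files (`annotation.gtf`, `reference.fa`,
#'   `families.tsv`, `metadata.tsv`, `expression.tsv`, `truth.tsv`,
#'   `truth.json`, `chrom_lengths.tsv` and per-sample
#'   `reports/<sample>.<caller>.tsv` in each caller's native dialect).
#' @return An object of class `sim_cohort`: a list with the in-memory
#'   normalized tables (`calls_a`, `calls_b`), `annotation`, `reference`
#'   (a `DNAStringSet`), `chrom_lengths`, `families` (a
#'   [gene_family_table()]), `family_df`, `metadata`, `expression`,
#'   `truth`, `expr_effects`, `config` and (when written) `paths`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  if (!inherits(config, "sim_config")) abort("'config' must be a sim_config")
  sim <- withr::with_seed(as.integer(config$seed), build_sim(config))
  if (!is.null(dir)) sim <- write_sim_files(sim, dir)
  sim
}

build_sim <- function(cfg) {
  gen <- build_toy_genome(cfg)
  ann <- gen$annotation
  genome <- gen$genome
  family_df <- build_family_table(ann)
  families <- gene_family_table(family_df$symbol, family_df$family_id)
  pools <- build_pools(ann, families, cfg)

  nonig_symbols <- ann$symbol[!ann$is_ig]
  chrom_of <- setNames(ann$chrom, ann$symbol)
  chrom_genes <- split(nonig_symbols, chrom_of[nonig_symbols])
  ann_by_symbol <- ann[match(ann$symbol, ann$symbol), ]
  rownames(ann_by_symbol) <- ann$symbol
  margin <- cfg$flank_len + 2L

  ## ---- sample plan -------------------------------------------------------
  ids_p <- sprintf("P%03d", seq_len(cfg$n_patients))
  ids_c <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  phenotype <- c(sample(c("kappa", "lambda"), cfg$n_patients, replace = TRUE,
                        prob = c(cfg$kappa_fraction, 1 - cfg$kappa_fraction)),
                 sample(c("kappa", "lambda"), cfg$n_cell_lines, replace = TRUE))
  is_hmm <- c(runif(cfg$n_patients) < cfg$hmm_fraction,
              rep(FALSE, cfg$n_cell_lines))
  is_patient <- c(rep(TRUE, cfg$n_patients), rep(FALSE, cfg$n_cell_lines))
  ids <- c(ids_p, ids_c)

  truth <- list()
  for (i in seq_along(ids)) {
    if (is_patient[i]) {
      if (runif(1) < cfg$zero_fraction) next
      p_ig <- if (is_hmm[i]) cfg$p_ig_hmm else cfg$p_ig_other
      has_ig <- runif(1) < p_ig
      burden <- draw_burden(1, if (has_ig) cfg$burden_ig_mean else
        cfg$burden_nonig_mean, cfg$burden_dispersion)
    } else {
      has_ig <- runif(1) < cfg$cl_p_ig
      burden <- draw_burden(1, cfg$cl_burden_mean, cfg$cl_burden_dispersion)
    }
    n_ig <- if (has_ig) 1L + rbinom(1, burden - 1L, cfg$ig_extra_frac) else 0L
    truth[[ids[i]]] <- sample_true_events(
      ids[i], burden, n_ig, phenotype[i], cfg, pools, families,
      nonig_symbols, chrom_of, chrom_genes)
  }
  truth <- do.call(rbind, c(truth, list(NULL)))
  rownames(truth) <- NULL

  ## ---- decoys and caller-specific false positives ------------------------
  extras <- list()
  for (i in seq_along(ids)) {
    s <- ids[i]
    taken <- with(truth[truth$sample_id == s, , drop = FALSE],
                  paste(gene5, gene3, sep = "\r"))
    fd <- sample_family_decoys(s, rpois(1, cfg$family_decoy_rate), family_df,
                               taken)
    fa <- sample_fp_events(s, rpois(1, cfg$fp_rate_a), "fp_a", fd$taken,
                           nonig_symbols)
    fb <- sample_fp_events(s, rpois(1, cfg$fp_rate_b), "fp_b", fa$taken,
                           nonig_symbols)
    extras[[s]] <- rbind(fd$rows, fa$rows, fb$rows)
  }
  truth <- rbind(truth, do.call(rbind, c(extras, list(NULL))))
  rownames(truth) <- NULL

  ## ---- breakpoints and planted flank homology ----------------------------
  n_ev <- nrow(truth)
  truth$bp5 <- vapply(seq_len(n_ev), function(i) {
    draw_breakpoint(ann_by_symbol[truth$gene5[i], ], gen$chrom_lengths, margin)
  }, integer(1))
  truth$bp3 <- vapply(seq_len(n_ev), function(i) {
    draw_breakpoint(ann_by_symbol[truth$gene3[i], ], gen$chrom_lengths, margin)
  }, integer(1))
  for (i in which(truth$homology_decoy)) {
    genome <- plant_flank_homology(genome,
                                   ann_by_symbol[truth$gene5[i], ], truth$bp5[i],
                                   ann_by_symbol[truth$gene3[i], ], truth$bp3[i],
                                   cfg$flank_len)
  }

  ## ---- caller reports ----------------------------------------------------
  shared <- truth$label %in% c("true", "family_decoy")
  fp_support <- function(n) as.integer(1 + rpois(n, 2))
  jit <- function(bp, gene) {
    g <- ann_by_symbol[gene, ]
    lo <- pmax(g$start, margin)
    hi <- pmin(g$end, gen$chrom_lengths[g$chrom] - margin)
    as.integer(clamp(bp + round(rnorm(length(bp), 0, cfg$jitter_sd)), lo, hi))
  }
  mk_calls <- function(idx, caller, bp5, bp3, support) {
    g5 <- ann_by_symbol[truth$gene5[idx], ]
    g3 <- ann_by_symbol[truth$gene3[idx], ]
    data.frame(sample_id = truth$sample_id[idx], caller = caller,
               gene5 = truth$gene5[idx], chrom5 = g5$chrom, bp5 = bp5,
               strand5 = g5$strand,
               gene3 = truth$gene3[idx], chrom3 = g3$chrom, bp3 = bp3,
               strand3 = g3$strand,
               junction_pairs = support, stringsAsFactors = FALSE)
  }
  idx_a <- which(shared | truth$label == "fp_a")
  idx_b <- which(shared | truth$label == "fp_b")
  calls_a <- mk_calls(idx_a, "tophat", truth$bp5[idx_a], truth$bp3[idx_a],
                      ifelse(truth$label[idx_a] == "fp_a",
                             fp_support(length(idx_a)),
                             true_support(length(idx_a), cfg)))
  calls_b <- mk_calls(idx_b, "mapsplice",
                      jit(truth$bp5[idx_b], truth$gene5[idx_b]),
                      jit(truth$bp3[idx_b], truth$gene3[idx_b]),
                      ifelse(truth$label[idx_b] == "fp_b",
                             fp_support(length(idx_b)),
                             true_support(length(idx_b), cfg)))
  # MapSplice reports support split over two count columns
  calls_b$multiple_paired_read_count <- rbinom(nrow(calls_b),
                                               calls_b$junction_pairs, 0.3)
  calls_b$unique_paired_read_count <-
    calls_b$junction_pairs - calls_b$multiple_paired_read_count

  ## ---- metadata ----------------------------------------------------------
  per_sample_true <- table(factor(truth$sample_id[truth$label == "true"],
                                  levels = ids))
  has_igh <- ids %in% truth$sample_id[truth$label == "true" &
                                        truth$ig_class == "IGH"]
  fish <- ifelse(is_patient,
                 runif(length(ids)) < ifelse(has_igh, cfg$p_fish_given_igh,
                                             cfg$p_fish_no_igh), NA)
  burden_p <- as.integer(per_sample_true[ids_p])
  # age acts on the rank scale: burden is heavily right-skewed, and the
  # age effect is a monotone trend, not a linear-in-count one
  rk <- rank(burden_p, ties.method = "average")
  z <- if (sd(rk) > 0) (rk - mean(rk)) / sd(rk) else rep(0, length(rk))
  age_p <- round(cfg$age_mean + cfg$age_sd *
                   (cfg$age_burden_cor * z +
                      sqrt(1 - cfg$age_burden_cor^2) * rnorm(length(z))), 1)
  metadata <- data.frame(
    sample_id = ids,
    population = ifelse(is_patient, "patient", "cell_line"),
    light_chain = phenotype,
    ploidy_group = ifelse(is_patient,
                          ifelse(is_hmm, "high_hyperdiploid", "other"),
                          "unknown"),
    fish_translocation = fish,
    age = c(age_p, rep(NA_real_, cfg$n_cell_lines)),
    stringsAsFactors = FALSE
  )

  ## ---- expression (patients) ---------------------------------------------
  ptruth <- truth[truth$label == "true" & truth$sample_id %in% ids_p, ,
                  drop = FALSE]
  fused_genes <- unique(c(ptruth$gene5, ptruth$gene3))
  background <- sample(setdiff(ann$symbol, fused_genes),
                       min(cfg$n_expr_background,
                           length(setdiff(ann$symbol, fused_genes))))
  expr_genes <- c(fused_genes, background)
  effects <- setNames(numeric(length(expr_genes)), expr_genes)
  hit <- runif(length(fused_genes)) < cfg$expr_effect_prob
  effects[fused_genes[hit]] <- cfg$expr_effect
  if ("NSD2" %in% fused_genes) effects[["NSD2"]] <- 2 * cfg$expr_effect
  baseline <- setNames(rnorm(length(expr_genes), cfg$expr_baseline_mean,
                             cfg$expr_baseline_sd), expr_genes)
  expr <- matrix(rnorm(length(expr_genes) * length(ids_p), 0, cfg$expr_sd),
                 nrow = length(expr_genes),
                 dimnames = list(expr_genes, ids_p))
  expr <- expr + baseline
  for (g in fused_genes) {
    if (effects[[g]] == 0) next
    fused_in <- unique(ptruth$sample_id[ptruth$gene5 == g | ptruth$gene3 == g])
    expr[g, fused_in] <- expr[g, fused_in] + effects[[g]]
  }

  structure(list(
    config = cfg,
    annotation = ann,
    reference = Biostrings::DNAStringSet(unlist(genome)),
    chrom_lengths = gen$chrom_lengths,
    families = families,
    family_df = family_df,
    pools = pools,
    calls_a = calls_a,
    calls_b = calls_b,
    metadata = metadata,
    expression = expr,
    truth = truth,
    expr_effects = effects
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic fusion cohort: %d patients, %d cell lines, %d true events (%d report rows)\n",
              x$config$n_patients, x$config$n_cell_lines,
              sum(x$truth$label == "true"), nrow(x$calls_a) + nrow(x$calls_b)))
  invisible(x)
}

## File output --------------------------------------------------------------

write_sim_files <- function(sim, dir) {
  dir.create(file.path(dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    annotation = file.path(dir, "annotation.gtf"),
    reference = file.path(dir, "reference.fa"),
    families = file.path(dir, "families.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv"),
    truth_json = file.path(dir, "truth.json"),
    chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
    reports = file.path(dir, "reports")
  )
  ann <- sim$annotation
  gtf <- sprintf('%s\tfusionscape_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
                 ann$chrom, ann$start, ann$end, ann$strand, ann$symbol,
                 ann$symbol)
  writeLines(gtf, paths$annotation)
  Biostrings::writeXStringSet(sim$reference, paths$reference)
  write.table(sim$family_df, paths$families, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = rownames(sim$expression), sim$expression,
                         check.names = FALSE),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth_json, dataframe = "rows")
  write.table(data.frame(chrom = names(sim$chrom_lengths),
                         length = as.integer(sim$chrom_lengths)),
              paths$chrom_lengths, sep = "\t", quote = FALSE, row.names = FALSE)

  for (s in unique(c(sim$calls_a$sample_id, sim$calls_b$sample_id))) {
    a <- sim$calls_a[sim$calls_a$sample_id == s, , drop = FALSE]
    tophat <- data.frame(gene_1 = a$gene5, chromosome_1 = a$chrom5,
                         breakpoint_1 = a$bp5 - 1L, strand_1 = a$strand5,
                         gene_2 = a$gene3, chromosome_2 = a$chrom3,
                         breakpoint_2 = a$bp3 - 1L, strand_2 = a$strand3,
                         spanning_mate_pairs = a$junction_pairs)
    write.table(tophat, file.path(paths$reports, sprintf("%s.tophat.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    b <- sim$calls_b[sim$calls_b$sample_id == s, , drop = FALSE]
    mapsplice <- data.frame(gene_5p = b$gene5,
                            chrom_5p = sub("^chr", "", b$chrom5),
                            pos_5p = b$bp5, strand_5p = b$strand5,
                            gene_3p = b$gene3,
                            chrom_3p = sub("^chr", "", b$chrom3),
                            pos_3p = b$bp3, strand_3p = b$strand3,
                            multiple_paired_read_count = b$multiple_paired_read_count,
                            unique_paired_read_count = b$unique_paired_read_count)
    write.table(mapsplice,
                file.path(paths$reports, sprintf("%s.mapsplice.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sim$paths <- paths
  sim
}
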