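## Synthetic cohort generator ----------------------------------------------
##
## Builds a fully synthetic study: a toy genome + annotation, an HGNC-style
## gene-family table, two callers' fusion reports per sample (with
## caller-specific false positives, breakpoint jitter and planted decoys),
## sample metadata, a log-expression matrix, and a ground-truth label table
## covering every emitted report row.

zipf_weights <- function(k) {
  w <- 1 / seq_len(k)
  w / sum(w)
}

#' Simulation configuration
#'
#' Parameters of the synthetic fusion cohort. The burden model is a
#' zero-inflated, zero-truncated negative binomial: a patient is fusion-free
#' with probability `zero_fraction`; otherwise it carries an immunoglobulin
#' fusion with probability `p_ig_given_fusion` (reduced for highly
#' hyperdiploid samples) and draws its total burden from
#' `1 + NB(mean - 1, dispersion)` with an Ig-status-specific mean. Recurrent
#' structure comes from Zipf-weighted hotspot pools of ordered gene pairs;
#' events not drawn from a pool are fresh, mostly sample-specific pairs, a
#' configurable fraction of which join two genes on the same chromosome
#' (read-through-like). Caller noise consists of per-caller false-positive
#' calls (never shared between callers), breakpoint jitter on caller B, and
#' planted same-family and flank-homology decoys.
#'
#' @param n_patients,n_cell_lines Cohort sizes.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration (including this seed).
#' @param zero_fraction Probability a patient has no true fusion.
#' @param p_ig_given_fusion Marginal probability that a fusion-carrying
#'   patient has at least one immunoglobulin fusion.
#' @param hmm_fraction Fraction of patients that are highly hyperdiploid
#'   (>= 53 chromosomes); their Ig probability is `p_ig_hmm`.
#' @param p_ig_hmm Ig probability for highly hyperdiploid patients; the
#'   probability for the remaining patients is solved so the marginal
#'   `p_ig_given_fusion` holds.
#' @param burden_ig_mean,burden_nonig_mean Mean total burden of
#'   fusion-carrying patients with / without an Ig fusion.
#' @param burden_dispersion Negative-binomial size parameter (small values
#'   give the heavy right tail seen in patients).
#' @param ig_extra_frac Probability that each additional fusion of an
#'   Ig-positive patient is itself an Ig fusion.
#' @param ig_class_probs Probability that an Ig fusion involves the
#'   heavy-chain locus; otherwise it involves the patient's light chain.
#' @param kappa_fraction Fraction of kappa light-chain phenotypes.
#' @param ig_fresh_fraction Probability an Ig fusion takes a fresh partner
#'   instead of a hotspot-pool pair ([study_preset()] solves this to hit the
#'   target unique-pair Ig share).
#' @param ig_pool_sizes Named vector: hotspot-pool sizes per Ig class.
#' @param nonig_pool_size,nonig_pool_fraction Size of the non-Ig recurrent
#'   pool and the probability a non-Ig event is drawn from it.
#' @param same_chr_fraction Fraction of fresh non-Ig events joining two
#'   genes on the same chromosome.
#' @param support_mu,support_size Negative-binomial parameters of the
#'   junction-pair support of true events (support is `3 + NB`, so true
#'   events always pass the read-support filter).
#' @param jitter_sd SD (bases) of caller B's breakpoint jitter.
#' @param fp_rate_a,fp_rate_b Poisson rates of caller-specific false calls
#'   per sample; their support is `1 + Poisson(2)`.
#' @param family_decoy_rate Poisson rate per sample of same-family decoy
#'   pairs (reported by both callers with passing support).
#' @param homology_decoy_frac Fraction of true events whose breakpoint
#'   flanks are rewritten to share 18 of 20 bases.
#' @param cl_burden_mean,cl_burden_dispersion,cl_p_ig Cell-line burden model
#'   (all cell lines have at least one fusion).
#' @param p_fish_given_igh,p_fish_no_igh Probability of a FISH-detected
#'   translocation flag given presence/absence of an IGH fusion.
#' @param age_mean,age_sd,age_burden_cor Patient age distribution and its
#'   correlation with fusion burden.
#' @param expr_effect,expr_effect_prob,expr_sd,expr_baseline_mean,expr_baseline_sd
#'   Expression model: per-gene baselines are `N(expr_baseline_mean,
#'   expr_baseline_sd)`; a gene receives a `+expr_effect` log-unit shift in
#'   fused samples with probability `expr_effect_prob`; residual SD is
#'   `expr_sd`.
#' @param n_expr_background Unfused background genes added to the matrix.
#' @param genes_per_chrom Baseline gene count per toy chromosome (scaled by
#'   per-chromosome density multipliers spanning a 3x range).
#' @param flank_len Flank length used when planting homology decoys.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 255L, n_cell_lines = 71L, seed = 1L,
                       zero_fraction = 0.118,
                       p_ig_given_fusion = 0.5363,
                       hmm_fraction = 0.2, p_ig_hmm = 0.25,
                       burden_ig_mean = 8.3, burden_nonig_mean = 3.8,
                       burden_dispersion = 0.9,
                       ig_extra_frac = 0.25,
                       ig_class_probs = c(IGH = 0.30),
                       kappa_fraction = 0.68,
                       ig_fresh_fraction = 0.45,
                       ig_pool_sizes = c(IGH = 20L, IGK = 30L, IGL = 6L),
                       nonig_pool_size = 96L, nonig_pool_fraction = 0.75,
                       same_chr_fraction = 0.542,
                       support_mu = 30, support_size = 0.6,
                       jitter_sd = 5,
                       fp_rate_a = 8, fp_rate_b = 3,
                       family_decoy_rate = 0.3,
                       homology_decoy_frac = 0.05,
                       cl_burden_mean = 6.1, cl_burden_dispersion = 3,
                       cl_p_ig = 0.591,
                       p_fish_given_igh = 0.7, p_fish_no_igh = 0.15,
                       age_mean = 56.6, age_sd = 5, age_burden_cor = 0.3,
                       expr_effect = 2, expr_effect_prob = 0.6, expr_sd = 1,
                       expr_baseline_mean = 8, expr_baseline_sd = 1.5,
                       n_expr_background = 100L,
                       genes_per_chrom = 38L,
                       flank_len = 20L) {
  cfg <- as.list(environment())
  fracs <- c("zero_fraction", "p_ig_given_fusion", "hmm_fraction", "p_ig_hmm",
             "ig_extra_frac", "kappa_fraction", "ig_fresh_fraction",
             "nonig_pool_fraction", "same_chr_fraction",
             "homology_decoy_frac", "cl_p_ig", "p_fish_given_igh",
             "p_fish_no_igh", "expr_effect_prob")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort("'%s' must be in [0, 1]", f)
  }
  if (n_patients < 1 || n_cell_lines < 1) abort("cohort sizes must be >= 1")
  if (burden_ig_mean <= 1 || burden_nonig_mean <= 1 || cl_burden_mean <= 1) {
    abort("burden means must exceed 1 (burden is 1 + negative binomial)")
  }
  # marginal Ig probability must be attainable given the hyperdiploid subgroup
  p_other <- (p_ig_given_fusion - hmm_fraction * p_ig_hmm) / (1 - hmm_fraction)
  if (is.nan(p_other) || p_other < 0 || p_other > 1) {
    abort("infeasible config: p_ig for non-hyperdiploid patients would be %.3f",
          p_other)
  }
  cfg$p_ig_other <- p_other
  structure(cfg, class = "sim_config")
}

## Expected unique-pair bookkeeping (shared by the preset solver) -----------

# expected distinct pairs drawn from a Zipf-weighted pool given n draws
expected_pool_used <- function(n_draws, pool_size) {
  sum(1 - exp(-n_draws * zipf_weights(pool_size)))
}

expected_event_counts <- function(cfg) {
  n_fus <- cfg$n_patients * (1 - cfg$zero_fraction)
  n_ig_pos <- n_fus * cfg$p_ig_given_fusion
  e_ig <- n_ig_pos * (1 + cfg$ig_extra_frac * (cfg$burden_ig_mean - 1))
  e_nonig <- n_ig_pos * (1 - cfg$ig_extra_frac) * (cfg$burden_ig_mean - 1) +
    n_fus * (1 - cfg$p_ig_given_fusion) * cfg$burden_nonig_mean
  list(ig = e_ig, nonig = e_nonig)
}

expected_ig_unique_share <- function(cfg, fresh_fraction) {
  ev <- expected_event_counts(cfg)
  p_igh <- cfg$ig_class_probs[["IGH"]]
  class_probs <- c(IGH = p_igh,
                   IGK = (1 - p_igh) * cfg$kappa_fraction,
                   IGL = (1 - p_igh) * (1 - cfg$kappa_fraction))
  uniq_ig <- 0
  for (cls in names(class_probs)) {
    n_c <- ev$ig * class_probs[[cls]]
    uniq_ig <- uniq_ig + n_c * fresh_fraction +
      expected_pool_used(n_c * (1 - fresh_fraction), cfg$ig_pool_sizes[[cls]])
  }
  uniq_nonig <- ev$nonig * (1 - cfg$nonig_pool_fraction) +
    expected_pool_used(ev$nonig * cfg$nonig_pool_fraction, cfg$nonig_pool_size)
  uniq_ig / (uniq_ig + uniq_nonig)
}

#' Study-calibrated simulation preset
#'
#' Returns a [sim_config()] whose parameters target the printed cohort
#' statistics of a myeloma fusion-landscape study: mean patient fusion
#' burden 5.5, 11.8% fusion-free patients, 47.3% of patients with an
#' immunoglobulin fusion, burden means of 8.3 versus 3.8 for patients with
#' versus without an Ig fusion (conditional on having one), an
#' immunoglobulin share of 36% of unique fusion pairs, kappa-dominated
#' light-chain involvement, and 255 patients plus 71 cell lines. The
#' fresh-versus-hotspot mixing fraction of Ig events is solved numerically
#' so the expected unique-pair Ig share equals the target.
#'
#' @param n_patients,n_cell_lines Cohort sizes.
#' @param seed Integer seed stored in the configuration.
#' @return A `sim_config` whose `targets` attribute documents the cohort
#'   statistics the preset aims at.
#' @export
study_preset <- function(n_patients = 255L, n_cell_lines = 71L, seed = 1L) {
  cfg <- sim_config(n_patients = n_patients, n_cell_lines = n_cell_lines,
                    seed = seed)
  f <- uniroot(function(x) expected_ig_unique_share(cfg, x) - 0.36,
               lower = 0.02, upper = 0.95, tol = 1e-6)$root
  cfg$ig_fresh_fraction <- f
  attr(cfg, "targets") <- list(
    burden_mean = 5.5,
    zero_fraction = 0.118,
    pct_samples_with_ig_fusion = 47.3,
    ig_unique_share = 36,
    burden_ig_mean = 8.3,
    burden_nonig_mean = 3.8
  )
  cfg
}

## Toy genome ---------------------------------------------------------------

# special gene placements: symbol -> chromosome; order within a chromosome
# follows this list
special_genes <- function() {
  list(chr14 = c("IGHM", "IGHG1", "IGHA1"),
       chr2 = c("IGKC", "IGKV1", "IGKV2"),
       chr22 = c("IGLC1", "IGLJ1"),
       chr4 = c("NSD2", "FGFR3"),
       chr6 = c("TXNDC5", "HIST1H2BC", "HIST1H2BD", "HIST1H2BE"),
       chr15 = c("B2M"),
       chr19 = c("JUND", "TPM4", "ISYNA1", "CSNK1G2", "OAZ1"),
       chr1 = c("JUN"),
       chr11 = c("CCND1", "IGHMBP2"),
       chr16 = c("WWOX"),
       chr12 = c("UBC"),
       chr7 = c("ACTB", "MAFK"))
}

ig_segment_genes <- function() {
  list(IGH = c("IGHM", "IGHG1", "IGHA1"),
       IGK = c("IGKC", "IGKV1", "IGKV2"),
       IGL = c("IGLC1", "IGLJ1"))
}

# per-chromosome gene-density multipliers spanning a ~3x range; chr19 is the
# high-density analog, the Ig chromosomes are ordinary
chrom_density_multipliers <- function() {
  mult <- rep(c(0.8, 1.0, 1.2, 1.5), length.out = 22)
  names(mult) <- paste0("chr", 1:22)
  mult["chr19"] <- 2.4
  mult["chr17"] <- 0.9
  mult
}

build_toy_genome <- function(cfg) {
  mult <- chrom_density_multipliers()
  specials <- special_genes()
  bases <- c("A", "C", "G", "T")
  ann <- list()
  seqs <- character(0)
  for (chrom in names(mult)) {
    n_genes <- max(4L, round(cfg$genes_per_chrom * mult[[chrom]]))
    n_genes <- max(n_genes, length(specials[[chrom]] %||% character()) + 2L)
    len <- sample(800:1600, n_genes, replace = TRUE)
    # fixed genomic footprint per gene on each chromosome, so gene density
    # (genes per Mb) genuinely spans the configured multiplier range
    footprint <- round(4500 / mult[[chrom]])
    gap <- pmax(150L, footprint - len + sample(-200:200, n_genes, replace = TRUE))
    start <- 2000L + cumsum(c(0L, (len + gap)[-n_genes]))
    end <- start + len - 1L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    sym <- sprintf("%s_G%03d", sub("^chr", "C", chrom), seq_len(n_genes))
    sp <- specials[[chrom]]
    if (!is.null(sp)) {
      # drop specials into the middle of the chromosome
      at <- seq(floor(n_genes / 2) - floor(length(sp) / 2), length.out = length(sp))
      sym[at] <- sp
    }
    ann[[chrom]] <- data.frame(symbol = sym, chrom = chrom, start = start,
                               end = end, strand = strand,
                               stringsAsFactors = FALSE)
    chrom_len <- end[n_genes] + 5000L
    seqs[[chrom]] <- paste(sample(bases, chrom_len, replace = TRUE),
                           collapse = "")
  }
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL
  ann$ig_class <- classify_ig_symbol(ann$symbol)
  ann$is_ig <- ann$ig_class != "none"
  list(annotation = ann, genome = seqs,
       chrom_lengths = setNames(nchar(seqs), names(seqs)))
}

build_family_table <- function(annotation) {
  sym <- c("HIST1H2BC", "HIST1H2BD", "HIST1H2BE")
  fam <- rep("FAM_HIST1H2B", 3)
  pool <- annotation$symbol[!annotation$is_ig &
                              !annotation$symbol %in% unlist(special_genes())]
  extra <- sample(pool, 8 * 4)
  sym <- c(sym, extra)
  fam <- c(fam, rep(sprintf("FAM%03d", 1:8), each = 4))
  data.frame(symbol = sym, family_id = fam, stringsAsFactors = FALSE)
}

# fixed ordered-pair hotspot pools with Zipf weights
build_pools <- function(annotation, families, cfg) {
  segs <- ig_segment_genes()
  nonig <- annotation$symbol[!annotation$is_ig]
  named_partners <- list(
    IGH = c("NSD2", "B2M", "TXNDC5", "WWOX", "JUND", "JUN"),
    IGK = c("B2M", "JUND", "JUN", "TXNDC5", "TPM4"),
    IGL = c("TXNDC5", "JUN")
  )
  ig_pool <- list()
  for (cls in names(segs)) {
    k <- cfg$ig_pool_sizes[[cls]]
    partners <- named_partners[[cls]]
    if (length(partners) < k) {
      partners <- c(partners,
                    sample(setdiff(nonig, partners), k - length(partners)))
    }
    partners <- partners[seq_len(k)]
    igg <- sample(segs[[cls]], k, replace = TRUE)
    ig_first <- runif(k) < 0.5
    ig_pool[[cls]] <- data.frame(
      gene5 = ifelse(ig_first, igg, partners),
      gene3 = ifelse(ig_first, partners, igg),
      weight = zipf_weights(k), stringsAsFactors = FALSE)
  }
  # non-Ig pool: mostly cross-chromosome pairs, never same-family
  k <- cfg$nonig_pool_size
  g5 <- character(k); g3 <- character(k)
  chrom_of <- setNames(annotation$chrom, annotation$symbol)
  i <- 1L
  while (i <= k) {
    a <- sample(nonig, 1)
    b <- if (runif(1) < 0.3) {
      cand <- nonig[chrom_of[nonig] == chrom_of[[a]] & nonig != a]
      if (length(cand)) sample(cand, 1) else sample(setdiff(nonig, a), 1)
    } else sample(setdiff(nonig, a), 1)
    if (shares_family(families, a, b)) next
    if (any(g5 == a & g3 == b, na.rm = TRUE)) next
    g5[i] <- a; g3[i] <- b; i <- i + 1L
  }
  nonig_pool <- data.frame(gene5 = g5, gene3 = g3, weight = zipf_weights(k),
                           stringsAsFactors = FALSE)
  list(ig = ig_pool, nonig = nonig_pool)
}
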