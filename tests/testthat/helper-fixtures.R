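# Hand-built fixtures shared across test files. Everything is generated in
# code; no binary data.

toy_annotation <- function() {
  data.frame(
    symbol = c("GENEA", "GENEB", "GENEC", "GENED", "IGHG1", "NSD2",
               "HIST1H2BC", "HIST1H2BD"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr14", "chr4", "chr6", "chr6"),
    start = c(10000L, 30000L, 20000000L, 10000L, 5000L, 5000L, 1000L, 9000L),
    end = c(20000L, 40000L, 20100000L, 20000L, 9000L, 9000L, 3000L, 11000L),
    strand = c("+", "-", "+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE
  ) -> ann
  ann$ig_class <- classify_ig_symbol(ann$symbol)
  ann$is_ig <- ann$ig_class != "none"
  ann
}

toy_families <- function() {
  gene_family_table(c("HIST1H2BC", "HIST1H2BD", "GENEA", "GENEA"),
                    c("FAM_H2B", "FAM_H2B", "FAM_X", "FAM_Y"))
}

# a deterministic 300-base toy contig whose bases we can index by hand
toy_reference <- function() {
  set.seed(424242)
  seqs <- c(
    chrT = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = ""),
    chrU = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  )
  Biostrings::DNAStringSet(seqs)
}

# quick constructor for normalized fusion-call rows
make_calls <- function(sample_id, gene5, gene3, junction_pairs,
                       caller = "tophat", bp5 = 1000L, bp3 = 2000L,
                       chrom5 = "chr1", chrom3 = "chr2",
                       strand5 = "+", strand3 = "+") {
  data.frame(sample_id = sample_id, caller = caller,
             gene5 = gene5, chrom5 = chrom5, bp5 = as.integer(bp5),
             strand5 = strand5,
             gene3 = gene3, chrom3 = chrom3, bp3 = as.integer(bp3),
             strand3 = strand3,
             junction_pairs = as.integer(junction_pairs),
             stringsAsFactors = FALSE)
}

# quick constructor for consensus rows with sensible defaults
make_consensus <- function(sample_id, gene5, gene3, jpA = 10L, jpB = 10L,
                           chrom5 = "chr1", bp5 = 1000L, strand5 = "+",
                           chrom3 = "chr2", bp3 = 2000L, strand3 = "+") {
  data.frame(sample_id = sample_id, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, bp5 = as.integer(bp5), strand5 = strand5,
             chrom3 = chrom3, bp3 = as.integer(bp3), strand3 = strand3,
             junction_pairs_A = as.integer(jpA),
             junction_pairs_B = as.integer(jpB),
             passed_support_filter = NA, passed_family_filter = NA,
             homology_escore = NA_real_,
             is_ig = NA, ig_class = NA_character_,
             is_recurrent = NA, is_same_chr_lt10Mb = NA,
             stringsAsFactors = FALSE)
}

# small, fast simulation configuration (light genome, small cohort)
small_config <- function(seed, n_patients = 12L, ...) {
  sim_config(n_patients = n_patients, n_cell_lines = 4L, seed = seed,
             genes_per_chrom = 12L, ...)
}

# run the consensus + filtering stages of the pipeline on a simulated cohort
run_pipeline <- function(sim) {
  cons <- suppressWarnings(
    intersect_cohort(sim$calls_a, sim$calls_b, sim$metadata))
  cons <- filter_gene_family(filter_read_support(cons), sim$families)
  classify_fusions(retained_fusions(cons), sim$annotation)
}

pair_key <- function(df) paste(df$sample_id, df$gene5, df$gene3)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- independent brute-force local alignment oracle -----------------------
# global affine-gap alignment score of two (short) strings; a gap of length
# L costs open + ext * L
nw_affine_global <- function(a, b, match, mismatch, open, ext) {
  s1 <- strsplit(a, "")[[1]]; s2 <- strsplit(b, "")[[1]]
  n <- length(s1); m <- length(s2)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (s1[i] == "N" || s2[j] == "N") 0 else
        if (s1[i] == s2[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive local score: best global score over all substring pairs
brute_local_score <- function(a, b, params) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sa <- substring(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      sc <- nw_affine_global(sa, substring(b, j1, j2),
                             params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
      if (sc > best) best <- sc
    }
  }
  best
}
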