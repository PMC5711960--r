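test_that("identical configurations produce byte-identical outputs", {
  cfg <- small_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(zero_fraction = 1.2), "zero_fraction")
  expect_error(sim_config(n_patients = 0), "cohort sizes")
  expect_error(sim_config(burden_ig_mean = 0.5), "burden means")
  # marginal Ig probability unattainable given the hyperdiploid subgroup
  expect_error(sim_config(p_ig_given_fusion = 0.9, hmm_fraction = 0.5,
                          p_ig_hmm = 0), "infeasible")
})

test_that("without caller noise the pipeline returns exactly the planted events", {
  sim <- simulate_cohort(small_config(seed = 15, fp_rate_a = 0, fp_rate_b = 0,
                                      family_decoy_rate = 0,
                                      homology_decoy_frac = 0))
  kept <- run_pipeline(sim)
  truth <- sim$truth[sim$truth$label == "true", ]
  expect_setequal(pair_key(kept), pair_key(truth))
  expect_equal(nrow(kept), nrow(truth))
})

test_that("truth labels cover every emitted report row, and callers share only true events", {
  sim <- simulate_cohort(small_config(seed = 25))
  tkey <- pair_key(sim$truth)
  expect_true(all(pair_key(sim$calls_a) %in% tkey))
  expect_true(all(pair_key(sim$calls_b) %in% tkey))
  lab <- setNames(sim$truth$label, tkey)
  expect_true(all(lab[pair_key(sim$calls_a)] %in%
                    c("true", "family_decoy", "fp_a")))
  expect_true(all(lab[pair_key(sim$calls_b)] %in%
                    c("true", "family_decoy", "fp_b")))
  # shared events appear once per caller; FPs only in their own caller
  both <- intersect(pair_key(sim$calls_a), pair_key(sim$calls_b))
  expect_setequal(both, tkey[sim$truth$label %in% c("true", "family_decoy")])
})

test_that("true events always satisfy the read-support minimum in both callers", {
  sim <- simulate_cohort(small_config(seed = 35))
  shared <- pair_key(sim$truth)[sim$truth$label %in% c("true", "family_decoy")]
  expect_true(all(
    sim$calls_a$junction_pairs[pair_key(sim$calls_a) %in% shared] >= 3))
  expect_true(all(
    sim$calls_b$junction_pairs[pair_key(sim$calls_b) %in% shared] >= 3))
})

test_that("planted homologous flanks score far below unrelated flanks", {
  sim <- simulate_cohort(small_config(seed = 45, n_patients = 40L,
                                      homology_decoy_frac = 0.2))
  kept <- run_pipeline(sim)
  scored <- score_homology(kept, sim$reference)
  decoy_keys <- pair_key(sim$truth)[sim$truth$homology_decoy]
  is_decoy <- pair_key(scored) %in% decoy_keys
  expect_gt(sum(is_decoy), 3)
  expect_lt(max(scored$homology_escore[is_decoy]),
            median(scored$homology_escore[!is_decoy]))
})

test_that("the written artifacts are readable through the package's own readers", {
  d <- withr::local_tempdir()
  sim <- simulate_cohort(small_config(seed = 55), dir = d)
  ann <- read_gene_annotation(file.path(d, "annotation.gtf"))
  expect_setequal(ann$symbol, sim$annotation$symbol)
  fam <- read_gene_families(file.path(d, "families.tsv"))
  expect_true(shares_family(fam, "HIST1H2BC", "HIST1H2BD"))
  meta <- read_sample_metadata(file.path(d, "metadata.tsv"))
  expect_equal(nrow(meta), nrow(sim$metadata))
  expr <- read_expression_matrix(file.path(d, "expression.tsv"))
  expect_equal(dim(expr), dim(sim$expression))
  s <- sim$metadata$sample_id[1]
  a <- read_caller_report(file.path(d, "reports", paste0(s, ".tophat.tsv")),
                          "tophat", sample_id = s)
  am <- sim$calls_a[sim$calls_a$sample_id == s, names(a)]
  expect_setequal(paste(a$gene5, a$gene3, a$bp5, a$junction_pairs),
                  paste(am$gene5, am$gene3, am$bp5, am$junction_pairs))
  b <- read_caller_report(file.path(d, "reports", paste0(s, ".mapsplice.tsv")),
                          "mapsplice", sample_id = s)
  bm <- sim$calls_b[sim$calls_b$sample_id == s, names(b)]
  expect_setequal(paste(b$gene5, b$gene3, b$bp5, b$junction_pairs),
                  paste(bm$gene5, bm$gene3, bm$bp5, bm$junction_pairs))
})

test_that("a planted monotone age effect on burden is recovered", {
  sim <- simulate_cohort(small_config(seed = 65, n_patients = 150L,
                                      age_burden_cor = 0.5))
  kept <- run_pipeline(sim)
  pc <- per_sample_counts(kept, sim$metadata, "patient")
  md <- sim$metadata[match(names(pc$counts), sim$metadata$sample_id), ]
  bc <- burden_vs_covariate(pc$counts, md$age, n_perm = 999, seed = 1)
  expect_gt(bc$rho, 0.2)
  expect_lt(bc$p_value, 0.05)
})

test_that("the study preset documents its cohort targets and stays near them", {
  cfg <- study_preset(seed = 3)
  tg <- attr(cfg, "targets")
  expect_equal(tg$burden_mean, 5.5)
  expect_equal(tg$zero_fraction, 0.118)
  expect_equal(tg$ig_unique_share, 36)
  expect_equal(c(tg$burden_ig_mean, tg$burden_nonig_mean), c(8.3, 3.8))
  sim <- simulate_cohort(cfg)
  true_p <- sim$truth[sim$truth$label == "true" &
                        grepl("^P", sim$truth$sample_id), ]
  counts <- table(factor(true_p$sample_id,
                         levels = sprintf("P%03d", 1:cfg$n_patients)))
  # single-seed check at 3 sampling standard errors
  se_mean <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - tg$burden_mean), 3 * se_mean)
  se_zero <- sqrt(0.118 * 0.882 / length(counts))
  expect_lt(abs(mean(counts == 0) - tg$zero_fraction), 3 * se_zero)
})
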