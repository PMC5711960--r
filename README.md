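# fusionscape

Consensus calling, filtering and cohort landscape statistics for expressed
fusion genes detected from bulk RNA-seq.

## What problem this solves

Split-read fusion callers have high, largely caller-specific false-positive
rates. A standard conservative design — used in studies of the expressed
fusion landscape of multiple myeloma, where the immunoglobulin loci (IGH,
14q32; kappa, 2p11; lambda, 22q11) dominate the picture — is to run two
callers and keep only events both report. `fusionscape` implements
everything downstream of the callers, for analysts post-processing fusion
reports into cohort-level results:

* **Normalization** of two report dialects (TopHat-Fusion-style,
  MapSplice-style) to a common schema: 1-based breakpoints, harmonized
  chromosome names, one junction-spanning read-pair count per caller
  (summing MapSplice's `multiple_paired_read_count` and
  `unique_paired_read_count`), alias resolution, per-pair collapsing.
* **Consensus**: the orientation-aware per-sample intersection — a fusion is
  validated when both callers report the same ordered (5′ gene, 3′ gene)
  pair, breakpoint disagreements notwithstanding. `IGHM–NSD2` and
  `NSD2–IGHM` are distinct events.
* **Filtering**: junction support ≥ 3 read pairs in *each* caller; removal
  of fusions whose partners share an HGNC gene family (paralog artifacts).
  Removed events are flagged, not deleted.
* **Breakpoint-flank homology**: for every event, the 20 bp flanks on each
  side of both breakpoints are cross-aligned (Smith–Waterman, +5/−4, affine
  gaps 12 + 4L) and summarized as `min(E_before, E_after)` with
  `E = K·m·n·exp(−λS)` — a small E-score marks a likely alignment artifact
  between homologous regions.
* **Landscape statistics**: unique/recurrent pair decomposition
  (Ig | recurrent non-Ig | others, with the same-chromosome < 10 Mb
  read-through share), per-sample burden, per-gene involvement, Ig class
  splits, and the per-chromosome fusion-count versus gene-density (genes/Mb)
  Pearson correlation with intra-chromosomal double counting.
* **Inference**: permutation tests (two-sample Kolmogorov–Smirnov, 99,999
  permutations; absolute mean difference, 9,999) with add-one empirical
  p-values; Spearman burden–covariate tests; fused-versus-unfused two-sided
  t-tests on log-expression for the 36 most recurrent partner genes with
  Benjamini–Hochberg adjustment.
* **Synthetic cohorts**: `simulate_cohort()` generates a complete study —
  toy genome, GTF, FASTA, both callers' reports with jitter/false
  positives/planted decoys, metadata, expression matrix and ground-truth
  labels — and `study_preset()` pins it to the cohort statistics of a
  255-patient / 71-cell-line myeloma study (mean burden 5.5, 11.8%
  fusion-free patients, 36% Ig share of unique pairs, burden 8.3 vs 3.8 for
  Ig versus non-Ig carriers).

## Worked example

```r
library(fusionscape)

cfg  <- study_preset(seed = 1)
sim  <- simulate_cohort(cfg)            # or read real reports with read_caller_report()
cons <- intersect_cohort(sim$calls_a, sim$calls_b, sim$metadata)
cons <- filter_gene_family(filter_read_support(cons), sim$families)
kept <- classify_fusions(retained_fusions(cons), sim$annotation)

summarize_landscape(kept, sim$metadata, "patient")
#> Fusion landscape (patient, 255 samples)
#>   fusions: 1448 total, 591 unique pairs
#>   unique-pair decomposition: Ig 38.1% | recurrent non-Ig 14.6% | others 47.4% (same-chr<10Mb: 52.1% of others)
#>   samples with >=1 Ig fusion: 49.0%
#>   mean fusions per sample: 5.68
```

1448 consensus fusions survive filtering, collapsing to 591 distinct
ordered gene pairs; 38% of those involve an immunoglobulin locus, about
half the patients carry at least one Ig fusion, and half of the
non-recurrent, non-Ig pairs join genes less than 10 Mb apart on one
chromosome (read-through candidates). Subgroup burden contrast:

```r
counts <- summarize_landscape(kept, sim$metadata, "patient")$per_sample_counts
igpos  <- unique(kept$sample_id[kept$is_ig %in% TRUE])
x <- counts[names(counts) %in% igpos & counts > 0]
y <- counts[!names(counts) %in% igpos & counts > 0]
mean_diff_permutation_test(x, y, n_perm = 9999, seed = 2)
#> Permutation test (mean_difference): observed = 5.356, p = 0.0001 (9999 permutations; n = 125 vs 100)
```

Patients carrying an Ig fusion have on average ~5.4 more fusions than
fusion-positive patients without one; no permuted relabeling reached the
observed contrast.

## Documentation

The methods vignette (`vignettes/fusion-landscape-methods.Rmd`) describes
the model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical choices and limitations.
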