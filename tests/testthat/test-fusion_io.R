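write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

test_that("mapsplice reports sum the two paired-read count columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_5p = "A", chrom_5p = "1", pos_5p = 100,
                       strand_5p = "+", gene_3p = "B", chrom_3p = "2",
                       pos_3p = 200, strand_3p = "-",
                       multiple_paired_read_count = 1,
                       unique_paired_read_count = 2), f)
  calls <- read_caller_report(f, "mapsplice", sample_id = "s1")
  expect_equal(calls$junction_pairs, 3L)
  expect_equal(calls$chrom5, "chr1")  # bare names get the chr prefix
  expect_equal(calls$bp5, 100L)       # already 1-based
})

test_that("tophat reports map the spanning-mate field and convert 0-based coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_1 = "A", chromosome_1 = "chr1", breakpoint_1 = 99,
                       strand_1 = "+", gene_2 = "B", chromosome_2 = "chr2",
                       breakpoint_2 = 199, strand_2 = "-",
                       spanning_mate_pairs = 7), f)
  calls <- read_caller_report(f, "tophat", sample_id = "s1")
  expect_equal(calls$junction_pairs, 7L)
  expect_equal(calls$bp5, 100L)
  expect_equal(calls$bp3, 200L)
})

test_that("empty report files give an empty call table, not an error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_equal(nrow(read_caller_report(f, "tophat", sample_id = "s1")), 0L)
  writeLines(paste(c("gene_1", "chromosome_1", "breakpoint_1", "strand_1",
                     "gene_2", "chromosome_2", "breakpoint_2", "strand_2",
                     "spanning_mate_pairs"), collapse = "\t"), f)
  expect_equal(nrow(read_caller_report(f, "tophat", sample_id = "s1")), 0L)
})

test_that("a missing mandatory column is reported by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_1 = "A", chromosome_1 = "chr1", breakpoint_1 = 99,
                       strand_1 = "+", gene_2 = "B", chromosome_2 = "chr2",
                       breakpoint_2 = 199, strand_2 = "-"), f)
  expect_error(read_caller_report(f, "tophat", sample_id = "s1"),
               "spanning_mate_pairs")
})

test_that("rows with unparseable gene symbols are dropped with a count", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_1 = c("A", ""), chromosome_1 = "chr1",
                       breakpoint_1 = 99, strand_1 = "+",
                       gene_2 = c("B", "C"), chromosome_2 = "chr2",
                       breakpoint_2 = 199, strand_2 = "-",
                       spanning_mate_pairs = 7), f)
  expect_message(calls <- read_caller_report(f, "tophat", sample_id = "s1"),
                 "dropped 1 row")
  expect_equal(calls$gene5, "A")
})

test_that("duplicate gene-pair rows collapse to the best-supported breakpoint", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_1 = c("A", "A", "A"), chromosome_1 = "chr1",
                       breakpoint_1 = c(99, 499, 999), strand_1 = "+",
                       gene_2 = c("B", "B", "C"), chromosome_2 = "chr2",
                       breakpoint_2 = 199, strand_2 = "-",
                       spanning_mate_pairs = c(4, 9, 2)), f)
  calls <- read_caller_report(f, "tophat", sample_id = "s1")
  expect_equal(nrow(calls), 2L)
  ab <- calls[calls$gene3 == "B", ]
  expect_equal(ab$junction_pairs, 9L)
  expect_equal(ab$bp5, 500L)  # the breakpoint of the kept row
})

test_that("gene aliases are resolved to the canonical symbol", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_1 = "IGHG1", chromosome_1 = "chr14",
                       breakpoint_1 = 99, strand_1 = "+",
                       gene_2 = "WHSC1", chromosome_2 = "chr4",
                       breakpoint_2 = 199, strand_2 = "+",
                       spanning_mate_pairs = 5), f)
  calls <- read_caller_report(f, "tophat", sample_id = "s1",
                              aliases = c(WHSC1 = "NSD2", MMSET = "NSD2"))
  expect_equal(calls$gene3, "NSD2")
})

test_that("immunoglobulin symbol classification follows the prefix rule with exclusions", {
  expect_equal(classify_ig_symbol(c("IGKC", "IGKV3-20", "IGHG1", "IGHM",
                                    "IGLC2", "IGLJ1")),
               c("IGK", "IGK", "IGH", "IGH", "IGL", "IGL"))
  # prefix look-alikes that are not locus segments
  expect_equal(classify_ig_symbol(c("IGHMBP2", "IGLL1", "IGLON5", "NSD2",
                                    "IGF1R")),
               rep("none", 5))
})

test_that("GTF annotation reading merges duplicate symbols to the widest span", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr4\tsrc\tgene\t100\t500\t.\t+\t.\tgene_id "WHSC1"; gene_name "WHSC1";',
    'chr4\tsrc\tgene\t400\t900\t.\t+\t.\tgene_id "MMSET"; gene_name "MMSET";',
    'chr2\tsrc\tgene\t10\t50\t.\t-\t.\tgene_id "IGKC"; gene_name "IGKC";',
    'chr11\tsrc\tgene\t10\t50\t.\t+\t.\tgene_id "IGHMBP2"; gene_name "IGHMBP2";'
  ), f)
  ann <- read_gene_annotation(f, aliases = c(WHSC1 = "NSD2", MMSET = "NSD2"))
  nsd2 <- ann[ann$symbol == "NSD2", ]
  expect_equal(nrow(nsd2), 1L)          # alias set resolves to one record
  expect_equal(c(nsd2$start, nsd2$end), c(100L, 900L))
  expect_equal(nsd2$ig_class, "none")
  expect_equal(ann$ig_class[ann$symbol == "IGKC"], "IGK")
  expect_equal(ann$ig_class[ann$symbol == "IGHMBP2"], "none")
})

test_that("annotation without gene features is a format error", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "A";', f)
  expect_error(read_gene_annotation(f), "no gene features")
})

test_that("gene-family tables use set semantics", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(symbol = c("HIST1H2BC", "HIST1H2BD", "DUP", "DUP", ""),
                       family_id = c("F1", "F1", "F2", "F3", "F9")), f)
  expect_message(fam <- read_gene_families(f), "skipped 1")
  expect_true(shares_family(fam, "HIST1H2BC", "HIST1H2BD"))
  expect_equal(family_ids(fam, "DUP")[[1]], c("F2", "F3"))  # union of rows
  expect_equal(family_ids(fam, "ABSENT")[[1]], character())
  expect_false(shares_family(fam, "ABSENT", "HIST1H2BC"))
})

test_that("the normalized fusion table round-trips losslessly", {
  x <- make_consensus(c("s1", "s2"), c("IGHG1", "GENEA"), c("NSD2", "GENEB"))
  x$homology_escore <- c(0.002, NA)
  x$passed_support_filter <- c(TRUE, FALSE)
  x$is_ig <- c(TRUE, FALSE)
  x$ig_class <- c("IGH", "none")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_table(x, f)
  back <- read_fusion_table(f)
  expect_equal(back, x)
  expect_true(any(grepl("0.002", readLines(f))))
  # empty table -> header-only file that reads back empty
  write_fusion_table(empty_consensus(), f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_fusion_table(f)), 0L)
})

test_that("sample metadata validates the population field", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(sample_id = c("s1", "s2"),
                       population = c("patient", "organoid")), f)
  expect_error(read_sample_metadata(f), "organoid")
  write_tsv(data.frame(sample_id = c("s1", "s2"),
                       population = c("patient", "cell_line"),
                       fish_translocation = c("TRUE", "FALSE"),
                       age = c("63", "NA")), f)
  meta <- read_sample_metadata(f)
  expect_type(meta$fish_translocation, "logical")
  expect_equal(meta$age, c(63, NA))
})

test_that("expression matrices must be finite", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene = c("A", "B"), s1 = c(1.5, 2), s2 = c(3, 4)), f)
  m <- read_expression_matrix(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["B", "s2"], 4)
  write_tsv(data.frame(gene = "A", s1 = Inf), f)
  expect_error(read_expression_matrix(f), "finite")
})
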