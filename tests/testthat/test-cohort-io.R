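test_that("BED12 gene models map blocks to exons and derive the TSS per strand", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\tG1\t0\t+\t100\t500\t0,0,0\t2\t50,100,\t0,300,",
    "chr2\t100\t500\tG2\t0\t-\t100\t500\t0,0,0\t1\t400,\t0,"),
    path)
  gm <- read_gene_models(path, "bed12")
  expect_equal(nrow(gm$genes), 2)
  e1 <- gm$exons[gm$exons$gene_id == "G1", ]
  expect_equal(e1$start, c(100, 400))
  expect_equal(e1$end, c(150, 500))
  expect_equal(gm$genes$tss[gm$genes$gene_id == "G1"], 100)  # plus strand
  expect_equal(gm$genes$tss[gm$genes$gene_id == "G2"], 499)  # minus strand
})

test_that("GTF coordinates convert from 1-based inclusive to half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "gene", 101, 500, ".", "+", ".", 'gene_id "G1";', sep = "\t"),
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", 'gene_id "G1";', sep = "\t"),
    paste("chr1", "src", "exon", 301, 500, ".", "+", ".", 'gene_id "G1";', sep = "\t")),
    path)
  gm <- read_gene_models(path, "gtf")
  expect_equal(gm$genes$start, 100)
  expect_equal(gm$genes$end, 500)
  expect_equal(gm$exons$start, c(100, 300))
})

test_that("malformed gene-model lines fail with the line number; bad strand rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\tG1\t0\t+\t100\t500\t0,0,0\t1\t400,\t0,",
    "chr1\t9000\t9500"), path)
  expect_error(read_gene_models(path, "bed12"), "line 2")
  writeLines("chr1\t100\t500\tG1\t0\t.\t100\t500\t0,0,0\t1\t400,\t0,", path)
  expect_error(read_gene_models(path, "bed12"), "strand")
})

test_that("fusion TSV reading keeps duplicates, drops negative counts, handles empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("sample_id", "caller", "gene5", "gene3", "chrom5", "pos5",
                 "strand5", "chrom3", "pos3", "strand3", "spanning_reads",
                 "bridging_reads"), collapse = "\t")
  row <- "T1\tcallerA\tGA\tGB\tchr1\t1000\t+\tchr2\t2000\t+\t12\t10"
  writeLines(c(hdr, row, row, sub("\t12\t10", "\t-3\t10", row)), path)
  expect_warning(calls <- read_fusion_calls(path), "negative")
  expect_equal(nrow(calls), 2)  # duplicate retained, negative dropped
  expect_equal(calls$spanning_reads, c(12, 12))
  expect_equal(calls$pos5, c(999, 999))  # 1-based file -> 0-based internal
  expect_equal(calls$isoform_key[1], "chr1:999:chr2:1999")

  writeLines(hdr, path)
  expect_equal(nrow(read_fusion_calls(path)), 0)
})

test_that("segment reading computes ploidy-normalized log-ratios and enforces the sidecar", {
  seg_path <- withr::local_tempfile(fileext = ".seg")
  pl_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\tcopy_number",
               "S1\tchr1\t1\t1000\t4",
               "S1\tchr1\t1001\t2000\t2",
               "S2\tchr1\t1\t2000\t3",
               "S3\tchr1\t1\t2000\t0"), seg_path)
  writeLines(c("sample\tploidy\tpurity",
               "S1\t2\t0.8", "S2\t3\t0.9", "S3\t2\t0.7"), pl_path)
  res <- read_segments(seg_path, pl_path)
  s <- res$segments
  expect_equal(s$log_ratio[s$sample_id == "S1"], c(1, 0))      # log2(4/2), log2(2/2)
  expect_equal(s$log_ratio[s$sample_id == "S2"], 0)            # triploid normalization
  expect_equal(s$log_ratio[s$sample_id == "S3"], log2(0.5 / 2))  # CN=0 floor
  expect_equal(s$start[1], 0)  # 1-based file -> 0-based internal

  writeLines(c("sample\tploidy\tpurity", "S1\t2\t0.8"), pl_path)
  expect_error(read_segments(seg_path, pl_path), "missing ploidy")

  writeLines(c("sample\tchrom\tstart\tend\tcopy_number",
               "S1\tchr1\t1\t1000\t4",
               "S1\tchr1\t500\t2000\t2"), seg_path)
  writeLines(c("sample\tploidy\tpurity", "S1\t2\t0.8"), pl_path)
  expect_error(read_segments(seg_path, pl_path), "[Oo]verlap")
})

test_that("verdicts round-trip losslessly through the TSV dialect", {
  gm <- toy_genes(data.frame(gene_id = c("GA", "GB"), chrom = c("chr1", "chr2"),
                             start = c(10000L, 20000L)))
  calls <- rbind(toy_call(gm, "GA", "GB"), toy_call(gm, "GB", "GA", sample_id = "T02"))
  v <- filter_cascade(calls, NULL, gm, toy_expr(gm, c("T01", "T02")))
  v <- tier_fusions(v, gm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_verdicts(v, path)
  back <- read_verdicts(path)
  for (col in c("sample_id", "gene5", "gene3", "pos5", "pos3", "status",
                "filter_reasons", "sv_tier", "wgs_confidence", "snp6_support"))
    expect_equal(back[[col]], v[[col]], info = col)
})

test_that("filtered verdict rows carry their reasons in the written table", {
  gm <- toy_genes(data.frame(gene_id = c("GA", "GB"), chrom = "chr1",
                             start = c(10000L, 30000L)))  # 14.5 kb gap
  calls <- toy_call(gm, "GA", "GB")
  v <- filter_cascade(calls, NULL, gm, toy_expr(gm, "T01"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_verdicts(v, path)
  back <- read_verdicts(path)
  expect_equal(back$status, "filtered")
  expect_match(back$filter_reasons, "readthrough")
})

test_that("genome FASTA and coverage tracks round-trip", {
  genome <- c(chr1 = "ACGTACGTAA", chr2 = "GGGCCCATAT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(genome, path)
  expect_equal(read_genome_fasta(path), genome)

  cov <- list("chr1:5:chr2:3" = list(cov5 = c(1, 2, 3.5), cov3 = c(9, 9)))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_coverage(cov, cpath)
  expect_equal(read_coverage(cpath), cov)
})
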