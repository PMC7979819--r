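make_screen_fixture <- function() {
  gm <- toy_genes(data.frame(
    gene_id = c("GA", "GB", "GC", "GD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(10000L, 200000L, 10000L, 200000L)))
  genome <- withr::with_seed(11, c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 300000, replace = TRUE), collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T"), 300000, replace = TRUE), collapse = "")))
  list(gm = gm, genome = genome)
}

test_that("fusion contigs take up to 110 bp per side and truncate at boundaries", {
  fx <- make_screen_fixture()
  call <- toy_call(fx$gm, "GA", "GC")
  ct <- build_fusion_contig(call, fx$genome)
  expect_equal(nchar(ct$contig), 220)
  expect_equal(ct$junction_offset, 110)
  expect_equal(ct$contig, paste0(
    substr(fx$genome["chr1"], call$pos5 - 109 + 1, call$pos5 + 1),
    substr(fx$genome["chr2"], call$pos3 + 1, call$pos3 + 110)))

  # 5' side truncated by the gene boundary when gene models are supplied:
  # breakpoint 60 bases into the gene leaves only 60 bp upstream in-gene
  call2 <- toy_call(fx$gm, "GA", "GC", pos5 = 10059L)
  ct2 <- build_fusion_contig(call2, fx$genome, fx$gm)
  expect_equal(ct2$junction_offset, 60)
  expect_equal(nchar(ct2$contig), 170)

  bad <- toy_call(fx$gm, "GA", "GC"); bad$pos5 <- 999999999L
  expect_error(build_fusion_contig(bad, fx$genome), "outside genome")
})

test_that("contig hits need a junction-spanning exact match, Q>30 and 20 bp overhang", {
  fx <- make_screen_fixture()
  ct <- build_fusion_contig(toy_call(fx$gm, "GA", "GC"), fx$genome)
  j <- ct$junction_offset
  sub <- function(a, b) substr(ct$contig, a, b)
  q <- function(n, v = 35) rep(v, n)

  r1 <- sub(95, 135)  # 25 bp past the junction at 110
  expect_true(contig_blacklist_hit(ct$contig, j, r1, q(nchar(r1))))
  r2 <- sub(100, 125)  # only 15 bp past the junction
  expect_false(contig_blacklist_hit(ct$contig, j, r2, q(nchar(r2))))
  expect_false(contig_blacklist_hit(ct$contig, j, r1, q(nchar(r1), 28)))  # mean Q 28
  expect_false(contig_blacklist_hit(ct$contig, j, r1, q(nchar(r1), 30)))  # strict > 30
  r3 <- sub(111, 160)  # does not span the junction
  expect_false(contig_blacklist_hit(ct$contig, j, r3, q(nchar(r3))))
  mut <- r1; substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_false(contig_blacklist_hit(ct$contig, j, mut, q(nchar(mut))))  # mismatch
})

test_that("contig hit detection equals a sliding-window oracle over all offsets", {
  fx <- make_screen_fixture()
  ct <- build_fusion_contig(toy_call(fx$gm, "GA", "GC"), fx$genome)
  j <- ct$junction_offset
  oracle <- function(contig, junction, read) {
    len <- nchar(read)
    for (s in seq_len(nchar(contig) - len + 1)) {
      if (substr(contig, s, s + len - 1) == read &&
          s <= junction && (s + len - 1) >= junction + 1 &&
          (s + len - 1) - junction >= 20) return(TRUE)
    }
    FALSE
  }
  withr::with_seed(7, {
    for (i in 1:200) {
      a <- sample.int(nchar(ct$contig) - 10, 1)
      b <- min(nchar(ct$contig), a + sample(20:80, 1))
      read <- substr(ct$contig, a, b)
      expect_equal(contig_blacklist_hit(ct$contig, j, read, rep(40, nchar(read))),
                   oracle(ct$contig, j, read),
                   info = sprintf("window %d-%d", a, b))
    }
  })
})

test_that("blacklist rules: >=2 control libraries, fetal rule, any control breakpoint", {
  fx <- make_screen_fixture()
  tumor <- toy_call(fx$gm, "GA", "GC")
  ct <- build_fusion_contig(tumor, fx$genome)
  hit_read <- substr(ct$contig, ct$junction_offset - 29, ct$junction_offset + 30)
  reads <- data.frame(sequence = hit_read,
                      qualities = paste(rep(38, nchar(hit_read)), collapse = ","))
  ctrl_call <- toy_call(fx$gm, "GB", "GD", sample_id = "C01")

  # qualifying reads in 2 of 3 libraries -> pair blacklisted
  bl <- build_blacklist(tumor, list(L1 = NULL, L2 = NULL, L3 = NULL),
                        control_reads = list(L1 = reads, L2 = reads),
                        genome = fx$genome, genes = fx$gm)
  expect_true("GA|GC" %in% bl$gene_pairs)

  # hit in 1 library only, pair never called in controls -> not blacklisted
  bl1 <- build_blacklist(tumor, list(L1 = NULL, L2 = NULL),
                         control_reads = list(L1 = reads),
                         genome = fx$genome, genes = fx$gm)
  expect_false("GA|GC" %in% bl1$gene_pairs)

  # breakpoint called once in one control -> breakpoint blacklisted
  bl2 <- build_blacklist(tumor, list(L1 = ctrl_call))
  expect_true(paste0("chr1:", ctrl_call$pos5) %in% bl2$breakpoints)

  # fetal rule: called in fetal + 2 adults
  fetal_sets <- list(fetal = ctrl_call, A1 = ctrl_call, A2 = ctrl_call)
  bl3 <- build_blacklist(tumor, fetal_sets, fetal_control = "fetal")
  expect_true("GB|GD" %in% bl3$gene_pairs)
  # called in fetal + only 1 adult and <2 total adult evidence -> pair only
  # via the >=2-library union rule (which it does meet: fetal + A1 = 2 libs)
  bl4 <- build_blacklist(tumor, list(fetal = ctrl_call, A1 = ctrl_call),
                         fetal_control = "fetal")
  expect_true("GB|GD" %in% bl4$gene_pairs)

  expect_warning(bl0 <- build_blacklist(tumor, list()), "no control")
  expect_length(bl0$gene_pairs, 0)
})

test_that("cascade rules fire on the documented boundary cases", {
  gm <- toy_genes(data.frame(
    gene_id = c("GA", "GB", "GC", "GD", "GE"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr1"),
    start = c(10000L, 45500L, 10000L, 200000L, 200000L)))
  expr <- toy_expr(gm, c("T01", "T02"), rpkm = 10)

  # partners 30 kb apart (gap = 45500 - 15500 = 30000), no other breakpoints
  rt <- toy_call(gm, "GA", "GB")
  v <- filter_cascade(rt, NULL, gm, expr)
  expect_equal(v$filter_reasons, "readthrough")

  # expression ratio: fusion reads 4 (spanning 2 + bridging 2), RPKM 10
  # -> (4/200)/10 = 0.002 < 0.01
  lo <- toy_call(gm, "GC", "GE", spanning = 2L, bridging = 2L, wt5 = 2L, wt3 = 2L)
  v <- filter_cascade(lo, NULL, gm, expr)
  expect_match(v$filter_reasons, "expr_ratio")

  # junction proportion: 3 junction vs 100 wildtype reads at both partners
  # -> 3/103 = 0.029 < 0.05 for both; reads large enough to pass the ratio
  jp <- toy_call(gm, "GC", "GE", spanning = 3L, bridging = 37L,
                 wt5 = 100L, wt3 = 100L)
  v <- filter_cascade(jp, NULL, gm, expr)
  expect_equal(v$filter_reasons, "junction_prop")
  # ...but 0.05 at one partner is enough to keep it
  jp$wt_reads3 <- 57L  # 3/60 = 0.05, not < 0.05
  expect_equal(filter_cascade(jp, NULL, gm, expr)$status, "pass")

  # same-gene circular artifact
  circ <- toy_call(gm, "GC", "GC", pos5 = 15000L, pos3 = 10100L)
  v <- filter_cascade(circ, NULL, gm, expr)
  expect_equal(v$filter_reasons, "circular")

  # gene absent from the expression matrix
  expect_warning(
    v <- filter_cascade(toy_call(gm, "GC", "GE"), NULL, gm,
                        expr[setdiff(rownames(expr), "GE"), , drop = FALSE]),
    "missing expression")
  expect_equal(v$filter_reasons, "missing_expression")
})

test_that("recurrent rule fires at >15 samples and is waived by other breakpoints", {
  gm <- toy_genes(data.frame(gene_id = c("GA", "GC"), chrom = c("chr1", "chr2"),
                             start = c(10000L, 10000L)))
  samples <- sprintf("T%02d", 1:16)
  expr <- toy_expr(gm, sprintf("T%02d", 1:17), rpkm = 10)
  calls <- do.call(rbind, lapply(samples, function(s)
    toy_call(gm, "GA", "GC", sample_id = s)))
  v <- filter_cascade(calls, NULL, gm, expr)
  expect_true(all(v$filter_reasons == "recurrent"))

  # 15 samples with the same event: not recurrent
  v15 <- filter_cascade(calls[1:15, ], NULL, gm, expr)
  expect_true(all(v15$status == "pass"))

  # a second distinct breakpoint in the same genes waives the rule
  extra <- toy_call(gm, "GA", "GC", sample_id = "T17", pos5 = 10100L)
  v2 <- filter_cascade(rbind(calls, extra), NULL, gm, expr)
  expect_true(all(v2$status == "pass"))
})

test_that("final status is order-invariant and monotone in the blacklist", {
  fx <- make_screen_fixture()
  expr <- toy_expr(fx$gm, c("T01", "T02"))
  calls <- rbind(toy_call(fx$gm, "GA", "GC"),
                 toy_call(fx$gm, "GB", "GD", sample_id = "T02"))
  v_fwd <- filter_cascade(calls, NULL, fx$gm, expr)
  v_rev <- filter_cascade(calls[2:1, ], NULL, fx$gm, expr)
  expect_equal(v_fwd$status, rev(v_rev$status))

  small <- structure(list(gene_pairs = "GA|GC", breakpoints = character(),
                          pair_libraries = c("GA|GC" = 2L)),
                     class = "fusion_blacklist")
  big <- structure(list(gene_pairs = c("GA|GC", "GB|GD"),
                        breakpoints = paste0("chr1:", calls$pos5),
                        pair_libraries = c("GA|GC" = 2L, "GB|GD" = 2L)),
                   class = "fusion_blacklist")
  v_small <- filter_cascade(calls, small, fx$gm, expr)
  v_big <- filter_cascade(calls, big, fx$gm, expr)
  # enlarging the blacklist never flips filtered -> pass
  expect_true(all(!(v_small$status == "filtered" & v_big$status == "pass")))
  expect_equal(v_big$status, c("filtered", "filtered"))
})
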