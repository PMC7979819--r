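# Genes used throughout: three exons at +0-500, +2500-3000, +5000-5500.
sv_fixture <- function() {
  toy_genes(data.frame(
    gene_id = c("GA", "GB", "GC", "GD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100000L, 400000L, 100000L, 400000L)))
}

sv_df <- function(sample_id, chrom1, pos1, chrom2 = chrom1, pos2 = pos1) {
  data.frame(sample_id = sample_id, chrom1 = chrom1, pos1 = pos1,
             chrom2 = chrom2, pos2 = pos2)
}

test_that("WGS confidence combines per-partner conditions as High/Intermediate/Low", {
  gm <- sv_fixture()
  # internal exon (exon 2) breakpoints on both partners
  call <- toy_call(gm, "GA", "GC")

  # breakpoints in introns adjacent to exon 2 of both partners -> High
  sv <- rbind(sv_df("T01", "chr1", 103200L),   # intron 1 of GA (100500-102500)... 103200 is intron? exon2 is 102500-103000; introns: 100500-102500, 103000-105000
              sv_df("T01", "chr2", 103500L))
  sv <- rbind(sv_df("T01", "chr1", 103500L), sv_df("T01", "chr2", 101000L))
  expect_equal(wgs_confidence(call, gm, sv), "High")

  # one partner intronic, the other only within 100 kb of the fused exon -> Intermediate
  sv2 <- rbind(sv_df("T01", "chr1", 103500L), sv_df("T01", "chr2", 180000L))
  expect_equal(wgs_confidence(call, gm, sv2), "Intermediate")

  # both partners only within 100 kb -> Low
  sv3 <- rbind(sv_df("T01", "chr1", 180000L), sv_df("T01", "chr2", 180000L))
  expect_equal(wgs_confidence(call, gm, sv3), "Low")

  # no breakpoint within 100 kb of either fused exon -> none
  sv4 <- rbind(sv_df("T01", "chr1", 250000L), sv_df("T01", "chr2", 250000L))
  expect_equal(wgs_confidence(call, gm, sv4), "none")

  # breakpoints from another sample never count
  expect_equal(wgs_confidence(call, gm,
                              rbind(sv_df("T99", "chr1", 103500L),
                                    sv_df("T99", "chr2", 101000L))), "none")
})

test_that("terminal fused exons are validated by intergenic breakpoints", {
  gm <- sv_fixture()
  # 5' breakpoint in the last exon of GA; WGS breakpoint between GA and GB
  call <- toy_call(gm, "GA", "GC", pos5 = 105200L)
  sv <- rbind(sv_df("T01", "chr1", 200000L),  # intergenic GA..GB
              sv_df("T01", "chr2", 101000L))  # intron adjacent to GC exon 2
  expect_equal(wgs_confidence(call, gm, sv), "High")

  # fusion breakpoint outside the gene body -> that side is condition none,
  # and one strong partner alone is not enough for a confidence level
  bad <- toy_call(gm, "GA", "GC", pos5 = 99000L)
  expect_warning(res <- wgs_confidence(bad, gm, sv), "not within gene")
  expect_equal(res, "none")
})

test_that("SNP-array support pads copy-number breakpoints by 250 kb per side", {
  gm <- sv_fixture()
  call <- toy_call(gm, "GA", "GC")  # bp5 at chr1:102999, bp3 at chr2:102500
  mk_bps <- function(...) do.call(rbind, list(...))
  bp <- function(chrom, pos) data.frame(sample_id = "T01", chrom = chrom, pos = pos)

  # bp5 200 kb from a boundary, bp3 unmatched -> left
  expect_equal(snp6_support(call, bp("chr1", 302999)), "left")
  # both matched -> both
  expect_equal(snp6_support(call, mk_bps(bp("chr1", 302999), bp("chr2", 102500))),
               "both")
  # 251 kb away -> that side unmatched
  expect_equal(snp6_support(call, bp("chr1", 102999 + 251000)), "none")
  # exactly 250 kb away still matches
  expect_equal(snp6_support(call, bp("chr1", 102999 + 250000)), "left")
})

test_that("snp6 support equals a brute-force all-pairs distance oracle", {
  gm <- sv_fixture()
  withr::with_seed(13, {
    for (rep in 1:50) {
      call <- toy_call(gm, "GA", "GC",
                       pos5 = sample.int(5e5, 1), pos3 = sample.int(5e5, 1))
      bps <- data.frame(sample_id = "T01",
                        chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                        pos = sample.int(5e5, 40))
      oracle_side <- function(chrom, pos) {
        d <- abs(bps$pos[bps$chrom == chrom] - pos)
        length(d) > 0 && min(d) <= 250e3
      }
      l <- oracle_side("chr1", call$pos5); r <- oracle_side("chr2", call$pos3)
      want <- if (l && r) "both" else if (l) "left" else if (r) "right" else "none"
      expect_equal(snp6_support(call, bps), want)
    }
  })
})

test_that("multi-isoform evidence needs two isoforms and one strong call", {
  gm <- sv_fixture()
  a <- toy_call(gm, "GA", "GC", spanning = 12L, bridging = 10L)           # sum 22
  b <- toy_call(gm, "GA", "GC", pos5 = 102600L, spanning = 3L, bridging = 2L)
  expect_true(isoform_evidence(rbind(a, b)))
  # single isoform, even with a big sum -> false
  big <- toy_call(gm, "GA", "GC", spanning = 30L, bridging = 10L)
  expect_false(isoform_evidence(big))
  # two isoforms, best sum exactly 20 -> false (strict >20)
  a20 <- toy_call(gm, "GA", "GC", spanning = 10L, bridging = 10L)
  expect_false(isoform_evidence(rbind(a20, b)))
  # two isoforms but no call with both read types positive -> false
  a0 <- toy_call(gm, "GA", "GC", spanning = 40L, bridging = 0L)
  expect_false(isoform_evidence(rbind(a0, b)))
})

test_that("the read-depth step statistic behaves as a standardized jump", {
  withr::with_seed(5, {
    cov5 <- c(rnorm(50, 100, 1), rnorm(50, 10, 1))
    cov3 <- rep(50, 100)
    s <- salvage_score(cov5, cov3)
    expect_gt(s, 50)  # ~90 / (sd ~1)
  })
  expect_equal(salvage_score(rep(50, 100), rep(50, 100)), 0)
  expect_equal(salvage_score(rep(0, 100), rep(0, 100)), 0)
  expect_error(salvage_score(numeric(0), rep(1, 10)), "too short")
})

test_that("tiers follow SV evidence; salvage restores filtered recurrent calls", {
  gm <- sv_fixture()
  expr <- toy_expr(gm, sprintf("T%02d", 1:17))
  call <- toy_call(gm, "GA", "GC")
  v <- filter_cascade(call, NULL, gm, expr)

  seg <- assign_states(rbind(
    seg_df("T01", "chr1", 0, 102999, 2),
    seg_df("T01", "chr1", 102999, 5e5, 4),
    seg_df("T01", "chr2", 0, 102500, 4),
    seg_df("T01", "chr2", 102500, 5e5, 2)))
  tv <- tier_fusions(v, gm, segments = seg)
  expect_equal(tv$snp6_support, "both")
  expect_equal(tv$sv_tier, "sv_supported")

  # no evidence at all -> expressed_only
  tv0 <- tier_fusions(v, gm)
  expect_equal(tv0$sv_tier, "expressed_only")

  # filtered recurrent-gene call restored by WGS High
  rec <- do.call(rbind, lapply(sprintf("T%02d", 1:16), function(s)
    toy_call(gm, "GA", "GC", sample_id = s)))
  vr <- filter_cascade(rec, NULL, gm, expr)
  expect_true(all(vr$status == "filtered"))
  sv <- do.call(rbind, lapply(sprintf("T%02d", 1:16), function(s)
    rbind(sv_df(s, "chr1", 103500L), sv_df(s, "chr2", 101000L))))
  tvr <- tier_fusions(vr, gm, sv = sv)
  expect_true(all(tvr$status == "pass"))
  expect_true(all(tvr$salvaged))
  expect_true(all(tvr$sv_tier == "sv_supported"))

  # salvage via the read-depth step alone
  cov <- list(list(cov5 = c(rep(100, 50), rep(10, 50)), cov3 = rep(50, 100)))
  names(cov) <- rec$isoform_key[1]
  tvs <- tier_fusions(vr, gm, coverage = cov)
  expect_true(all(tvs$status == "pass"))

  # adding SV evidence never demotes: tiers with evidence >= tiers without
  rank <- function(x) match(x, c("none", "expressed_only", "sv_supported"))
  expect_true(all(rank(tv$sv_tier) >= rank(tv0$sv_tier)))
})
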