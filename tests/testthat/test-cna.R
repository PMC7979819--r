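test_that("adjacent segments merge by size-weighted mean below the 0.25 tolerance", {
  s <- data.frame(sample_id = "S1", chrom = "chr1",
                  start = c(0, 100), end = c(100, 400),
                  copy_number = c(2, 2), log_ratio = c(0.10, 0.30))
  m <- merge_adjacent(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$log_ratio, (100 * 0.10 + 300 * 0.30) / 400)  # 0.25

  # difference exactly 0.25 never merges (strict <)
  s2 <- transform(s, log_ratio = c(0.10, 0.35))
  expect_equal(nrow(merge_adjacent(s2)), 2)

  # single segment unchanged; unsorted input rejected
  expect_equal(merge_adjacent(s[1, ]), s[1, ])
  expect_error(merge_adjacent(s[2:1, ]), "sorted")
})

test_that("merging is idempotent and conserves covered length and weighted mean", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      bounds <- sort(sample.int(1e6, n + 1))
      s <- data.frame(sample_id = "S1", chrom = "chr1",
                      start = bounds[-(n + 1)], end = bounds[-1],
                      copy_number = 2, log_ratio = rnorm(n, 0, 0.3))
      m <- merge_adjacent(s)
      expect_equal(merge_adjacent(m), m)  # fixpoint
      expect_equal(sum(m$end - m$start), sum(s$end - s$start))
      expect_lt(abs(sum((m$end - m$start) * m$log_ratio) -
                    sum((s$end - s$start) * s$log_ratio)), 1e-9)
      # no remaining mergeable adjacency
      if (nrow(m) > 1) expect_true(all(abs(diff(m$log_ratio)) >= 0.25))
    }
  })
})

test_that("reciprocal overlap matches its definition and a per-base oracle", {
  a <- list(chrom = "chr1", start = 100, end = 200)
  b <- list(chrom = "chr1", start = 150, end = 250)
  expect_equal(reciprocal_overlap(a, b), 0.5)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(a, list(chrom = "chr1", start = 300, end = 400)), 0)
  expect_equal(reciprocal_overlap(a, list(chrom = "chr2", start = 100, end = 200)), 0)

  withr::with_seed(31, {
    for (i in 1:1000) {
      x <- sort(sample.int(500, 2)); y <- sort(sample.int(500, 2))
      if (x[1] == x[2]) x[2] <- x[2] + 1
      if (y[1] == y[2]) y[2] <- y[2] + 1
      aa <- list(chrom = "chr1", start = x[1], end = x[2])
      bb <- list(chrom = "chr1", start = y[1], end = y[2])
      expect_identical(reciprocal_overlap(aa, bb), ro_oracle(aa, bb))
    }
  })
})

test_that("germline filtering applies the 50%/80% reciprocal-overlap stages and re-merges", {
  seg <- rbind(
    seg_df("S1", "chr1", 0e6, 1.0e6, 2),
    seg_df("S1", "chr1", 1.0e6, 1.1e6, 1),   # ~0.71 RO with gold variant
    seg_df("S1", "chr1", 1.1e6, 2.0e6, 2),
    seg_df("S1", "chr2", 0e6, 1.0e6, 2),
    seg_df("S1", "chr2", 1.0e6, 1.1e6, 1),   # 0.7 RO with supporting variant: kept
    seg_df("S1", "chr2", 1.1e6, 2.0e6, 2))
  db <- list(
    gold = data.frame(chrom = "chr1", start = 1.02e6, end = 1.09e6, freq = 0.05),
    supporting = data.frame(chrom = "chr2", start = 1.0e6, end = 1.143e6,
                            freq = 0.05, study_size = 100))
  out <- filter_germline(seg, db)
  # chr1: loss removed (gold stage) and the flanking neutrals re-merged
  chr1 <- out[out$chrom == "chr1", ]
  expect_equal(nrow(chr1), 1)
  expect_equal(c(chr1$start, chr1$end), c(0, 2e6))
  # chr2: 0.7 < 0.8 so the supporting stage keeps the loss
  expect_equal(nrow(out[out$chrom == "chr2", ]), 3)

  # 80% reciprocal overlap with a supporting variant is removed
  db2 <- list(gold = NULL,
              supporting = data.frame(chrom = "chr2", start = 1.0e6, end = 1.12e6,
                                      freq = 0.05, study_size = 100))
  out2 <- filter_germline(seg[4:6, ], db2)
  expect_equal(nrow(out2), 1)

  expect_warning(same <- filter_germline(seg, list(gold = NULL, supporting = NULL)),
                 "empty")
  expect_equal(same, seg)
})

test_that("state assignment and broad/focal splitting follow the thresholds", {
  seg <- rbind(seg_df("S1", "chr1", 0, 1e6, 0),
               seg_df("S1", "chr1", 1e6, 2e6, 1),
               seg_df("S1", "chr1", 2e6, 3e6, 2),
               seg_df("S1", "chr1", 3e6, 4e6, 3),
               seg_df("S1", "chr1", 4e6, 5e6, 5))
  st <- assign_states(seg)
  expect_equal(st$state, c("deletion", "loss", "neutral", "gain", "amplification"))
  # log_ratio 1.3 -> amplification; 0.1 -> neutral
  s <- seg_df("S1", "chr1", 0, 1e6, 2)
  s$log_ratio <- 1.3
  expect_equal(assign_states(s)$state, "amplification")
  s$log_ratio <- 0.1
  expect_equal(assign_states(s)$state, "neutral")

  sc <- split_broad_focal(rbind(seg_df("S1", "chr1", 0, 13e6, 3),
                                seg_df("S1", "chr2", 0, 12e6, 3),
                                seg_df("S1", "chr3", 0, 50e3, 3)))
  expect_equal(sc$scope, c("broad", "focal", "focal"))
})

test_that("gene-level state is first past the post with the 50% gain rule", {
  gene <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  # segment A covers 25%, B covers 45% -> gene takes B's state
  seg <- assign_states(rbind(seg_df("S1", "chr1", 1000, 1250, 2),
                             seg_df("S1", "chr1", 1550, 2000, 5)))
  st <- gene_level_state(gene, seg)
  expect_equal(st$state, "neutral")  # B wins but amplification needs >= 50%
  # widen B to 50% -> amplification sticks
  seg2 <- assign_states(rbind(seg_df("S1", "chr1", 1000, 1250, 2),
                              seg_df("S1", "chr1", 1500, 2000, 5)))
  expect_equal(gene_level_state(gene, seg2)$state, "amplification")
  # a winning loss segment needs any overlap only
  seg3 <- assign_states(seg_df("S1", "chr1", 1900, 2000, 1))
  expect_equal(gene_level_state(gene, seg3)$state, "loss")
  # no overlap at all -> neutral, uncovered
  seg4 <- assign_states(seg_df("S1", "chr1", 5000, 6000, 1))
  st4 <- gene_level_state(gene, seg4)
  expect_equal(st4$state, "neutral")
  expect_equal(st4$covered_frac, 0)
})

test_that("gene-level state agrees with a brute-force per-base oracle", {
  withr::with_seed(41, {
    for (i in 1:1000) {
      gene <- data.frame(chrom = "chr1", start = 0, end = 200)
      n <- sample(1:5, 1)
      bounds <- sort(sample(0:300, n + 1))
      bounds <- bounds[!duplicated(bounds)]
      if (length(bounds) < 2) next
      seg <- assign_states(seg_df("S1", "chr1", bounds[-length(bounds)],
                                  bounds[-1], sample(0:5, length(bounds) - 1,
                                                     replace = TRUE)))
      expect_equal(gene_level_state(gene, seg)$state,
                   gene_state_oracle(gene, seg))
    }
  })
})

test_that("Kruskal-Wallis H, its permutation null and Benjamini-Hochberg check out", {
  kw <- kruskal.test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(unname(kw$statistic), 3), 3.857)

  # exhaustive permutation distribution of H over all 3|3 splits
  vals <- 1:6
  hs <- apply(combn(6, 3), 2, function(idx)
    unname(kruskal.test(list(vals[idx], vals[-idx]))$statistic))
  p_perm <- mean(hs >= unname(kw$statistic) - 1e-9)
  expect_equal(p_perm, 2 / 20)  # only the two extreme splits reach H = 3.857
  # the chi-square approximation is crude at n = 3 + 3; agreement is loose
  expect_lt(abs(kw$p.value - p_perm), 0.06)

  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  withr::with_seed(51, {
    p <- runif(25)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  })
})

test_that("the responsive-gene test groups states, applies BH, and handles degenerate genes", {
  states <- rbind(
    RESP = c(rep("neutral", 6), rep("amplification", 6)),
    FLAT = c(rep("neutral", 6), rep("gain", 6)),
    ONE  = rep("neutral", 12))
  colnames(states) <- sprintf("S%02d", 1:12)
  expr <- rbind(RESP = c(rnorm(6, 0, .1), rnorm(6, 5, .1)),
                FLAT = rnorm(12), ONE = rnorm(12))
  colnames(expr) <- colnames(states)
  withr::with_seed(61, res <- cn_responsive_test(states, expr))
  expect_true(res$responsive[res$gene_id == "RESP"])
  expect_true(is.na(res$p_value[res$gene_id == "ONE"]))   # single category -> NA
  expect_true(is.na(res$responsive[res$gene_id == "ONE"]))
  expect_equal(res$n_gain[res$gene_id == "RESP"], 6)
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
})

test_that("neutral-state normalization divides by the neutral median", {
  expr <- c(a = 20, b = 10, c = 8, d = 40)
  states <- c(a = "gain", b = "neutral", c = "neutral", d = "amplification")
  # neutral median = 9 -> a: 20/9
  expect_equal(neutral_normalize(expr, states)[["a"]], 20 / 9)
  states2 <- c(a = "neutral", b = "neutral", c = "neutral", d = "gain")
  expect_equal(neutral_normalize(expr, states2)[["b"]], 1.0)
  expect_error(neutral_normalize(expr, rep("gain", 4)), "no neutral")
  expect_error(neutral_normalize(c(a = 0, b = 2), c(a = "neutral", b = "gain")),
               "zero")
  # log-space convention subtracts the neutral median
  expect_equal(neutral_normalize(expr, states, log_space = TRUE)[["a"]], 11)
})
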