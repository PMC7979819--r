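# Small programmatic fixtures shared across test files.

# A two-chromosome toy gene set: per gene three 500 bp exons with 2 kb
# introns, built directly (not via make_genome) so coordinates are exact.
toy_genes <- function(specs) {
  # specs: data.frame gene_id, chrom, start, strand
  exoff <- list(c(0L, 500L), c(2500L, 3000L), c(5000L, 5500L))
  genes <- data.frame(gene_id = specs$gene_id, chrom = specs$chrom,
                      start = specs$start, end = specs$start + 5500L,
                      strand = specs$strand %||% "+")
  exons <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i)
    do.call(rbind, lapply(exoff, function(e)
      data.frame(gene_id = specs$gene_id[i], start = specs$start[i] + e[1],
                 end = specs$start[i] + e[2])))))
  gene_models(genes, exons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One fusion-call row with sane defaults; fields overridable.
toy_call <- function(gm, gene5, gene3, sample_id = "T01",
                     pos5 = NULL, pos3 = NULL, spanning = 15L, bridging = 10L,
                     wt5 = 50L, wt3 = 50L) {
  ex5 <- gm$exons[gm$exons$gene_id == gene5, ]
  ex3 <- gm$exons[gm$exons$gene_id == gene3, ]
  g5 <- gm$genes[gm$genes$gene_id == gene5, ]
  g3 <- gm$genes[gm$genes$gene_id == gene3, ]
  df <- data.frame(sample_id = sample_id, caller = "callerA",
                   gene5 = gene5, gene3 = gene3,
                   chrom5 = g5$chrom, pos5 = pos5 %||% (ex5$end[2] - 1L),
                   strand5 = "+",
                   chrom3 = g3$chrom, pos3 = pos3 %||% ex3$start[2],
                   strand3 = "+",
                   spanning_reads = spanning, bridging_reads = bridging,
                   wt_reads5 = wt5, wt_reads3 = wt3, contig = NA_character_)
  df$isoform_key <- paste(df$chrom5, df$pos5, df$chrom3, df$pos3, sep = ":")
  df
}

# Uniform RPKM matrix over a gene model set.
toy_expr <- function(gm, samples, rpkm = 5) {
  matrix(rpkm, nrow(gm$genes), length(samples),
         dimnames = list(gm$genes$gene_id, samples))
}

# Segment data.frame builder (0-based internal coordinates).
seg_df <- function(sample_id, chrom, start, end, copy_number, ploidy = 2,
                   cn_floor = 0.5) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             copy_number = copy_number,
             log_ratio = log2(ifelse(copy_number == 0, cn_floor, copy_number) / ploidy))
}

# Per-base counting oracle for reciprocal overlap (integer coordinates).
ro_oracle <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  pa <- seq(a$start, a$end - 1)
  pb <- seq(b$start, b$end - 1)
  ov <- length(intersect(pa, pb))
  if (ov == 0) return(0)
  min(ov / length(pa), ov / length(pb))
}

# Brute-force per-base oracle for the gene-level state rule.
gene_state_oracle <- function(gene, segments) {
  pos <- seq(gene$start, gene$end - 1)
  seg <- segments[segments$chrom == gene$chrom, , drop = FALSE]
  if (nrow(seg) == 0) return("neutral")
  cover <- vapply(seq_len(nrow(seg)), function(i)
    sum(pos >= seg$start[i] & pos < seg$end[i]), numeric(1))
  if (all(cover == 0)) return("neutral")
  i <- which.max(cover)
  st <- seg$state[i]
  if (st %in% c("gain", "amplification") && cover[i] / length(pos) < 0.5)
    st <- "neutral"
  st
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration: sum of the
# probabilities of all tables (same margins) no more likely than observed.
fisher_oracle <- function(n11, n10, n01, n00) {
  m <- n11 + n10          # row 1 total
  n <- n01 + n00          # row 2 total
  k <- n11 + n01          # column 1 total
  kk <- max(0, k - n):min(k, m)
  probs <- dhyper(kk, m, n, k)
  p_obs <- dhyper(n11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
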