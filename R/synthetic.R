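## Synthetic cohort generator. Every planted item carries its generating
## parameters in a truth table, so downstream tests are joins of pipeline
## verdicts against planted truth. All generators are deterministic per
## seed and leave the caller's RNG state untouched.

GENE_EXON_OFFSETS <- list(c(0L, 500L), c(2500L, 3000L), c(5000L, 5500L))
GENE_LEN <- 5500L

#' Generate a random genome with non-overlapping multi-exon genes
#'
#' Genes (three 500 bp exons, 2 kb introns) are laid out per chromosome with
#' alternating spacing: consecutive gene pairs sit about 20 kb apart (inside
#' the readthrough window) while the pairs themselves are separated widely,
#' so both near and far gene pairs exist by construction. Layout and
#' sequence are byte-identical for identical arguments.
#'
#' @param n_chrom number of chromosomes.
#' @param genes_per_chrom genes per chromosome (> 0).
#' @param chrom_len chromosome length in bp.
#' @param seed RNG seed.
#' @param sequence generate the nucleotide sequence (set `FALSE` when only
#'   gene models are needed, e.g. for copy-number simulations on long
#'   chromosomes).
#' @return list with `genome` (named character vector or `NULL`) and
#'   `genes` ([gene_models()]).
#' @export
make_genome <- function(n_chrom = 2, genes_per_chrom = 50, chrom_len = 5e6,
                        seed = 1, sequence = TRUE) {
  if (genes_per_chrom <= 0) stopf("genes_per_chrom must be positive")
  if (n_chrom <= 0) stopf("n_chrom must be positive")
  with_seed(seed, {
    margin <- 50e3; close_gap <- 20e3
    n <- genes_per_chrom
    n_close <- n %/% 2
    n_far <- n - n_close
    far_gap <- (chrom_len - 2 * margin - n * GENE_LEN - n_close * close_gap) / n_far
    if (far_gap <= 50e3)
      stopf("infeasible packing: %d genes do not fit in %g bp with >50 kb spacing",
            n, chrom_len)
    genes <- list(); exons <- list(); genome <- character()
    for (ci in seq_len(n_chrom)) {
      chrom <- paste0("chr", ci)
      cur <- margin
      for (gi in seq_len(n)) {
        gid <- sprintf("G%d_%03d", ci, gi)
        start <- as.integer(round(cur))
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, start = start, end = start + GENE_LEN,
          strand = "+")
        for (eo in GENE_EXON_OFFSETS)
          exons[[length(exons) + 1L]] <- data.frame(
            gene_id = gid, start = start + eo[1], end = start + eo[2])
        gap <- if (gi %% 2 == 1) close_gap else far_gap + runif(1, -5e3, 5e3)
        cur <- cur + GENE_LEN + gap
        if (cur > chrom_len) stopf("infeasible packing on %s", chrom)
      }
      if (sequence)
        genome[[chrom]] <- paste(sample(c("A", "C", "G", "T"), chrom_len,
                                        replace = TRUE), collapse = "")
    }
    list(genome = if (sequence) genome else NULL,
         genes = gene_models(do.call(rbind, genes), do.call(rbind, exons)))
  })
}

default_fusion_classes <- function() {
  c(true_sv = 10, expressed_only = 5, readthrough = 5, circular = 5,
    control_shared = 5, recurrent_artifact = 1)
}

## Baseline segments covering each chromosome at CN = ploidy, split at an
## arbitrary midpoint so the raw SEG exercises the merge step.
baseline_segments <- function(sample_id, chroms, chrom_len, ploidy) {
  do.call(rbind, lapply(chroms, function(ch) {
    mid <- round(chrom_len / 3)
    data.frame(sample_id = sample_id, chrom = ch,
               start = c(0, mid), end = c(mid, chrom_len),
               copy_number = ploidy)
  }))
}

## Insert an event segment [start, end) at copy number `cn` into a sample's
## baseline, splitting whatever it lands on.
insert_event <- function(seg, chrom, start, end, cn) {
  on <- seg$chrom == chrom
  keep <- seg[!on, , drop = FALSE]
  s <- seg[on, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(s))) {
    a <- s$start[i]; b <- s$end[i]
    if (b <= start || a >= end) { out[[length(out) + 1L]] <- s[i, ]; next }
    if (a < start) out[[length(out) + 1L]] <-
        data.frame(sample_id = s$sample_id[i], chrom = chrom, start = a,
                   end = start, copy_number = s$copy_number[i])
    if (b > end) out[[length(out) + 1L]] <-
        data.frame(sample_id = s$sample_id[i], chrom = chrom, start = end,
                   end = b, copy_number = s$copy_number[i])
  }
  out[[length(out) + 1L]] <- data.frame(sample_id = s$sample_id[1], chrom = chrom,
                                        start = start, end = end, copy_number = cn)
  res <- rbind(keep, do.call(rbind, out))
  res[order(res$sample_id, res$chrom, res$start), , drop = FALSE]
}

#' Plant fusion evidence classes into a synthetic cohort
#'
#' Emits tumor fusion calls of six classes with the evidence each pipeline
#' rule keys on: `true_sv` fusions get matching WGS breakpoint pairs,
#' copy-number change points at both breakpoints, a coverage step at the
#' junction and read support above all thresholds; `expressed_only` fusions
#' pass every filter but carry no genomic evidence; `readthrough` artifacts
#' join gene pairs under 50 kb apart; `circular` artifacts place both
#' breakpoints in one gene; `control_shared` artifacts emit qualifying
#' contig-matching reads in two control libraries; `recurrent_artifact`
#' repeats one breakpoint pair in 16 tumors. Control read sets include ~10%
#' low-quality decoy reads.
#'
#' @param sim output of [make_genome()] (with sequence).
#' @param n_tumors,n_controls cohort sizes.
#' @param class_counts named counts per class (see
#'   `default_fusion_classes()`).
#' @param seed RNG seed.
#' @return list: `tumor_calls`, `control_calls` (named list),
#'   `control_reads` (named list), `expr` (RPKM matrix), `wgs_sv`,
#'   `segments`, `profiles`, `coverage` (per isoform_key), `truth`
#'   (data.frame with class and intended filter reason per planted call).
#' @export
plant_fusions <- function(sim, n_tumors = 60, n_controls = 8,
                          class_counts = default_fusion_classes(), seed = 1) {
  genome <- sim$genome; gm <- sim$genes
  stopifnot(!is.null(genome))
  cc <- default_fusion_classes()
  cc[names(class_counts)] <- class_counts
  n_recur_samples <- 16L
  n_single <- sum(cc[c("true_sv", "expressed_only", "readthrough", "circular",
                       "control_shared")])
  if (n_single > n_tumors)
    stopf("%d single-sample fusions do not fit in %d tumors", n_single, n_tumors)
  if (cc[["recurrent_artifact"]] > 0 && n_tumors < n_recur_samples)
    stopf("recurrent artifacts need at least %d tumors", n_recur_samples)
  with_seed(seed, {
    gtab <- gm$genes
    chroms <- unique(gtab$chrom)
    tumors <- sprintf("T%02d", seq_len(n_tumors))
    controls <- sprintf("C%02d", seq_len(n_controls))

    ## gene bookkeeping: close pairs (consecutive odd/even on one chromosome)
    ## for readthroughs, far cross-chromosome pairs for everything else
    by_chrom <- split(gtab$gene_id, gtab$chrom)
    close_pairs <- list(); far_pool <- list()
    for (ch in chroms) {
      ids <- by_chrom[[ch]]
      for (k in seq_len(length(ids) %/% 2))
        close_pairs[[length(close_pairs) + 1L]] <- c(ids[2 * k - 1], ids[2 * k])
    }
    if (cc[["readthrough"]] > length(close_pairs))
      stopf("not enough close gene pairs for %d readthroughs", cc[["readthrough"]])
    rt_pairs <- close_pairs[seq_len(cc[["readthrough"]])]
    used <- unlist(rt_pairs)
    remaining <- lapply(chroms, function(ch) setdiff(by_chrom[[ch]], used))
    if (length(remaining) < 2) stopf("need at least 2 chromosomes")
    take_far_pair <- local({
      i <- 0L
      function() {
        i <<- i + 1L
        if (i > min(lengths(remaining))) stopf("not enough genes for fusion classes")
        c(remaining[[1]][i], remaining[[2]][i])
      }
    })

    ## breakpoints: 5' at the last base of exon 2 (internal), 3' at the
    ## first base of exon 2 of the partner
    bp5_of <- function(gid) {
      ex <- gene_exons(gm, gid); ex$end[2] - 1L
    }
    bp3_of <- function(gid) {
      ex <- gene_exons(gm, gid); ex$start[2]
    }
    chrom_of <- function(gid) gene_row(gm, gid)$chrom

    calls <- list(); truth <- list(); wgs <- list(); coverage <- list()
    profiles <- data.frame(sample_id = tumors, ploidy = 2, purity = 0.8,
                           aneuploid = FALSE)
    segs <- do.call(rbind, lapply(tumors, function(s)
      baseline_segments(s, chroms, nchar(genome[[1]]), 2)))
    next_sample <- local({
      i <- 0L
      function() { i <<- i + 1L; tumors[i] }
    })
    add_call <- function(sample, g5, g3, pos5 = bp5_of(g5), pos3 = bp3_of(g3),
                         spanning = 15L, bridging = 10L, wt = 50L) {
      calls[[length(calls) + 1L]] <<- data.frame(
        sample_id = sample, caller = "callerA", gene5 = g5, gene3 = g3,
        chrom5 = chrom_of(g5), pos5 = pos5, strand5 = "+",
        chrom3 = chrom_of(g3), pos3 = pos3, strand3 = "+",
        spanning_reads = spanning, bridging_reads = bridging,
        wt_reads5 = wt, wt_reads3 = wt, contig = NA_character_)
    }
    add_truth <- function(class, sample, g5, g3, pos5, pos3, reason) {
      truth[[length(truth) + 1L]] <<- data.frame(
        class = class, sample_id = sample, gene5 = g5, gene3 = g3,
        isoform_key = paste(chrom_of(g5), pos5, chrom_of(g3), pos3, sep = ":"),
        intended_reason = reason)
    }

    for (i in seq_len(cc[["true_sv"]])) {
      pr <- take_far_pair(); s <- next_sample()
      p5 <- bp5_of(pr[1]); p3 <- bp3_of(pr[2])
      add_call(s, pr[1], pr[2], p5, p3)
      add_truth("true_sv", s, pr[1], pr[2], p5, p3, NA_character_)
      ## WGS breakpoints in the introns adjacent to the fused exons
      e5 <- gene_exons(gm, pr[1]); e3 <- gene_exons(gm, pr[2])
      wgs[[length(wgs) + 1L]] <- data.frame(
        sample_id = s, chrom1 = chrom_of(pr[1]), pos1 = e5$end[2] + 500L,
        chrom2 = chrom_of(pr[2]), pos2 = e3$end[1] + 500L)
      ## copy-number change at both breakpoints
      ss <- segs[segs$sample_id == s, , drop = FALSE]
      ss <- insert_event(ss, chrom_of(pr[1]), p5,
                         nchar(genome[[chrom_of(pr[1])]]), 4)
      ss <- insert_event(ss, chrom_of(pr[2]), 0, p3, 4)
      segs <- rbind(segs[segs$sample_id != s, , drop = FALSE], ss)
      segs <- segs[order(segs$sample_id, segs$chrom, segs$start), ]
      ## coverage step at the junction
      key <- paste(chrom_of(pr[1]), p5, chrom_of(pr[2]), p3, sep = ":")
      coverage[[key]] <- list(
        cov5 = c(rnorm(50, 100, 3), rnorm(50, 20, 3)),
        cov3 = c(rnorm(50, 20, 3), rnorm(50, 100, 3)))
    }
    for (i in seq_len(cc[["expressed_only"]])) {
      pr <- take_far_pair(); s <- next_sample()
      p5 <- bp5_of(pr[1]); p3 <- bp3_of(pr[2])
      add_call(s, pr[1], pr[2], p5, p3)
      add_truth("expressed_only", s, pr[1], pr[2], p5, p3, NA_character_)
    }
    for (i in seq_len(cc[["readthrough"]])) {
      pr <- rt_pairs[[i]]; s <- next_sample()
      p5 <- bp5_of(pr[1]); p3 <- bp3_of(pr[2])
      add_call(s, pr[1], pr[2], p5, p3)
      add_truth("readthrough", s, pr[1], pr[2], p5, p3, "readthrough")
    }
    for (i in seq_len(cc[["circular"]])) {
      g <- take_far_pair()[1]; s <- next_sample()
      ex <- gene_exons(gm, g)
      p5 <- ex$end[2] - 1L; p3 <- ex$start[1]
      add_call(s, g, g, p5, p3)
      add_truth("circular", s, g, g, p5, p3, "circular")
    }
    shared_pairs <- lapply(seq_len(cc[["control_shared"]]), function(i) take_far_pair())
    for (i in seq_along(shared_pairs)) {
      pr <- shared_pairs[[i]]; s <- next_sample()
      p5 <- bp5_of(pr[1]); p3 <- bp3_of(pr[2])
      add_call(s, pr[1], pr[2], p5, p3)
      add_truth("control_shared", s, pr[1], pr[2], p5, p3, "blacklist_pair")
    }
    if (cc[["recurrent_artifact"]] > 0) {
      for (i in seq_len(cc[["recurrent_artifact"]])) {
        pr <- take_far_pair()
        p5 <- bp5_of(pr[1]); p3 <- bp3_of(pr[2])
        rs <- tumors[seq(n_tumors - n_recur_samples + 1, n_tumors)]
        for (s in rs) {
          add_call(s, pr[1], pr[2], p5, p3)
          add_truth("recurrent_artifact", s, pr[1], pr[2], p5, p3, "recurrent")
        }
      }
    }
    tumor_calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(sample_id = character(), caller = character(),
                 gene5 = character(), gene3 = character(),
                 chrom5 = character(), pos5 = integer(), strand5 = character(),
                 chrom3 = character(), pos3 = integer(), strand3 = character(),
                 spanning_reads = integer(), bridging_reads = integer(),
                 wt_reads5 = integer(), wt_reads3 = integer(),
                 contig = character())
    tumor_calls$isoform_key <- fusion_isoform_key(tumor_calls)

    ## expression: RPKM ~ 5 for every gene, every tumor
    expr <- matrix(pmax(0.5, rnorm(nrow(gtab) * n_tumors, 5, 0.5)),
                   nrow(gtab), n_tumors, dimnames = list(gtab$gene_id, tumors))

    ## control reads: contig-matching reads for control_shared pairs in two
    ## libraries, plus low-quality decoys for the same contigs elsewhere
    control_reads <- setNames(vector("list", n_controls), controls)
    read_from_contig <- function(pr) {
      call <- tumor_calls[tumor_calls$gene5 == pr[1] & tumor_calls$gene3 == pr[2], ][1, ]
      ct <- build_fusion_contig(call, genome, gm)
      j <- ct$junction_offset
      substr(ct$contig, j - 29, j + 30)  # spans the junction, 30 bp overhang
    }
    for (lib in controls) control_reads[[lib]] <-
      data.frame(sequence = character(), qualities = character())
    for (i in seq_along(shared_pairs)) {
      sq <- read_from_contig(shared_pairs[[i]])
      good <- paste(round(runif(nchar(sq), 35, 40)), collapse = ",")
      bad <- paste(round(runif(nchar(sq), 20, 28)), collapse = ",")
      for (lib in controls[1:2]) {
        control_reads[[lib]] <- rbind(control_reads[[lib]],
                                      data.frame(sequence = sq, qualities = good))
      }
      ## ~10% of reads fall below the mean-Q30 bar: same sequence, low quality
      control_reads[[controls[3]]] <- rbind(control_reads[[controls[3]]],
                                            data.frame(sequence = sq, qualities = bad))
    }
    control_calls <- setNames(lapply(controls, function(x)
      data.frame(sample_id = character(), caller = character(),
                 gene5 = character(), gene3 = character(),
                 chrom5 = character(), pos5 = integer(), strand5 = character(),
                 chrom3 = character(), pos3 = integer(), strand3 = character(),
                 spanning_reads = integer(), bridging_reads = integer())),
      controls)

    wgs_sv <- if (length(wgs)) do.call(rbind, wgs) else
      data.frame(sample_id = character(), chrom1 = character(), pos1 = integer(),
                 chrom2 = character(), pos2 = integer())
    truth <- do.call(rbind, truth)
    rownames(segs) <- NULL
    list(tumor_calls = tumor_calls, control_calls = control_calls,
         control_reads = control_reads, expr = expr, wgs_sv = wgs_sv,
         segments = segs, profiles = profiles, coverage = coverage,
         truth = truth)
  })
}

#' Plant copy-number structure and copy-number-responsive genes
#'
#' Emits raw (split, unmerged) segments for a cohort: every sample has a
#' flat baseline at its ploidy; about a quarter of samples are aneuploid
#' (ploidy 3). Responsive genes receive focal amplifications (copy number
#' twice the ploidy) in `n_aberrant` samples with an expression shift of
#' `effect_log2`; broad (> 12 Mb) gains give null genes genuine mixed
#' copy-number categories without any expression shift; germline CNV losses
#' are drawn to overlap the emitted gold/supporting catalogs at the
#' filtering thresholds.
#'
#' @param genes [gene_models()] (use a long-chromosome layout, e.g.
#'   `make_genome(2, 105, 30e6, sequence = FALSE)`).
#' @param n_samples cohort size.
#' @param n_responsive planted responsive genes.
#' @param n_aberrant aberrant samples per responsive gene (>= 8).
#' @param effect_log2 expression shift in aberrant samples (log2 units).
#' @param noise_sd log2 expression noise.
#' @param aneuploid_frac fraction of samples at ploidy 3.
#' @param seed RNG seed.
#' @return list: `segments` (raw), `profiles`, `expr` (RPKM matrix over all
#'   genes), `germline` (db list, already threshold-filtered), `truth`
#'   (responsive genes with their aberrant samples; germline segment
#'   records).
#' @export
plant_cna <- function(genes, n_samples = 40, n_responsive = 10, n_aberrant = 12,
                      effect_log2 = 1.0, noise_sd = 0.5, aneuploid_frac = 0.24,
                      seed = 1) {
  gm <- genes; gtab <- gm$genes
  chroms <- unique(gtab$chrom)
  chrom_len <- max(gtab$end) + 50e3
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    n_aneu <- round(aneuploid_frac * n_samples)
    ploidy <- c(rep(3, n_aneu), rep(2, n_samples - n_aneu))
    profiles <- data.frame(sample_id = samples, ploidy = ploidy,
                           purity = round(runif(n_samples, 0.6, 0.95), 2),
                           aneuploid = ploidy != 2)

    seg_list <- lapply(seq_len(n_samples), function(i)
      baseline_segments(samples[i], chroms, chrom_len, ploidy[i]))
    names(seg_list) <- samples

    ## broad gains (13 Mb) over the head of each chromosome in two sample
    ## blocks, so genes there have genuine gain/neutral category splits
    broad_len <- 13e6
    broad1 <- samples[seq(1, min(10, n_samples))]
    broad2 <- samples[seq(min(11, n_samples), min(20, n_samples))]
    for (s in broad1) seg_list[[s]] <- insert_event(
      seg_list[[s]], chroms[1], 0, broad_len,
      round(profiles$ploidy[profiles$sample_id == s] * 1.5))
    if (length(chroms) > 1) for (s in broad2) seg_list[[s]] <- insert_event(
      seg_list[[s]], chroms[2], 0, broad_len,
      round(profiles$ploidy[profiles$sample_id == s] * 1.5))

    ## responsive genes: outside the broad regions, focal amp in n_aberrant
    ## samples
    candidates <- gtab[gtab$chrom == chroms[1] & gtab$start > broad_len + 1e6, ]
    if (nrow(candidates) < n_responsive)
      stopf("not enough genes outside the broad region for %d responsive genes",
            n_responsive)
    resp_genes <- candidates$gene_id[seq_len(n_responsive)]
    aberrant <- list()
    for (g in resp_genes) {
      gs <- gtab[gtab$gene_id == g, ]
      ab <- sample(samples, n_aberrant)
      aberrant[[g]] <- ab
      for (s in ab) {
        pl <- profiles$ploidy[profiles$sample_id == s]
        seg_list[[s]] <- insert_event(seg_list[[s]], gs$chrom,
                                      gs$start - 2e4, gs$end + 2e4, 2 * pl)
      }
    }

    ## germline CNV losses overlapping the emitted catalogs
    gold <- data.frame(chrom = chroms[length(chroms)],
                       start = seq(broad_len + 2e6, by = 1.1e6,
                                   length.out = 5) + 612e3,
                       end = NA, freq = 0.05)
    gold$end <- gold$start + 1e5
    supp <- data.frame(chrom = chroms[length(chroms)],
                       start = seq(broad_len + 2e6, by = 1.3e6,
                                   length.out = 5) + 517e3,
                       end = NA, freq = 0.04, study_size = 120)
    supp$end <- supp$start + 1e5
    germ_truth <- list()
    germ_samples <- sample(samples, max(3, round(0.3 * n_samples)))
    for (s in germ_samples) {
      gv <- gold[sample.int(nrow(gold), 1), ]
      st <- gv$start - 2e4; en <- gv$end + 2e4   # reciprocal overlap ~0.71
      seg_list[[s]] <- insert_event(seg_list[[s]], gv$chrom, st, en, 1)
      germ_truth[[length(germ_truth) + 1L]] <- data.frame(
        sample_id = s, chrom = gv$chrom, start = st, end = en, kind = "gold")
      sv <- supp[sample.int(nrow(supp), 1), ]
      st <- sv$start - 5e3; en <- sv$end + 5e3   # reciprocal overlap ~0.91
      seg_list[[s]] <- insert_event(seg_list[[s]], sv$chrom, st, en, 1)
      germ_truth[[length(germ_truth) + 1L]] <- data.frame(
        sample_id = s, chrom = sv$chrom, start = st, end = en, kind = "supporting")
    }

    segments <- do.call(rbind, seg_list)
    segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ]
    rownames(segments) <- NULL

    ## expression: log2 baseline per gene + noise; responsive genes shifted
    ## in their aberrant samples
    base <- rnorm(nrow(gtab), 3, 1)
    logex <- matrix(base, nrow(gtab), n_samples) +
      matrix(rnorm(nrow(gtab) * n_samples, 0, noise_sd), nrow(gtab))
    dimnames(logex) <- list(gtab$gene_id, samples)
    for (g in resp_genes)
      logex[g, aberrant[[g]]] <- logex[g, aberrant[[g]]] + effect_log2
    expr <- 2^logex

    truth <- list(
      responsive = data.frame(
        gene_id = resp_genes,
        aberrant_samples = vapply(aberrant, paste, "", collapse = ";")),
      null_genes = setdiff(gtab$gene_id, resp_genes),
      germline = do.call(rbind, germ_truth))
    list(segments = segments, profiles = profiles, expr = expr,
         germline = list(gold = gold, supporting = supp), truth = truth)
  })
}

#' Plant promoter-methylation driver structure
#'
#' Driver genes get bimodal promoter betas anti-correlated with expression
#' (hypermethylated cluster expresses lower); rejection-class genes exercise
#' the minimum-cluster-size and minimum-beta-difference filters; null genes
#' are unimodal. Each driver gene carries two correlated promoter probes
#' (merged into a probe set downstream) plus one probe beyond 1500 bp of the
#' TSS that must be discarded.
#'
#' @param genes [gene_models()] supplying gene ids and TSS positions.
#' @param n_samples cohort size (>= 20).
#' @param n_driver planted hyper drivers.
#' @param n_small_cluster genes whose minor beta cluster holds 4% of samples.
#' @param n_small_diff genes with beta separation 0.2 (below the 0.25 bar).
#' @param n_null unimodal null genes.
#' @param driver_means beta means of the two driver clusters (difference is
#'   the planted `diff_mean`).
#' @param expr_shift z-score expression shift of the hypermethylated
#'   cluster (negative = silenced).
#' @param beta_sd within-cluster beta standard deviation.
#' @param seed RNG seed.
#' @return list: `betas` (probes x samples), `probes` (annotation), `expr_z`
#'   (genes x samples), `truth`.
#' @export
plant_methyl <- function(genes, n_samples = 100, n_driver = 10,
                         n_small_cluster = 3, n_small_diff = 3, n_null = 200,
                         driver_means = c(0.2, 0.6), expr_shift = -1.5,
                         beta_sd = 0.05, seed = 1) {
  gtab <- genes$genes
  n_need <- n_driver + n_small_cluster + n_small_diff + n_null
  if (nrow(gtab) < n_need)
    stopf("need %d genes but gene models supply %d", n_need, nrow(gtab))
  with_seed(seed, {
    samples <- sprintf("M%03d", seq_len(n_samples))
    ids <- gtab$gene_id[seq_len(n_need)]
    classes <- rep(c("driver", "small_cluster", "small_diff", "null"),
                   c(n_driver, n_small_cluster, n_small_diff, n_null))
    probes <- list(); betas <- list(); exprz <- list(); truth <- list()
    clip <- function(x) pmin(0.99, pmax(0.01, x))
    for (i in seq_along(ids)) {
      g <- ids[i]; cls <- classes[i]
      if (cls == "driver") {
        n_hi <- round(0.3 * n_samples)
        hi <- sample(samples, n_hi)
        mu <- ifelse(samples %in% hi, driver_means[2], driver_means[1])
        signal <- clip(rnorm(n_samples, mu, beta_sd))
        z <- rnorm(n_samples, 0.45, 0.25) + ifelse(samples %in% hi, expr_shift, 0)
        ## two correlated promoter probes + one beyond the promoter window
        for (k in 1:2) {
          pid <- sprintf("%s_p%d", g, k)
          probes[[length(probes) + 1L]] <- data.frame(
            probe_id = pid, gene_id = g, tss_distance = c(-200, 350)[k])
          betas[[pid]] <- clip(signal + rnorm(n_samples, 0, 0.01))
        }
        pid <- sprintf("%s_far", g)
        probes[[length(probes) + 1L]] <- data.frame(
          probe_id = pid, gene_id = g, tss_distance = 1600)
        betas[[pid]] <- clip(rnorm(n_samples, 0.5, 0.05))
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = g, class = cls, diff_mean = diff(driver_means),
          expr_shift = expr_shift, frac_high = n_hi / n_samples,
          expected_reason = NA_character_)
      } else {
        if (cls == "small_cluster") {
          n_hi <- max(2, round(0.04 * n_samples))
          hi <- sample(samples, n_hi)
          mu <- ifelse(samples %in% hi, driver_means[2], driver_means[1])
          reason <- "min_cluster"
        } else if (cls == "small_diff") {
          hi <- sample(samples, round(0.3 * n_samples))
          mu <- ifelse(samples %in% hi, 0.6, 0.4)
          reason <- "diff_mean"
        } else {
          hi <- character(); mu <- 0.45
          reason <- "k1"
        }
        signal <- clip(rnorm(n_samples, mu, if (cls == "small_diff") 0.04 else beta_sd))
        z <- rnorm(n_samples, 0, 1) + ifelse(samples %in% hi, expr_shift, 0)
        pid <- sprintf("%s_p1", g)
        probes[[length(probes) + 1L]] <- data.frame(
          probe_id = pid, gene_id = g, tss_distance = -150)
        betas[[pid]] <- signal
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = g, class = cls, diff_mean = NA_real_, expr_shift = NA_real_,
          frac_high = length(hi) / n_samples, expected_reason = reason)
      }
      exprz[[g]] <- z
    }
    beta_m <- do.call(rbind, betas)
    colnames(beta_m) <- samples
    z_m <- do.call(rbind, exprz)
    colnames(z_m) <- samples
    list(betas = beta_m, probes = do.call(rbind, probes), expr_z = z_m,
         truth = do.call(rbind, truth))
  })
}

#' Plant one exemplar variant per filter rule
#'
#' Emits an annotated variant table containing, for every rule of the
#' cascade, at least one variant that fails exactly that rule, plus clean
#' somatic variants, a COSMIC-rescued dbSNP hotspot and a
#' realignment-rescued low-pileup call.
#'
#' @param n_samples sample ids to spread the calls over.
#' @param seed RNG seed (used only to assign samples).
#' @return list: `calls` (variant data.frame), `truth` (intended status and
#'   reason per call).
#' @export
plant_variants <- function(n_samples = 10, seed = 1) {
  clean <- function(id, kind = "SNV", consequence = "missense") data.frame(
    variant_id = id, chrom = "chr1", pos = 0L, ref = "A", alt = "T",
    kind = kind, depth = 60L, alt_reads = 20L, consequence = consequence,
    population_af_max = 0.0005, radar_editing = FALSE,
    intron_exact_deletion = FALSE, softclip_only = FALSE, cosmic_count = 0L,
    in_snp_db = FALSE, sift = 0.001, polyphen_hdiv = 0.999,
    polyphen_hvar = 0.999, mutation_taster = "disease_causing",
    mutation_assessor = "functional", hp_base = NA_character_,
    hp_run_length = NA_integer_,
    snp_db_positions = "000000000000000000000", ebcall_p = 1e-5,
    mpileup_alt_reads = 20L)
  rows <- list(); truth <- list()
  add <- function(row, status, reason = NA_character_) {
    rows[[length(rows) + 1L]] <<- row
    truth[[length(truth) + 1L]] <<- data.frame(
      variant_id = row$variant_id, intended_status = status,
      intended_reason = reason)
  }
  r <- clean("v_pop_af"); r$population_af_max <- 0.02
  add(r, "filtered", "pop_af")
  r <- clean("v_radar"); r$radar_editing <- TRUE
  add(r, "filtered", "radar")
  r <- clean("v_intron_del", kind = "deletion"); r$ref <- "AGGTAAGTAG"; r$alt <- "A"
  r$intron_exact_deletion <- TRUE
  add(r, "filtered", "intron_deletion")
  r <- clean("v_softclip"); r$softclip_only <- TRUE
  add(r, "filtered", "softclip")
  r <- clean("v_low_support"); r$alt_reads <- 4L; r$mpileup_alt_reads <- 4L
  add(r, "filtered", "low_support")
  r <- clean("v_homopolymer", kind = "insertion"); r$ref <- "A"; r$alt <- "AA"
  r$hp_base <- "A"; r$hp_run_length <- 6L
  add(r, "filtered", "homopolymer")
  r <- clean("v_snp_cluster")
  r$snp_db_positions <- paste(rep("1", 21), collapse = "")
  add(r, "filtered", "snp_cluster")
  r <- clean("v_snp_db"); r$in_snp_db <- TRUE
  add(r, "filtered", "snp_db")
  r <- clean("v_benign"); r$sift <- 0.2
  add(r, "filtered", "benign")
  r <- clean("v_ebcall"); r$ebcall_p <- 0.01; r$mpileup_alt_reads <- 22L
  r$alt_reads <- 22L
  add(r, "filtered", "ebcall")
  add(clean("v_clean_snv"), "pass")
  r <- clean("v_clean_frameshift", kind = "insertion", consequence = "frameshift")
  r$ref <- "A"; r$alt <- "ACT"
  r$sift <- NA; r$polyphen_hdiv <- NA; r$polyphen_hvar <- NA
  r$mutation_taster <- NA; r$mutation_assessor <- NA
  add(r, "pass")
  r <- clean("v_cosmic_rescue"); r$in_snp_db <- TRUE; r$cosmic_count <- 12L
  add(r, "pass")
  r <- clean("v_realign_rescue"); r$ebcall_p <- 0.01; r$mpileup_alt_reads <- 3L
  add(r, "pass")
  calls <- do.call(rbind, rows)
  with_seed(seed, {
    calls$sample_id <- sample(sprintf("V%02d", seq_len(n_samples)),
                              nrow(calls), replace = TRUE)
  })
  calls$pos <- seq_len(nrow(calls)) * 1000L
  list(calls = calls, truth = do.call(rbind, truth))
}

#' Write a full synthetic cohort to disk
#'
#' Generates the fusion, copy-number, methylation and variant components
#' with sub-seeds derived from `seed` and writes every file in the standard
#' dialects plus `truth.json`. Outputs are byte-identical for identical
#' seeds and parameters.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master RNG seed.
#' @param n_tumors,n_controls fusion cohort sizes.
#' @return invisibly, a named list of generated objects and file paths.
#' @export
simulate_cohort <- function(out_dir, seed = 42, n_tumors = 60, n_controls = 8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  fus_genome <- make_genome(2, 50, 5e6, seed = seed)
  fus <- plant_fusions(fus_genome, n_tumors, n_controls, seed = seed + 1)
  cna_genome <- make_genome(2, 110, 30e6, seed = seed + 2, sequence = FALSE)
  cna <- plant_cna(cna_genome$genes, seed = seed + 3)
  methyl <- plant_methyl(cna_genome$genes, seed = seed + 4)
  vars <- plant_variants(seed = seed + 5)

  write_genome_fasta(fus_genome$genome, p("genome.fa"))
  write_gene_models_bed12(fus_genome$genes, p("genes.bed"))
  write_gene_models_bed12(cna_genome$genes, p("cna_genes.bed"))
  write_fusion_calls(fus$tumor_calls, p("tumor_fusions.tsv"))
  dir.create(p("controls"), showWarnings = FALSE)
  for (lib in names(fus$control_calls))
    write_fusion_calls(fus$control_calls[[lib]], p("controls", paste0(lib, "_calls.tsv")))
  for (lib in names(fus$control_reads))
    write.table(fus$control_reads[[lib]], p("controls", paste0(lib, "_reads.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedpe(fus$wgs_sv, p("sv.bedpe"))
  write_segments(fus$segments, p("fusion_segments.seg"))
  write.table(fus$profiles, p("fusion_ploidy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(fus$expr, p("fusion_rpkm.tsv"), "gene_id")
  write_coverage(fus$coverage, p("coverage.tsv"))

  write_segments(cna$segments, p("cna_segments.seg"))
  write.table(cna$profiles, p("cna_ploidy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(cna$expr, p("cna_rpkm.tsv"), "gene_id")
  gold <- cna$germline$gold; gold$start <- gold$start + 1
  supp <- cna$germline$supporting; supp$start <- supp$start + 1
  write.table(gold, p("dgv_gold.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(supp, p("dgv_supporting.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  write_matrix_tsv(methyl$betas, p("methyl_betas.tsv"), "probe_id")
  write.table(methyl$probes, p("methyl_probes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(methyl$expr_z, p("methyl_zscores.tsv"), "gene_id")

  write_variant_calls(vars$calls, p("variants.tsv"))

  truth <- list(seed = seed,
                fusions = fus$truth,
                cna_responsive = cna$truth$responsive,
                cna_null_genes = cna$truth$null_genes,
                cna_germline = cna$truth$germline,
                methyl = methyl$truth,
                variants = vars$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fusion_genome = fus_genome, fusions = fus,
                 cna_genes = cna_genome$genes, cna = cna, methyl = methyl,
                 variants = vars, dir = out_dir))
}

#' Write / read junction coverage tracks
#'
#' Long TSV: isoform_key, side (5/3), comma-joined per-base depths.
#'
#' @param coverage named list of `list(cov5=, cov3=)`.
#' @param path TSV path.
#' @export
write_coverage <- function(coverage, path) {
  rows <- list()
  for (key in names(coverage)) {
    rows[[length(rows) + 1L]] <- data.frame(
      isoform_key = key, side = c(5L, 3L),
      depths = c(paste(round(coverage[[key]]$cov5, 3), collapse = ","),
                 paste(round(coverage[[key]]$cov3, 3), collapse = ",")))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(isoform_key = character(), side = integer(), depths = character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(df$isoform_key)) {
    s <- df[df$isoform_key == key, ]
    out[[key]] <- list(
      cov5 = as.numeric(strsplit(s$depths[s$side == 5], ",")[[1]]),
      cov3 = as.numeric(strsplit(s$depths[s$side == 3], ",")[[1]]))
  }
  out
}

#' Write gene models as BED12
#' @param gm [gene_models()] object.
#' @param path output path.
#' @export
write_gene_models_bed12 <- function(gm, path) {
  g <- gm$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    ex <- gene_exons(gm, g$gene_id[i])
    paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0, g$strand[i],
          g$start[i], g$end[i], "0,0,0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - g$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
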