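## Copy-number segment post-processing: size-weighted merging of similar
## adjacent segments, germline CNV filtering against gold/supporting
## catalogs, state assignment, broad/focal splitting, gene-level state calls
## and Kruskal-Wallis detection of copy-number-responsive genes.

#' Merge adjacent copy-number segments with similar log-ratios
#'
#' Within each sample and chromosome, any run of adjacent segments whose
#' consecutive log-ratios differ by strictly less than `tolerance` is
#' replaced by a single segment whose log-ratio (and copy number) is the
#' segment-length-weighted mean of the run. Applied iteratively until a
#' fixpoint; never merges across chromosomes or samples.
#'
#' @param segments segment data.frame (sample_id, chrom, start, end,
#'   copy_number, log_ratio), sorted and non-overlapping per chromosome.
#' @param tolerance merge threshold on adjacent log-ratio differences
#'   (default 0.25, strict `<`).
#' @return merged segment data.frame.
#' @export
merge_adjacent <- function(segments, tolerance = 0.25) {
  if (nrow(segments) == 0) return(segments)
  check_disjoint_sorted(segments)
  ## strict d < tolerance, with a 1e-9 guard so differences sitting exactly
  ## on the threshold (up to float representation) never merge
  mergeable <- function(d) tolerance - d > 1e-9
  merge_group <- function(s) {
    repeat {
      if (nrow(s) < 2) return(s)
      d <- abs(diff(s$log_ratio))
      if (!any(mergeable(d))) return(s)
      ## maximal runs of mergeable adjacencies
      run_id <- cumsum(c(0, as.integer(!mergeable(d))))
      s <- do.call(rbind, lapply(split(s, run_id), function(r) {
        if (nrow(r) == 1) return(r)
        w <- r$end - r$start
        data.frame(sample_id = r$sample_id[1], chrom = r$chrom[1],
                   start = min(r$start), end = max(r$end),
                   copy_number = sum(w * r$copy_number) / sum(w),
                   log_ratio = sum(w * r$log_ratio) / sum(w))
      }))
      s <- s[order(s$start), , drop = FALSE]
    }
  }
  key <- paste(segments$sample_id, segments$chrom)
  parts <- lapply(split(segments[, c("sample_id", "chrom", "start", "end",
                                     "copy_number", "log_ratio")],
                        factor(key, levels = unique(key))), merge_group)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Remove germline copy-number variants from segment profiles
#'
#' Stage 1 removes segments with at least 50% reciprocal overlap to any gold
#' catalog variant, then re-merges; stage 2 removes segments with at least
#' 80% reciprocal overlap to any supporting-catalog variant, then re-merges
#' again. The catalogs are expected pre-restricted ([read_germline_db()]) to
#' gold variants at >= 1% frequency and supporting variants from studies of
#' >= 50 subjects at >= 1% in-study frequency.
#'
#' @param segments merged segment data.frame.
#' @param db list with `gold` and `supporting` interval data.frames (either
#'   may be `NULL`).
#' @param cfg configuration list.
#' @return filtered and re-merged segment data.frame.
#' @export
filter_germline <- function(segments, db, cfg = shhland_config()) {
  if (is.null(db$gold) && is.null(db$supporting)) {
    warnf("empty germline catalog: segments unchanged")
    return(segments)
  }
  drop_overlapping <- function(seg, catalog, min_ro) {
    if (is.null(catalog) || nrow(catalog) == 0 || nrow(seg) == 0) return(seg)
    keep <- vapply(seq_len(nrow(seg)), function(i) {
      s <- seg[i, ]
      cand <- catalog[catalog$chrom == s$chrom, , drop = FALSE]
      if (nrow(cand) == 0) return(TRUE)
      ro <- vapply(seq_len(nrow(cand)), function(j)
        reciprocal_overlap(s, cand[j, ]), numeric(1))
      all(ro < min_ro)
    }, logical(1))
    seg[keep, , drop = FALSE]
  }
  seg <- drop_overlapping(segments, db$gold, cfg$germline.gold_ro)
  seg <- merge_adjacent(seg, cfg$merge_tolerance)
  seg <- drop_overlapping(seg, db$supporting, cfg$germline.supporting_ro)
  merge_adjacent(seg, cfg$merge_tolerance)
}

#' Assign copy-number states to segments
#'
#' Default mapping (thresholds configurable): `deletion` when the copy
#' number is 0, `loss` when the log-ratio is at most -0.25, `amplification`
#' at log-ratio >= 1.0, `gain` at log-ratio >= 0.25, otherwise `neutral`.
#'
#' @param segments segment data.frame with `copy_number` and `log_ratio`.
#' @param cfg configuration list.
#' @return segments with a `state` column.
#' @export
assign_states <- function(segments, cfg = shhland_config()) {
  lr <- segments$log_ratio
  state <- rep("neutral", nrow(segments))
  state[lr >= cfg$state.gain] <- "gain"
  state[lr >= cfg$state.amp] <- "amplification"
  state[lr <= cfg$state.loss] <- "loss"
  state[segments$copy_number < 0.5] <- "deletion"
  segments$state <- state
  segments
}

#' Split segments into broad and focal
#'
#' `broad` when the segment spans strictly more than 12 Mb, `focal` when
#' equal to or less than 12 Mb.
#'
#' @param segments segment data.frame.
#' @param cfg configuration list.
#' @return segments with a `scope` column.
#' @export
split_broad_focal <- function(segments, cfg = shhland_config()) {
  segments$scope <- ifelse(segments$end - segments$start > cfg$focal_max_len,
                           "broad", "focal")
  segments
}

#' Gene-level copy-number state (first past the post)
#'
#' The gene takes the log-ratio and state of the segment overlapping the
#' greatest amount of it, regardless of whether that is a majority. A
#' gain/amplification winner must additionally cover at least 50% of the
#' gene, else the gene is demoted to neutral; any overlap by a
#' loss/deletion winner confers that status. A gene with no overlapping
#' segment is neutral (`uncovered`).
#'
#' @param gene one-row data.frame with `chrom`, `start`, `end`.
#' @param segments one sample's state-assigned segments.
#' @return list with `state`, `log_ratio`, `source_scope`, `covered_frac`.
#' @export
gene_level_state <- function(gene, segments) {
  seg <- segments[segments$chrom == gene$chrom, , drop = FALSE]
  glen <- gene$end - gene$start
  if (nrow(seg)) {
    ov <- overlap_len(gene$start, gene$end, seg$start, seg$end)
    seg <- seg[ov > 0, , drop = FALSE]; ov <- ov[ov > 0]
  } else ov <- numeric()
  if (!nrow(seg))
    return(list(state = "neutral", log_ratio = NA_real_,
                source_scope = NA_character_, covered_frac = 0))
  i <- which.max(ov)
  state <- seg$state[i]
  frac <- ov[i] / glen
  if (state %in% c("gain", "amplification") && frac < 0.5) state <- "neutral"
  list(state = state, log_ratio = seg$log_ratio[i],
       source_scope = if (!is.null(seg$scope)) seg$scope[i] else NA_character_,
       covered_frac = frac)
}

#' Gene-level state calls for a whole cohort
#'
#' Applies [gene_level_state()] to every gene and sample.
#'
#' @param genes [gene_models()].
#' @param segments state-assigned segments for all samples.
#' @return data.frame gene_id, sample_id, state, log_ratio, source_scope.
#' @export
gene_cn_calls <- function(genes, segments) {
  samples <- unique(segments$sample_id)
  gtab <- genes$genes
  res <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[k], , drop = FALSE]
    rows <- lapply(seq_len(nrow(gtab)), function(i) {
      st <- gene_level_state(gtab[i, ], seg)
      data.frame(gene_id = gtab$gene_id[i], sample_id = samples[k],
                 state = st$state, log_ratio = st$log_ratio,
                 source_scope = st$source_scope)
    })
    res[[k]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene-by-sample state matrix
#' @param calls data.frame from [gene_cn_calls()].
#' @return character matrix genes x samples.
#' @export
gene_state_matrix <- function(calls) {
  genes <- unique(calls$gene_id); samples <- unique(calls$sample_id)
  m <- matrix("neutral", length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(calls$gene_id, genes), match(calls$sample_id, samples))] <- calls$state
  m
}

## Collapse the five states into the three tested categories.
collapse_states <- function(state) {
  out <- rep("neutral", length(state))
  out[state %in% c("deletion", "loss")] <- "loss"
  out[state %in% c("gain", "amplification")] <- "gain"
  out
}

#' Detect copy-number-responsive genes
#'
#' For each gene, samples are grouped by collapsed copy-number category
#' (loss-like, neutral, gain-like) and expression is compared across groups
#' with the Kruskal-Wallis test (chi-square approximation, tie-corrected).
#' P-values are adjusted with Benjamini-Hochberg across tested genes; a gene
#' is responsive when its adjusted value falls below 0.05. Genes with fewer
#' than two categories holding at least two samples each are reported NA and
#' excluded from the FDR.
#'
#' @param states gene-by-sample character state matrix
#'   ([gene_state_matrix()]).
#' @param expr expression matrix (genes x samples) aligned by dimnames;
#'   typically RPKM.
#' @param cfg configuration list.
#' @return data.frame gene_id, h_statistic, p_value, q_value, responsive,
#'   n_loss, n_neutral, n_gain.
#' @export
cn_responsive_test <- function(states, expr, cfg = shhland_config()) {
  common_genes <- intersect(rownames(states), rownames(expr))
  common_samples <- intersect(colnames(states), colnames(expr))
  res <- data.frame(gene_id = common_genes, h_statistic = NA_real_,
                    p_value = NA_real_, q_value = NA_real_, responsive = NA,
                    n_loss = 0L, n_neutral = 0L, n_gain = 0L)
  for (i in seq_along(common_genes)) {
    g <- common_genes[i]
    cat3 <- collapse_states(states[g, common_samples])
    counts <- table(factor(cat3, levels = c("loss", "neutral", "gain")))
    res$n_loss[i] <- counts[["loss"]]
    res$n_neutral[i] <- counts[["neutral"]]
    res$n_gain[i] <- counts[["gain"]]
    if (sum(counts >= 2) < 2) next
    keep <- cat3 %in% names(counts)[counts >= 2]
    kw <- kruskal.test(expr[g, common_samples][keep], factor(cat3[keep]))
    res$h_statistic[i] <- unname(kw$statistic)
    res$p_value[i] <- kw$p.value
  }
  tested <- !is.na(res$p_value)
  res$q_value[tested] <- p.adjust(res$p_value[tested], method = "BH")
  res$responsive <- !is.na(res$q_value) & res$q_value < cfg$test.cn_responsive_q
  res$responsive[!tested] <- NA
  res
}

#' Normalize an expression row by its neutral-state median
#'
#' Divides each sample's value by the median over copy-number-neutral
#' samples (or subtracts it when `log_space = TRUE`).
#'
#' @param expr_row named numeric vector of expression values.
#' @param states_row character state vector aligned to `expr_row`.
#' @param log_space subtract instead of divide.
#' @return normalized numeric vector.
#' @export
neutral_normalize <- function(expr_row, states_row, log_space = FALSE) {
  neutral <- collapse_states(states_row) == "neutral"
  if (!any(neutral)) stopf("no neutral samples to normalize against")
  m <- median(expr_row[neutral])
  if (log_space) return(expr_row - m)
  if (m == 0) stopf("neutral-state median is zero; cannot form ratios")
  expr_row / m
}
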