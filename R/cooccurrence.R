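## Alteration matrix construction and pairwise co-occurrence / mutual
## exclusivity testing. Co-occurrence uses the two-sided Fisher exact test;
## exclusivity uses a margin-preserving checkerboard-swap permutation null
## (a documented stand-in for groupwise mutual-exclusivity tests, keeping
## the same margins-aware intent).

#' Build the binary alteration matrix
#'
#' A sample carries an event for a panel gene when it has a passing somatic
#' mutation, a high-level copy-number state (amplification or deletion), or
#' an SV-supported fusion involving that gene. Arm-level events are passed
#' through as their own features.
#'
#' @param panel character vector of feature identifiers (genes and arm
#'   labels) to include; every feature must be resolvable.
#' @param samples character vector of cohort sample ids (matrix columns).
#' @param variant_verdicts optional output of [run_variant_cascade()] with a
#'   `gene_id` column.
#' @param cn_calls optional output of [gene_cn_calls()].
#' @param fusion_verdicts optional output of [tier_fusions()].
#' @param arm_events optional data.frame `sample_id`, `feature` of arm-level
#'   gains/losses.
#' @return binary integer matrix features x samples.
#' @export
build_matrix <- function(panel, samples, variant_verdicts = NULL,
                         cn_calls = NULL, fusion_verdicts = NULL,
                         arm_events = NULL) {
  if (length(panel) == 0) stopf("empty driver panel")
  if (anyDuplicated(panel)) stopf("duplicated panel feature(s)")
  m <- matrix(0L, length(panel), length(samples),
              dimnames = list(panel, samples))
  mark <- function(feature, sample) {
    ok <- feature %in% panel & sample %in% samples
    f <- feature[ok]; s <- sample[ok]
    if (length(f)) m[cbind(match(f, panel), match(s, samples))] <<- 1L
  }
  known <- character()
  if (!is.null(variant_verdicts) && nrow(variant_verdicts)) {
    stopifnot(!is.null(variant_verdicts$gene_id))
    keep <- variant_verdicts$status == "pass"
    mark(variant_verdicts$gene_id[keep], variant_verdicts$sample_id[keep])
    known <- c(known, variant_verdicts$gene_id)
  }
  if (!is.null(cn_calls) && nrow(cn_calls)) {
    keep <- cn_calls$state %in% c("amplification", "deletion")
    mark(cn_calls$gene_id[keep], cn_calls$sample_id[keep])
    known <- c(known, cn_calls$gene_id)
  }
  if (!is.null(fusion_verdicts) && nrow(fusion_verdicts)) {
    keep <- fusion_verdicts$status == "pass" &
      fusion_verdicts$sv_tier == "sv_supported"
    mark(fusion_verdicts$gene5[keep], fusion_verdicts$sample_id[keep])
    mark(fusion_verdicts$gene3[keep], fusion_verdicts$sample_id[keep])
    known <- c(known, fusion_verdicts$gene5, fusion_verdicts$gene3)
  }
  if (!is.null(arm_events) && nrow(arm_events)) {
    mark(arm_events$feature, arm_events$sample_id)
    known <- c(known, arm_events$feature)
  }
  unknown <- setdiff(panel, known)
  if (length(unknown))
    stopf("panel feature(s) with no event source: %s", paste(unknown, collapse = ", "))
  m
}

pair_contingency <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

#' Fisher co-occurrence test over all feature pairs
#'
#' Two-sided exact p-values per pair from the hypergeometric distribution,
#' Benjamini-Hochberg adjusted across pairs. A pair co-occurs significantly
#' when `q < 0.01` and the odds ratio exceeds 1.
#'
#' @param m binary alteration matrix ([build_matrix()]).
#' @param cfg configuration list.
#' @return data.frame feature_a, feature_b, n11, n10, n01, n00, odds_ratio,
#'   p_cooccur, q_cooccur, cooccurrent.
#' @export
fisher_cooccurrence <- function(m, cfg = shhland_config()) {
  if (nrow(m) < 2) stopf("need at least two features")
  idx <- utils::combn(rownames(m), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- m[idx[1, j], ]; b <- m[idx[2, j], ]
    ct <- pair_contingency(a, b)
    or <- (ct["n11"] * ct["n00"]) / (ct["n10"] * ct["n01"])
    p <- if (sum(a) == 0 || sum(b) == 0) 1 else
      fisher.test(matrix(ct[c("n11", "n10", "n01", "n00")], 2, byrow = TRUE))$p.value
    data.frame(feature_a = idx[1, j], feature_b = idx[2, j],
               n11 = ct[["n11"]], n10 = ct[["n10"]], n01 = ct[["n01"]],
               n00 = ct[["n00"]], odds_ratio = unname(or), p_cooccur = p)
  })
  out <- do.call(rbind, rows)
  out$q_cooccur <- p.adjust(out$p_cooccur, method = "BH")
  out$cooccurrent <- out$q_cooccur < cfg$test.pair_q & out$odds_ratio > 1
  out
}

## One checkerboard swap attempt: pick two rows and two columns at random;
## if the 2x2 submatrix is a checkerboard, flip it. Preserves all row and
## column sums exactly.
swap_step <- function(m) {
  r <- sample.int(nrow(m), 2); c <- sample.int(ncol(m), 2)
  sub <- m[r, c]
  if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] && sub[1, 1] != sub[1, 2]) {
    m[r, c] <- 1L - sub
  }
  m
}

## A null matrix drawn by a chain of checkerboard swaps.
swap_null <- function(m, n_swaps) {
  for (i in seq_len(n_swaps)) m <- swap_step(m)
  m
}

#' Permutation test of mutual exclusivity
#'
#' The observed co-occurrence count of each pair is compared against a null
#' that preserves every gene's event total and every sample's event total
#' exactly, generated by checkerboard swap randomization of the binary
#' matrix. The one-sided p-value is
#' `(1 + #{null n11 <= observed n11}) / (1 + n_perm)`; small values mean the
#' pair overlaps less than the margins predict. Benjamini-Hochberg across
#' pairs; significant exclusivity at `q < 0.01`.
#'
#' @param m binary alteration matrix.
#' @param n_perm number of null matrices (>= 100).
#' @param seed RNG seed (required for reproducibility).
#' @param burnin,thin swap counts before the first draw and between draws
#'   (defaults scale with the number of events).
#' @param cfg configuration list.
#' @return data.frame feature_a, feature_b, n11, p_exclusive, q_exclusive,
#'   exclusive.
#' @export
permutation_exclusivity <- function(m, n_perm = 1000, seed = NULL,
                                    burnin = NULL, thin = NULL,
                                    cfg = shhland_config()) {
  if (n_perm < 100) stopf("n_perm must be at least 100")
  if (nrow(m) < 2) stopf("need at least two features")
  n_events <- sum(m)
  if (n_events == 0 || all(m == 1)) warnf("degenerate matrix: swaps are no-ops")
  burnin <- burnin %||% (10L * max(1L, n_events))
  thin <- thin %||% max(1L, n_events)
  idx <- utils::combn(rownames(m), 2)
  obs <- vapply(seq_len(ncol(idx)), function(j)
    sum(m[idx[1, j], ] == 1 & m[idx[2, j], ] == 1), integer(1))
  le_count <- integer(ncol(idx))
  with_seed(seed, {
    cur <- swap_null(m, burnin)
    for (b in seq_len(n_perm)) {
      cur <- swap_null(cur, thin)
      null_n11 <- vapply(seq_len(ncol(idx)), function(j)
        sum(cur[idx[1, j], ] == 1 & cur[idx[2, j], ] == 1), integer(1))
      le_count <- le_count + as.integer(null_n11 <= obs)
    }
  })
  p <- (1 + le_count) / (1 + n_perm)
  out <- data.frame(feature_a = idx[1, ], feature_b = idx[2, ], n11 = obs,
                    p_exclusive = p)
  out$q_exclusive <- p.adjust(out$p_exclusive, method = "BH")
  out$exclusive <- out$q_exclusive < cfg$test.pair_q
  out
}

#' Joint co-occurrence / exclusivity pair table
#'
#' @param m binary alteration matrix.
#' @param n_perm,seed passed to [permutation_exclusivity()].
#' @param cfg configuration list.
#' @return merged data.frame of [fisher_cooccurrence()] and
#'   [permutation_exclusivity()] results.
#' @export
pair_tests <- function(m, n_perm = 1000, seed = NULL, cfg = shhland_config()) {
  co <- fisher_cooccurrence(m, cfg)
  ex <- permutation_exclusivity(m, n_perm = n_perm, seed = seed, cfg = cfg)
  merge(co, ex[, c("feature_a", "feature_b", "p_exclusive", "q_exclusive",
                   "exclusive")],
        by = c("feature_a", "feature_b"), sort = FALSE)
}

#' Long-format event table for oncoprint-style plotting
#'
#' @param m binary alteration matrix.
#' @return data.frame sample, feature, event.
#' @export
event_long_table <- function(m) {
  idx <- which(m == 1L, arr.ind = TRUE)
  data.frame(sample = colnames(m)[idx[, 2]], feature = rownames(m)[idx[, 1]],
             event = 1L)
}
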