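## Promoter-methylation driver detection: promoter probe grouping, beta-value
## mixture clustering, and the effect-size filters with the
## diff-mean x diff-expression ranking score.

#' Group promoter probes per gene
#'
#' Keeps probes within 1500 bp of the transcription start site, then, within
#' each gene, averages probes whose beta profiles correlate (Pearson r at or
#' above `methyl.probe_corr`, default 0.7) into probe sets; the remaining
#' probes are analyzed individually. Grouping is complete-linkage on
#' `1 - r`, so every pair inside a set meets the threshold.
#'
#' @param probes probe annotation data.frame: `probe_id`, `gene_id`,
#'   `tss_distance` (signed bp).
#' @param betas probes-by-samples beta matrix (rownames = probe ids).
#' @param cfg configuration list.
#' @return list with `units` (data.frame unit_id, gene_id, probe_ids
#'   semicolon-joined, n_probes) and `betas` (units x samples matrix).
#'   Genes with no promoter probe are absent.
#' @export
promoter_probes <- function(probes, betas, cfg = shhland_config()) {
  stopifnot(all(c("probe_id", "gene_id", "tss_distance") %in% names(probes)))
  probes <- probes[abs(probes$tss_distance) <= cfg$methyl.tss_max_dist, , drop = FALSE]
  probes <- probes[probes$probe_id %in% rownames(betas), , drop = FALSE]
  units <- list(); unit_betas <- list()
  for (g in unique(probes$gene_id)) {
    pid <- probes$probe_id[probes$gene_id == g]
    b <- betas[pid, , drop = FALSE]
    if (any(b < 0 | b > 1)) stopf("beta values outside [0,1] for gene '%s'", g)
    groups <- if (length(pid) == 1) list(pid) else {
      r <- suppressWarnings(cor(t(b)))
      r[is.na(r)] <- 0
      hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
      mem <- stats::cutree(hc, h = 1 - cfg$methyl.probe_corr)
      unname(split(pid, mem))
    }
    for (grp in groups) {
      uid <- if (length(grp) == 1) grp else paste0(g, "_set_", length(units) + 1L)
      units[[length(units) + 1L]] <- data.frame(
        unit_id = uid, gene_id = g,
        probe_ids = paste(grp, collapse = ";"), n_probes = length(grp))
      unit_betas[[length(unit_betas) + 1L]] <-
        if (length(grp) == 1) b[grp, ] else colMeans(b[grp, , drop = FALSE])
    }
  }
  if (!length(units))
    return(list(units = data.frame(unit_id = character(), gene_id = character(),
                                   probe_ids = character(), n_probes = integer()),
                betas = matrix(numeric(), 0, ncol(betas),
                               dimnames = list(NULL, colnames(betas)))))
  units <- do.call(rbind, units)
  bm <- do.call(rbind, unit_betas)
  rownames(bm) <- units$unit_id
  colnames(bm) <- colnames(betas)
  list(units = units, betas = bm)
}

#' Fit a beta-value mixture model for one promoter unit
#'
#' Univariate Gaussian mixtures with 1-3 components (unequal variances) are
#' fitted to the unit's beta values and the component count is selected by
#' BIC. Fitting is deterministic: initialization uses model-based
#' hierarchical agglomeration, so repeated fits agree. One-component fits
#' mark non-driver units.
#'
#' @param beta numeric vector of beta values (one per sample; >= 20
#'   recommended).
#' @param max_k maximum component count (default 3).
#' @return list of class `methyl_clusters`: `k`, `means` (ascending),
#'   `proportions`, `assignments` (component index per sample, aligned to
#'   ascending means), `bic`.
#' @export
fit_methyl_clusters <- function(beta, max_k = 3) {
  if (length(beta) < 20)
    warnf("mixture fit on %d samples; >= 20 recommended", length(beta))
  if (sd(beta) < 1e-8) {
    return(structure(list(k = 1L, means = mean(beta), proportions = 1,
                          assignments = rep(1L, length(beta)), bic = NA_real_),
                     class = "methyl_clusters"))
  }
  fit <- tryCatch(
    mclust::Mclust(beta, G = seq_len(max_k), modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- mclust::Mclust(beta, G = 1, modelNames = "V", verbose = FALSE)
  means <- as.numeric(fit$parameters$mean)
  ord <- order(means)
  remap <- match(seq_along(ord), ord)
  pro <- fit$parameters$pro %||% 1
  structure(list(k = as.integer(fit$G),
                 means = means[ord],
                 proportions = as.numeric(pro)[ord],
                 assignments = remap[fit$classification],
                 bic = unname(fit$bic)),
            class = "methyl_clusters")
}

#' @export
print.methyl_clusters <- function(x, ...) {
  cat(sprintf("methyl_clusters: k=%d, means = %s\n", x$k,
              paste(sprintf("%.3f", x$means), collapse = ", ")))
  invisible(x)
}

#' Driver filters for one clustered promoter unit
#'
#' Rejects the unit when any methylation cluster holds fewer than 5% of the
#' samples; otherwise computes the beta difference (`diff_mean`) and the
#' z-score expression difference (`diff_exp`) between the two extreme
#' clusters (lowest- and highest-mean components) and rejects when
#' `|diff_mean| < 0.25` or `|diff_exp| < 0.75`. Direction is `hyper` when
#' the higher-beta cluster has the lower expression, `hypo` otherwise; the
#' ranking score is `|diff_mean * diff_exp|`.
#'
#' @param model `methyl_clusters` fit for the unit.
#' @param expr_z z-scored expression of the unit's gene, aligned to the
#'   samples the model was fitted on.
#' @param cfg configuration list.
#' @return list with `call` (one-row data.frame, or `NULL`) and `reason`
#'   (rejection reason, or `NA`). Reasons: `k1`, `min_cluster`, `diff_mean`,
#'   `diff_exp`.
#' @export
driver_filter <- function(model, expr_z, cfg = shhland_config()) {
  reject <- function(reason) list(call = NULL, reason = reason)
  if (model$k < 2) return(reject("k1"))
  if (min(model$proportions) < cfg$methyl.min_cluster_frac ||
      min(table(factor(model$assignments, levels = seq_len(model$k)))) <
        cfg$methyl.min_cluster_frac * length(model$assignments))
    return(reject("min_cluster"))
  lo <- 1L; hi <- model$k  # extreme clusters: min-mean and max-mean
  diff_mean <- model$means[hi] - model$means[lo]
  z_lo <- mean(expr_z[model$assignments == lo])
  z_hi <- mean(expr_z[model$assignments == hi])
  diff_exp <- z_hi - z_lo
  if (abs(diff_mean) < cfg$methyl.min_diff_mean) return(reject("diff_mean"))
  if (abs(diff_exp) < cfg$methyl.min_diff_exp) return(reject("diff_exp"))
  direction <- if (diff_exp < 0) "hyper" else "hypo"
  list(call = data.frame(direction = direction, diff_mean = diff_mean,
                         diff_exp = diff_exp,
                         score = abs(diff_mean * diff_exp)),
       reason = NA_character_)
}

#' Scan a cohort for promoter-methylation driver genes
#'
#' Runs [promoter_probes()], [fit_methyl_clusters()] and [driver_filter()]
#' over every gene and returns calls ranked by score (descending) together
#' with the rejection reason for every analyzed unit.
#'
#' @param betas probes-by-samples beta matrix.
#' @param probes probe annotation data.frame (`probe_id`, `gene_id`,
#'   `tss_distance`).
#' @param expr_z z-scored expression matrix (genes x samples).
#' @param cfg configuration list.
#' @return data.frame unit_id, gene_id, k, direction, diff_mean, diff_exp,
#'   score, called, reason; called rows first, by descending score.
#' @export
methyl_driver_scan <- function(betas, probes, expr_z, cfg = shhland_config()) {
  pp <- promoter_probes(probes, betas, cfg)
  samples <- intersect(colnames(pp$betas), colnames(expr_z))
  rows <- list()
  for (i in seq_len(nrow(pp$units))) {
    u <- pp$units[i, ]
    if (!u$gene_id %in% rownames(expr_z)) next
    model <- fit_methyl_clusters(pp$betas[u$unit_id, samples])
    res <- driver_filter(model, expr_z[u$gene_id, samples], cfg)
    rows[[i]] <- data.frame(
      unit_id = u$unit_id, gene_id = u$gene_id, k = model$k,
      direction = if (is.null(res$call)) NA_character_ else res$call$direction,
      diff_mean = if (is.null(res$call)) NA_real_ else res$call$diff_mean,
      diff_exp = if (is.null(res$call)) NA_real_ else res$call$diff_exp,
      score = if (is.null(res$call)) NA_real_ else res$call$score,
      called = !is.null(res$call), reason = res$reason)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(unit_id = character(), gene_id = character(),
                                      k = integer(), direction = character(),
                                      diff_mean = numeric(), diff_exp = numeric(),
                                      score = numeric(), called = logical(),
                                      reason = character()))
  out <- out[order(-out$called, -ifelse(is.na(out$score), -Inf, out$score)), ]
  rownames(out) <- NULL
  out
}
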