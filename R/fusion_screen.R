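## Fusion screening: blacklist construction from control RNA-seq libraries
## and the tumor-side filter cascade. Rule identifiers are stable strings:
## blacklist_pair, blacklist_bp, circular, readthrough, recurrent,
## expr_ratio, junction_prop, missing_expression.

#' Build the chimeric contig for a fusion call
#'
#' Concatenates up to `flank` bases ending at the 5' junction base with up to
#' `flank` bases starting at the 3' junction base, truncating at chromosome
#' (and, when gene models are supplied, gene-body) boundaries where
#' necessary. The returned junction offset is the number of 5'-side bases, so
#' the junction falls between contig positions `offset` and `offset + 1`.
#'
#' @param call one-row fusion-call data.frame (internal 0-based positions).
#' @param genome named character vector of chromosome sequences.
#' @param genes optional [gene_models()]; when given, flanks stop at the
#'   partner gene boundaries (transcript ends).
#' @param flank maximum bases per side (default 110).
#' @return list with `contig` (string) and `junction_offset`.
#' @export
build_fusion_contig <- function(call, genome, genes = NULL, flank = 110) {
  get_seq <- function(chrom, from0, to0) {  # 0-based inclusive bounds
    if (!chrom %in% names(genome)) stopf("chromosome '%s' not in genome", chrom)
    n <- nchar(genome[[chrom]])
    if (from0 > to0) return("")
    substr(genome[[chrom]], from0 + 1, min(to0 + 1, n))
  }
  chrom5 <- call$chrom5; pos5 <- call$pos5
  chrom3 <- call$chrom3; pos3 <- call$pos3
  if (!chrom5 %in% names(genome) || pos5 < 0 || pos5 >= nchar(genome[[chrom5]]))
    stopf("5' breakpoint %s:%d outside genome", chrom5, pos5)
  if (!chrom3 %in% names(genome) || pos3 < 0 || pos3 >= nchar(genome[[chrom3]]))
    stopf("3' breakpoint %s:%d outside genome", chrom3, pos3)
  lo5 <- max(0, pos5 - flank + 1)
  hi3 <- min(nchar(genome[[chrom3]]) - 1, pos3 + flank - 1)
  if (!is.null(genes)) {
    g5 <- gene_row(genes, call$gene5); g3 <- gene_row(genes, call$gene3)
    lo5 <- max(lo5, g5$start)
    hi3 <- min(hi3, g3$end - 1)
  }
  left <- get_seq(chrom5, lo5, pos5)
  right <- get_seq(chrom3, pos3, hi3)
  if (nchar(left) == 0 || nchar(right) == 0)
    stopf("empty genomic context at fusion junction")
  list(contig = paste0(left, right), junction_offset = nchar(left))
}

#' Test whether a control read qualifies as a contig blacklist hit
#'
#' A hit requires an exact, ungapped, full-length match of the read anywhere
#' in the contig, mean base quality strictly above `min_quality`, the
#' alignment to span the junction, and at least `min_overhang` bases past the
#' junction.
#'
#' @param contig contig string.
#' @param junction_offset 5'-side length as returned by
#'   [build_fusion_contig()].
#' @param read_seq read sequence.
#' @param read_qual numeric vector of per-base qualities (same length).
#' @param min_overhang required bases past the junction (default 20).
#' @param min_quality mean base quality must exceed this (default 30).
#' @return logical flag.
#' @export
contig_blacklist_hit <- function(contig, junction_offset, read_seq, read_qual,
                                 min_overhang = 20, min_quality = 30) {
  stopifnot(nchar(read_seq) == length(read_qual))
  if (mean(read_qual) <= min_quality) return(FALSE)
  len <- nchar(read_seq)
  if (len == 0 || len > nchar(contig)) return(FALSE)
  hits <- gregexpr(read_seq, contig, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(FALSE)
  for (s in hits) {           # s is 1-based alignment start in the contig
    e <- s + len - 1
    spans <- s <= junction_offset && e >= junction_offset + 1
    if (spans && (e - junction_offset) >= min_overhang) return(TRUE)
  }
  FALSE
}

#' Build fusion blacklists from control libraries
#'
#' Two evidence routes feed the gene-pair blacklist: (a) the fusion contig of
#' a tumor call carries a qualifying control read ([contig_blacklist_hit()]),
#' and (b) the pair is itself called in a control library. A pair is
#' blacklisted when either kind of evidence appears in at least two control
#' libraries, or when it is called in the designated fetal control library
#' plus at least two adult ones. Every breakpoint called in any control
#' library is blacklisted outright.
#'
#' @param tumor_calls fusion-call data.frame (tumor cohort).
#' @param control_call_sets named list of per-library fusion-call data.frames.
#' @param control_reads named list of per-library read tables with columns
#'   `sequence` and `qualities` (comma-separated per-base scores); may be
#'   `NULL`.
#' @param genome named character vector; required when `control_reads` given.
#' @param genes optional [gene_models()] passed to [build_fusion_contig()].
#' @param fetal_control name of the fetal control library, or `NULL`.
#' @param cfg configuration list.
#' @return object of class `fusion_blacklist`: list with `gene_pairs`
#'   (character set of `A|B` keys), `breakpoints` (`chrom:pos` keys) and
#'   `pair_libraries` (per-pair library counts behind the decision).
#' @export
build_blacklist <- function(tumor_calls, control_call_sets, control_reads = NULL,
                            genome = NULL, genes = NULL, fetal_control = NULL,
                            cfg = shhland_config()) {
  n_ctrl <- length(control_call_sets)
  if (n_ctrl == 0 && length(control_reads %||% list()) == 0) {
    warnf("no control libraries: returning an empty blacklist")
    return(structure(list(gene_pairs = character(), breakpoints = character(),
                          pair_libraries = integer()), class = "fusion_blacklist"))
  }
  lib_names <- union(names(control_call_sets) %||% as.character(seq_len(n_ctrl)),
                     names(control_reads) %||% character())
  ## evidence[pair] = set of libraries with contig-hit or called-pair evidence
  evidence <- list()
  add_evidence <- function(pairs, lib) {
    for (p in unique(pairs)) evidence[[p]] <<- union(evidence[[p]], lib)
  }

  ## (a) contig hits of control reads on tumor fusion contigs
  if (!is.null(control_reads) && length(control_reads) && nrow(tumor_calls)) {
    stopifnot(!is.null(genome))
    uniq <- tumor_calls[!duplicated(tumor_calls$isoform_key), , drop = FALSE]
    contigs <- lapply(seq_len(nrow(uniq)), function(i)
      build_fusion_contig(uniq[i, , drop = FALSE], genome, genes,
                          flank = cfg$fusion.contig_flank))
    for (lib in names(control_reads)) {
      reads <- control_reads[[lib]]
      if (is.null(reads) || nrow(reads) == 0) next
      quals <- lapply(strsplit(reads$qualities, ","), as.numeric)
      hit_pairs <- character()
      for (i in seq_len(nrow(uniq))) {
        ct <- contigs[[i]]
        for (r in seq_len(nrow(reads))) {
          if (contig_blacklist_hit(ct$contig, ct$junction_offset,
                                   reads$sequence[r], quals[[r]],
                                   min_overhang = cfg$fusion.min_overhang,
                                   min_quality = cfg$fusion.min_read_quality)) {
            hit_pairs <- c(hit_pairs, pair_key(uniq$gene5[i], uniq$gene3[i]))
            break
          }
        }
      }
      add_evidence(hit_pairs, lib)
    }
  }

  ## (b) pairs and breakpoints called in control libraries
  breakpoints <- character()
  called_in <- list()  # pair -> libraries where the pair was *called*
  for (lib in names(control_call_sets) %||% character()) {
    cc <- control_call_sets[[lib]]
    if (is.null(cc) || nrow(cc) == 0) next
    pairs <- pair_key(cc$gene5, cc$gene3)
    add_evidence(pairs, lib)
    for (p in unique(pairs)) called_in[[p]] <- union(called_in[[p]], lib)
    breakpoints <- c(breakpoints, bp_key(cc$chrom5, cc$pos5), bp_key(cc$chrom3, cc$pos3))
  }

  n_evidence <- vapply(evidence, length, integer(1))
  blacklisted <- names(n_evidence)[n_evidence >= 2]
  if (!is.null(fetal_control)) {
    adult <- setdiff(lib_names, fetal_control)
    fetal_rule <- vapply(names(called_in), function(p) {
      libs <- called_in[[p]]
      fetal_control %in% libs && length(intersect(libs, adult)) >= 2
    }, logical(1))
    blacklisted <- union(blacklisted, names(called_in)[fetal_rule])
  }
  structure(list(gene_pairs = sort(unique(blacklisted)),
                 breakpoints = sort(unique(breakpoints)),
                 pair_libraries = n_evidence),
            class = "fusion_blacklist")
}

#' @export
print.fusion_blacklist <- function(x, ...) {
  cat(sprintf("fusion_blacklist: %d gene pair(s), %d breakpoint(s)\n",
              length(x$gene_pairs), length(x$breakpoints)))
  invisible(x)
}

#' Write / read a blacklist TSV
#' @param blacklist a `fusion_blacklist`.
#' @param path TSV path.
#' @export
write_blacklist <- function(blacklist, path) {
  df <- rbind(
    if (length(blacklist$gene_pairs))
      data.frame(kind = "pair", key = blacklist$gene_pairs,
                 n_control_libraries = as.integer(
                   blacklist$pair_libraries[blacklist$gene_pairs] %||% NA)),
    if (length(blacklist$breakpoints))
      data.frame(kind = "breakpoint", key = blacklist$breakpoints,
                 n_control_libraries = NA_integer_))
  if (is.null(df)) df <- data.frame(kind = character(), key = character(),
                                    n_control_libraries = integer())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blacklist
#' @export
read_blacklist <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(gene_pairs = df$key[df$kind == "pair"],
                 breakpoints = df$key[df$kind == "breakpoint"],
                 pair_libraries = setNames(df$n_control_libraries[df$kind == "pair"],
                                           df$key[df$kind == "pair"])),
            class = "fusion_blacklist")
}

## Gap between the nearest boundaries of two gene bodies; Inf across
## chromosomes, 0 when the bodies touch or overlap.
gene_gap <- function(g5, g3) {
  if (g5$chrom != g3$chrom) return(Inf)
  max(0, max(g5$start, g3$start) - min(g5$end, g3$end))
}

#' Apply the fusion filter cascade
#'
#' Annotates every tumor call with all failing rules among: blacklisted pair
#' or breakpoint; same-gene circular-RNA artifact; readthrough (gene bodies
#' within 50 kb); highly recurrent breakpoint (the same event in more than 15
#' samples); expression ratio `((fusion reads)/200 bp)/RPKM < 0.01` at either
#' partner; junction read proportion `< 0.05` at both partners. The
#' readthrough and recurrent rules are waived when other distinct fusion
#' breakpoints are detected in the same genes across the cohort. A call
#' passes iff no rule fails.
#'
#' @param calls fusion-call data.frame for the tumor cohort.
#' @param blacklist a `fusion_blacklist` (may be empty).
#' @param genes [gene_models()] covering every partner gene.
#' @param expr RPKM matrix (genes x samples).
#' @param cfg configuration list.
#' @return verdict data.frame: the call columns plus `status`
#'   (`pass`/`filtered`) and `filter_reasons` (semicolon-joined rule ids).
#' @export
filter_cascade <- function(calls, blacklist = NULL, genes, expr,
                           cfg = shhland_config()) {
  n <- nrow(calls)
  reasons <- vector("list", n)
  if (n == 0) {
    out <- calls; out$status <- character(); out$filter_reasons <- character()
    return(out)
  }
  bl_pairs <- blacklist$gene_pairs %||% character()
  bl_bps <- blacklist$breakpoints %||% character()
  bl_bp_df <- if (length(bl_bps)) {
    parts <- strsplit(bl_bps, ":", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[`, "", 1),
               pos = as.integer(vapply(parts, `[`, "", 2)))
  } else NULL
  bp_match <- function(chrom, pos) {
    if (is.null(bl_bp_df)) return(FALSE)
    any(bl_bp_df$chrom == chrom & abs(bl_bp_df$pos - pos) <= cfg$fusion.bp_window)
  }

  ## cohort-wide per-gene breakpoint registry (for the exemption clause) and
  ## per-event sample recurrence
  gene_bps <- list()
  for (i in seq_len(n)) {
    gene_bps[[calls$gene5[i]]] <- union(gene_bps[[calls$gene5[i]]],
                                        bp_key(calls$chrom5[i], calls$pos5[i]))
    gene_bps[[calls$gene3[i]]] <- union(gene_bps[[calls$gene3[i]]],
                                        bp_key(calls$chrom3[i], calls$pos3[i]))
  }
  event_samples <- tapply(calls$sample_id, calls$isoform_key,
                          function(s) length(unique(s)))
  has_wt <- !is.null(calls$wt_reads5) && !is.null(calls$wt_reads3)
  if (!has_wt)
    warnf("wildtype junction read columns absent: junction-proportion rule skipped")

  fusion_reads <- if (identical(cfg$fusion.reads, "spanning_only")) {
    calls$spanning_reads
  } else calls$spanning_reads + calls$bridging_reads

  for (i in seq_len(n)) {
    cl <- calls[i, , drop = FALSE]
    r <- character()
    if (pair_key(cl$gene5, cl$gene3) %in% bl_pairs) r <- c(r, "blacklist_pair")
    if (bp_match(cl$chrom5, cl$pos5) || bp_match(cl$chrom3, cl$pos3))
      r <- c(r, "blacklist_bp")

    g5 <- gene_row(genes, cl$gene5); g3 <- gene_row(genes, cl$gene3)
    in_gene <- function(g, chrom, pos) g$chrom == chrom && pos >= g$start && pos < g$end
    circular <- cl$gene5 == cl$gene3 ||
      (in_gene(g5, cl$chrom5, cl$pos5) && in_gene(g5, cl$chrom3, cl$pos3)) ||
      (in_gene(g3, cl$chrom5, cl$pos5) && in_gene(g3, cl$chrom3, cl$pos3))
    if (circular) r <- c(r, "circular")

    ## exemption: another distinct breakpoint seen in either partner gene
    other_bp <- length(setdiff(gene_bps[[cl$gene5]], bp_key(cl$chrom5, cl$pos5))) > 0 ||
      length(setdiff(gene_bps[[cl$gene3]], bp_key(cl$chrom3, cl$pos3))) > 0
    if (cl$gene5 != cl$gene3 &&
        gene_gap(g5, g3) < cfg$fusion.readthrough_max_gap && !other_bp)
      r <- c(r, "readthrough")
    if (event_samples[[cl$isoform_key]] > cfg$fusion.recurrent_max_samples && !other_bp)
      r <- c(r, "recurrent")

    ## expression-ratio rule
    samp <- cl$sample_id
    rpkm5 <- if (cl$gene5 %in% rownames(expr) && samp %in% colnames(expr))
      expr[cl$gene5, samp] else NA
    rpkm3 <- if (cl$gene3 %in% rownames(expr) && samp %in% colnames(expr))
      expr[cl$gene3, samp] else NA
    if (is.na(rpkm5) || is.na(rpkm3)) {
      warnf("missing expression for %s-%s in %s", cl$gene5, cl$gene3, samp)
      r <- c(r, "missing_expression")
    } else {
      per_bp <- fusion_reads[i] / 200
      ratio5 <- if (rpkm5 > 0) per_bp / rpkm5 else Inf
      ratio3 <- if (rpkm3 > 0) per_bp / rpkm3 else Inf
      if (ratio5 < cfg$fusion.expr_ratio_min || ratio3 < cfg$fusion.expr_ratio_min)
        r <- c(r, "expr_ratio")
    }

    ## junction-proportion rule (needs wildtype junction read counts)
    if (has_wt && !is.na(cl$wt_reads5) && !is.na(cl$wt_reads3)) {
      p5 <- cl$spanning_reads / (cl$spanning_reads + cl$wt_reads5)
      p3 <- cl$spanning_reads / (cl$spanning_reads + cl$wt_reads3)
      if (p5 < cfg$fusion.junction_prop_min && p3 < cfg$fusion.junction_prop_min)
        r <- c(r, "junction_prop")
    }
    reasons[[i]] <- r
  }
  out <- calls
  out$status <- ifelse(lengths(reasons) == 0, "pass", "filtered")
  out$filter_reasons <- join_reasons(reasons)
  out
}
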