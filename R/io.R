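## Readers and writers for every dialect the pipeline touches. External files
## use the field-standard 1-based inclusive coordinates; everything internal
## is 0-based half-open, converted only here at the boundary.

#' Construct a gene-model set
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) and optionally `symbol`, `biotype`.
#' @param exons data.frame with `gene_id`, `start`, `end`, one row per exon.
#' @return an object of class `gene_models`: a list with elements `genes`
#'   (per-gene table including the derived `tss`) and `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stopf("duplicated gene_id in gene models")
  if (!all(genes$strand %in% c("+", "-")))
    stopf("unknown strand value(s): %s",
          paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  check_intervals(genes, "gene")
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  ord <- order(match(exons$gene_id, genes$gene_id), exons$start)
  exons <- exons[ord, c("gene_id", "start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    gi <- genes[genes$gene_id == g, , drop = FALSE]
    if (nrow(gi) == 0) stopf("exon references unknown gene '%s'", g)
    if (any(e$start < gi$start) || any(e$end > gi$end))
      stopf("exon outside gene body for '%s'", g)
    if (nrow(e) > 1 && any(e$end[-nrow(e)] > e$start[-1]))
      stopf("overlapping exons in '%s'", g)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

gene_row <- function(gm, gene_id) {
  i <- match(gene_id, gm$genes$gene_id)
  if (is.na(i)) stopf("gene '%s' not in gene models", gene_id)
  gm$genes[i, , drop = FALSE]
}

gene_exons <- function(gm, gene_id) {
  gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
}

#' Read gene models from BED12 or a minimal GTF
#'
#' BED12 blocks become exons; GTF `gene`/`exon` features (1-based inclusive)
#' are converted to internal 0-based half-open coordinates. The TSS is
#' `start` for plus-strand genes and `end - 1` for minus-strand genes.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (format == "bed12") parse_bed12(lines) else parse_gtf(lines)
}

parse_bed12 <- function(lines) {
  genes <- list(); exons <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t| +")[[1]]
    if (length(f) < 12) stopf("BED12 parse error at line %d: %d field(s)", i, length(f))
    strand <- f[6]
    if (!strand %in% c("+", "-")) stopf("unknown strand '%s' at line %d", strand, i)
    start <- suppressWarnings(as.integer(f[2])); end <- suppressWarnings(as.integer(f[3]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    if (anyNA(c(start, end, n_blocks))) stopf("BED12 parse error at line %d", i)
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offs <- as.integer(strsplit(f[12], ",")[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks)
      stopf("BED12 block count mismatch at line %d", i)
    genes[[i]] <- data.frame(gene_id = f[4], chrom = f[1], start = start,
                             end = end, strand = strand)
    exons[[i]] <- data.frame(gene_id = f[4], start = start + offs,
                             end = start + offs + sizes)
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

parse_gtf <- function(lines) {
  gtf_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]+)"'), attrs))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  genes <- list(); exons <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stopf("GTF parse error at line %d: %d field(s)", i, length(f))
    feature <- f[3]
    if (!feature %in% c("gene", "exon")) next
    start <- suppressWarnings(as.integer(f[4])) - 1L  # 1-based incl -> 0-based half-open
    end <- suppressWarnings(as.integer(f[5]))
    if (anyNA(c(start, end))) stopf("GTF parse error at line %d", i)
    strand <- f[7]
    if (!strand %in% c("+", "-")) stopf("unknown strand '%s' at line %d", strand, i)
    gid <- gtf_attr(f[9], "gene_id")
    if (is.na(gid)) stopf("missing gene_id at line %d", i)
    if (feature == "gene") {
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = f[1], start = start, end = end, strand = strand,
        symbol = gtf_attr(f[9], "gene_name") %||% gid,
        biotype = gtf_attr(f[9], "gene_biotype") %||% "protein_coding")
    } else {
      exons[[length(exons) + 1L]] <- data.frame(gene_id = gid, start = start, end = end)
    }
  }
  exons <- do.call(rbind, exons)
  if (length(genes) == 0) {  # derive gene bodies from exons
    stopifnot(!is.null(exons))
    genes <- NULL
    stopf("GTF without gene features is not supported")
  } else genes <- do.call(rbind, genes)
  genes$symbol[is.na(genes$symbol)] <- genes$gene_id[is.na(genes$symbol)]
  genes$biotype[is.na(genes$biotype)] <- "protein_coding"
  gene_models(genes, exons)
}

fusion_required_cols <- c("sample_id", "caller", "gene5", "gene3",
                          "chrom5", "pos5", "strand5",
                          "chrom3", "pos3", "strand3",
                          "spanning_reads", "bridging_reads")

#' Read fusion calls in the unified TSV dialect
#'
#' One row per caller-reported chimeric transcript. `pos5`/`pos3` are the
#' 1-based positions of the last 5' base and first 3' base of the junction in
#' the file, stored 0-based internally. Optional columns: `contig`,
#' `wt_reads5`, `wt_reads3` (wildtype junction reads per partner, used by the
#' junction-proportion filter). Rows with negative read counts are dropped
#' with a warning. Duplicate rows are retained; deduplication is the screen's
#' job.
#'
#' @param path TSV path.
#' @param caller optional caller id overriding the file's `caller` column.
#' @return data.frame of fusion calls with an `isoform_key` (breakpoint-pair
#'   identifier) column.
#' @export
read_fusion_calls <- function(path, caller = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(sample_id = character(), caller = character(),
                     gene5 = character(), gene3 = character(),
                     chrom5 = character(), pos5 = integer(), strand5 = character(),
                     chrom3 = character(), pos3 = integer(), strand3 = character(),
                     spanning_reads = integer(), bridging_reads = integer(),
                     contig = character(), isoform_key = character())
    return(df)
  }
  missing <- setdiff(setdiff(fusion_required_cols, "caller"), names(df))
  if (length(missing)) stopf("fusion TSV missing column(s): %s", paste(missing, collapse = ", "))
  if (!is.null(caller)) df$caller <- caller
  if (is.null(df$caller)) stopf("fusion TSV missing column(s): caller")
  bad <- df$spanning_reads < 0 | df$bridging_reads < 0
  if (any(bad)) {
    warnf("dropping %d fusion row(s) with negative read counts", sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  df$pos5 <- as.integer(df$pos5) - 1L
  df$pos3 <- as.integer(df$pos3) - 1L
  if (is.null(df$contig)) df$contig <- NA_character_
  df$isoform_key <- fusion_isoform_key(df)
  rownames(df) <- NULL
  df
}

fusion_isoform_key <- function(calls) {
  paste(calls$chrom5, calls$pos5, calls$chrom3, calls$pos3, sep = ":")
}

#' Write fusion calls in the unified TSV dialect
#' @param calls data.frame as returned by [read_fusion_calls()].
#' @param path output path.
#' @export
write_fusion_calls <- function(calls, path) {
  out <- calls
  out$pos5 <- out$pos5 + 1L
  out$pos3 <- out$pos3 + 1L
  out$isoform_key <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments (SEG) with a ploidy/purity sidecar
#'
#' The SEG file has columns `sample`, `chrom`, `start` (1-based), `end`,
#' `copy_number`; the sidecar TSV has `sample`, `ploidy`, `purity` and an
#' optional `aneuploid` flag. Log-ratios are computed as
#' `log2(copy_number / ploidy)`; copy number 0 is floored at `cn_floor`
#' (default 0.5) so homozygous deletions stay finite.
#'
#' @param seg_path SEG file path.
#' @param ploidy_path sidecar TSV path.
#' @param cfg configuration list from [shhland_config()].
#' @return list with `segments` (sample_id, chrom, start, end, copy_number,
#'   log_ratio; 0-based half-open) and `profiles` (sample_id, ploidy, purity,
#'   aneuploid).
#' @export
read_segments <- function(seg_path, ploidy_path, cfg = shhland_config()) {
  seg <- read.delim(seg_path, stringsAsFactors = FALSE)
  names(seg)[names(seg) == "sample"] <- "sample_id"
  need <- c("sample_id", "chrom", "start", "end", "copy_number")
  missing <- setdiff(need, names(seg))
  if (length(missing)) stopf("SEG missing column(s): %s", paste(missing, collapse = ", "))
  seg$start <- as.numeric(seg$start) - 1  # 1-based inclusive -> 0-based half-open
  seg$end <- as.numeric(seg$end)
  check_intervals(seg, "segment")
  prof <- read.delim(ploidy_path, stringsAsFactors = FALSE)
  names(prof)[names(prof) == "sample"] <- "sample_id"
  if (!all(c("sample_id", "ploidy") %in% names(prof)))
    stopf("ploidy sidecar must have columns sample, ploidy")
  if (is.null(prof$purity)) prof$purity <- 1
  if (is.null(prof$aneuploid)) prof$aneuploid <- FALSE
  if (any(prof$ploidy <= 0)) stopf("non-positive ploidy")
  no_prof <- setdiff(seg$sample_id, prof$sample_id)
  if (length(no_prof)) stopf("missing ploidy for sample(s): %s", paste(no_prof, collapse = ", "))
  seg <- seg[order(seg$sample_id, seg$chrom, seg$start), , drop = FALSE]
  check_disjoint_sorted(seg)
  ploidy <- prof$ploidy[match(seg$sample_id, prof$sample_id)]
  seg$log_ratio <- log2(ifelse(seg$copy_number == 0, cfg$cn_floor, seg$copy_number) / ploidy)
  rownames(seg) <- NULL
  list(segments = seg[, c(need, "log_ratio")], profiles = prof)
}

#' Write segments back to SEG (1-based)
#' @param segments internal segment data.frame.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start + 1, end = segments$end,
                    copy_number = segments$copy_number)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

verdict_cols <- c("status", "filter_reasons", "sv_tier", "wgs_confidence",
                  "snp6_support", "salvage_score")

#' Write fusion verdicts to TSV
#'
#' One row per call with the call fields, the pass/filtered status, the
#' semicolon-joined filter reasons and the SV-support tiering fields. Writing
#' then reading yields a field-wise identical table.
#'
#' @param verdicts verdict data.frame from [filter_cascade()] / [tier_fusions()].
#' @param path output path.
#' @export
write_verdicts <- function(verdicts, path) {
  out <- verdicts
  out$pos5 <- out$pos5 + 1L
  out$pos3 <- out$pos3 + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a verdict TSV written by [write_verdicts()]
#' @param path TSV path.
#' @return verdict data.frame (internal coordinates).
#' @export
read_verdicts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  df$pos5 <- df$pos5 - 1L
  df$pos3 <- df$pos3 - 1L
  df$filter_reasons[is.na(df$filter_reasons)] <- ""
  df
}

#' Read WGS structural-variant breakpoint pairs from BEDPE
#'
#' Standard 10-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2`, no header); the `name` column carries the sample
#' id. Each end's `start` is taken as the 0-based breakpoint position.
#'
#' @param path BEDPE path.
#' @return data.frame sample_id, chrom1, pos1, chrom2, pos2.
#' @export
read_bedpe <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 7) {
    if (nrow(df) == 0)
      return(data.frame(sample_id = character(), chrom1 = character(), pos1 = integer(),
                        chrom2 = character(), pos2 = integer()))
    stopf("BEDPE needs at least 7 columns")
  }
  data.frame(sample_id = as.character(df[[7]]),
             chrom1 = as.character(df[[1]]), pos1 = as.integer(df[[2]]),
             chrom2 = as.character(df[[4]]), pos2 = as.integer(df[[5]]))
}

#' Write breakpoint pairs to BEDPE
#' @param sv data.frame as from [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(sv, path) {
  out <- data.frame(sv$chrom1, sv$pos1, sv$pos1 + 1L, sv$chrom2, sv$pos2,
                    sv$pos2 + 1L, sv$sample_id, 0L, "+", "+")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read germline CNV catalogs (gold and supporting lists)
#'
#' TSVs with columns `chrom`, `start` (1-based), `end`, `freq` and, for the
#' supporting list, `study_size`. On load the lists are restricted to the
#' variants the filter actually uses: gold variants at population frequency
#' >= 1% and supporting variants from studies of >= 50 subjects at >= 1%
#' in-study frequency (cutoffs configurable).
#'
#' @param gold_path,supporting_path TSV paths; either may be `NULL`.
#' @param cfg configuration list.
#' @return list with elements `gold` and `supporting` (0-based data.frames).
#' @export
read_germline_db <- function(gold_path = NULL, supporting_path = NULL,
                             cfg = shhland_config()) {
  load_one <- function(path) {
    if (is.null(path)) return(NULL)
    df <- read.delim(path, stringsAsFactors = FALSE)
    df$start <- as.numeric(df$start) - 1
    check_intervals(df, "germline variant")
    if (any(df$freq < 0 | df$freq > 1)) stopf("germline variant frequency outside [0,1]")
    df
  }
  gold <- load_one(gold_path)
  if (!is.null(gold)) gold <- gold[gold$freq >= cfg$germline.gold_min_freq, , drop = FALSE]
  supp <- load_one(supporting_path)
  if (!is.null(supp)) {
    if (is.null(supp$study_size)) stopf("supporting list needs a study_size column")
    if (any(supp$study_size <= 0)) stopf("non-positive study_size")
    supp <- supp[supp$study_size >= cfg$germline.supporting_min_study &
                   supp$freq >= cfg$germline.supporting_min_freq, , drop = FALSE]
  }
  list(gold = gold, supporting = supp)
}

#' Read / write a numeric matrix TSV (row names in the first column)
#' @param path TSV path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with row and column names.
#' @param rowname_header header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, rowname_header = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a genome as FASTA
#'
#' The in-memory genome is a named character vector of chromosome sequences.
#'
#' @param genome named character vector.
#' @param path FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Row-standardize an expression matrix
#'
#' Z-scores each gene (row) across samples; rows with zero variance are left
#' at 0.
#'
#' @param m genes-by-samples numeric matrix.
#' @return matrix of the same shape.
#' @export
expr_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}
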