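## Post-annotation somatic-variant filter cascade for RNA-seq calls. Each
## rule is a pure predicate on an annotated call row; the cascade records
## every failing rule. Rule identifiers: pop_af, radar, intron_deletion,
## softclip, low_support, homopolymer, snp_cluster, snp_db, benign, ebcall.

## The variant table dialect (TSV columns; NA/absent where not applicable):
##   sample_id chrom pos ref alt kind depth alt_reads consequence
##   population_af_max radar_editing intron_exact_deletion softclip_only
##   cosmic_count in_snp_db sift polyphen_hdiv polyphen_hvar
##   mutation_taster mutation_assessor hp_base hp_run_length
##   snp_db_positions (0/1 string, call at the center) ebcall_p
##   mpileup_alt_reads

na_false <- function(x) !is.na(x) & x

#' Population allele-frequency rule
#'
#' Fails when the maximum allele frequency over the population databases
#' exceeds 0.01 (strict; a variant at exactly 0.01 passes). A missing
#' annotation counts as 0.
#'
#' @param call one-row variant data.frame.
#' @param cfg configuration list.
#' @return `TRUE` when the rule fails (variant removed).
#' @export
frequency_filter <- function(call, cfg = shhland_config()) {
  af <- call$population_af_max
  if (is.null(af) || is.na(af)) {
    warnf("population_af_max missing; treated as 0")
    af <- 0
  }
  af > cfg$variant.max_pop_af
}

#' Context rules: RNA editing, intron-matched deletions, soft-clip-only
#' support, low read support
#'
#' @param call one-row variant data.frame.
#' @param cfg configuration list.
#' @return named logical vector `radar`, `intron_deletion`, `softclip`,
#'   `low_support` (`TRUE` = rule fails).
#' @export
context_filters <- function(call, cfg = shhland_config()) {
  c(radar = na_false(call$radar_editing),
    intron_deletion = identical(call$kind, "deletion") &&
      na_false(call$intron_exact_deletion),
    softclip = na_false(call$softclip_only),
    low_support = call$alt_reads < cfg$variant.min_alt_reads)
}

## The inserted/deleted sequence implied by ref/alt (VCF-style alleles with
## the shared anchor base first), or "" for substitutions.
indel_sequence <- function(ref, alt) {
  if (nchar(alt) > nchar(ref)) substr(alt, nchar(ref) + 1, nchar(alt))
  else if (nchar(ref) > nchar(alt)) substr(ref, nchar(alt) + 1, nchar(ref))
  else ""
}

#' Homopolymer indel rule
#'
#' An insertion or deletion fails when it sits on a reference homopolymer
#' run of at least 5 bases and the inserted/deleted bases are a run of that
#' same base (so the event merely stretches or shrinks the homopolymer).
#' SNVs never fail this rule.
#'
#' @param call one-row variant data.frame with `hp_base` and
#'   `hp_run_length` annotated from the reference.
#' @param cfg configuration list.
#' @return `TRUE` when the rule fails.
#' @export
homopolymer_filter <- function(call, cfg = shhland_config()) {
  if (!call$kind %in% c("insertion", "deletion")) return(FALSE)
  if (is.na(call$hp_run_length) || call$hp_run_length < cfg$variant.homopolymer_min_run)
    return(FALSE)
  seq <- indel_sequence(call$ref, call$alt)
  nchar(seq) > 0 &&
    all(strsplit(seq, "")[[1]] == call$hp_base)
}

#' Germline SNP-cluster rule
#'
#' Fails when the call lies inside a maximal run of at least 10 consecutive
#' positions that are all registered in the germline SNP database. The
#' `snp_db_positions` annotation is a 0/1 string over a window centered on
#' the call.
#'
#' @param call one-row variant data.frame.
#' @param cfg configuration list.
#' @return `TRUE` when the rule fails.
#' @export
snp_cluster_filter <- function(call, cfg = shhland_config()) {
  s <- call$snp_db_positions
  if (is.null(s) || is.na(s) || !nzchar(s)) return(FALSE)
  bits <- as.integer(strsplit(s, "")[[1]])
  if (length(bits) < cfg$variant.snp_cluster_min_run) {
    warnf("snp_db_positions window shorter than %d", cfg$variant.snp_cluster_min_run)
    return(FALSE)
  }
  center <- (length(bits) + 1L) %/% 2L
  if (bits[center] != 1L) return(FALSE)
  run <- rle(bits)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  i <- which(starts <= center & ends >= center)
  run$values[i] == 1L && run$lengths[i] >= cfg$variant.snp_cluster_min_run
}

#' Pathogenicity rules: dbSNP rescue and benign-prediction removal
#'
#' Two rules. `snp_db`: a missense, synonymous or non-frameshift-indel
#' variant registered in a germline SNP database fails unless it is a COSMIC
#' hotspot (at least 10 samples). `benign`: a variant below the COSMIC
#' hotspot count fails when any available predictor calls it benign
#' (SIFT >= 0.05, PolyPhen-2 HDIV <= 0.908, PolyPhen-2 HVAR <= 0.956,
#' MutationTaster polymorphism or polymorphism_automatic, MutationAssessor
#' predicted non-functional). Missing scores cannot fail a clause.
#'
#' @param call one-row variant data.frame.
#' @param cfg configuration list.
#' @return named logical vector `snp_db`, `benign`.
#' @export
pathogenicity_filter <- function(call, cfg = shhland_config()) {
  cosmic <- if (is.na(call$cosmic_count)) 0 else call$cosmic_count
  hotspot <- cosmic >= cfg$variant.min_cosmic
  snp_db <- call$consequence %in% c("missense", "synonymous", "nonframeshift_indel") &&
    na_false(call$in_snp_db) && !hotspot
  benign_signals <- c(
    !is.na(call$sift) && call$sift >= cfg$variant.sift_benign,
    !is.na(call$polyphen_hdiv) && call$polyphen_hdiv <= cfg$variant.polyphen_hdiv_benign,
    !is.na(call$polyphen_hvar) && call$polyphen_hvar <= cfg$variant.polyphen_hvar_benign,
    !is.na(call$mutation_taster) &&
      call$mutation_taster %in% c("polymorphism", "polymorphism_automatic"),
    !is.na(call$mutation_assessor) &&
      call$mutation_assessor == "predicted non-functional")
  c(snp_db = snp_db, benign = !hotspot && any(benign_signals))
}

#' Empirical Bayes (EBCall-style) significance rule
#'
#' Fails when the call's empirical-Bayes p-value is at or above 1e-3, unless
#' the call is realignment-rescued: the pileup-based caller saw fewer than 5
#' variant reads, or fewer than half the variant reads the primary caller
#' saw (pileup cannot evaluate reads recovered by local realignment). A
#' missing p-value passes with a warning.
#'
#' @param call one-row variant data.frame with `ebcall_p` and optional
#'   `mpileup_alt_reads`.
#' @param cfg configuration list.
#' @return `TRUE` when the rule fails.
#' @export
ebcall_filter <- function(call, cfg = shhland_config()) {
  p <- call$ebcall_p
  if (is.null(p) || is.na(p)) {
    warnf("ebcall_p missing; rule skipped")
    return(FALSE)
  }
  if (p < cfg$variant.max_ebcall_p) return(FALSE)
  mp <- call$mpileup_alt_reads
  if (!is.null(mp) && !is.na(mp) &&
      (mp < cfg$variant.min_alt_reads || mp < call$alt_reads / 2)) return(FALSE)
  TRUE
}

#' Run the full variant filter cascade
#'
#' Evaluates every rule on every call (rules are order-independent pure
#' predicates) and returns a verdict per call: `pass` iff no rule fails,
#' with the exhaustive set of failing rules otherwise. A call kept only
#' because its COSMIC count rescued it from the dbSNP/benign rules is
#' marked `rescued_by = "cosmic"`.
#'
#' @param calls annotated variant data.frame (see the dialect comment at the
#'   top of the file; missing optional columns are treated as NA).
#' @param cfg configuration list.
#' @return data.frame: the call columns plus `status`, `reasons`
#'   (semicolon-joined) and `rescued_by`.
#' @export
run_variant_cascade <- function(calls, cfg = shhland_config()) {
  optional <- c("population_af_max", "radar_editing", "intron_exact_deletion",
                "softclip_only", "cosmic_count", "in_snp_db", "sift",
                "polyphen_hdiv", "polyphen_hvar", "mutation_taster",
                "mutation_assessor", "hp_base", "hp_run_length",
                "snp_db_positions", "ebcall_p", "mpileup_alt_reads")
  for (col in optional) if (is.null(calls[[col]])) calls[[col]] <- NA
  if (any(calls$alt_reads > calls$depth, na.rm = TRUE))
    stopf("alt_reads exceeds depth")
  n <- nrow(calls)
  reasons <- vector("list", n)
  rescued <- character(n)
  for (i in seq_len(n)) {
    cl <- calls[i, , drop = FALSE]
    r <- character()
    if (frequency_filter(cl, cfg)) r <- c(r, "pop_af")
    ctx <- context_filters(cl, cfg)
    r <- c(r, names(ctx)[ctx])
    if (homopolymer_filter(cl, cfg)) r <- c(r, "homopolymer")
    if (snp_cluster_filter(cl, cfg)) r <- c(r, "snp_cluster")
    pf <- pathogenicity_filter(cl, cfg)
    r <- c(r, names(pf)[pf])
    if (ebcall_filter(cl, cfg)) r <- c(r, "ebcall")
    cosmic <- if (is.na(cl$cosmic_count)) 0 else cl$cosmic_count
    rescued[i] <- if (length(r) == 0 && cosmic >= cfg$variant.min_cosmic &&
                      (na_false(cl$in_snp_db))) "cosmic" else "none"
    reasons[[i]] <- r
  }
  out <- calls
  out$status <- ifelse(lengths(reasons) == 0, "pass", "filtered")
  out$reasons <- join_reasons(reasons)
  out$rescued_by <- rescued
  out
}

#' Read / write the annotated variant TSV dialect
#' @param path TSV path.
#' @return variant data.frame.
#' @export
read_variant_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                   colClasses = "character")
  ## free-text / sequence columns must never be numerically coerced (a 0/1
  ## membership string would collapse to scientific notation)
  protect <- c("variant_id", "sample_id", "chrom", "ref", "alt", "kind",
               "consequence", "mutation_taster", "mutation_assessor",
               "hp_base", "snp_db_positions")
  for (col in setdiff(names(df), protect))
    df[[col]] <- utils::type.convert(df[[col]], as.is = TRUE)
  df
}

#' @rdname read_variant_calls
#' @param calls variant data.frame.
#' @export
write_variant_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
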