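#' Default pipeline configuration
#'
#' Returns the full set of tunable thresholds used across the pipeline, with
#' the published filter values as defaults. Any subset can be overridden via
#' `...`; unknown keys are an error so typos surface immediately.
#'
#' @param ... named overrides, e.g. `fusion.expr_ratio_min = 0.02`.
#'
#' @details Keys (defaults in brackets):
#' \describe{
#'   \item{cn_floor}{copy number used in place of 0 when computing log-ratios,
#'     so homozygous deletions stay finite but extreme \[0.5\].}
#'   \item{merge_tolerance}{adjacent segments whose log-ratios differ by less
#'     than this are merged \[0.25\].}
#'   \item{focal_max_len}{segments of length less than or equal to this are focal, longer ones
#'     broad \[12e6 bp\].}
#'   \item{state.loss, state.gain, state.amp}{log-ratio cutoffs for loss /
#'     gain / amplification calls \[-0.25, 0.25, 1.0\].}
#'   \item{germline.gold_ro, germline.supporting_ro}{reciprocal-overlap
#'     fractions against the gold / supporting germline CNV lists \[0.5, 0.8\].}
#'   \item{fusion.readthrough_max_gap}{max gap between gene bodies for the
#'     readthrough rule \[50e3 bp\].}
#'   \item{fusion.recurrent_max_samples}{events seen in more than this many
#'     samples are recurrent artifacts \[15\].}
#'   \item{fusion.expr_ratio_min}{min ((fusion reads)/200 bp)/RPKM per
#'     partner \[0.01\].}
#'   \item{fusion.junction_prop_min}{min junction read proportion; a call
#'     fails only when below it at both partners \[0.05\].}
#'   \item{fusion.reads}{which read counts constitute "fusion reads" for the
#'     expression-ratio rule: "spanning_plus_bridging" or "spanning_only".}
#'   \item{fusion.bp_window}{breakpoint-blacklist matching window in bp \[0\].}
#'   \item{fusion.contig_flank}{bases taken on each side of the junction when
#'     building fusion contigs \[110\].}
#'   \item{fusion.min_overhang}{control-read overhang past the junction for a
#'     contig blacklist hit \[20 bp\].}
#'   \item{fusion.min_read_quality}{mean base quality a control read must
#'     exceed \[30\].}
#'   \item{sv.snp6_pad}{window around SNP-array copy-number breakpoints \[250e3 bp\].}
#'   \item{sv.wgs_window}{window around the fused exon edge for low-confidence
#'     WGS support \[100e3 bp\].}
#'   \item{sv.isoform_min_sum}{spanning+bridging must exceed this for
#'     multi-isoform evidence \[20\].}
#'   \item{sv.salvage_threshold}{read-depth step statistic at or above which a
#'     filtered recurrent call is salvage-eligible \[3.0\].}
#'   \item{methyl.tss_max_dist}{promoter probes lie within this distance of
#'     the TSS \[1500 bp\].}
#'   \item{methyl.probe_corr}{Pearson correlation at or above which promoter
#'     probes of a gene are averaged into a probe set \[0.7\].}
#'   \item{methyl.min_cluster_frac}{smallest admissible methylation cluster \[0.05\].}
#'   \item{methyl.min_diff_mean}{min beta difference between extreme
#'     clusters \[0.25\].}
#'   \item{methyl.min_diff_exp}{min z-score expression difference between the
#'     same clusters \[0.75\].}
#'   \item{variant.max_pop_af}{population allele-frequency cutoff \[0.01\].}
#'   \item{variant.min_alt_reads}{minimum variant-supporting reads \[5\].}
#'   \item{variant.homopolymer_min_run}{homopolymer run length at which indels
#'     are filtered \[5\].}
#'   \item{variant.snp_cluster_min_run}{length of an all-dbSNP run that marks
#'     a germline SNP cluster \[10\].}
#'   \item{variant.min_cosmic}{COSMIC sample count at which a variant is
#'     rescued from the dbSNP / benign rules \[10\].}
#'   \item{variant.sift_benign, variant.polyphen_hdiv_benign,
#'     variant.polyphen_hvar_benign}{score cutoffs for the benign rule
#'     \[0.05, 0.908, 0.956\].}
#'   \item{variant.max_ebcall_p}{calls with an EBCall p-value at or above this
#'     fail unless realignment-rescued \[1e-3\].}
#'   \item{test.cn_responsive_q, test.pair_q}{FDR cutoffs for
#'     copy-number-responsive genes and alteration-pair tests \[0.05, 0.01\].}
#' }
#'
#' @return a named list of configuration values.
#' @export
#' @examples
#' cfg <- shhland_config(fusion.bp_window = 5)
#' cfg$fusion.bp_window
shhland_config <- function(...) {
  cfg <- list(
    cn_floor                    = 0.5,
    merge_tolerance             = 0.25,
    focal_max_len               = 12e6,
    state.loss                  = -0.25,
    state.gain                  = 0.25,
    state.amp                   = 1.0,
    germline.gold_ro            = 0.5,
    germline.supporting_ro      = 0.8,
    germline.gold_min_freq      = 0.01,
    germline.supporting_min_freq = 0.01,
    germline.supporting_min_study = 50,
    fusion.readthrough_max_gap  = 50e3,
    fusion.recurrent_max_samples = 15,
    fusion.expr_ratio_min       = 0.01,
    fusion.junction_prop_min    = 0.05,
    fusion.reads                = "spanning_plus_bridging",
    fusion.bp_window            = 0,
    fusion.contig_flank         = 110,
    fusion.min_overhang         = 20,
    fusion.min_read_quality     = 30,
    sv.snp6_pad                 = 250e3,
    sv.wgs_window               = 100e3,
    sv.isoform_min_sum          = 20,
    sv.salvage_threshold        = 3.0,
    methyl.tss_max_dist         = 1500,
    methyl.probe_corr           = 0.7,
    methyl.min_cluster_frac     = 0.05,
    methyl.min_diff_mean        = 0.25,
    methyl.min_diff_exp         = 0.75,
    variant.max_pop_af          = 0.01,
    variant.min_alt_reads       = 5,
    variant.homopolymer_min_run = 5,
    variant.snp_cluster_min_run = 10,
    variant.min_cosmic          = 10,
    variant.sift_benign         = 0.05,
    variant.polyphen_hdiv_benign = 0.908,
    variant.polyphen_hvar_benign = 0.956,
    variant.max_ebcall_p        = 1e-3,
    test.cn_responsive_q        = 0.05,
    test.pair_q                 = 0.01
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are coerced to numeric where possible. Used by the command-line
#' wrapper; programmatic callers normally use [shhland_config()] directly.
#'
#' @param path text file of overrides.
#' @return a full config list with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    over[[key]] <- if (!is.na(num)) num else val
  }
  do.call(shhland_config, over)
}
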