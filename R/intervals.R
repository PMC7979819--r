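## Genomic intervals are plain data.frame rows with columns chrom, start, end
## (0-based, half-open) and optionally strand. All interval arithmetic in the
## package goes through the helpers below.

#' Length of the intersection of two half-open intervals
#'
#' @param a_start,a_end,b_start,b_end interval bounds (0-based, half-open);
#'   vectorized.
#' @return integer overlap length, 0 when disjoint.
#' @export
overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Reciprocal overlap of two genomic intervals
#'
#' The minimum of the two mutual overlap fractions, the symmetric similarity
#' used when matching copy-number segments against germline CNV catalogs.
#' Intervals on different chromosomes have reciprocal overlap 0.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return a fraction in \[0, 1\].
#' @export
#' @examples
#' reciprocal_overlap(list(chrom = "chr1", start = 100, end = 200),
#'                    list(chrom = "chr1", start = 150, end = 250))
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- overlap_len(a$start, a$end, b$start, b$end)
  if (ov <= 0) return(0)
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

## Validate a segment/interval data.frame. Returns invisibly or stops.
check_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start < df$end))
  if (length(bad)) stopf("%s rows with start >= end: %s", what,
                         paste(head(bad, 5), collapse = ", "))
  if (any(!nzchar(df$chrom))) stopf("%s with empty chrom", what)
  invisible(df)
}

## Assert per-sample, per-chromosome segments are sorted and non-overlapping.
check_disjoint_sorted <- function(seg, what = "segments") {
  key <- paste(seg$sample_id, seg$chrom)
  for (k in unique(key)) {
    s <- seg[key == k, , drop = FALSE]
    o <- order(s$start)
    if (any(o != seq_len(nrow(s)))) stopf("%s not sorted within %s", what, k)
    if (nrow(s) > 1 && any(s$end[-nrow(s)] > s$start[-1]))
      stopf("overlapping %s within %s", what, k)
  }
  invisible(seg)
}
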