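#' @keywords internal
"_PACKAGE"

#' @importFrom stats kruskal.test fisher.test p.adjust median sd var rnorm runif rbinom setNames cor quantile
#' @importFrom utils read.delim write.table head tail
#' @importFrom mclust Mclust mclustBIC
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

join_reasons <- function(reasons) {
  vapply(reasons, function(r) paste(sort(unique(r)), collapse = ";"), character(1))
}

split_reasons <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE), unique)
}

## Canonical unordered gene-pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

bp_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
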