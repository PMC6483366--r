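#' @importFrom methods is
#' @importFrom stats cor dist prcomp quantile rbinom rlnorm rnorm runif sd
#'   setNames median rgamma IQR predict chisq.test
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-task seed from a master seed
#'
#' Counter-based scheme: a deterministic affine map of the master seed and a
#' task index, reduced modulo 2^31 - 1 so the result is always a valid R
#' integer seed. Used wherever one master seed must fan out to independent
#' reproducible sub-tasks (per-sample catalogs, per-run CV folds, per-class
#' grid searches).
#'
#' @param master integer master seed.
#' @param index integer task counter (>= 0).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(index))
  m <- 2147483647
  s <- (abs(master) %% m) * 1009 + index * 7919 + 1
  as.integer(s %% (m - 1) + 1)
}

# internal: 0-based half-open data.frame (chrom,start,end) -> GRanges
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# internal: validate a mutation catalog data.frame
check_catalog <- function(catalog) {
  need <- c("chrom", "start", "end", "ref", "alt", "variant_class")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) {
    stop("mutation catalog lacks required columns: ", paste(miss, collapse = ", "))
  }
  invisible(catalog)
}

# internal: logical vector, TRUE where catalog record overlaps any interval.
# `intervals` is a 0-based half-open data.frame (chrom,start,end).
overlaps_any <- function(catalog, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0 || nrow(catalog) == 0) {
    return(rep(FALSE, nrow(catalog)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(catalog), as_granges0(intervals))
  out <- rep(FALSE, nrow(catalog))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# internal: stable window identifier "chrom:start-end"
window_ids <- function(windows) {
  paste0(windows$chrom, ":", windows$start, "-", windows$end)
}

# internal: reverse complement of a DNA string vector (ACGT alphabet)
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}
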