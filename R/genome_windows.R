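#' Build a megabase window grid over autosomes
#'
#' Tiles each autosome with fixed-width windows in 0-based half-open
#' coordinates. The terminal partial window of each chromosome is kept as a
#' short window; its reduced alignable length is absorbed by the per-Mb
#' density normalization downstream. Sex chromosomes (X and Y, with or
#' without a "chr" prefix) are excluded.
#'
#' @param chromosome_lengths named numeric vector or list, chromosome name to
#'   length in bp.
#' @param window_bp window width in bp (default 1e6).
#' @return a `window_set`: data.frame with columns `chrom`, `start`, `end`,
#'   `alignable_bp`, `retained`, plus attributes `assay_mode` and
#'   `retention_threshold_bp` (unset until [filter_windows()]).
#'   `alignable_bp` is initialized to the full window length.
#' @export
build_windows <- function(chromosome_lengths, window_bp = 1e6) {
  chromosome_lengths <- unlist(chromosome_lengths)
  if (length(chromosome_lengths) == 0) stop("empty chromosome length map")
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (window_bp <= 0) stop("window_bp must be positive")
  sex <- grepl("^(chr)?[XY]$", names(chromosome_lengths), ignore.case = TRUE)
  if (any(sex)) {
    message("excluding sex chromosome(s): ",
            paste(names(chromosome_lengths)[sex], collapse = ", "))
    chromosome_lengths <- chromosome_lengths[!sex]
  }
  pieces <- lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  out$alignable_bp <- out$end - out$start
  out$retained <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("window_set", "data.frame"),
            assay_mode = NA_character_, retention_threshold_bp = NA_real_)
}

#' Set per-window alignable lengths from a mappability mask
#'
#' For each window, `alignable_bp` becomes the total number of bases shared
#' with the supplied interval set (e.g. the perfectly-mappable intervals of
#' an alignability track, or exome capture regions in WES mode). Intervals
#' are merged before counting so overlapping mask entries are never counted
#' twice.
#'
#' @param windows a `window_set` from [build_windows()].
#' @param alignable_intervals data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return the `window_set` with updated `alignable_bp`.
#' @export
apply_alignability <- function(windows, alignable_intervals) {
  stopifnot(is.data.frame(alignable_intervals))
  if (any(alignable_intervals$start < 0) ||
      any(alignable_intervals$end < alignable_intervals$start)) {
    stop("invalid intervals: start < 0 or end < start")
  }
  chrom_max <- tapply(windows$end, windows$chrom, max)
  iv_chr <- as.character(alignable_intervals$chrom)
  known <- iv_chr %in% names(chrom_max)
  if (any(known & alignable_intervals$end > chrom_max[iv_chr])) {
    stop("alignability intervals extend beyond chromosome bounds")
  }
  win_gr <- as_granges0(windows)
  mask_gr <- GenomicRanges::reduce(as_granges0(alignable_intervals))
  hits <- GenomicRanges::findOverlaps(win_gr, mask_gr)
  ov <- GenomicRanges::pintersect(win_gr[S4Vectors::queryHits(hits)],
                                  mask_gr[S4Vectors::subjectHits(hits)])
  acc <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  windows$alignable_bp <- 0
  windows$alignable_bp[as.integer(names(acc))] <- as.numeric(acc)
  windows
}

#' Flag windows retained for feature computation
#'
#' WGS mode keeps windows with at least 100 kb of perfectly alignable
#' sequence; WES mode keeps windows with at least 10 kb covered by capture
#' regions (in WES mode `alignable_bp` must hold capture-covered bp).
#' Windows exactly at the threshold are retained; only strictly smaller
#' ones are discarded. The order of retained windows defines the RMD
#' feature order.
#'
#' @param windows a `window_set` with `alignable_bp` populated.
#' @param mode "WGS" or "WES".
#' @param threshold_bp optional override of the retention threshold.
#' @return the `window_set` with `retained` set and attributes
#'   `assay_mode` / `retention_threshold_bp` recorded.
#' @export
filter_windows <- function(windows, mode = c("WGS", "WES"), threshold_bp = NULL) {
  mode <- match.arg(mode)
  thr <- threshold_bp %||% if (mode == "WGS") 1e5 else 1e4
  windows$retained <- windows$alignable_bp >= thr
  attr(windows, "assay_mode") <- mode
  attr(windows, "retention_threshold_bp") <- thr
  windows
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows (%d retained) on %d chromosome(s)",
              nrow(x), sum(x$retained), length(unique(x$chrom))))
  if (!is.na(attr(x, "assay_mode"))) {
    cat(sprintf("; mode %s, retention threshold %g bp",
                attr(x, "assay_mode"), attr(x, "retention_threshold_bp")))
  }
  cat("\n")
  invisible(x)
}

# internal: subset preserving window_set attributes
retained_windows <- function(windows) {
  out <- windows[windows$retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}
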