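#' Emulate whole-exome sequencing from a WGS catalog
#'
#' Keeps only mutations overlapping the capture intervals. When per-interval
#' retention probabilities are supplied (emulating unevenly covered exons),
#' each kept mutation additionally survives an independent coin flip with
#' the probability of the capture interval it overlaps.
#'
#' @param catalog mutation catalog data.frame.
#' @param capture_intervals data.frame `chrom`, `start`, `end` (0-based
#'   half-open), optionally with a `retention_prob` column in [0, 1].
#' @param seed integer seed (used only when retention probabilities exist).
#' @return the subset catalog.
#' @export
simulate_wes <- function(catalog, capture_intervals, seed = 1) {
  check_catalog(catalog)
  keep <- overlaps_any(catalog, capture_intervals)
  out <- catalog[keep, , drop = FALSE]
  if ("retention_prob" %in% names(capture_intervals) && nrow(out)) {
    pr <- capture_intervals$retention_prob
    if (any(pr < 0 | pr > 1)) stop("retention probabilities must lie in [0, 1]")
    hits <- GenomicRanges::findOverlaps(as_granges0(out),
                                        as_granges0(capture_intervals))
    p <- tapply(pr[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits), max)
    pvec <- rep(1, nrow(out))
    pvec[as.integer(names(p))] <- as.numeric(p)
    set.seed(seed)
    out <- out[runif(nrow(out)) < pvec, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Random mutation dropout
#'
#' Removes each mutation independently with the given probability,
#' emulating false-negative mutation calls from low coverage or purity.
#'
#' @param catalog mutation catalog data.frame.
#' @param rate dropout probability in [0, 1].
#' @param seed integer seed.
#' @return the subset catalog (`rate = 0` returns the input unchanged).
#' @export
dropout <- function(catalog, rate, seed = 1) {
  check_catalog(catalog)
  if (rate < 0 || rate > 1) stop("dropout rate must lie in [0, 1]")
  if (rate == 0) return(catalog)
  set.seed(seed)
  out <- catalog[runif(nrow(catalog)) >= rate, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classifier degradation under mutation dropout
#'
#' For each dropout rate: perturb every catalog, recompute the requested
#' feature blocks, cross-validate with the supplied configuration, and
#' report the median-across-classes AUPRC (mean and sd over CV runs). The
#' same CV seed is used at every rate, so the rate-0 row reproduces the
#' unperturbed cross-validation exactly.
#'
#' @param cohort a `synthetic_cohort` (or any list with `catalogs` and
#'   `labels`).
#' @param windows filtered `window_set`.
#' @param regions region sets (driver exclusion for features).
#' @param rates dropout rates (the full-scale grid is 0.5, 0.75, 0.95,
#'   0.98, 0.99, 0.999).
#' @param feature_blocks subset of "RMD", "MS96", "OGM".
#' @param config a `classifier_config`.
#' @return data.frame with `block`, `rate`, `median_auprc` (mean over runs
#'   of the per-run median across classes) and `sd_auprc`.
#' @export
degradation_experiment <- function(cohort, windows, regions,
                                   rates = c(0, 0.5, 0.75, 0.95),
                                   feature_blocks = "RMD",
                                   config = classifier_config()) {
  out <- list()
  for (rate in rates) {
    catalogs <- cohort$catalogs
    if (rate > 0) {
      catalogs <- lapply(seq_along(catalogs), function(i) {
        dropout(catalogs[[i]], rate,
                seed = derive_seed(config$seed, round(rate * 1e4) * 1000 + i))
      })
      names(catalogs) <- names(cohort$catalogs)
    }
    for (block in feature_blocks) {
      x <- build_feature_matrix(catalogs, windows, regions, blocks = block)
      cv <- crossvalidate(x, cohort$labels[rownames(x)], config)
      m <- cv_class_metrics(cv)
      med_by_run <- tapply(m$auprc, m$run, median)
      out[[length(out) + 1]] <- data.frame(
        block = block, rate = rate,
        median_auprc = mean(med_by_run),
        sd_auprc = if (length(med_by_run) > 1) sd(med_by_run) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Assemble a combined feature matrix from named blocks
#'
#' Convenience builder used by the experiment harnesses: computes any
#' combination of RMD, MS96 and OGM blocks (plus the reduced RMD
#' representations) for a set of catalogs and binds them column-wise.
#' Driver coding regions (with flanks) are excluded from the passenger
#' features (RMD and MS96) and define the OGM gene features.
#'
#' @param catalogs named list of mutation catalogs (or a
#'   `synthetic_cohort`).
#' @param windows filtered `window_set`.
#' @param regions region sets with `driver`, `pathways`, `hotspots`.
#' @param blocks character vector among "RMD", "MS96", "OGM",
#'   "RMD_kmedoids", "RMD_PCA".
#' @param rmd_k medoid count for "RMD_kmedoids" (default 50 at desk scale;
#'   the full-scale configuration uses 500).
#' @param rmd_pcs component count for "RMD_PCA" (default 20; full scale
#'   100).
#' @param min_mutations RMD quality threshold per sample.
#' @return samples x features numeric matrix; block membership is encoded
#'   in the column-name prefixes.
#' @export
build_feature_matrix <- function(catalogs, windows, regions,
                                 blocks = c("RMD", "MS96", "OGM"),
                                 rmd_k = 50, rmd_pcs = 20,
                                 min_mutations = 50) {
  if (is.list(catalogs) && !is.data.frame(catalogs) &&
      !is.null(catalogs[["catalogs"]])) {
    catalogs <- catalogs[["catalogs"]]  # cohort-like container
  }
  ann <- driver_annotation(regions$driver, regions$pathways %||% list(),
                           regions$hotspots)
  excl <- ann$gene_regions[, c("chrom", "start", "end")]
  parts <- list()
  rmd_needed <- any(blocks %in% c("RMD", "RMD_kmedoids", "RMD_PCA"))
  if (rmd_needed) {
    rmd <- rmd_matrix(catalogs, windows, driver_exclusion = excl,
                      min_mutations = min_mutations)
  }
  for (b in blocks) {
    parts[[b]] <- switch(b,
      RMD = rmd,
      RMD_kmedoids = {
        r <- reduce_kmedoids(rmd, k = min(rmd_k, ncol(rmd)))
        colnames(r) <- sub("^RMD:", "RMD_kmedoids:", colnames(r))
        r
      },
      RMD_PCA = reduce_pca(rmd, n_components = min(rmd_pcs, nrow(rmd), ncol(rmd))),
      MS96 = ms96_matrix(catalogs, driver_exclusion = excl),
      OGM = ogm_matrix(catalogs, ann),
      stop("unknown feature block: ", b))
  }
  do.call(cbind, parts[blocks])
}
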