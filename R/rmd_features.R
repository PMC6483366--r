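#' Regional mutation density vector of one tumor
#'
#' Counts somatic mutations (SNVs and indels) per retained megabase window,
#' after removing mutations that overlap the driver-gene exclusion
#' intervals. Each count is divided by the window's alignable length in Mb,
#' and the resulting densities are divided by their mean over retained
#' windows, so the vector has mean 1 and is invariant to uniform changes in
#' mutation burden. A mutation is assigned to the window containing its
#' start position (an indel spanning a window boundary goes to the window
#' of its start); mutations outside any retained window are ignored.
#'
#' @param catalog mutation catalog data.frame.
#' @param windows filtered `window_set`.
#' @param driver_exclusion optional intervals (0-based half-open) whose
#'   overlapping mutations are dropped before counting.
#' @param min_mutations quality threshold: samples with fewer usable
#'   mutations are flagged `low_content` (they still get a vector).
#' @param sample_id optional identifier stored on the result.
#' @return an `rmd_vector`: list with `sample_id`, `values` (named over
#'   retained windows, mean 1 when any mutation was usable, all zero
#'   otherwise), `n_mutations_used`, `low_content`.
#' @export
compute_rmd <- function(catalog, windows, driver_exclusion = NULL,
                        min_mutations = 50, sample_id = NA_character_) {
  check_catalog(catalog)
  ret <- retained_windows(windows)
  if (nrow(ret) == 0) stop("window set has no retained windows")
  if (nrow(catalog)) {
    catalog <- catalog[!overlaps_any(catalog, driver_exclusion), , drop = FALSE]
  }
  counts <- count_in_windows(catalog, ret)
  n_used <- sum(counts)
  dens <- counts / (ret$alignable_bp / 1e6)
  values <- if (n_used > 0) dens / mean(dens) else rep(0, nrow(ret))
  structure(list(sample_id = sample_id,
                 values = setNames(values, window_ids(ret)),
                 n_mutations_used = as.integer(n_used),
                 low_content = n_used < min_mutations),
            class = "rmd_vector")
}

# internal: per-window mutation counts by start position; windows must be
# sorted, non-overlapping within chromosome (gaps allowed).
count_in_windows <- function(catalog, windows) {
  counts <- numeric(nrow(windows))
  if (nrow(catalog) == 0) return(counts)
  widx <- split(seq_len(nrow(windows)), windows$chrom)
  midx <- split(seq_len(nrow(catalog)), as.character(catalog$chrom))
  for (ch in intersect(names(widx), names(midx))) {
    wi <- widx[[ch]]
    starts <- catalog$start[midx[[ch]]]
    slot <- findInterval(starts, windows$start[wi])
    ok <- slot >= 1 & starts < windows$end[wi][pmax(slot, 1)]
    tab <- table(slot[ok])
    counts[wi[as.integer(names(tab))]] <- counts[wi[as.integer(names(tab))]] + as.numeric(tab)
  }
  counts
}

#' RMD feature matrix for a set of catalogs
#'
#' @param catalogs named list of mutation catalogs.
#' @param windows filtered `window_set`.
#' @param driver_exclusion optional exclusion intervals.
#' @param min_mutations per-sample quality threshold (see [compute_rmd()]).
#' @return numeric matrix, samples x retained windows, columns prefixed
#'   "RMD:". Attributes `n_mutations_used` and `low_content` carry the
#'   per-sample bookkeeping.
#' @export
rmd_matrix <- function(catalogs, windows, driver_exclusion = NULL,
                       min_mutations = 50) {
  vecs <- lapply(names(catalogs), function(sid) {
    compute_rmd(catalogs[[sid]], windows, driver_exclusion = driver_exclusion,
                min_mutations = min_mutations, sample_id = sid)
  })
  m <- do.call(rbind, lapply(vecs, `[[`, "values"))
  rownames(m) <- names(catalogs)
  colnames(m) <- paste0("RMD:", names(vecs[[1]]$values))
  attr(m, "n_mutations_used") <-
    setNames(vapply(vecs, `[[`, integer(1), "n_mutations_used"), names(catalogs))
  attr(m, "low_content") <-
    setNames(vapply(vecs, `[[`, logical(1), "low_content"), names(catalogs))
  m
}

#' Reduce RMD columns by k-medoids clustering of windows
#'
#' Clusters the window columns with partitioning around medoids on the
#' dissimilarity 1 - Pearson correlation between columns, and keeps only
#' the k medoid columns — removing correlated windows while keeping
#' interpretable (real-window) features. `pam` on a fixed dissimilarity
#' matrix is deterministic.
#'
#' @param mat samples x windows numeric matrix.
#' @param k number of medoids (the full-scale configuration uses 500).
#' @return the matrix restricted to the k medoid columns; attribute
#'   `medoids` records their names.
#' @export
reduce_kmedoids <- function(mat, k) {
  if (k <= 0 || k > ncol(mat)) stop("k must be in [1, ncol(mat)]")
  if (k == ncol(mat)) {
    out <- mat
    attr(out, "medoids") <- colnames(mat)
    return(out)
  }
  cc <- suppressWarnings(cor(mat))
  cc[is.na(cc)] <- 0  # constant columns: treat as uncorrelated
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  fit <- cluster::pam(d, k = k, diss = TRUE)
  med <- fit$medoids
  out <- mat[, med, drop = FALSE]
  attr(out, "medoids") <- med
  out
}

#' Reduce RMD columns by principal component analysis
#'
#' Column-centered projection onto the leading principal components,
#' ordered by decreasing explained variance (the full-scale configuration
#' uses 100 components).
#'
#' @param mat samples x windows numeric matrix.
#' @param n_components number of components, at most `min(n-1, p)`.
#' @return scores matrix (samples x components, columns "RMD_PC1", ...);
#'   attributes `rotation`, `center` and `explained_variance`.
#' @export
reduce_pca <- function(mat, n_components) {
  if (n_components < 1 || n_components > min(nrow(mat), ncol(mat))) {
    stop("n_components must be in [1, min(n_samples, n_columns)]")
  }
  sds <- apply(mat, 2, sd)
  if (all(sds == 0)) {
    stop("degenerate matrix: all columns constant (",
         paste(head(colnames(mat), 5), collapse = ", "), " ...)")
  }
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(fit$x))
  out <- fit$x[, seq_len(n_components), drop = FALSE]
  colnames(out) <- paste0("RMD_PC", seq_len(n_components))
  attr(out, "rotation") <- fit$rotation[, seq_len(n_components), drop = FALSE]
  attr(out, "center") <- fit$center
  attr(out, "explained_variance") <- fit$sdev^2 / sum(fit$sdev^2)
  out
}
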