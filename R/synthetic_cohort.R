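#' Generative profile of one synthetic cancer type
#'
#' Bundles the class-specific parameters of the cohort generator: relative
#' per-window mutation rates, a 96-channel trinucleotide spectrum mixture,
#' per-driver-gene hit probabilities, and a log-normal per-sample mutation
#' burden. Validates the container invariants (mixture sums to 1, window
#' intensity has mean 1 over retained windows, probabilities in [0,1]).
#'
#' @param class_label class name.
#' @param window_intensity non-negative vector over retained windows; will be
#'   rescaled to mean 1 if `rescale = TRUE` (default), otherwise must already
#'   have mean 1.
#' @param channel_mixture probability vector of length 96 (package channel
#'   order, see [ms96_channels()]).
#' @param driver_prob named vector, gene id to probability of harboring at
#'   least one driver mutation.
#' @param burden_log_mean,burden_log_sd log-normal parameters of the
#'   per-sample passenger mutation count (`burden_log_mean = -Inf` gives a
#'   zero-burden class).
#' @param indel_fraction proportion of passenger mutations emitted as indels,
#'   in [0, 1).
#' @param rescale rescale `window_intensity` to mean 1 (default TRUE).
#' @return a `class_profile` list.
#' @export
class_profile <- function(class_label, window_intensity, channel_mixture,
                          driver_prob = numeric(0),
                          burden_log_mean = log(3000), burden_log_sd = 0.4,
                          indel_fraction = 0.1, rescale = TRUE) {
  stopifnot(is.character(class_label), length(class_label) == 1)
  if (any(window_intensity < 0)) stop("window_intensity must be non-negative")
  if (all(window_intensity == 0)) stop("window_intensity must not be all zero")
  if (rescale) window_intensity <- window_intensity / mean(window_intensity)
  if (abs(mean(window_intensity) - 1) > 1e-9) {
    stop("window_intensity mean must equal 1")
  }
  if (length(channel_mixture) != 96) stop("channel_mixture must have length 96")
  if (any(channel_mixture < 0)) stop("channel_mixture entries must be >= 0")
  if (abs(sum(channel_mixture) - 1) > 1e-9) stop("channel_mixture must sum to 1")
  if (length(driver_prob) && (any(driver_prob < 0) || any(driver_prob > 1))) {
    stop("driver_prob values must lie in [0, 1]")
  }
  if (indel_fraction < 0 || indel_fraction >= 1) {
    stop("indel_fraction must lie in [0, 1)")
  }
  structure(list(class_label = class_label,
                 window_intensity = as.numeric(window_intensity),
                 channel_mixture = as.numeric(channel_mixture),
                 driver_prob = driver_prob,
                 burden_log_mean = burden_log_mean,
                 burden_log_sd = burden_log_sd,
                 indel_fraction = indel_fraction),
            class = "class_profile")
}

#' Build a small synthetic genome: window grid plus region sets
#'
#' Stands in for a reference assembly with its mappability mask: chromosomes
#' of equal length are tiled into windows whose alignable fractions are drawn
#' uniformly from `alignable_fraction_range`. Driver-gene coding intervals,
#' pathway membership, exome capture intervals and hotspot positions are
#' placed deterministically given the seed.
#'
#' @param n_chromosomes,windows_per_chromosome,window_bp grid dimensions.
#' @param alignable_fraction_range pair of fractions in (0, 1].
#' @param seed integer seed.
#' @param n_driver_genes number of driver genes (10 kb coding intervals).
#' @param n_pathways pathways the genes are partitioned into.
#' @param n_hotspots number of hotspot positions.
#' @param capture_fraction fraction of each window covered by capture
#'   intervals (one contiguous capture region per window).
#' @return list with `windows` (a `window_set`, WGS-filtered at 100 kb) and
#'   `regions`: `driver` (gene, chrom, start, end), `pathways` (named list of
#'   gene ids), `capture` (chrom, start, end), `hotspots` (chrom, pos
#'   1-based).
#' @export
make_toy_genome <- function(n_chromosomes = 4, windows_per_chromosome = 25,
                            window_bp = 1e6,
                            alignable_fraction_range = c(0.6, 1),
                            seed = 1, n_driver_genes = 20, n_pathways = 6,
                            n_hotspots = 25, capture_fraction = 0.03) {
  stopifnot(n_chromosomes >= 1, windows_per_chromosome >= 1, window_bp > 0)
  r <- alignable_fraction_range
  if (length(r) != 2 || r[1] > r[2] || r[1] <= 0 || r[2] > 1) {
    stop("alignable_fraction_range must be (min, max) with 0 < min <= max <= 1")
  }
  set.seed(derive_seed(seed, 0))
  chrom_len <- windows_per_chromosome * window_bp
  lens <- setNames(rep(chrom_len, n_chromosomes), paste0("chr", seq_len(n_chromosomes)))
  windows <- build_windows(lens, window_bp)
  frac <- runif(nrow(windows), r[1], r[2])
  windows$alignable_bp <- round(frac * (windows$end - windows$start))
  windows <- filter_windows(windows, "WGS")

  rand_pos <- function(n, width) {
    ch <- sample(names(lens), n, replace = TRUE)
    st <- floor(runif(n, 0, chrom_len - width))
    data.frame(chrom = ch, start = st, end = st + width, stringsAsFactors = FALSE)
  }
  driver <- rand_pos(n_driver_genes, 1e4)
  driver <- cbind(gene = paste0("GENE", seq_len(n_driver_genes)), driver)
  pw_assign <- sample(rep_len(seq_len(n_pathways), n_driver_genes))
  pathways <- split(driver$gene, paste0("PW", pw_assign))
  cap_w <- round(capture_fraction * window_bp)
  cap_off <- floor(runif(nrow(windows), 0, window_bp - cap_w))
  capture <- data.frame(chrom = windows$chrom,
                        start = windows$start + cap_off,
                        end = pmin(windows$start + cap_off + cap_w, windows$end),
                        stringsAsFactors = FALSE)
  hs <- rand_pos(n_hotspots, 1)
  hotspots <- data.frame(chrom = hs$chrom, pos = hs$start + 1,
                         stringsAsFactors = FALSE)
  list(windows = windows,
       regions = list(driver = driver, pathways = pathways,
                      capture = capture, hotspots = hotspots))
}

#' Well-separated default class profiles for a synthetic cohort
#'
#' Each class gets an independent log-normal window-intensity landscape
#' (log-sd 0.6), a sparse Dirichlet spectrum mixture (concentration 0.5),
#' and a driver-gene profile with a low background hit rate plus a few
#' class-specific frequently-hit genes. These defaults emulate cohorts whose
#' classes differ in all three feature families at once.
#'
#' @param genome result of [make_toy_genome()].
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @param burden_log_mean,burden_log_sd shared burden parameters.
#' @param intensity_log_sd spread of the per-window log-intensities.
#' @param indel_fraction shared indel proportion.
#' @return list of `class_profile` objects labelled "TYPE1", "TYPE2", ...
#' @export
default_profiles <- function(genome, n_classes = 4, seed = 1,
                             burden_log_mean = log(3000), burden_log_sd = 0.4,
                             intensity_log_sd = 0.6, indel_fraction = 0.1) {
  set.seed(derive_seed(seed, 1))
  nw <- sum(genome$windows$retained)
  genes <- genome$regions$driver$gene
  lapply(seq_len(n_classes), function(k) {
    wi <- exp(rnorm(nw, 0, intensity_log_sd))
    mix <- rgamma(96, shape = 0.5)
    mix <- mix / sum(mix)
    dp <- setNames(rep(0.05, length(genes)), genes)
    marker <- sample(genes, min(3, length(genes)))
    dp[marker] <- 0.6
    class_profile(paste0("TYPE", k), wi, mix, driver_prob = dp,
                  burden_log_mean = burden_log_mean,
                  burden_log_sd = burden_log_sd,
                  indel_fraction = indel_fraction)
  })
}

#' Draw one synthetic mutation catalog
#'
#' The passenger count N is log-normal (rounded); passengers fall into
#' retained windows with probability proportional to window intensity times
#' alignable length, uniformly within the window. Each SNV draws a
#' trinucleotide channel from the class mixture and stores its context
#' string on the record; a fraction of mutations are emitted as 1-bp
#' deletions with no channel. Independently, each driver gene harbors a
#' mutation (placed uniformly in its coding interval) with its profile
#' probability. Driver mutations are additional to N.
#'
#' @param profile a `class_profile`; `window_intensity` must match the
#'   number of retained windows.
#' @param windows a filtered `window_set`.
#' @param regions region sets from [make_toy_genome()] (uses `driver`).
#' @param seed integer seed.
#' @return mutation catalog data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `ref`, `alt`, `variant_class`, `context`.
#' @export
sample_catalog <- function(profile, windows, regions = NULL, seed = 1) {
  stopifnot(inherits(profile, "class_profile"))
  ret <- retained_windows(windows)
  if (nrow(ret) == 0) stop("window set has no retained windows")
  if (length(profile$window_intensity) != nrow(ret)) {
    stop("window_intensity length (", length(profile$window_intensity),
         ") does not match retained window count (", nrow(ret), ")")
  }
  set.seed(seed)
  n <- if (is.infinite(profile$burden_log_mean) && profile$burden_log_mean < 0) 0L
       else as.integer(round(rlnorm(1, profile$burden_log_mean, profile$burden_log_sd)))
  channels <- ms96_channels()
  ch_p5 <- substr(channels, 1, 1)
  ch_ref <- substr(channels, 3, 3)
  ch_alt <- substr(channels, 5, 5)
  ch_p3 <- substr(channels, 7, 7)

  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      ref = character(0), alt = character(0),
                      variant_class = character(0), context = character(0),
                      stringsAsFactors = FALSE)
  parts <- list()
  if (n > 0) {
    w <- profile$window_intensity * ret$alignable_bp
    widx <- sample.int(nrow(ret), n, replace = TRUE, prob = w)
    pos0 <- ret$start[widx] + floor(runif(n) * (ret$end[widx] - ret$start[widx]))
    is_indel <- runif(n) < profile$indel_fraction
    ch <- sample.int(96, n, replace = TRUE, prob = profile$channel_mixture)
    ref <- ch_ref[ch]
    alt <- ch_alt[ch]
    ctx <- paste0(ch_p5[ch], ref, ch_p3[ch])
    vc <- rep("SNV", n)
    end <- pos0 + 1
    if (any(is_indel)) {
      # 1-bp deletions: ref = deleted base + anchor, no spectrum channel
      anchor <- sample(BASES, sum(is_indel), replace = TRUE)
      ref[is_indel] <- paste0(anchor, ref[is_indel])
      alt[is_indel] <- anchor
      ctx[is_indel] <- NA_character_
      vc[is_indel] <- "indel"
      end[is_indel] <- pos0[is_indel] + 2
    }
    parts$passengers <- data.frame(chrom = ret$chrom[widx], start = pos0,
                                   end = end, ref = ref, alt = alt,
                                   variant_class = vc, context = ctx,
                                   stringsAsFactors = FALSE)
  }
  if (length(profile$driver_prob) && !is.null(regions$driver)) {
    dg <- regions$driver
    pr <- profile$driver_prob[dg$gene]
    pr[is.na(pr)] <- 0
    hit <- runif(nrow(dg)) < pr
    if (any(hit)) {
      dgh <- dg[hit, , drop = FALSE]
      pos0 <- floor(runif(nrow(dgh), dgh$start, dgh$end))
      ch <- sample.int(96, nrow(dgh), replace = TRUE,
                       prob = profile$channel_mixture)
      parts$drivers <- data.frame(chrom = dgh$chrom, start = pos0,
                                  end = pos0 + 1, ref = ch_ref[ch],
                                  alt = ch_alt[ch], variant_class = "SNV",
                                  context = paste0(ch_p5[ch], ch_ref[ch], ch_p3[ch]),
                                  stringsAsFactors = FALSE)
    }
  }
  out <- if (length(parts)) do.call(rbind, unname(parts)) else empty
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_per_class` catalogs per profile. Per-sample seeds are derived
#' from the master seed with the counter scheme of [derive_seed()], so the
#' cohort is reproducible byte-for-byte and samples could be generated in
#' parallel. Samples are alternately tagged with the entries of
#' `dataset_tags` to support external-validation splits.
#'
#' @param profiles list of `class_profile` with distinct labels.
#' @param windows,regions genome pieces from [make_toy_genome()].
#' @param n_per_class samples per class (>= 1).
#' @param seed master seed.
#' @param dataset_tags character vector cycled over samples within a class.
#' @return a `synthetic_cohort`: list with `catalogs` (named list),
#'   `labels`, `dataset_tag` (named character vectors), and `seed`.
#' @export
generate_cohort <- function(profiles, windows, regions, n_per_class, seed = 1,
                            dataset_tags = c("setA", "setB")) {
  if (length(profiles) < 2) stop("need at least 2 class profiles")
  labs <- vapply(profiles, `[[`, character(1), "class_label")
  if (anyDuplicated(labs)) stop("duplicate class labels in profiles")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  catalogs <- list(); labels <- character(0); tags <- character(0)
  counter <- 0L
  for (p in profiles) {
    for (i in seq_len(n_per_class)) {
      counter <- counter + 1L
      sid <- sprintf("%s_S%03d", p$class_label, i)
      catalogs[[sid]] <- sample_catalog(p, windows, regions,
                                        seed = derive_seed(seed, counter))
      labels[sid] <- p$class_label
      tags[sid] <- dataset_tags[(i - 1) %% length(dataset_tags) + 1]
    }
  }
  structure(list(catalogs = catalogs, labels = labels, dataset_tag = tags,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d classes (seed %s)\n",
              length(x$catalogs), length(unique(x$labels)), format(x$seed)))
  print(table(x$labels))
  invisible(x)
}
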