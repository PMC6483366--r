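BASES <- c("A", "C", "G", "T")

# Substitution types read strand-symmetrically with reference base C or A.
SUBSTITUTIONS <- c("C>G", "C>T", "C>A", "A>T", "A>G", "A>C")

#' The 96 trinucleotide spectrum channels in canonical order
#'
#' Channel order is substitution-major (C>G, C>T, C>A, A>T, A>G, A>C), then
#' 5' base (A, C, G, T), then 3' base (A, C, G, T). Substitutions are read
#' strand-symmetrically with the reference pyrimidine/purine pair collapsed
#' onto reference bases C and A; this differs from the COSMIC convention
#' (reference C and T) — see [ms96_to_cosmic()].
#'
#' @return character vector of 96 channel names like `"A[C>T]A"`.
#' @export
ms96_channels <- function() {
  out <- character(0)
  for (sub in SUBSTITUTIONS) {
    for (p5 in BASES) {
      for (p3 in BASES) {
        out <- c(out, paste0(p5, "[", sub, "]", p3))
      }
    }
  }
  out
}

#' Collapse a stranded (trinucleotide, alt) pair onto one of 96 channels
#'
#' If the central (mutated) reference base is C or A the channel is read
#' directly; if it is G or T, trinucleotide and alternate allele are
#' reverse-complemented first, mapping onto a C- or A-reference channel.
#' The map sends the 192 stranded possibilities 2-to-1 onto 96 channels.
#'
#' @param trinucleotide character vector of 3-mers centred on the mutated base.
#' @param alt character vector of alternate alleles (single base).
#' @return character vector of channel names; `NA` where the context or alt
#'   contains an ambiguous base or alt equals the reference base.
#' @export
collapse_channel <- function(trinucleotide, alt) {
  trinucleotide <- toupper(trinucleotide)
  alt <- toupper(alt)
  stopifnot(length(trinucleotide) == length(alt))
  out <- rep(NA_character_, length(alt))
  ok <- grepl("^[ACGT]{3}$", trinucleotide) & alt %in% BASES
  center <- substr(trinucleotide, 2, 2)
  ok <- ok & center != alt
  flip <- ok & center %in% c("G", "T")
  trinucleotide[flip] <- revcomp(trinucleotide[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  center <- substr(trinucleotide, 2, 2)
  out[ok] <- paste0(substr(trinucleotide[ok], 1, 1), "[", center[ok], ">",
                    alt[ok], "]", substr(trinucleotide[ok], 3, 3))
  out
}

#' Compute the 96-channel mutation spectrum of one tumor
#'
#' Counts strand-collapsed single-nucleotide substitutions per trinucleotide
#' channel and normalizes to relative frequencies. Indels carry no channel
#' and are ignored. Mutations overlapping the driver-gene exclusion
#' intervals are excluded before counting.
#'
#' Contexts are taken from the catalog's `context` column when present
#' (synthetic catalogs store them directly); otherwise they are extracted
#' from `context_source`, a reference genome as a named
#' [Biostrings::DNAStringSet] or path to a FASTA file. When extracting from
#' a reference, the base at the mutated position must match the record's
#' ref allele; mismatching records are skipped and counted in `n_skipped`.
#'
#' @param catalog mutation catalog data.frame.
#' @param driver_exclusion optional data.frame of intervals to exclude.
#' @param context_source optional reference genome (DNAStringSet or FASTA path).
#' @param sample_id optional sample identifier stored on the result.
#' @return an `ms96_vector`: list with `sample_id`, `frequencies` (named
#'   length-96, summing to 1 when any SNV was usable), `n_snvs_used`,
#'   `n_skipped`, and `low_content` flag (TRUE when no SNV was usable).
#' @export
compute_spectrum <- function(catalog, driver_exclusion = NULL,
                             context_source = NULL, sample_id = NA_character_) {
  check_catalog(catalog)
  channels <- ms96_channels()
  if (nrow(catalog)) {
    catalog <- catalog[!overlaps_any(catalog, driver_exclusion), , drop = FALSE]
  }
  snvs <- catalog[catalog$variant_class == "SNV", , drop = FALSE]
  n_skipped <- 0L
  ctx <- if ("context" %in% names(snvs)) as.character(snvs$context) else
    rep(NA_character_, nrow(snvs))
  need <- is.na(ctx)
  if (any(need)) {
    if (is.null(context_source)) {
      stop("catalog has SNVs without stored context and no context_source given")
    }
    genome <- if (is.character(context_source)) {
      Biostrings::readDNAStringSet(context_source)
    } else context_source
    names(genome) <- sub("\\s.*$", "", names(genome))
    idx <- which(need)
    for (i in idx) {
      ch <- as.character(snvs$chrom[i])
      p <- snvs$start[i] + 1  # 1-based position of the mutated base
      if (!ch %in% names(genome) || p < 2 || p + 1 > length(genome[[ch]])) {
        n_skipped <- n_skipped + 1L
        next
      }
      tri <- as.character(Biostrings::subseq(genome[[ch]], p - 1, p + 1))
      if (toupper(substr(tri, 2, 2)) != toupper(snvs$ref[i])) {
        n_skipped <- n_skipped + 1L  # reference mismatch
        next
      }
      ctx[i] <- toupper(tri)
    }
  }
  chan <- collapse_channel(ctx[!is.na(ctx)], snvs$alt[!is.na(ctx)])
  n_skipped <- n_skipped + sum(is.na(chan))
  chan <- chan[!is.na(chan)]
  counts <- table(factor(chan, levels = channels))
  n_used <- sum(counts)
  freqs <- if (n_used > 0) as.numeric(counts) / n_used else rep(0, 96)
  structure(list(sample_id = sample_id,
                 frequencies = setNames(freqs, channels),
                 n_snvs_used = as.integer(n_used),
                 n_skipped = as.integer(n_skipped),
                 low_content = n_used == 0L),
            class = "ms96_vector")
}

#' Convert channel names or a spectrum to COSMIC pyrimidine ordering
#'
#' The package's channels use reference bases C and A; COSMIC uses the
#' pyrimidine pair C and T. A-reference channels are reverse-complemented
#' onto T-reference ones; spectra are reordered into the standard COSMIC
#' sequence (C>A, C>G, C>T, T>A, T>C, T>G; contexts alphabetical).
#'
#' @param x either a character vector of channel names or an `ms96_vector`.
#' @return renamed character vector, or the spectrum reordered with COSMIC
#'   channel names.
#' @export
ms96_to_cosmic <- function(x) {
  rename1 <- function(nm) {
    p5 <- substr(nm, 1, 1); refb <- substr(nm, 3, 3)
    altb <- substr(nm, 5, 5); p3 <- substr(nm, 7, 7)
    flip <- refb == "A"
    tri <- paste0(p5, refb, p3)
    tri[flip] <- revcomp(tri[flip])
    altb[flip] <- chartr("ACGT", "TGCA", altb[flip])
    paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", altb, "]",
           substr(tri, 3, 3))
  }
  cosmic_order <- function() {
    out <- character(0)
    for (sub in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")) {
      for (p5 in BASES) for (p3 in BASES) {
        out <- c(out, paste0(p5, "[", sub, "]", p3))
      }
    }
    out
  }
  if (is.character(x)) return(rename1(x))
  stopifnot(inherits(x, "ms96_vector"))
  freqs <- x$frequencies
  names(freqs) <- rename1(names(freqs))
  x$frequencies <- freqs[cosmic_order()]
  x
}

#' Spectrum feature matrix for a set of catalogs
#'
#' @param catalogs named list of mutation catalogs.
#' @param driver_exclusion optional exclusion intervals.
#' @param context_source optional reference genome for context extraction.
#' @return numeric matrix, samples x 96 channels, columns prefixed "MS96:".
#'   Attribute `n_snvs_used` holds the per-sample usable SNV counts.
#' @export
ms96_matrix <- function(catalogs, driver_exclusion = NULL, context_source = NULL) {
  vecs <- lapply(names(catalogs), function(sid) {
    compute_spectrum(catalogs[[sid]], driver_exclusion = driver_exclusion,
                     context_source = context_source, sample_id = sid)
  })
  m <- do.call(rbind, lapply(vecs, function(v) v$frequencies))
  rownames(m) <- names(catalogs)
  colnames(m) <- paste0("MS96:", ms96_channels())
  attr(m, "n_snvs_used") <- setNames(vapply(vecs, `[[`, integer(1), "n_snvs_used"),
                                     names(catalogs))
  m
}
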