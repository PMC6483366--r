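#' Driver annotation bundle for OGM features
#'
#' Validates and packages the three driver feature definitions: coding-exon
#' intervals per gene (with +/-5 nt flanks applied here unless
#' `flank = 0`), pathway membership, and recurrent hotspot positions
#' (each expanded to an 11-bp window, center +/-5 nt). Pathway members
#' absent from the gene regions are kept but reported.
#'
#' @param gene_regions data.frame with `gene`, `chrom`, `start`, `end`
#'   (0-based half-open coding intervals, possibly several per gene).
#' @param pathway_members named list, pathway id to character vector of genes.
#' @param hotspots data.frame with `chrom`, `pos` (1-based center).
#' @param flank flank width in nt added to each side of gene intervals and
#'   hotspot centers (default 5).
#' @return a `driver_annotation` list with flanked `gene_regions`,
#'   `pathway_members`, `hotspot_windows` (0-based half-open 11-bp
#'   intervals with a `hotspot` id column), and `unmapped_genes`.
#' @export
driver_annotation <- function(gene_regions, pathway_members = list(),
                              hotspots = NULL, flank = 5) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_regions)))
  gr <- gene_regions
  gr$start <- pmax(gr$start - flank, 0)
  gr$end <- gr$end + flank
  unmapped <- setdiff(unlist(pathway_members), unique(gr$gene))
  if (length(unmapped)) {
    message("pathway member(s) without gene regions: ",
            paste(unmapped, collapse = ", "))
  }
  hw <- NULL
  if (!is.null(hotspots) && nrow(hotspots)) {
    stopifnot(all(c("chrom", "pos") %in% names(hotspots)))
    hw <- data.frame(
      hotspot = paste0(hotspots$chrom, ":", hotspots$pos),
      chrom = hotspots$chrom,
      start = hotspots$pos - 1 - flank,  # 1-based center -> 0-based, minus flank
      end = hotspots$pos + flank,
      stringsAsFactors = FALSE)
  }
  structure(list(gene_regions = gr, pathway_members = pathway_members,
                 hotspot_windows = hw, unmapped_genes = unmapped,
                 flank = flank),
            class = "driver_annotation")
}

# internal: per-feature maximum score (or 1) of catalog records overlapping
# each interval group; groups = factor-like ids aligned with `intervals` rows.
hits_by_group <- function(catalog, intervals, groups, scores = NULL) {
  ids <- unique(groups)
  out <- setNames(numeric(length(ids)), ids)
  if (nrow(catalog) == 0 || is.null(intervals) || nrow(intervals) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges0(catalog), as_granges0(intervals))
  if (length(hits) == 0) return(out)
  g <- groups[S4Vectors::subjectHits(hits)]
  v <- if (is.null(scores)) rep(1, length(hits)) else scores[S4Vectors::queryHits(hits)]
  mx <- tapply(v, g, max)
  mx <- mx[!is.na(mx)]
  out[names(mx)] <- as.numeric(mx)
  out
}

#' Per-gene driver mutation indicator bits
#'
#' Bit g is 1 iff any SNV or indel in the catalog overlaps any flanked
#' coding interval of gene g.
#'
#' @param catalog mutation catalog data.frame.
#' @param annotation a `driver_annotation`.
#' @return named binary vector over genes (order of first appearance in the
#'   gene regions).
#' @export
gene_bits <- function(catalog, annotation) {
  check_catalog(catalog)
  gr <- annotation$gene_regions
  bits <- hits_by_group(catalog, gr, factor(gr$gene, levels = unique(gr$gene)))
  as.integer(bits > 0) -> v
  setNames(v, names(bits))
}

#' Per-pathway driver mutation bits (OR over member genes)
#'
#' @param gbits named binary vector from [gene_bits()].
#' @param pathway_members named list, pathway id to gene ids.
#' @return named binary vector over pathways.
#' @export
pathway_bits <- function(gbits, pathway_members) {
  vapply(pathway_members, function(genes) {
    as.integer(any(gbits[intersect(genes, names(gbits))] > 0))
  }, integer(1))
}

#' Per-hotspot mutation bits
#'
#' Bit h is 1 iff any mutation overlaps the 11-bp window centred on
#' hotspot h (center position +/- 5 nt).
#'
#' @param catalog mutation catalog data.frame.
#' @param annotation a `driver_annotation` with hotspot windows.
#' @return named binary vector over hotspots (empty if none defined).
#' @export
hotspot_bits <- function(catalog, annotation) {
  hw <- annotation$hotspot_windows
  if (is.null(hw)) return(setNames(integer(0), character(0)))
  bits <- hits_by_group(catalog, hw, factor(hw$hotspot, levels = unique(hw$hotspot)))
  setNames(as.integer(bits > 0), names(bits))
}

#' Assemble the OGM feature vector of one tumor
#'
#' Concatenates gene, pathway and hotspot features in that order.
#' `impact_mode = "none"` gives the plain binary vector. In `"threshold"`
#' mode only variants with impact score strictly greater than `threshold`
#' support a bit; in `"weight"` mode each gene/hotspot indicator is
#' replaced by the maximum score of its supporting variants (pathway
#' entries by the maximum over member genes).
#'
#' @param catalog mutation catalog data.frame.
#' @param annotation a `driver_annotation`.
#' @param impact_mode "none", "threshold" or "weight".
#' @param scores per-variant impact scores: numeric vector aligned with
#'   catalog rows, or a data.frame keyed by `chrom`, `pos` (1-based), `ref`,
#'   `alt` with a `score` column. Required in threshold/weight modes.
#' @param threshold score cutoff for threshold mode (strict `>`).
#' @return named numeric vector (genes, then pathways, then hotspots);
#'   binary except in weight mode.
#' @export
assemble_ogm <- function(catalog, annotation,
                         impact_mode = c("none", "threshold", "weight"),
                         scores = NULL, threshold = 10) {
  impact_mode <- match.arg(impact_mode)
  check_catalog(catalog)
  if (impact_mode != "none") {
    sc <- resolve_scores(catalog, scores)
    if (anyNA(sc)) {
      bad <- which(is.na(sc))
      stop("missing impact scores for record(s): ",
           paste(head(paste0(catalog$chrom[bad], ":", catalog$start[bad] + 1,
                             catalog$ref[bad], ">", catalog$alt[bad]), 10),
                 collapse = ", "))
    }
  }
  if (impact_mode == "threshold") {
    catalog <- catalog[sc > threshold, , drop = FALSE]
    impact_mode <- "none"
    sc <- NULL
  }
  gr <- annotation$gene_regions
  gene_lv <- factor(gr$gene, levels = unique(gr$gene))
  if (impact_mode == "weight") {
    g <- hits_by_group(catalog, gr, gene_lv, scores = sc)
    p <- vapply(annotation$pathway_members, function(genes) {
      m <- g[intersect(genes, names(g))]
      if (length(m)) max(m) else 0
    }, numeric(1))
    hw <- annotation$hotspot_windows
    h <- if (is.null(hw)) setNames(numeric(0), character(0)) else
      hits_by_group(catalog, hw, factor(hw$hotspot, levels = unique(hw$hotspot)),
                    scores = sc)
  } else {
    g <- as.numeric(gene_bits(catalog, annotation))
    names(g) <- levels(gene_lv)
    p <- as.numeric(pathway_bits(setNames(g, levels(gene_lv)),
                                 annotation$pathway_members))
    names(p) <- names(annotation$pathway_members)
    hb <- hotspot_bits(catalog, annotation)
    h <- setNames(as.numeric(hb), names(hb))
  }
  c(setNames(as.numeric(g), paste0("gene:", names(g))),
    setNames(as.numeric(p), paste0("pathway:", names(p))),
    setNames(as.numeric(h), paste0("hotspot:", names(h))))
}

# internal: align per-variant scores with catalog rows
resolve_scores <- function(catalog, scores) {
  if (is.null(scores)) {
    if ("impact_score" %in% names(catalog)) return(catalog$impact_score)
    stop("impact mode requires per-variant scores")
  }
  if (is.numeric(scores)) {
    stopifnot(length(scores) == nrow(catalog))
    return(scores)
  }
  stopifnot(is.data.frame(scores),
            all(c("chrom", "pos", "ref", "alt", "score") %in% names(scores)))
  key <- function(ch, pos1, ref, alt) paste(ch, pos1, ref, alt, sep = "|")
  idx <- match(key(catalog$chrom, catalog$start + 1, catalog$ref, catalog$alt),
               key(scores$chrom, scores$pos, scores$ref, scores$alt))
  scores$score[idx]
}

#' OGM feature matrix for a set of catalogs
#'
#' @param catalogs named list of mutation catalogs.
#' @param annotation a `driver_annotation`.
#' @param ... passed to [assemble_ogm()] (impact mode, scores, threshold).
#' @return numeric matrix, samples x OGM features, columns prefixed "OGM:".
#' @export
ogm_matrix <- function(catalogs, annotation, ...) {
  vecs <- lapply(catalogs, assemble_ogm, annotation = annotation, ...)
  m <- do.call(rbind, vecs)
  rownames(m) <- names(catalogs)
  colnames(m) <- paste0("OGM:", names(vecs[[1]]))
  m
}
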