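toy_annotation <- function() {
  genes <- data.frame(gene = c("G1", "G1", "G2", "G3"),
                      chrom = "chr1",
                      start = c(100, 300, 1000, 5000),
                      end = c(200, 400, 1100, 5100),
                      stringsAsFactors = FALSE)
  driver_annotation(genes,
                    pathway_members = list(P1 = c("G1", "G2"), P2 = "G3"),
                    hotspots = data.frame(chrom = "chr1", pos = c(100, 2000)))
}

test_that("gene bits flag any overlap with flanked coding intervals", {
  ann <- toy_annotation()
  expect_equal(unname(gene_bits(toy_catalog(numeric(0)), ann)), c(0L, 0L, 0L))
  # exon [100,200) + 5 nt flanks -> [95,205): SNV at 0-based 204 in, 205 out
  expect_equal(unname(gene_bits(toy_catalog(204), ann)), c(1L, 0L, 0L))
  expect_equal(unname(gene_bits(toy_catalog(205), ann)), c(0L, 0L, 0L))
  expect_equal(unname(gene_bits(toy_catalog(94), ann)), c(0L, 0L, 0L))
  expect_equal(unname(gene_bits(toy_catalog(95), ann)), c(1L, 0L, 0L))
})

test_that("gene bits agree with a naive per-mutation interval scan", {
  ann <- toy_annotation()
  set.seed(8)
  for (rep in 1:5) {
    cat_ <- toy_catalog(sample(0:6000, 30))
    bits <- gene_bits(cat_, ann)
    gr <- ann$gene_regions
    oracle <- vapply(unique(gr$gene), function(g) {
      iv <- gr[gr$gene == g, ]
      hit <- FALSE
      for (m in seq_len(nrow(cat_))) {
        for (j in seq_len(nrow(iv))) {
          if (cat_$start[m] < iv$end[j] && cat_$end[m] > iv$start[j]) hit <- TRUE
        }
      }
      as.integer(hit)
    }, integer(1))
    expect_equal(bits, oracle)
  }
})

test_that("pathway bits are the OR of member gene bits", {
  members <- list(P = c("A", "B"))
  expect_equal(unname(pathway_bits(c(A = 0L, B = 1L), members)), 1L)
  expect_equal(unname(pathway_bits(c(A = 0L, B = 0L), members)), 0L)
  # exhaustive truth table for three members
  tri <- list(P = c("A", "B", "C"))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    bits <- c(A = a, B = b, C = cc)
    expect_equal(unname(pathway_bits(bits, tri)), as.integer(a | b | cc))
    expect_gte(pathway_bits(bits, tri), max(bits))
  }
})

test_that("hotspot windows span the center position plus/minus 5 nt", {
  ann <- toy_annotation()
  # center 1-based 100 -> 1-based window 95..105
  expect_equal(unname(hotspot_bits(toy_catalog(104), ann)), c(1L, 0L))  # pos 105
  expect_equal(unname(hotspot_bits(toy_catalog(105), ann)), c(0L, 0L))  # pos 106
  expect_equal(unname(hotspot_bits(toy_catalog(94), ann)), c(1L, 0L))   # pos 95
  expect_equal(unname(hotspot_bits(toy_catalog(93), ann)), c(0L, 0L))   # pos 94
  # naive oracle over random catalogs
  set.seed(9)
  hw <- ann$hotspot_windows
  for (rep in 1:5) {
    cat_ <- toy_catalog(sample(0:2500, 40))
    bits <- hotspot_bits(cat_, ann)
    oracle <- vapply(seq_len(nrow(hw)), function(h) {
      as.integer(any(cat_$start < hw$end[h] & cat_$end > hw$start[h]))
    }, integer(1))
    expect_equal(unname(bits), oracle)
  }
})

test_that("assemble_ogm concatenates gene, pathway and hotspot blocks in order", {
  ann <- toy_annotation()
  v <- assemble_ogm(toy_catalog(c(150, 2000)), ann)
  expect_equal(names(v), c("gene:G1", "gene:G2", "gene:G3",
                           "pathway:P1", "pathway:P2",
                           "hotspot:chr1:100", "hotspot:chr1:2000"))
  # 150 hits G1 (and so P1); 2000 hits only the second hotspot window
  expect_equal(unname(v), c(1, 0, 0, 1, 0, 0, 1))
})

test_that("threshold mode keeps only variants scored strictly above the cutoff", {
  ann <- toy_annotation()
  cat_ <- toy_catalog(150)
  v_low <- assemble_ogm(cat_, ann, impact_mode = "threshold",
                        scores = 9.5, threshold = 10)
  v_high <- assemble_ogm(cat_, ann, impact_mode = "threshold",
                         scores = 10.5, threshold = 10)
  expect_equal(unname(v_low["gene:G1"]), 0)
  expect_equal(unname(v_high["gene:G1"]), 1)
  # threshold -Inf reproduces plain binary mode exactly
  cat2 <- toy_catalog(c(150, 1050, 2000))
  expect_equal(assemble_ogm(cat2, ann, impact_mode = "threshold",
                            scores = c(1, 2, 3), threshold = -Inf),
               assemble_ogm(cat2, ann))
})

test_that("weight mode takes per-feature maxima and degenerates to binary at score 1", {
  ann <- toy_annotation()
  cat_ <- toy_catalog(c(150, 160, 1050))
  v <- assemble_ogm(cat_, ann, impact_mode = "weight", scores = c(3, 7, 2))
  expect_equal(unname(v["gene:G1"]), 7)
  expect_equal(unname(v["gene:G2"]), 2)
  expect_equal(unname(v["pathway:P1"]), 7)  # max over member genes
  v1 <- assemble_ogm(cat_, ann, impact_mode = "weight", scores = c(1, 1, 1))
  expect_equal(v1, assemble_ogm(cat_, ann))
  # missing scores are a validation error naming the records
  expect_error(assemble_ogm(cat_, ann, impact_mode = "weight",
                            scores = c(3, NA, 2)), "missing impact scores")
})

test_that("scores can be joined from a keyed table", {
  ann <- toy_annotation()
  cat_ <- toy_catalog(c(150, 1050))
  tab <- data.frame(chrom = "chr1", pos = c(151, 1051), ref = "C", alt = "T",
                    score = c(15, 5), stringsAsFactors = FALSE)
  v <- assemble_ogm(cat_, ann, impact_mode = "threshold", scores = tab,
                    threshold = 10)
  expect_equal(unname(v[c("gene:G1", "gene:G2")]), c(1, 0))
})

test_that("adding a mutation never clears a bit (monotonicity)", {
  ann <- toy_annotation()
  set.seed(10)
  for (rep in 1:5) {
    base <- toy_catalog(sample(0:6000, 10))
    more <- rbind(base, toy_catalog(sample(0:6000, 5)))
    expect_true(all(assemble_ogm(more, ann) >= assemble_ogm(base, ann)))
  }
})

test_that("pathway members without regions are reported as unmapped", {
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 100, end = 200)
  expect_message(ann <- driver_annotation(genes, list(P = c("G1", "GX"))),
                 "GX")
  expect_equal(ann$unmapped_genes, "GX")
})
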