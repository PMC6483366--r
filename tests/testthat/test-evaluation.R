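# brute-force oracles: Mann-Whitney pair counting and per-threshold PR recount
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

auprc_step_oracle <- function(scores, y) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(y[sel]) / sum(sel)
    rec <- sum(y[sel]) / sum(y)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("ROC AUC matches hand-counted examples", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc(c(0.9, 0.2, 0.4, 0.6), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.5)  # 2 of 4 concordant pairs
  expect_warning(roc_auc(c(1, 2), c(TRUE, TRUE)), "one class")
})

test_that("AUC equals the pair-counting oracle (ties counted one half)", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    expect_equal(roc_auc(scores, y)$auc, auc_pair_oracle(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent library implementation", {
  set.seed(15)
  for (i in 1:5) {
    scores <- rnorm(40)
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone score rescaling", {
  set.seed(16)
  scores <- rnorm(30); y <- rep(c(TRUE, FALSE), 15)
  a <- roc_auc(scores, y)$auc
  expect_equal(roc_auc(exp(scores / 2) + 7, y)$auc, a)
})

test_that("AUPRC handles the degenerate classifiers and matches the step oracle", {
  expect_equal(pr_auprc(c(3, 2, 1), c(TRUE, TRUE, FALSE))$auprc, 1.0)
  # score-constant classifier: flat precision at prevalence
  expect_equal(pr_auprc(rep(1, 10), rep(c(TRUE, FALSE), c(3, 7)))$auprc, 0.3)
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    expect_equal(pr_auprc(scores, y)$auprc, auprc_step_oracle(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("precision, recall and F follow their definitions", {
  pred <- rep(c("A", "B"), c(10, 10))
  true <- c(rep("A", 8), rep("B", 2), rep("B", 8), rep("A", 2))
  expect_equal(unname(prf(pred, true, "A")), c(0.8, 0.8, 0.8))
  perfect <- prf(c("A", "B"), c("A", "B"), "A")
  expect_equal(unname(perfect), c(1, 1, 1))
  none <- prf(rep("B", 4), c("A", "A", "B", "B"), "A")
  expect_equal(unname(none["precision"]), 0)
  expect_true(isTRUE(attr(none, "undefined_precision")))
})

test_that("recall at a precision level scans thresholds correctly", {
  curve <- list(precision = c(1.0, 0.9, 0.7), recall = c(0.2, 0.5, 0.8))
  expect_equal(recall_at_precision(curve, 0.8), 0.5)
  expect_equal(recall_at_precision(list(precision = c(0.5, 0.6),
                                        recall = c(0.3, 0.9)), 0.8), 0)
  expect_equal(recall_at_precision(list(precision = 1, recall = 1), 0.8), 1)
  # non-increasing in the level
  set.seed(18)
  pr <- pr_auprc(rnorm(40), sample(c(TRUE, FALSE), 40, replace = TRUE))
  levels <- seq(0.1, 0.9, by = 0.1)
  recalls <- vapply(levels, function(l) recall_at_precision(pr, l), numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("confusion matrices are row-normalized with recoverable counts", {
  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(perfect), diag(3), ignore_attr = TRUE)
  set.seed(19)
  true <- sample(LETTERS[1:3], 60, replace = TRUE)
  pred <- sample(LETTERS[1:3], 60, replace = TRUE)
  cm <- confusion_matrix(pred, true)
  expect_equal(unname(rowSums(cm)), rep(1, 3), tolerance = 1e-9)
  counts <- attr(cm, "counts")
  for (a in LETTERS[1:3]) for (b in LETTERS[1:3]) {
    expect_equal(counts[a, b], sum(true == a & pred == b))
  }
})

test_that("complementarity partitions samples by which classifier is correct", {
  true <- c("x", "x", "x", "x", "x")
  pa <- c("x", "x", "x", "o", "o")  # correct on 1,2,3
  pb <- c("o", "x", "x", "x", "o")  # correct on 2,3,4
  cp <- complementarity(pa, pb, true, "RMD", "MS96")
  expect_equal(cp$n_both, 2)
  expect_equal(cp$n_only_a, 1)
  expect_equal(cp$n_only_b, 1)
  expect_equal(cp$n_neither, 1)
  same <- complementarity(pa, pa, true)
  expect_equal(same$n_only_a + same$n_only_b, 0)
  set.seed(20)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    t2 <- sample(c("x", "y"), n, replace = TRUE)
    cp2 <- complementarity(sample(c("x", "y"), n, TRUE),
                           sample(c("x", "y"), n, TRUE), t2)
    expect_equal(cp2$n_both + cp2$n_only_a + cp2$n_only_b + cp2$n_neither, n)
  }
})

test_that("recall gains are percentage-point differences between nested sets", {
  pr1 <- list(precision = c(1, 0.9), recall = c(0.2, 0.4))
  pr2 <- list(precision = c(1, 0.9), recall = c(0.3, 0.9))
  g <- recall_gain(list(A = pr1, B = pr2), level = 0.8)
  expect_true(is.na(g$gain_pp[1]))
  expect_equal(g$gain_pp[2], 50)  # 0.9 - 0.4 in pp
  same <- recall_gain(list(A = pr1, B = pr1))
  expect_equal(same$gain_pp[2], 0)
  expect_true(all(abs(g$gain_pp[-1]) <= 100))
})

test_that("a perfect marker feature tops all four importance rankings", {
  set.seed(21)
  n <- 60
  labels <- rep(c("pos", "rest"), each = n / 2)
  x <- cbind(marker = as.numeric(labels == "pos") + rnorm(n, sd = 0.03),
             matrix(rnorm(n * 11), ncol = 11,
                    dimnames = list(NULL, paste0("noise", 1:11))))
  fi <- feature_importance(x, labels, positive = "pos", top_n = 5, seed = 2)
  for (m in names(fi$rankings)) {
    expect_equal(fi$rankings[[m]][1], "marker")
  }
  expect_true("marker" %in% fi$consensus)
  # consensus is always a subset of the union of the top lists
  top_union <- unique(unlist(lapply(fi$rankings, head, 5)))
  expect_true(all(fi$consensus %in% top_union))
  expect_error(feature_importance(x, labels, positive = "absent"), "absent")
})
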