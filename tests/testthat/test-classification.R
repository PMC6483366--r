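test_that("class weights follow w_c = n / (K * n_c)", {
  labs <- c(rep("A", 10), rep("B", 30), rep("C", 40), rep("D", 20))
  w <- class_weights(labs)
  expect_equal(unname(w["A"]), 100 / (4 * 10))
  expect_equal(unname(class_weights(rep(c("A", "B"), 25))), c(1, 1))
  # algebraic identity over random label multisets
  set.seed(11)
  for (rep in 1:10) {
    labs <- sample(LETTERS[1:sample(2:6, 1)], 80, replace = TRUE)
    w <- class_weights(labs)
    tab <- table(labs)
    expect_equal(sum(w[names(tab)] * tab), 80)
  }
  expect_error(class_weights(character(0)), "empty")
})

test_that("a separable toy is fit perfectly and deterministically", {
  toy <- separable_toy()
  cfg <- small_config(seed = 3)
  ms <- train_ovr(toy$x, toy$labels, cfg)
  expect_named(ms$models, c("alpha", "beta"))
  sc <- decision_scores(ms, toy$x)
  expect_equal(dim(sc), c(40, 2))
  expect_equal(assign_class(sc), toy$labels)
  # class-k training samples outscore the other class on their own model
  expect_true(all(sc[toy$labels == "alpha", "alpha"] >
                    sc[toy$labels == "alpha", "beta"]))
  ms2 <- train_ovr(toy$x, toy$labels, cfg)
  expect_equal(ms$models$alpha$C, ms2$models$alpha$C)
  expect_equal(ms$models$alpha$gamma, ms2$models$alpha$gamma)
  expect_identical(decision_scores(ms2, toy$x), sc)
})

test_that("the random forest path trains 500 trees and scores in [0,1]", {
  toy <- separable_toy(n_per_class = 15)
  cfg <- small_config(algorithm = "random-forest", seed = 4)
  ms <- train_ovr(toy$x, toy$labels, cfg)
  expect_equal(ms$models$alpha$fit$ntree, 500)
  sc <- decision_scores(ms, toy$x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(assign_class(sc), toy$labels)
})

test_that("training rejects degenerate inputs", {
  toy <- separable_toy()
  expect_error(train_ovr(toy$x, rep("A", 40), small_config()), "at least 2")
  bad <- toy$x; bad[1, 1] <- NA
  expect_error(train_ovr(bad, toy$labels, small_config()), "missing values")
  expect_error(classifier_config(C_grid = numeric(0)), "non-empty")
  expect_error(classifier_config(cv_folds = 1), "cv_folds")
})

test_that("assign_class is argmax with alphabetical tie-break", {
  sc <- matrix(c(0.9, 0.1), nrow = 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(assign_class(sc), "A")
  tie <- matrix(c(0.5, 0.5), nrow = 1, dimnames = list(NULL, c("zeta", "alpha")))
  expect_equal(assign_class(tie), "alpha")
  set.seed(12)
  m <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  oracle <- apply(m, 1, function(r) colnames(m)[which.max(r)])
  expect_equal(assign_class(m), oracle)
})

test_that("cross-validation folds are stratified, exhaustive and non-overlapping", {
  toy <- separable_toy(n_per_class = 12)
  cfg <- small_config(folds = 3, repeats = 2, seed = 5)
  cv <- crossvalidate(toy$x, toy$labels, cfg)
  for (r in 1:2) {
    sub <- cv[cv$run == r, ]
    # every sample held out exactly once per run; union is the full set
    expect_equal(sort(sub$sample), sort(rownames(toy$x)))
    # per-class fold sizes differ by at most 1
    tab <- table(sub$fold, sub$true)
    expect_lte(max(apply(tab, 2, function(cc) diff(range(cc)))), 1)
  }
  expect_error(crossvalidate(toy$x[1:14, ], toy$labels[1:14],
                             small_config(folds = 5)), "fewer samples")
  # determinism of the full pipeline
  cv2 <- crossvalidate(toy$x, toy$labels, cfg)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
})

test_that("cv metrics summarize per run and class", {
  toy <- separable_toy(n_per_class = 12)
  cv <- crossvalidate(toy$x, toy$labels, small_config(folds = 3, repeats = 2))
  m <- cv_class_metrics(cv)
  expect_equal(nrow(m), 4)  # 2 runs x 2 classes
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  s <- cv_summary(cv)
  expect_setequal(s$class, c("alpha", "beta"))
  expect_true(all(c("auc_mean", "auc_median", "auc_sd", "auc_iqr",
                    "auprc_mean") %in% names(s)))
  expect_equal(s$auc_mean, c(1, 1))  # separable by construction
})

test_that("external splits are disjoint, exhaustive and validated", {
  toy <- separable_toy(n_per_class = 10)
  tags <- rep(c("src1", "src2"), 10)
  sp <- split_train_external(toy$x, toy$labels, tags, "src2")
  expect_length(intersect(sp$train$samples, sp$test$samples), 0)
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x), 20)
  expect_error(split_train_external(toy$x, toy$labels, tags, character(0)),
               "non-empty")
  expect_error(split_train_external(toy$x, toy$labels, tags, "nope"),
               "no sample")
  # class roster mismatch is reported when a class exists only on one side
  tags2 <- rep("src1", 20)
  tags2[toy$labels == "beta"] <- "src2"
  expect_message(split_train_external(toy$x, toy$labels, tags2, "src2"),
                 "mismatch")
})

test_that("label permutation preserves the multiset and is seeded", {
  labs <- rep(c("A", "B", "C"), times = c(5, 10, 15))
  p1 <- permute_labels(labs, seed = 9)
  expect_equal(sort(p1), sort(labs))
  expect_identical(p1, permute_labels(labs, seed = 9))
  expect_false(identical(p1, permute_labels(labs, seed = 10)))
})

test_that("in-fold elastic net selects informative features from the training fold only", {
  set.seed(13)
  n <- 60
  indicator <- rep(c(1, 0), each = n / 2)
  x <- cbind(marker = indicator + rnorm(n, sd = 0.05),
             allzero = rep(0, n),
             matrix(rnorm(n * 8), ncol = 8,
                    dimnames = list(NULL, paste0("noise", 1:8))))
  y <- rep(c("pos", "neg"), each = n / 2)
  keep <- select_features_in_fold(x, y, seed = 2)
  expect_true("marker" %in% keep)
  expect_false("allzero" %in% keep)
  # selection is a pure function of the training fold
  expect_identical(keep, select_features_in_fold(x, y, seed = 2))
  # the cross-validation harness records per-fold selections computed on
  # training folds; altering rows outside a fold's training set must not
  # change that fold's selection
  cfg <- small_config(folds = 2, repeats = 1, seed = 3)
  cfg$feature_selection <- "elastic-net"
  cv <- crossvalidate(x, y, cfg)
  sel <- attr(cv, "selected_features")
  expect_length(sel, 2)
  fold_of <- setNames(cv$fold, cv$sample)
  test_rows_f1 <- as.integer(names(fold_of)[fold_of == 1])
  x2 <- x
  x2[test_rows_f1, "noise1"] <- x2[test_rows_f1, "noise1"] + 100
  cv2 <- crossvalidate(x2, y, cfg)
  expect_identical(sel$run1_fold1, attr(cv2, "selected_features")$run1_fold1)
})
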