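#' ROC curve and area under it
#'
#' AUC is computed from the rank statistic (equivalent to the Mann-Whitney
#' U with ties counted one half); the curve is the staircase of (FPR, TPR)
#' points at every distinct score threshold.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels logical (or coercible) positive-class indicator.
#' @return list with `fpr`, `tpr` (curve, including the (0,0) and (1,1)
#'   anchors) and `auc`. `auc` is `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    warning("only one class present; AUC undefined")
    return(list(fpr = c(0, 1), tpr = c(0, 1), auc = NA_real_))
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; so <- scores[o]
  last <- c(diff(so) != 0, TRUE)  # last index of each distinct score
  tp <- cumsum(ys)[last]; fp <- cumsum(!ys)[last]
  list(fpr = c(0, fp / n0), tpr = c(0, tp / n1), auc = auc)
}

#' Precision-recall curve and area under it
#'
#' The curve consists of one (recall, precision) point per distinct score
#' threshold; the area uses step-wise interpolation (sum of recall
#' increments times the precision at that threshold), the conservative
#' convention — no linear interpolation between PR points.
#'
#' @param scores numeric decision scores.
#' @param labels logical positive-class indicator.
#' @return list with `recall`, `precision`, `thresholds` and `auprc`.
#' @export
pr_auprc <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(y))
  n1 <- sum(y)
  if (n1 == 0 || all(y)) {
    warning("only one class present; AUPRC undefined")
    return(list(recall = numeric(0), precision = numeric(0),
                thresholds = numeric(0), auprc = NA_real_))
  }
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; so <- scores[o]
  last <- c(diff(so) != 0, TRUE)
  tp <- cumsum(ys)[last]; fp <- cumsum(!ys)[last]
  rec <- tp / n1
  prec <- tp / (tp + fp)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(recall = rec, precision = prec, thresholds = so[last], auprc = auprc)
}

#' Precision, recall and F-score of one class
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F = their harmonic mean.
#' When the class is never predicted, precision is undefined and reported
#' as 0 with the `undefined_precision` attribute set.
#'
#' @param predicted,true label vectors.
#' @param class the class evaluated.
#' @return named numeric vector (precision, recall, f); possibly with
#'   attribute `undefined_precision = TRUE`.
#' @export
prf <- function(predicted, true, class) {
  predicted <- as.character(predicted); true <- as.character(true)
  tp <- sum(predicted == class & true == class)
  fp <- sum(predicted == class & true != class)
  fn <- sum(predicted != class & true == class)
  flag <- FALSE
  if (tp + fp == 0) { p <- 0; flag <- TRUE } else p <- tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  out <- c(precision = p, recall = r, f = f)
  if (flag) attr(out, "undefined_precision") <- TRUE
  out
}

#' Recall at a fixed precision level
#'
#' Maximum recall over score thresholds whose precision is at least the
#' level (0.8 corresponds to a 20% false discovery rate); 0 when no
#' threshold reaches the level.
#'
#' @param pr a precision-recall curve from [pr_auprc()].
#' @param level precision level (default 0.8).
#' @return recall in [0, 1].
#' @export
recall_at_precision <- function(pr, level = 0.8) {
  ok <- pr$precision >= level
  if (!any(ok)) return(0)
  max(pr$recall[ok])
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes, columns predicted classes; each row sums to 1
#' (the fraction of that class's samples assigned to each prediction).
#' Raw counts are kept in the `counts` attribute.
#'
#' @param predicted,true label vectors.
#' @return numeric matrix with `counts` attribute.
#' @export
confusion_matrix <- function(predicted, true) {
  lv <- sort(union(unique(as.character(true)), unique(as.character(predicted))))
  counts <- table(factor(as.character(true), levels = lv),
                  factor(as.character(predicted), levels = lv))
  counts <- unclass(as.matrix(counts))
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs == 0, 1, rs)
  attr(norm, "counts") <- counts
  norm
}

#' Complementarity partition of two classifiers
#'
#' Splits the samples by which of two feature sets classifies them
#' correctly (argmax assignment equals truth): both, only A, only B,
#' neither. The four counts sum to the number of samples.
#'
#' @param predicted_a,predicted_b predicted labels of the two classifiers.
#' @param true true labels.
#' @param set_a,set_b display names of the two feature sets.
#' @return a `complementarity` list with `n_both`, `n_only_a`, `n_only_b`,
#'   `n_neither`, `n`, `set_a`, `set_b`.
#' @export
complementarity <- function(predicted_a, predicted_b, true,
                            set_a = "A", set_b = "B") {
  ca <- as.character(predicted_a) == as.character(true)
  cb <- as.character(predicted_b) == as.character(true)
  structure(list(n_both = sum(ca & cb), n_only_a = sum(ca & !cb),
                 n_only_b = sum(!ca & cb), n_neither = sum(!ca & !cb),
                 n = length(true), set_a = set_a, set_b = set_b),
            class = "complementarity")
}

#' @export
print.complementarity <- function(x, ...) {
  cat(sprintf("complementarity (%s vs %s), n = %d\n", x$set_a, x$set_b, x$n))
  cat(sprintf("  both correct: %d\n  only %s: %d\n  only %s: %d\n  neither: %d\n",
              x$n_both, x$set_a, x$n_only_a, x$set_b, x$n_only_b, x$n_neither))
  invisible(x)
}

#' Percentage-point recall gains between nested feature sets
#'
#' Given precision-recall curves of increasingly rich feature sets (e.g.
#' drivers only, drivers + spectra, drivers + spectra + RMD), reports the
#' recall at the precision level for each and the percentage-point gain of
#' each set over the previous one — the extra fraction of patients
#' correctly classified at the same false discovery rate.
#'
#' @param pr_list named list of PR curves (from [pr_auprc()]), in order of
#'   increasing feature-set size.
#' @param level precision level (default 0.8).
#' @return data.frame with `feature_set`, `recall`, `gain_pp` (NA for the
#'   first set).
#' @export
recall_gain <- function(pr_list, level = 0.8) {
  rec <- vapply(pr_list, recall_at_precision, numeric(1), level = level)
  data.frame(feature_set = names(pr_list), recall = as.numeric(rec),
             gain_pp = c(NA, diff(rec) * 100), stringsAsFactors = FALSE)
}

#' Consensus feature importance over four selection methods
#'
#' Ranks every feature for a one-vs-rest contrast by (i) elastic-net
#' coefficient magnitude, (ii) random-forest Gini importance, (iii)
#' Relief-F weight (k nearest hits/misses on z-scored features) and (iv)
#' information gain (features discretized into equal-frequency bins). The
#' consensus set contains the features ranked in the top `top_n` by two or
#' more methods.
#'
#' @param x samples x features matrix.
#' @param labels class labels.
#' @param positive the class contrasted against the rest.
#' @param methods subset of the four method names.
#' @param top_n top-list size (default 25).
#' @param relief_k neighbors for Relief-F (default 10).
#' @param ig_bins equal-frequency bins for information gain (default 10).
#' @param seed integer seed (elastic-net lambda CV, forest).
#' @return list with `rankings` (named list of feature names, best first)
#'   and `consensus` (features in the top `top_n` of >= 2 methods, ordered
#'   by mean rank).
#' @export
feature_importance <- function(x, labels, positive,
                               methods = c("elastic-net", "rf-importance",
                                           "relief-f", "information-gain"),
                               top_n = 25, relief_k = 10, ig_bins = 10,
                               seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  y <- factor(ifelse(as.character(labels) == positive, "pos", "rest"),
              levels = c("pos", "rest"))
  if (length(unique(y)) < 2) stop("positive class absent or universal")
  p <- ncol(x)
  rank_desc <- function(w) colnames(x)[order(-w, seq_len(p))]
  rankings <- list()
  for (m in methods) {
    w <- switch(m,
      "elastic-net" = {
        set.seed(derive_seed(seed, 11))
        fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0.5,
                                 nfolds = 5)
        cf <- as.numeric(glmnet::coef.glmnet(fit$glmnet.fit,
                                             s = fit$lambda.min))[-1]
        abs(cf)
      },
      "rf-importance" = {
        set.seed(derive_seed(seed, 12))
        fit <- randomForest::randomForest(x, y, ntree = 500)
        as.numeric(fit$importance[, "MeanDecreaseGini"])
      },
      "relief-f" = relieff_weights(x, y, k = relief_k),
      "information-gain" = info_gain_weights(x, y, bins = ig_bins))
    rankings[[m]] <- rank_desc(w)
  }
  tops <- lapply(rankings, head, top_n)
  cnt <- table(unlist(tops))
  consensus <- names(cnt)[cnt >= 2]
  if (length(consensus)) {
    mean_rank <- vapply(consensus, function(f) {
      mean(vapply(rankings, function(r) match(f, r), numeric(1)))
    }, numeric(1))
    consensus <- consensus[order(mean_rank)]
  }
  list(rankings = rankings, consensus = consensus)
}

# internal: Relief-F weights with k nearest hits/misses per instance
relieff_weights <- function(x, y, k = 10) {
  n <- nrow(x); p <- ncol(x)
  xz <- apply_scaler(x, fit_scaler(x))
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  d <- as.matrix(dist(xz))
  w <- numeric(p)
  ych <- as.character(y)
  for (i in seq_len(n)) {
    same <- which(ych == ych[i]); same <- same[same != i]
    diff_ <- which(ych != ych[i])
    kh <- min(k, length(same)); km <- min(k, length(diff_))
    if (kh == 0 || km == 0) next
    hits <- same[order(d[i, same])][seq_len(kh)]
    misses <- diff_[order(d[i, diff_])][seq_len(km)]
    dh <- abs(sweep(x[hits, , drop = FALSE], 2, x[i, ])) # hit distances per feature
    dm <- abs(sweep(x[misses, , drop = FALSE], 2, x[i, ]))
    w <- w + colMeans(sweep(dm, 2, rng, "/")) - colMeans(sweep(dh, 2, rng, "/"))
  }
  w / n
}

# internal: information gain with equal-frequency discretization
info_gain_weights <- function(x, y, bins = 10) {
  entropy <- function(f) {
    pr <- table(f) / length(f)
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }
  hy <- entropy(y)
  apply(x, 2, function(col) {
    br <- unique(quantile(col, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(0)
    b <- cut(col, breaks = br, include.lowest = TRUE)
    cond <- 0
    for (lv in levels(b)) {
      idx <- b == lv
      if (any(idx)) cond <- cond + mean(idx) * entropy(y[idx])
    }
    hy - cond
  })
}
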