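#' Classifier configuration
#'
#' Houses the learning algorithm and its metaparameters. For the RBF-kernel
#' SVM, `C_grid` and `gamma_grid` define the grid searched by inner
#' cross-validation to maximize class-weighted accuracy (defaults follow
#' the LibSVM practice of exponentially spaced grids); the random forest
#' trains a fixed 500-tree ensemble with no tuning.
#'
#' @param algorithm "svm-rbf" or "random-forest".
#' @param C_grid,gamma_grid positive numeric grids for the SVM.
#' @param n_trees forest size.
#' @param class_weighting "balanced-formula" (weight n / (K * n_c), applied
#'   to the binary one-vs-rest labels) or "none".
#' @param cv_folds,cv_repeats outer cross-validation shape.
#' @param inner_folds folds of the inner grid-search CV.
#' @param feature_selection "none" or "elastic-net" (in-fold selection of
#'   features with non-zero elastic-net coefficients).
#' @param seed master seed for every stochastic step.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(algorithm = c("svm-rbf", "random-forest"),
                              C_grid = 2^seq(-5, 15, by = 2),
                              gamma_grid = 2^seq(-15, 3, by = 2),
                              n_trees = 500,
                              class_weighting = c("balanced-formula", "none"),
                              cv_folds = 5, cv_repeats = 10, inner_folds = 3,
                              feature_selection = c("none", "elastic-net"),
                              seed = 1) {
  algorithm <- match.arg(algorithm)
  class_weighting <- match.arg(class_weighting)
  feature_selection <- match.arg(feature_selection)
  if (algorithm == "svm-rbf" && (!length(C_grid) || !length(gamma_grid))) {
    stop("svm-rbf requires non-empty C and gamma grids")
  }
  if (any(C_grid <= 0) || any(gamma_grid <= 0)) stop("grids must be positive")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(algorithm = algorithm, C_grid = C_grid,
                 gamma_grid = gamma_grid, n_trees = n_trees,
                 class_weighting = class_weighting, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, inner_folds = inner_folds,
                 feature_selection = feature_selection, seed = seed),
            class = "classifier_config")
}

#' Class weights for imbalanced multiclass data
#'
#' The weight of class c is the total number of samples divided by the
#' number of classes times the number of samples of that class:
#' w_c = n / (K * n_c). Balanced classes get weight 1, and
#' sum_c w_c * n_c = n for any label multiset.
#'
#' @param labels factor or character vector of class labels.
#' @return named numeric vector of weights.
#' @export
class_weights <- function(labels) {
  tab <- table(as.character(labels))
  if (any(tab == 0) || length(tab) == 0) stop("empty class in labels")
  n <- sum(tab)
  k <- length(tab)
  setNames(as.numeric(n / (k * tab)), names(tab))
}

# internal: z-score scaler fit on training rows; constant columns get sd 1
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(x, s) scale(x, center = s$center, scale = s$scale)

# internal: stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# internal: class-weighted accuracy
weighted_accuracy <- function(pred, truth, w) {
  wt <- w[as.character(truth)]
  sum(wt * (as.character(pred) == as.character(truth))) / sum(wt)
}

# internal: fit one binary one-vs-rest model on already scaled data
fit_binary <- function(xs, ybin, config, seed) {
  w <- if (config$class_weighting == "balanced-formula") class_weights(ybin)
       else setNames(c(1, 1), c("pos", "rest"))
  if (config$algorithm == "random-forest") {
    set.seed(seed)
    fit <- randomForest::randomForest(xs, ybin, ntree = config$n_trees)
    return(list(kind = "rf", fit = fit))
  }
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid)
  if (nrow(grid) > 1) {
    fold <- stratified_folds(as.character(ybin), config$inner_folds, seed)
    score <- vapply(seq_len(nrow(grid)), function(i) {
      accs <- vapply(seq_len(config$inner_folds), function(f) {
        tr <- fold != f
        if (length(unique(ybin[tr])) < 2 || !any(!tr)) return(NA_real_)
        fit <- e1071::svm(xs[tr, , drop = FALSE], ybin[tr], kernel = "radial",
                          cost = grid$C[i], gamma = grid$gamma[i],
                          class.weights = w, scale = FALSE)
        pred <- predict(fit, xs[!tr, , drop = FALSE])
        weighted_accuracy(pred, ybin[!tr], w)
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(score)  # ties: first grid point
  } else best <- 1L
  fit <- e1071::svm(xs, ybin, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], class.weights = w, scale = FALSE)
  list(kind = "svm", fit = fit, C = grid$C[best], gamma = grid$gamma[best])
}

#' Train one-vs-rest classifiers
#'
#' Fits one binary model per class against the pooled remaining classes.
#' Features are standardized (per-feature z-score fit on the training
#' data); the SVM grid search runs an inner stratified cross-validation on
#' the training data only. Deterministic given (data, config, seed).
#'
#' @param x samples x features numeric matrix (no missing values).
#' @param labels class labels, one per row of `x`.
#' @param config a `classifier_config`.
#' @return a `trained_model_set`: per-class models, the shared scaler,
#'   class roster and config.
#' @export
train_ovr <- function(x, labels, config = classifier_config()) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (anyNA(x)) stop("feature matrix contains missing values")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  models <- lapply(seq_along(classes), function(k) {
    ybin <- factor(ifelse(labels == classes[k], "pos", "rest"),
                   levels = c("pos", "rest"))
    fit_binary(xs, ybin, config, seed = derive_seed(config$seed, k))
  })
  names(models) <- classes
  structure(list(models = models, scaler = scaler, classes = classes,
                 features = colnames(x), config = config),
            class = "trained_model_set")
}

#' Per-class decision scores
#'
#' One real score per (sample, class); higher means more confident that the
#' sample belongs to the class. SVM models return the signed distance to
#' the separating hyperplane (oriented toward the positive class); random
#' forests return the fraction of trees voting for the class.
#'
#' @param model_set a `trained_model_set`.
#' @param x samples x features matrix with the training feature columns.
#' @return numeric matrix, samples x classes.
#' @export
decision_scores <- function(model_set, x) {
  if (!is.null(model_set$features)) {
    x <- x[, model_set$features, drop = FALSE]
  }
  xs <- apply_scaler(x, model_set$scaler)
  out <- vapply(model_set$models, function(m) {
    if (m$kind == "svm") {
      dv <- attr(predict(m$fit, xs, decision.values = TRUE), "decision.values")
      v <- as.numeric(dv[, 1])
      # e1071 orients decision values toward the first factor level ("pos")
      if (!startsWith(colnames(dv)[1], "pos")) v <- -v
      v
    } else {
      as.numeric(predict(m$fit, xs, type = "prob")[, "pos"])
    }
  }, numeric(nrow(xs)))
  out <- matrix(out, nrow = nrow(xs),
                dimnames = list(rownames(x), model_set$classes))
  out
}

#' Assign each sample to the highest-scoring class
#'
#' Argmax over per-class scores; exact ties are broken by alphabetical
#' class order (the fixed column order of the score matrix).
#'
#' @param scores samples x classes score matrix with class column names.
#' @return character vector of predicted labels.
#' @export
assign_class <- function(scores) {
  cls <- colnames(scores)[order(colnames(scores))]
  s <- scores[, cls, drop = FALSE]
  cls[apply(s, 1, which.max)]
}

#' Repeated stratified cross-validation
#'
#' Runs `cv_repeats` independent rounds of stratified `cv_folds`-fold
#' cross-validation. In each fold a full one-vs-rest model set is trained
#' on the training portion (including scaling, grid search, and optional
#' in-fold elastic-net feature selection) and held-out decision scores are
#' recorded, so every sample is scored exactly once per run.
#'
#' @param x samples x features matrix.
#' @param labels class labels.
#' @param config a `classifier_config`.
#' @return a `cv_scores` data.frame: `run`, `fold`, `sample`, `true`,
#'   `pred`, and one `score.<class>` column per class. Attribute
#'   `selected_features` records per (run, fold) subsets when in-fold
#'   selection is on.
#' @export
crossvalidate <- function(x, labels, config = classifier_config()) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  tab <- table(labels)
  if (any(tab < config$cv_folds)) {
    stop("class(es) ", paste(names(tab)[tab < config$cv_folds], collapse = ", "),
         " have fewer samples than cv_folds; reduce cv_folds or merge classes")
  }
  classes <- sort(unique(labels))
  sample_ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rows <- list()
  selections <- list()
  for (run in seq_len(config$cv_repeats)) {
    fold <- stratified_folds(labels, config$cv_folds,
                             seed = derive_seed(config$seed, 1000 + run))
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      xtr <- x[tr, , drop = FALSE]
      xte <- x[!tr, , drop = FALSE]
      if (config$feature_selection == "elastic-net") {
        keep <- select_features_in_fold(xtr, labels[tr],
                                        seed = derive_seed(config$seed,
                                                           run * 100 + f))
        selections[[sprintf("run%d_fold%d", run, f)]] <- keep
        xtr <- xtr[, keep, drop = FALSE]
        xte <- xte[, keep, drop = FALSE]
      }
      fold_cfg <- config
      fold_cfg$seed <- derive_seed(config$seed, run * 10000 + f)
      ms <- train_ovr(xtr, labels[tr], fold_cfg)
      sc <- decision_scores(ms, xte)
      df <- data.frame(run = run, fold = f, sample = sample_ids[!tr],
                       true = labels[!tr], stringsAsFactors = FALSE)
      df$pred <- assign_class(sc)
      colnames(sc) <- paste0("score.", colnames(sc))
      rows[[length(rows) + 1]] <- cbind(df, as.data.frame(sc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cv_scores", "data.frame"),
            classes = classes, config = config,
            selected_features = if (length(selections)) selections else NULL)
}

#' Per-run per-class metrics from cross-validation scores
#'
#' For each run, held-out scores pooled across folds give one ROC AUC and
#' one PR AUPRC per class (one-vs-rest).
#'
#' @param cv a `cv_scores` data.frame from [crossvalidate()].
#' @return data.frame with `run`, `class`, `auc`, `auprc`.
#' @export
cv_class_metrics <- function(cv) {
  classes <- attr(cv, "classes")
  out <- list()
  for (run in unique(cv$run)) {
    sub <- cv[cv$run == run, , drop = FALSE]
    for (cl in classes) {
      s <- sub[[paste0("score.", cl)]]
      y <- sub$true == cl
      out[[length(out) + 1]] <- data.frame(
        run = run, class = cl,
        auc = roc_auc(s, y)$auc,
        auprc = pr_auprc(s, y)$auprc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summary statistics of cross-validation metrics
#'
#' @param cv a `cv_scores` data.frame.
#' @return data.frame per class with mean, median, sd and IQR of AUC and
#'   AUPRC across runs.
#' @export
cv_summary <- function(cv) {
  m <- cv_class_metrics(cv)
  do.call(rbind, lapply(split(m, m$class), function(d) {
    data.frame(class = d$class[1],
               auc_mean = mean(d$auc), auc_median = median(d$auc),
               auc_sd = sd(d$auc), auc_iqr = IQR(d$auc),
               auprc_mean = mean(d$auprc), auprc_median = median(d$auprc),
               auprc_sd = sd(d$auprc), auprc_iqr = IQR(d$auprc),
               stringsAsFactors = FALSE)
  }))
}

#' Split samples into training and external validation sets by dataset tag
#'
#' @param x samples x features matrix.
#' @param labels class labels aligned with rows.
#' @param dataset_tags per-sample dataset/source tags.
#' @param holdout_tags tags forming the external test set.
#' @return list with `train` and `test`, each holding `x`, `labels` and
#'   `samples`; classes absent from either side are reported via message.
#' @export
split_train_external <- function(x, labels, dataset_tags, holdout_tags) {
  if (!length(holdout_tags)) stop("holdout_tags must be non-empty")
  if (!any(dataset_tags %in% holdout_tags)) stop("no sample carries a holdout tag")
  te <- dataset_tags %in% holdout_tags
  if (all(te)) stop("holdout tags cover every sample; nothing left to train on")
  mismatch <- union(setdiff(labels[te], labels[!te]), setdiff(labels[!te], labels[te]))
  if (length(mismatch)) {
    message("class roster mismatch between train and holdout: ",
            paste(mismatch, collapse = ", "))
  }
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  list(train = list(x = x[!te, , drop = FALSE], labels = labels[!te],
                    samples = ids[!te]),
       test = list(x = x[te, , drop = FALSE], labels = labels[te],
                   samples = ids[te]))
}

#' Uniformly permute class labels
#'
#' Used for the label-randomization null: a classifier trained on permuted
#' labels should score at chance (AUC about 0.5). The label multiset is
#' preserved.
#'
#' @param labels class labels.
#' @param seed integer seed.
#' @return permuted labels (same type and length).
#' @export
permute_labels <- function(labels, seed) {
  set.seed(seed)
  labels[sample(length(labels))]
}

#' In-fold elastic-net feature selection
#'
#' Fits a multinomial elastic-net model on the training fold only and
#' returns the features with at least one non-zero coefficient at the
#' cross-validated lambda. Intended to be applied to both the training and
#' the test fold of the same split; because it never sees the test fold,
#' it cannot leak information.
#'
#' @param x_train training fold matrix.
#' @param labels_train training fold labels.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed integer seed for the internal lambda cross-validation.
#' @return character vector of selected feature names (falls back to all
#'   features, with a message, if the model selects none).
#' @export
select_features_in_fold <- function(x_train, labels_train, alpha = 0.5, seed = 1) {
  set.seed(seed)
  y <- factor(labels_train)
  fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
  fit <- glmnet::cv.glmnet(x_train, y, family = fam, alpha = alpha, nfolds = 3)
  cf <- glmnet::coef.glmnet(fit$glmnet.fit, s = fit$lambda.min)
  if (!is.list(cf)) cf <- list(cf)
  nz <- unique(unlist(lapply(cf, function(m) rownames(m)[as.numeric(m) != 0])))
  nz <- setdiff(nz, "(Intercept)")
  keep <- intersect(colnames(x_train), nz)
  if (!length(keep)) {
    message("elastic net selected no features; keeping all")
    keep <- colnames(x_train)
  }
  keep
}
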