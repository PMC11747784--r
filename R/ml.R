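as_feature_matrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  m
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic sample is `x_new = x_i + lambda * (x_j - x_i)` with `x_i`
#' a minority-class sample, `x_j` one of its `k` Euclidean-nearest
#' minority-class neighbors, and `lambda ~ Uniform(0, 1)` — a convex
#' combination of the parent pair. The minority class is oversampled up to
#' the majority count, so class counts are equal afterwards.
#'
#' @param features Numeric matrix or data frame, samples x features.
#' @param labels Class labels, one per row; exactly two classes.
#' @param k Neighbor count; default `min(5, minority size - 1)`. Values at
#'   or above the minority size are clamped with a warning.
#' @param lambda Optional fixed interpolation weight (mainly for testing);
#'   default draws fresh uniforms.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `smote_set`: `features` (matrix with originals
#'   first), `labels`, `synthetic_mask`, and `parents` (two-column matrix of
#'   parent row indices for synthetic rows).
#' @export
smote_augment <- function(features, labels, k = NULL, lambda = NULL,
                          seed = NULL) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  counts <- sort(table(labels))
  if (length(counts) != 2L) stop("need exactly two classes", call. = FALSE)
  minority <- names(counts)[1]
  n_min <- counts[[1]]
  n_new <- counts[[2]] - n_min
  if (n_new == 0L) {
    return(structure(list(features = x, labels = labels,
                          synthetic_mask = rep(FALSE, nrow(x)),
                          parents = matrix(0L, 0, 2)),
                     class = "smote_set"))
  }
  if (n_min < 2L) {
    stop("minority class has a single sample: no neighbor to interpolate",
         call. = FALSE)
  }
  k <- k %||% min(5L, n_min - 1L)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (k >= n_min) {
    warning("k = ", k, " >= minority size ", n_min, "; clamped to ",
            n_min - 1L, call. = FALSE)
    k <- n_min - 1L
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  min_idx <- which(labels == minority)
  syn <- matrix(0, n_new, ncol(x))
  parents <- matrix(0L, n_new, 2)
  if (n_new > 0L) {
    d <- as.matrix(stats::dist(x[min_idx, , drop = FALSE]))
    base <- sample(seq_along(min_idx), n_new, replace = TRUE)
    for (s in seq_len(n_new)) {
      i <- base[s]
      nn <- order(d[i, ])[-1][seq_len(k)]   # k nearest, self excluded
      j <- nn[sample.int(k, 1L)]
      lam <- lambda %||% stats::runif(1)
      syn[s, ] <- x[min_idx[i], ] + lam * (x[min_idx[j], ] - x[min_idx[i], ])
      parents[s, ] <- c(min_idx[i], min_idx[j])
    }
  }
  out_x <- rbind(x, syn)
  rownames(out_x) <- NULL
  structure(list(features = out_x,
                 labels = c(labels, rep(minority, n_new)),
                 synthetic_mask = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)),
                 parents = parents),
            class = "smote_set")
}

#' k-nearest-neighbor prediction
#'
#' Majority label among the `k` Euclidean-nearest training rows. Class ties
#' break toward the tied class with the smallest summed distance, then
#' lexicographically.
#'
#' @param train_x,train_y Training features (samples x features) and labels.
#' @param test_x Feature matrix to predict.
#' @param k Neighbor count (default 5; must satisfy `1 <= k <= nrow(train_x)`).
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 5L) {
  train_x <- as_feature_matrix(train_x)
  test_x <- as_feature_matrix(test_x)
  train_y <- as.character(train_y)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)
  if (k > nrow(train_x)) stop("`k` exceeds the training size", call. = FALSE)
  apply(test_x, 1, function(p) {
    d <- sqrt(colSums((t(train_x) - p)^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    sums <- vapply(top, function(cl) sum(d[nn][train_y[nn] == cl]), numeric(1))
    sort(top[sums == min(sums)])[1]
  })
}

entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-based decision tree
#'
#' A deterministic axis-aligned binary tree: at each node every midpoint
#' between consecutive distinct feature values is a candidate threshold, and
#' the split maximizing the information gain (parent Shannon entropy minus
#' the size-weighted child entropies, in bits) is chosen; ties break toward
#' the lowest feature index, then the lowest threshold. Leaves predict the
#' majority label (ties lexicographic). Growth stops at `max_depth`, on pure
#' nodes, below `min_split` samples, or when no split has positive gain. No
#' pruning is applied.
#'
#' @param x Numeric matrix or data frame, samples x features.
#' @param y Class labels.
#' @param max_depth Depth cap (default 5).
#' @param min_split Minimum node size to attempt a split.
#' @return An object of class `cvd_dtree`.
#' @export
dt_fit <- function(x, y, max_depth = 5L, min_split = 2L) {
  x <- as_feature_matrix(x)
  y <- as.character(y)
  if (nrow(x) < 1L) stop("empty training set", call. = FALSE)

  majority <- function(lab) {
    tab <- table(lab)
    sort(names(tab)[tab == max(tab)])[1]
  }
  grow <- function(idx, depth) {
    lab <- y[idx]
    leaf <- list(leaf = TRUE, label = majority(lab), n = length(idx))
    if (depth >= max_depth || length(idx) < min_split ||
        length(unique(lab)) == 1L) {
      return(leaf)
    }
    parent_e <- entropy_bits(lab)
    best <- list(gain = 0)
    for (j in seq_len(ncol(x))) {
      v <- x[idx, j]
      u <- sort(unique(v))
      if (length(u) < 2L) next
      for (thr in (u[-1] + u[-length(u)]) / 2) {
        left <- v <= thr
        e <- (sum(left) * entropy_bits(lab[left]) +
              sum(!left) * entropy_bits(lab[!left])) / length(idx)
        gain <- parent_e - e
        if (gain > best$gain + 1e-12) {
          best <- list(gain = gain, feature = j, threshold = thr)
        }
      }
    }
    if (best$gain <= 0) return(leaf)
    left <- x[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         gain = best$gain, n = length(idx),
         left = grow(idx[left], depth + 1L),
         right = grow(idx[!left], depth + 1L))
  }
  structure(list(root = grow(seq_len(nrow(x)), 0L),
                 features = colnames(x)),
            class = "cvd_dtree")
}

#' @rdname dt_fit
#' @param model A fitted `cvd_dtree`.
#' @export
dt_predict <- function(model, x) {
  x <- as_feature_matrix(x)
  walk <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$threshold) node$left else node$right
    }
    node$label
  }
  apply(x, 1, function(r) walk(model$root, r))
}

#' Polynomial-kernel support vector machine
#'
#' Trains a soft-margin SVM with the inhomogeneous polynomial kernel
#' `K(x, x') = (1 + x . x')^d` (degree `d`, penalty `C`). The quadratic
#' program is solved by [e1071::svm()], parameterized so the kernel is
#' exactly this form (`gamma = 1`, `coef0 = 1`, no internal rescaling);
#' features are expected to be standardized by the caller, as the
#' cross-validation driver does.
#'
#' @param x Samples x features matrix (standardized).
#' @param y Class labels; exactly two classes must be present.
#' @param degree Polynomial degree `d` (default 3).
#' @param cost Penalty `C` (default 1).
#' @return An object of class `cvd_svm` wrapping the fitted model.
#' @export
svm_fit <- function(x, y, degree = 3, cost = 1) {
  x <- as_feature_matrix(x)
  y <- as.character(y)
  if (length(unique(y)) != 2L) {
    stop("SVM training needs exactly two classes", call. = FALSE)
  }
  fit <- e1071::svm(x, factor(y), kernel = "polynomial", degree = degree,
                    gamma = 1, coef0 = 1, cost = cost, scale = FALSE)
  structure(list(fit = fit, degree = degree, cost = cost),
            class = "cvd_svm")
}

#' @rdname svm_fit
#' @param model A fitted `cvd_svm`.
#' @export
svm_predict <- function(model, x) {
  as.character(stats::predict(model$fit, as_feature_matrix(x)))
}

#' Confusion matrix with CVD as the positive class
#'
#' @param truth,pred Label vectors.
#' @param positive The positive-class label (default `"cvd"`).
#' @return An object of class `cvd_confusion` with counts `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_matrix <- function(truth, pred, positive = "cvd") {
  truth <- as.character(truth); pred <- as.character(pred)
  structure(list(
    tp = sum(truth == positive & pred == positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive),
    fn = sum(truth == positive & pred != positive),
    positive = positive
  ), class = "cvd_confusion")
}

#' @export
print.cvd_confusion <- function(x, ...) {
  cat("<cvd_confusion> positive =", x$positive, "\n")
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Precision, recall, specificity and F1 from a confusion matrix
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` (sensitivity),
#' `specificity = TN/(TN+FP)`, `f1 = 2PR/(P+R)`. A zero denominator yields 0
#' by convention, with the metric named in the `undefined` field.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble: `accuracy` (%), `precision`, `recall`,
#'   `specificity`, `f1`, `undefined` (list column of metric names that had
#'   zero denominators).
#' @export
confusion_metrics <- function(cm) {
  undef <- character()
  frac <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      0
    } else {
      num / den
    }
  }
  precision <- frac(cm$tp, cm$tp + cm$fp, "precision")
  recall <- frac(cm$tp, cm$tp + cm$fn, "recall")
  specificity <- frac(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- frac(2 * precision * recall, precision + recall, "f1")
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  tibble::tibble(accuracy = frac(cm$tp + cm$tn, total, "accuracy") * 100,
                 precision = precision, recall = recall,
                 specificity = specificity, f1 = f1,
                 undefined = list(undef))
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(x, s) {
  sweep(sweep(x, 2, s$mu), 2, s$sd, `/`)
}

stratified_folds <- function(labels, k_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(k_folds), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits the subjects into `k_folds` stratified folds; per fold, features
#' are z-scored with training-fold statistics (for the distance- and
#' margin-based KNN and SVM), SMOTE is optionally applied, the classifier is
#' trained and the held-out fold scored. Accuracy is the percentage of
#' correctly assigned responses; a confusion matrix is pooled over folds.
#'
#' `smote_mode` controls where balancing happens: `"fold_internal"`
#' (default) applies SMOTE to the training portion of each fold only, which
#' avoids leaking synthetic points derived from test subjects;
#' `"global"` balances the whole set first and then cross-validates the
#' augmented samples (the balance-then-CV order some studies use);
#' `"none"` skips SMOTE.
#'
#' @param features Numeric matrix/data frame or a feature tibble from
#'   [extract_features()] (its `subject_id`/`label`/`target_frequency`
#'   columns are dropped from the predictors).
#' @param labels Class labels; taken from a feature tibble's `label` column
#'   when omitted.
#' @param classifier `"dt"`, `"knn"`, or `"svm"`.
#' @param feature_set `"psd+cca"` (default), `"psd"`, or `"cca"`; selects
#'   columns by their canonical name prefix when present.
#' @param k_folds Number of folds (default 5).
#' @param smote_mode See Details.
#' @param smote_k SMOTE neighbor count; default `min(5, minority - 1)`.
#' @param knn_k,dt_max_depth,svm_degree,svm_cost Classifier hyperparameters.
#' @param seed Integer seed for the fold split (and SMOTE draws).
#' @return An object of class `cvd_cv_report` with per-fold accuracies,
#'   their mean and sd (%), the pooled confusion matrix and derived metrics.
#'   Use [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
kfold_cv <- function(features, labels = NULL,
                     classifier = c("dt", "knn", "svm"),
                     feature_set = c("psd+cca", "psd", "cca"),
                     k_folds = 5L,
                     smote_mode = c("fold_internal", "global", "none"),
                     smote_k = NULL, knn_k = 5L, dt_max_depth = 5L,
                     svm_degree = 3, svm_cost = 1, seed = 1L) {
  classifier <- match.arg(classifier)
  feature_set <- match.arg(feature_set)
  smote_mode <- match.arg(smote_mode)
  if (is.data.frame(features)) {
    labels <- labels %||% features$label
    features <- features[, setdiff(names(features),
                                   c("subject_id", "label",
                                     "target_frequency")), drop = FALSE]
  }
  x <- as_feature_matrix(features)
  if (feature_set != "psd+cca" && !is.null(colnames(x))) {
    keep <- startsWith(colnames(x), paste0(feature_set, "_"))
    if (any(keep)) x <- x[, keep, drop = FALSE]
  }
  y <- as.character(labels)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2L) {
    stop("cross-validation needs both classes present", call. = FALSE)
  }
  if (nrow(x) < k_folds) stop("fewer samples than folds", call. = FALSE)

  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  if (smote_mode == "global") {
    bal <- smote_augment(x, y, k = smote_k)
    x <- bal$features
    y <- bal$labels
  }
  fold <- stratified_folds(y, k_folds)
  standardized <- classifier %in% c("knn", "svm")

  acc <- numeric(k_folds)
  pooled <- list(truth = character(), pred = character())
  for (f in seq_len(k_folds)) {
    tr_x <- x[fold != f, , drop = FALSE]; tr_y <- y[fold != f]
    te_x <- x[fold == f, , drop = FALSE]; te_y <- y[fold == f]
    if (length(unique(tr_y)) < 2L) {
      stop("fold ", f, " has a single class in training; use fewer folds",
           call. = FALSE)
    }
    if (standardized) {
      s <- standardize_fit(tr_x)
      tr_x <- standardize_apply(tr_x, s)
      te_x <- standardize_apply(te_x, s)
    }
    if (smote_mode == "fold_internal") {
      bal <- smote_augment(tr_x, tr_y, k = smote_k)
      tr_x <- bal$features
      tr_y <- bal$labels
    }
    pred <- switch(classifier,
      dt = dt_predict(dt_fit(tr_x, tr_y, max_depth = dt_max_depth), te_x),
      knn = knn_predict(tr_x, tr_y, te_x, k = min(knn_k, nrow(tr_x))),
      svm = svm_predict(svm_fit(tr_x, tr_y, degree = svm_degree,
                                cost = svm_cost), te_x))
    acc[f] <- mean(pred == te_y) * 100
    pooled$truth <- c(pooled$truth, te_y)
    pooled$pred <- c(pooled$pred, pred)
  }
  cm <- confusion_matrix(pooled$truth, pooled$pred)
  metrics <- confusion_metrics(cm)
  structure(list(classifier = classifier, feature_set = feature_set,
                 k_folds = k_folds, smote_mode = smote_mode,
                 fold_accuracies = acc,
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 confusion = cm,
                 precision = metrics$precision, recall = metrics$recall,
                 specificity = metrics$specificity, f1 = metrics$f1,
                 n = nrow(x), seed = seed),
            class = "cvd_cv_report")
}

#' @export
print.cvd_cv_report <- function(x, ...) {
  cat(sprintf("<cvd_cv_report> %s / %s: mean accuracy %.2f%% (sd %.2f) over %d folds\n",
              toupper(x$classifier), x$feature_set, x$mean_accuracy,
              x$sd_accuracy, x$k_folds))
  cat(sprintf("  precision %.3f  recall %.3f  specificity %.3f  F1 %.3f  (SMOTE: %s)\n",
              x$precision, x$recall, x$specificity, x$f1, x$smote_mode))
  invisible(x)
}

#' Cross-validate every classifier and feature set
#'
#' Convenience grid over classifiers and feature sets, the layout in which
#' SSVEP classification results are usually reported.
#'
#' @inheritParams kfold_cv
#' @param classifiers,feature_sets Grid to evaluate.
#' @param ... Passed to [kfold_cv()].
#' @return A tibble with one row per (classifier, feature_set):
#'   `mean_accuracy`, `sd_accuracy` (%), `precision`, `recall`, `f1`, and a
#'   `report` list column of `cvd_cv_report` objects.
#' @export
classify_all <- function(features, labels = NULL,
                         classifiers = c("dt", "knn", "svm"),
                         feature_sets = "psd+cca", ...) {
  grid <- expand.grid(classifier = classifiers, feature_set = feature_sets,
                      stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(grid)), function(i) {
    rep <- kfold_cv(features, labels, classifier = grid$classifier[i],
                    feature_set = grid$feature_set[i], ...)
    tibble::tibble(classifier = rep$classifier, feature_set = rep$feature_set,
                   mean_accuracy = rep$mean_accuracy,
                   sd_accuracy = rep$sd_accuracy,
                   precision = rep$precision, recall = rep$recall,
                   f1 = rep$f1, report = list(rep))
  }) |> dplyr::bind_rows()
}
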