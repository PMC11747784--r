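#' Tidy a cross-validation report
#'
#' @param x A `cvd_cv_report` from [kfold_cv()].
#' @param ... Unused.
#' @return One row per fold: `fold`, `accuracy` (%).
#' @exportS3Method generics::tidy
tidy.cvd_cv_report <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, feature_set = x$feature_set,
                 fold = seq_along(x$fold_accuracies),
                 accuracy = x$fold_accuracies)
}

#' @rdname tidy.cvd_cv_report
#' @return `glance()`: a one-row summary with mean/sd accuracy, confusion
#'   counts and derived metrics.
#' @exportS3Method generics::glance
glance.cvd_cv_report <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, feature_set = x$feature_set,
                 k_folds = x$k_folds, smote_mode = x$smote_mode,
                 mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
                 tp = x$confusion$tp, tn = x$confusion$tn,
                 fp = x$confusion$fp, fn = x$confusion$fn,
                 precision = x$precision, recall = x$recall,
                 specificity = x$specificity, f1 = x$f1, n = x$n)
}

#' Tidy a confusion matrix into count rows
#'
#' @param x A `cvd_confusion` from [confusion_matrix()].
#' @param ... Unused.
#' @return A tibble with `truth`, `prediction`, `count`.
#' @exportS3Method generics::tidy
tidy.cvd_confusion <- function(x, ...) {
  pos <- x$positive
  neg <- paste0("non-", pos)
  tibble::tibble(
    truth = c(pos, pos, neg, neg),
    prediction = c(pos, neg, pos, neg),
    count = c(x$tp, x$fn, x$fp, x$tn))
}
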