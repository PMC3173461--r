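#' Percent of samples classified correctly
#'
#' Combines the four confusion counts of a two-class test into the percent
#' correct, reported to one decimal place. Count order follows the
#' evaluation-grid convention: actual replete (+P) predicted deficient
#' (-P), actual deficient predicted replete, actual replete predicted
#' replete, actual deficient predicted deficient.
#'
#' @param n_replete_pred_deficient,n_deficient_pred_replete Misclassified
#'   counts.
#' @param n_replete_pred_replete,n_deficient_pred_deficient Correct counts.
#' @return Percent correct, rounded to one decimal.
#' @export
#' @examples
#' percent_correct(5, 7, 10, 8)  # 60.0
percent_correct <- function(n_replete_pred_deficient,
                            n_deficient_pred_replete,
                            n_replete_pred_replete,
                            n_deficient_pred_deficient) {
  counts <- c(n_replete_pred_deficient, n_deficient_pred_replete,
              n_replete_pred_replete, n_deficient_pred_deficient)
  if (any(counts < 0)) {
    abort_pistatus("Counts must be nonnegative.", "pistatus_domain_error")
  }
  total <- sum(counts)
  if (total == 0) {
    abort_pistatus("Total count must be positive.", "pistatus_domain_error")
  }
  round(100 * (n_replete_pred_replete + n_deficient_pred_deficient) / total, 1)
}

confusion_row <- function(actual, predicted) {
  tibble::tibble(
    n_replete_pred_deficient = sum(actual == "replete" &
                                     predicted == "deficient"),
    n_deficient_pred_replete = sum(actual == "deficient" &
                                     predicted == "replete"),
    n_replete_pred_replete = sum(actual == "replete" &
                                   predicted == "replete"),
    n_deficient_pred_deficient = sum(actual == "deficient" &
                                       predicted == "deficient")
  )
}

#' Sweep gene-set sizes and kernels
#'
#' For every combination of diagnostic-set size and kernel: ranks genes on
#' the training set by Golub score, selects a balanced set of `k` genes,
#' fits the SVM on the training samples, predicts margins for the test
#' samples, and tabulates the confusion counts and percent correct. With a
#' fixed seed and inputs the grid is deterministic.
#'
#' @param train,test Feature tibbles sharing a gene universe (positive
#'   median-scaled signals, e.g. from [prepare_features()]; Golub scoring
#'   uses their log2 internally).
#' @param train_classes,test_classes Class per sample column.
#' @param sizes Integer vector of diagnostic-set sizes; all must be at most
#'   the shared gene count.
#' @param kernels Kernel labels or [kernel_spec()]s (default all four:
#'   poly1-3 and rbf).
#' @param C Soft-margin cost.
#' @param balanced Balanced Golub selection (see [select_diagnostic()]).
#' @param normalize Sample-vector normalization passed to [svm_train()];
#'   the default `"l2"` makes train and test feature scales comparable.
#' @return A `pi_grid` tibble: one row per (kernel, size) with the four
#'   confusion counts and `percent_correct`.
#' @export
evaluate_grid <- function(train, train_classes, test, test_classes,
                          sizes, kernels = c("poly1", "poly2", "poly3", "rbf"),
                          C = 1, balanced = TRUE,
                          normalize = "l2") {
  check_expr_tbl(train, "train")
  check_expr_tbl(test, "test")
  shared <- intersect(train$gene_id, test$gene_id)
  if (any(sizes > length(shared))) {
    abort_pistatus("Every size must be at most the shared gene count.",
                   "pistatus_domain_error")
  }
  if (any(sizes <= 0)) {
    abort_pistatus("Sizes must be positive.", "pistatus_domain_error")
  }
  train <- train[train$gene_id %in% shared, ]
  test_classes <- as_class_vector(test_classes, ncol(test) - 1)
  scores <- golub_scores(log2_features(train), train_classes)
  rows <- list()
  for (k in sizes) {
    genes <- select_diagnostic(scores, k, balanced = balanced)$gene_id
    tr_k <- train[match(genes, train$gene_id), ]
    te_k <- test[match(genes, test$gene_id), ]
    for (kern in kernels) {
      spec <- parse_kernel(kern)
      fit <- svm_train(tr_k, train_classes, spec, C = C,
                       normalize = normalize)
      pred <- predict_margins(fit, te_k)
      cc <- confusion_row(test_classes, pred$predicted_class)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(kernel = kernel_label(spec), k = as.integer(k)),
        cc,
        tibble::tibble(percent_correct = percent_correct(
          cc$n_replete_pred_deficient, cc$n_deficient_pred_replete,
          cc$n_replete_pred_replete, cc$n_deficient_pred_deficient
        ))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pi_grid", class(out))
  out
}
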