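#' Map diagnostic genes onto another platform
#'
#' Projects a diagnostic gene set through an ortholog (or probe) mapping
#' table: the mapped feature set is the distinct targets of the mapped
#' sources, in map-file order (so one-to-many records resolve best-first).
#' The report lists sources with no mapping and targets hit by several
#' sources (many-to-one collapses).
#'
#' @param diagnostic Character vector of source gene ids, or a tibble with
#'   a `gene_id` column (e.g. from [select_diagnostic()]).
#' @param map Tibble with columns `source_gene_id`, `target_gene_id`.
#' @return A list of class `pi_mapping`: `features` (character vector of
#'   target ids), `unmapped` (sources with no record), `collapsed` (tibble
#'   `target_gene_id`, `n_sources` for targets with several sources), and
#'   `records` (the used mapping rows).
#' @export
map_features <- function(diagnostic, map) {
  if (is.data.frame(diagnostic)) diagnostic <- diagnostic$gene_id
  if (nrow(map) == 0 || !all(c("source_gene_id", "target_gene_id") %in%
                               names(map))) {
    abort_pistatus(
      "`map` must be a non-empty table with source_gene_id and target_gene_id.",
      "pistatus_data_error"
    )
  }
  if (any(!nzchar(map$source_gene_id)) || any(!nzchar(map$target_gene_id))) {
    abort_pistatus("Mapping ids must be non-empty.", "pistatus_data_error")
  }
  used <- map[map$source_gene_id %in% diagnostic, ]
  ## Best-first: keep the first record for each source, in map order.
  used <- used[!duplicated(used$source_gene_id), ]
  if (nrow(used) == 0) {
    abort_pistatus("No diagnostic gene has a mapping record.",
                   "pistatus_no_mappable_features_error")
  }
  features <- unique(used$target_gene_id)
  counts <- table(used$target_gene_id)
  collapsed <- tibble::tibble(
    target_gene_id = names(counts)[counts > 1],
    n_sources = as.integer(counts[counts > 1])
  )
  structure(
    list(
      features = features,
      unmapped = setdiff(diagnostic, used$source_gene_id),
      collapsed = collapsed,
      records = tibble::as_tibble(used)
    ),
    class = "pi_mapping"
  )
}

#' @export
print.pi_mapping <- function(x, ...) {
  cat("<pi_mapping> ", length(x$features), " target features from ",
      nrow(x$records), " mapped sources (", length(x$unmapped),
      " unmapped, ", nrow(x$collapsed), " many-to-one)\n", sep = "")
  invisible(x)
}

#' Project expression through a mapping
#'
#' Builds a target-platform expression table from source-platform data:
#' each target feature takes the arithmetic mean of the log2 signals of the
#' sources mapped to it (back-transformed to the linear scale).
#'
#' @param x Source expression tibble of positive signals.
#' @param mapping A `pi_mapping` from [map_features()].
#' @return Expression tibble on target feature ids.
#' @export
project_expression <- function(x, mapping) {
  check_expr_tbl(x)
  recs <- mapping$records[mapping$records$source_gene_id %in% x$gene_id, ]
  if (nrow(recs) == 0) {
    abort_pistatus("No mapped source is present in `x`.",
                   "pistatus_alignment_error")
  }
  values <- log2(expr_values(x))
  out <- rowsum(values[match(recs$source_gene_id, x$gene_id), , drop = FALSE],
                group = recs$target_gene_id)
  out <- out / as.vector(table(recs$target_gene_id)[rownames(out)])
  ord <- match(intersect(mapping$features, rownames(out)), rownames(out))
  expr_tbl(2^out[ord, , drop = FALSE], rownames(out)[ord], value_kind(x))
}

#' Classify samples on a second platform
#'
#' Trains an SVM on a labelled reference experiment restricted to the
#' mapped diagnostic features and predicts margin values for test samples
#' on the same platform, under the deficient = +1 convention. Both matrices
#' are median-scaled within their own dataset, and sample feature vectors
#' are L2-normalized over the mapped features before training and
#' prediction.
#'
#' @param mapping A `pi_mapping`, or a character vector of target feature
#'   ids.
#' @param reference Labelled reference expression tibble (positive
#'   signals).
#' @param reference_classes Class per reference sample.
#' @param test Test expression tibble on the same platform.
#' @param spec Kernel (label or [kernel_spec()]).
#' @param C Soft-margin cost.
#' @param scale_by How test genes are median-scaled: `"reference"`
#'   (default) divides each test gene by the gene's median in the labelled
#'   reference, anchoring the two datasets to a common per-gene scale and
#'   keeping one-class test sets (e.g. non-target stresses, all Pi replete)
#'   classifiable; `"own"` scales the test set within itself, which only
#'   separates test sets containing both classes.
#' @return List with `margins` (a `pi_margins` tibble), `model` (the
#'   `pi_svm`), and `features` used.
#' @export
cross_platform_classify <- function(mapping, reference, reference_classes,
                                    test, spec = "poly1", C = 1,
                                    scale_by = c("reference", "own")) {
  scale_by <- match.arg(scale_by)
  features <- if (inherits(mapping, "pi_mapping")) mapping$features else mapping
  check_expr_tbl(reference, "reference")
  check_expr_tbl(test, "test")
  missing_ref <- setdiff(features, reference$gene_id)
  missing_test <- setdiff(features, test$gene_id)
  if (length(missing_ref) > 0 || length(missing_test) > 0) {
    abort_pistatus(
      sprintf("%d mapped feature(s) missing from the reference and %d from the test matrix.",
              length(missing_ref), length(missing_test)),
      "pistatus_alignment_error"
    )
  }
  ref_f <- prepare_features(reference)
  test_f <- if (scale_by == "own") {
    prepare_features(test)
  } else {
    ref_med <- apply(expr_values(reference), 1, stats::median)
    expr_tbl(expr_values(test)[match(reference$gene_id, test$gene_id), ,
                               drop = FALSE] / ref_med,
             reference$gene_id, "median_scaled")
  }
  ref_k <- ref_f[match(features, ref_f$gene_id), ]
  test_k <- test_f[match(features, test_f$gene_id), ]
  if (anyNA(ref_k$gene_id) || anyNA(test_k$gene_id)) {
    abort_pistatus("Mapped features lost during scaling.",
                   "pistatus_alignment_error")
  }
  fit <- svm_train(ref_k, reference_classes, spec, C = C, normalize = "l2")
  list(margins = predict_margins(fit, test_k), model = fit,
       features = features)
}
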