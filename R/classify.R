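#' Label the dye-swap training set
#'
#' Treats the two-colour time course as one-colour data (one training sample
#' per labelled sample-channel) and assigns Pi-status classes: samples from
#' the first day (before starvation takes effect) and the final day (after
#' re-supply), and all samples supplied with Pi throughout, are Pi replete;
#' Pi-starved samples at the intermediate days are Pi deficient. The default
#' design yields 84 labelled samples, 54 replete and 30 deficient.
#'
#' @param meta Sample-channel metadata with `treatment` and `day`.
#' @param replete_days Days at which even `minus_P` samples are replete
#'   (default `c(0, 31)`: treatment start and post-re-supply).
#' @return `meta` with added `class` (`"replete"`/`"deficient"`) and `y`
#'   (`-1`/`+1`; deficient coded +1).
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_design(n_genes = 20, seed = 1))
#' table(build_training_labels(sim$meta)$class)
build_training_labels <- function(meta, replete_days = c(0L, 31L)) {
  if (anyNA(meta$day) || anyNA(meta$treatment)) {
    abort_pistatus("Every sample needs a day and a treatment.",
                   "pistatus_metadata_error")
  }
  meta |>
    dplyr::mutate(
      class = ifelse(.data$treatment == "plus_P" |
                       .data$day %in% replete_days,
                     "replete", "deficient"),
      y = ifelse(.data$class == "deficient", 1, -1)
    )
}

as_class_vector <- function(classes, n) {
  if (is.numeric(classes)) {
    classes <- ifelse(classes > 0, "deficient", "replete")
  }
  if (length(classes) != n || !all(classes %in% c("deficient", "replete"))) {
    abort_pistatus(
      "`classes` must give 'deficient' or 'replete' for every sample.",
      "pistatus_metadata_error"
    )
  }
  classes
}

#' Golub signal-to-noise scores
#'
#' Scores each gene by `(mean_deficient - mean_replete) / (sd_deficient +
#' sd_replete)` over log2 features; positive scores mark genes induced in Pi
#' deficient samples. Zero denominators are floored at `1e-9` times the mean
#' class-sd sum across genes.
#'
#' @param x Feature tibble (`gene_id` + one column per sample, log2 scale;
#'   see [prepare_features()]).
#' @param classes Class per sample column (`"deficient"`/`"replete"`, or a
#'   numeric coding with deficient > 0).
#' @return Tibble `gene_id`, `score`.
#' @export
golub_scores <- function(x, classes) {
  check_expr_tbl(x)
  values <- expr_values(x)
  classes <- as_class_vector(classes, ncol(values))
  def <- classes == "deficient"
  if (sum(def) < 2 || sum(!def) < 2) {
    abort_pistatus("Both classes need at least two samples.",
                   "pistatus_metadata_error")
  }
  mu_d <- rowMeans(values[, def, drop = FALSE])
  mu_r <- rowMeans(values[, !def, drop = FALSE])
  sd_d <- apply(values[, def, drop = FALSE], 1, stats::sd)
  sd_r <- apply(values[, !def, drop = FALSE], 1, stats::sd)
  denom <- sd_d + sd_r
  eps <- 1e-9 * mean(denom[denom > 0])
  if (!is.finite(eps) || eps == 0) eps <- 1e-12
  tibble::tibble(gene_id = x$gene_id,
                 score = unname((mu_d - mu_r) / pmax(denom, eps)))
}

#' Select a balanced diagnostic gene set
#'
#' Picks `k` genes from ranked Golub scores: the `ceiling(k/2)` most
#' positive and `floor(k/2)` most negative scores (balanced selection, the
#' original signal-to-noise practice), or the top `k` by absolute score when
#' `balanced = FALSE`. Ties are broken by lexicographic gene id, so the
#' output is deterministic.
#'
#' @param scores Tibble `gene_id`, `score` from [golub_scores()].
#' @param k Number of genes to select (`0 < k <=` genes scored).
#' @param balanced Use balanced top-positive/top-negative selection?
#' @return Tibble `gene_id`, `score`, `side` (`"up"`/`"down"`), positives
#'   first (descending score), then negatives (ascending score).
#' @export
select_diagnostic <- function(scores, k, balanced = TRUE) {
  if (k <= 0) {
    abort_pistatus("`k` must be positive.", "pistatus_domain_error")
  }
  if (k > nrow(scores)) {
    abort_pistatus("`k` exceeds the number of scored genes.",
                   "pistatus_domain_error")
  }
  if (balanced) {
    ord <- order(-scores$score, scores$gene_id)
    n_pos <- ceiling(k / 2)
    n_neg <- floor(k / 2)
    top <- scores[ord[seq_len(n_pos)], ]
    rest <- scores[-ord[seq_len(n_pos)], , drop = FALSE]
    bottom <- rest[order(rest$score, rest$gene_id)[seq_len(n_neg)], ]
    out <- dplyr::bind_rows(
      dplyr::mutate(top, side = "up"),
      dplyr::mutate(bottom, side = "down")
    )
  } else {
    ord <- order(-abs(scores$score), scores$gene_id)
    out <- scores[ord[seq_len(k)], ]
    out$side <- ifelse(out$score >= 0, "up", "down")
  }
  tibble::as_tibble(out)
}

#' Kernel specification
#'
#' Kernels available to the class predictor: homogeneous polynomial dot
#' products `(u . v)^degree` of order 1-3, and the radial basis kernel
#' `exp(-gamma * ||u - v||^2)`.
#'
#' @param family `"poly_dot"` or `"rbf"`.
#' @param degree Polynomial order (1, 2, or 3); `poly_dot` only.
#' @param gamma Positive width parameter; `rbf` only. `NULL` resolves at
#'   training time to `1 / (n_features x mean feature variance)`.
#' @param offset Constant added to the dot product before exponentiation
#'   (default 0, the homogeneous convention).
#' @return A list of class `pi_kernel`.
#' @export
kernel_spec <- function(family = c("poly_dot", "rbf"), degree = NULL,
                        gamma = NULL, offset = 0) {
  family <- match.arg(family)
  if (family == "poly_dot") {
    if (is.null(degree) || !degree %in% 1:3) {
      abort_pistatus("`degree` must be 1, 2 or 3 for poly_dot kernels.",
                     "pistatus_design_error")
    }
    if (!is.null(gamma)) {
      abort_pistatus("`gamma` applies to rbf kernels only.",
                     "pistatus_design_error")
    }
  } else {
    if (!is.null(degree)) {
      abort_pistatus("`degree` applies to poly_dot kernels only.",
                     "pistatus_design_error")
    }
    if (!is.null(gamma) && gamma <= 0) {
      abort_pistatus("`gamma` must be positive.", "pistatus_design_error")
    }
  }
  structure(list(family = family, degree = degree, gamma = gamma,
                 offset = offset),
            class = "pi_kernel")
}

#' Parse a kernel label
#'
#' Shorthand labels: `"poly1"`, `"poly2"`, `"poly3"` (dot product of that
#' order) and `"rbf"`.
#'
#' @param label Kernel label or an existing [kernel_spec()].
#' @return A `pi_kernel`.
#' @export
parse_kernel <- function(label) {
  if (inherits(label, "pi_kernel")) return(label)
  switch(label,
    poly1 = kernel_spec("poly_dot", degree = 1),
    poly2 = kernel_spec("poly_dot", degree = 2),
    poly3 = kernel_spec("poly_dot", degree = 3),
    rbf = kernel_spec("rbf"),
    abort_pistatus(sprintf("Unknown kernel label '%s'.", label),
                   "pistatus_design_error")
  )
}

kernel_label <- function(spec) {
  if (spec$family == "poly_dot") paste0("poly", spec$degree) else "rbf"
}

#' Evaluate a kernel between two vectors
#'
#' @param u,v Equal-length numeric vectors.
#' @param spec A [kernel_spec()]; `rbf` needs an explicit `gamma`.
#' @return A single kernel value.
#' @export
#' @examples
#' kernel_value(c(1, 2), c(3, 4), kernel_spec("poly_dot", degree = 2))  # 121
kernel_value <- function(u, v, spec) {
  if (length(u) != length(v)) {
    abort_pistatus("`u` and `v` must have equal length.",
                   "pistatus_domain_error")
  }
  drop(kernel_matrix(matrix(u, nrow = 1), matrix(v, nrow = 1), spec))
}

## Kernel Gram matrix between row-sample matrices.
kernel_matrix <- function(x, y, spec) {
  if (spec$family == "poly_dot") {
    (tcrossprod(x, y) + spec$offset)^spec$degree
  } else {
    gamma <- spec$gamma
    if (is.null(gamma)) {
      abort_pistatus("rbf kernel needs a resolved `gamma`.",
                     "pistatus_design_error")
    }
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    exp(-gamma * d2)
  }
}

resolve_gamma <- function(spec, x) {
  if (spec$family == "rbf" && is.null(spec$gamma)) {
    v <- mean(apply(x, 2, stats::var))
    spec$gamma <- 1 / (ncol(x) * max(v, .Machine$double.eps))
  }
  spec
}

#' Prepare classifier features
#'
#' Median-scales each gene within its own dataset: the feature
#' representation seen by the SVM kernels is the positive median-scaled
#' signal (centred at 1), on which homogeneous polynomial kernels of any
#' order are informative. Cross-dataset comparability rests on this
#' within-dataset scaling. Golub scoring works on the log2 of these
#' features (see [golub_scores()]).
#'
#' @param x Expression tibble of positive signals.
#' @return Median-scaled feature tibble.
#' @export
prepare_features <- function(x) {
  median_scale(x)
}

## Log2 transform of a positive feature tibble, for signal-to-noise scoring.
log2_features <- function(x) {
  expr_tbl(log2(pmax(expr_values(x), .Machine$double.eps)), x$gene_id,
           "log2")
}
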