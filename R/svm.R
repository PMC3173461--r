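#' Train a soft-margin kernel SVM
#'
#' Solves the C-SVM dual by sequential minimal optimization (maximal
#' violating pair working-set selection) to KKT tolerance `tol`, giving the
#' decision function `f(x) = sum_i alpha_i y_i K(x_i, x) + b` with the class
#' coding deficient = +1, replete = -1. Margin values are `f(x)`: positive
#' margins call a sample Pi deficient, negative Pi replete.
#'
#' @param x Feature tibble (`gene_id` + one column per training sample;
#'   positive median-scaled signals from [prepare_features()]).
#' @param classes Class per sample column (`"deficient"`/`"replete"` or a
#'   numeric coding with deficient > 0).
#' @param spec [kernel_spec()] or label; an rbf `gamma` left `NULL` resolves
#'   to `1 / (n_features x mean feature variance)` on the training set.
#' @param C Soft-margin cost (default 1).
#' @param tol KKT violation tolerance (default 1e-6).
#' @param max_iter Iteration cap; exceeding it raises a convergence error.
#' @param normalize `"none"` (default) trains on the features as given;
#'   `"l2"` scales every sample's feature vector to unit Euclidean norm
#'   before training (and, via the stored model, before prediction), making
#'   margins invariant to any global rescaling of the features — the
#'   convention used for cross-dataset class prediction.
#' @return An object of class `pi_svm`.
#' @export
#' @examples
#' x <- tibble::tibble(gene_id = "g1", s1 = 0, s2 = 0, s3 = 2, s4 = 2)
#' fit <- svm_train(x, c("replete", "replete", "deficient", "deficient"),
#'                  "poly1")
#' predict_margins(fit, tibble::tibble(gene_id = "g1", t1 = 3))
svm_train <- function(x, classes, spec, C = 1, tol = 1e-6,
                      max_iter = NULL, normalize = c("none", "l2")) {
  normalize = match.arg(normalize)
  check_expr_tbl(x)
  spec <- parse_kernel(spec)
  values <- expr_values(x)
  if (any(!is.finite(values))) {
    abort_pistatus("Features must be finite.", "pistatus_data_error")
  }
  classes <- as_class_vector(classes, ncol(values))
  y <- ifelse(classes == "deficient", 1, -1)
  if (length(unique(y)) < 2) {
    abort_pistatus("Both classes must be present in the training set.",
                   "pistatus_metadata_error")
  }
  xt <- t(values)                      # samples x features
  if (normalize == "l2") xt <- l2_normalize(xt)
  spec <- resolve_gamma(spec, xt)
  n <- nrow(xt)
  if (is.null(max_iter)) max_iter <- max(200L * n, 20000L)
  k <- kernel_matrix(xt, xt, spec)

  alpha <- numeric(n)
  grad <- rep(-1, n)                   # gradient of 0.5 a'Qa - e'a
  it <- 0L
  viol <- Inf
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      abort_pistatus(
        sprintf("SMO did not converge within %d iterations (violation %.3g).",
                max_iter, viol),
        "pistatus_convergence_error"
      )
    }
    score <- -y * grad
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(score[up])]
    j <- which(low)[which.min(score[low])]
    viol <- score[i] - score[j]
    if (viol < tol) break
    quad <- k[i, i] + k[j, j] - 2 * k[i, j]
    if (quad <= 0) quad <- 1e-12
    t_step <- viol / quad
    t_step <- min(t_step,
                  if (y[i] > 0) C - alpha[i] else alpha[i],
                  if (y[j] > 0) alpha[j] else C - alpha[j])
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * y * (k[, i] - k[, j])
  }

  ## Bias from free support vectors, else the midpoint of the KKT interval.
  f_nob <- y * (grad + 1)
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) {
    mean(y[free] - f_nob[free])
  } else {
    score <- -y * grad
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    hi <- if (any(up)) max(score[up]) else 0
    lo <- if (any(low)) min(score[low]) else 0
    (hi + lo) / 2
  }

  sv <- which(alpha > 1e-10)
  structure(
    list(
      kernel = spec, C = C, features = x$gene_id,
      sample_ids = colnames(values),
      alpha = alpha, y = y, b = b,
      sv_index = sv, coef = (alpha * y)[sv],
      x_sv = xt[sv, , drop = FALSE],
      iterations = it, tol = tol, normalize = normalize,
      class_coding = c(deficient = 1, replete = -1)
    ),
    class = "pi_svm"
  )
}

## Scale each sample (row) vector to unit Euclidean norm; zero rows pass
## through unchanged.
l2_normalize <- function(xt) {
  norms <- sqrt(rowSums(xt^2))
  norms[norms == 0] <- 1
  xt / norms
}

#' @export
print.pi_svm <- function(x, ...) {
  cat("<pi_svm> ", kernel_label(x$kernel), " kernel, C = ", x$C, ", ",
      length(x$sv_index), "/", length(x$y), " support vectors, ",
      length(x$features), " genes; deficient coded +1\n", sep = "")
  invisible(x)
}

#' Margin values for new samples
#'
#' Evaluates the SVM decision function for each test sample. The margin is
#' the signed distance-like score from the separating hyperplane under the
#' deficient = +1 coding: positive margins predict Pi deficient, negative
#' Pi replete.
#'
#' @param model A `pi_svm` fit.
#' @param x Feature tibble containing (at least) all of the model's feature
#'   genes, on the training feature scale.
#' @return Tibble `sample_id`, `margin`, `predicted_class` of class
#'   `pi_margins`.
#' @export
predict_margins <- function(model, x) {
  check_expr_tbl(x)
  missing <- setdiff(model$features, x$gene_id)
  if (length(missing) > 0) {
    abort_pistatus(
      sprintf("Test data is missing %d model feature gene(s), e.g. %s.",
              length(missing), missing[1]),
      "pistatus_alignment_error"
    )
  }
  values <- expr_values(x)[match(model$features, x$gene_id), , drop = FALSE]
  xt <- t(values)
  if (identical(model$normalize, "l2")) xt <- l2_normalize(xt)
  kk <- kernel_matrix(xt, model$x_sv, model$kernel)
  margin <- unname(drop(kk %*% model$coef) + model$b)
  out <- tibble::tibble(
    sample_id = colnames(values),
    margin = margin,
    predicted_class = ifelse(margin > 0, "deficient", "replete")
  )
  class(out) <- c("pi_margins", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted SVM
#'
#' One row per support vector: sample id, class label, dual coefficient
#' `alpha`, and signed coefficient `alpha * y`.
#'
#' @param x A `pi_svm` fit.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pi_svm
#' @export
tidy.pi_svm <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids[x$sv_index],
    class = ifelse(x$y[x$sv_index] > 0, "deficient", "replete"),
    alpha = x$alpha[x$sv_index],
    coef = x$coef
  )
}

#' One-row summary of a fitted SVM
#'
#' @param x A `pi_svm` fit.
#' @param ... Unused.
#' @return Tibble with kernel family/parameters, `C`, support-vector count,
#'   bias, feature count and iteration count.
#' @method glance pi_svm
#' @export
glance.pi_svm <- function(x, ...) {
  tibble::tibble(
    kernel = kernel_label(x$kernel),
    degree = if (is.null(x$kernel$degree)) NA_integer_ else x$kernel$degree,
    gamma = if (is.null(x$kernel$gamma)) NA_real_ else x$kernel$gamma,
    C = x$C,
    n_support = length(x$sv_index),
    n_features = length(x$features),
    bias = x$b,
    iterations = x$iterations
  )
}

#' Serialize a fitted SVM to JSON
#'
#' Writes a plain-text JSON artifact holding the kernel specification,
#' support-vector features, dual coefficients, bias and gene order, readable
#' by [read_svm_model()].
#'
#' @param model A `pi_svm` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  payload <- list(
    kernel = list(family = model$kernel$family,
                  degree = model$kernel$degree,
                  gamma = model$kernel$gamma,
                  offset = model$kernel$offset),
    C = model$C, b = model$b,
    features = model$features,
    support_sample_ids = model$sample_ids[model$sv_index],
    coef = model$coef,
    x_sv = apply(model$x_sv, 1, identity, simplify = FALSE),
    normalize = model$normalize,
    class_coding = as.list(model$class_coding)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized SVM
#'
#' @param path Path written by [write_svm_model()].
#' @return A `pi_svm` usable with [predict_margins()].
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- kernel_spec(p$kernel$family,
                      degree = p$kernel$degree,
                      gamma = p$kernel$gamma,
                      offset = if (is.null(p$kernel$offset)) 0 else p$kernel$offset)
  x_sv <- if (is.list(p$x_sv)) do.call(rbind, p$x_sv) else matrix(p$x_sv, nrow = length(p$coef))
  structure(
    list(
      kernel = spec, C = p$C, features = p$features,
      sample_ids = p$support_sample_ids,
      alpha = abs(p$coef), y = sign(p$coef), b = p$b,
      sv_index = seq_along(p$coef), coef = p$coef,
      x_sv = x_sv, iterations = NA_integer_, tol = NA_real_,
      normalize = if (is.null(p$normalize)) "none" else p$normalize,
      class_coding = c(deficient = 1, replete = -1)
    ),
    class = "pi_svm"
  )
}
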