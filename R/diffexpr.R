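#' Differential-expression parameters
#'
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param min_timepoints Minimum number of time points beyond the fold
#'   threshold (default 2).
#' @param n_groups Number of response groups cut from the clustering tree
#'   (default 8).
#' @return A list of class `pi_de_params`.
#' @export
de_params <- function(alpha = 0.01, fc_threshold = 1.5, min_timepoints = 2L,
                      n_groups = 8L) {
  if (alpha <= 0 || alpha >= 1) {
    abort_pistatus("`alpha` must lie in (0, 1).", "pistatus_design_error")
  }
  if (fc_threshold <= 1) {
    abort_pistatus("`fc_threshold` must exceed 1.", "pistatus_design_error")
  }
  if (min_timepoints < 1) {
    abort_pistatus("`min_timepoints` must be at least 1.",
                   "pistatus_design_error")
  }
  structure(
    list(alpha = alpha, fc_threshold = fc_threshold,
         min_timepoints = as.integer(min_timepoints),
         n_groups = as.integer(n_groups)),
    class = "pi_de_params"
  )
}

#' Per-gene per-day fold changes
#'
#' For each gene and sampling day, the ratio of the mean signal over treated
#' (`minus_P`) samples to the mean over control (`plus_P`) samples.
#'
#' @param x Expression tibble (median-scaled signals recommended).
#' @param meta Sample metadata with `treatment` and `day`.
#' @return A tibble `gene_id` + one `fc_d<day>` column per day.
#' @export
fold_changes <- function(x, meta) {
  check_expr_tbl(x)
  values <- expr_values(align_columns_to_meta(x, meta, "x"))
  days <- sort(unique(meta$day))
  fc <- vapply(days, function(d) {
    trt <- meta$day == d & meta$treatment == "minus_P"
    ctl <- meta$day == d & meta$treatment == "plus_P"
    if (!any(trt) || !any(ctl)) {
      abort_pistatus(
        sprintf("Day %s is missing one of the two treatments.", d),
        "pistatus_design_error"
      )
    }
    rowMeans(values[, trt, drop = FALSE]) /
      rowMeans(values[, ctl, drop = FALSE])
  }, numeric(nrow(values)))
  if (!is.matrix(fc)) fc <- matrix(fc, nrow = nrow(values))
  colnames(fc) <- sprintf("fc_d%d", days)
  dplyr::bind_cols(tibble::tibble(gene_id = x$gene_id),
                   tibble::as_tibble(fc))
}

#' Treatment-response ANOVA p-values
#'
#' Fits, per gene, a two-factor fixed-effects ANOVA of log2 signal on
#' day x treatment and tests the treatment main effect and the
#' treatment-by-day interaction jointly against the day-only model
#' (extra-sum-of-squares F test), so genes responding at any subset of days
#' are detectable. Genes with no residual and no effect variance get p = 1.
#'
#' @param x Expression tibble of positive signals (log2 taken internally).
#' @param meta Sample metadata with `treatment` and `day`; at least two
#'   replicates per day x treatment cell are required.
#' @return Tibble `gene_id`, `p_raw`.
#' @export
anova_pvalues <- function(x, meta) {
  check_expr_tbl(x)
  values <- expr_values(align_columns_to_meta(x, meta, "x"))
  cell <- interaction(meta$day, meta$treatment, drop = TRUE)
  if (any(table(cell) < 2)) {
    abort_pistatus("Every day x treatment cell needs >= 2 replicates.",
                   "pistatus_design_error")
  }
  y <- t(log2(pmax(values, .Machine$double.eps)))
  day_f <- factor(meta$day)
  trt_f <- factor(meta$treatment)
  x_red <- stats::model.matrix(~day_f)
  x_full <- stats::model.matrix(~day_f * trt_f)
  qr_red <- qr(x_red)
  qr_full <- qr(x_full)
  rss_red <- colSums(qr.resid(qr_red, y)^2)
  rss_full <- colSums(qr.resid(qr_full, y)^2)
  df1 <- qr_full$rank - qr_red$rank
  df2 <- nrow(y) - qr_full$rank
  fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  ## Degenerate genes: no variance anywhere -> no evidence of effect.
  degenerate <- rss_full < 1e-12 & (rss_red - rss_full) < 1e-12
  p[degenerate] <- 1
  if (all(degenerate)) {
    abort_pistatus("All genes have zero within-cell variance.",
                   "pistatus_degenerate_anova_error")
  }
  tibble::tibble(gene_id = x$gene_id, p_raw = unname(pmin(pmax(p, 0), 1)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values `q(i) = min_(j>=i) m * p(j) / j` over the sorted
#' raw p-values, capped at 1. Controls the false discovery rate for
#' independent or positively dependent tests.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_pistatus("p-values must lie in [0, 1].", "pistatus_domain_error")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
  q
}

#' Call differentially expressed genes
#'
#' A gene is called up-regulated when its adjusted p is below `alpha` and
#' its fold change exceeds `fc_threshold` at `min_timepoints` or more days;
#' down-regulated when the fold change falls below `1/fc_threshold` at that
#' many days. A gene may carry both calls (at different days) but is counted
#' once in the DE set.
#'
#' @param fc Fold-change tibble from [fold_changes()].
#' @param p Tibble with `gene_id` and `p_raw` (adjusted internally), or with
#'   a precomputed `p_adj` column.
#' @param params [de_params()].
#' @return A `pi_de` tibble: `gene_id`, the `fc_d*` columns, `p_raw`,
#'   `p_adj`, `up_call`, `down_call`, `de`, `group` (`NA` until clustered).
#' @export
call_de <- function(fc, p, params = de_params()) {
  if (!identical(fc$gene_id, p$gene_id)) {
    abort_pistatus("`fc` and `p` must be aligned by gene.",
                   "pistatus_alignment_error")
  }
  if (!"p_adj" %in% names(p)) {
    p$p_adj <- bh_adjust(p$p_raw)
  }
  fc_cols <- grep("^fc_d", names(fc), value = TRUE)
  fc_m <- as.matrix(fc[, fc_cols])
  if (any(fc_m <= 0)) {
    abort_pistatus("Fold changes must be positive.", "pistatus_domain_error")
  }
  sig <- p$p_adj < params$alpha
  up <- sig & rowSums(fc_m > params$fc_threshold) >= params$min_timepoints
  down <- sig & rowSums(fc_m < 1 / params$fc_threshold) >= params$min_timepoints
  out <- dplyr::bind_cols(
    fc,
    tibble::tibble(
      p_raw = if ("p_raw" %in% names(p)) p$p_raw else NA_real_,
      p_adj = p$p_adj,
      up_call = up, down_call = down, de = up | down,
      group = NA_character_
    )
  )
  class(out) <- c("pi_de", class(out))
  out
}

## Centered (Pearson) correlation distance between profile rows; constant
## rows are mutually at distance 0 and at distance 1 from varying rows.
correlation_distance <- function(m) {
  centred <- m - rowMeans(m)
  norms <- sqrt(rowSums(centred^2))
  num <- tcrossprod(centred)
  den <- outer(norms, norms)
  r <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  both_const <- outer(norms == 0, norms == 0, "&")
  r[both_const] <- 1
  d <- 1 - r
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Cluster DE genes into response groups
#'
#' Agglomerative hierarchical clustering (average linkage) of per-gene log2
#' fold-change profiles under centred-correlation distance, cut into exactly
#' `n_groups` groups by descending merge height. Groups are labelled with
#' Roman numerals in order of decreasing size.
#'
#' @param de A `pi_de` tibble (only rows with `de == TRUE` are clustered) or
#'   any tibble with `gene_id` and `fc_d*` columns.
#' @param n_groups Number of groups to cut.
#' @return The input with `group` filled in for clustered genes, plus the
#'   `hclust` tree in the `"tree"` attribute.
#' @export
hierarchical_cluster <- function(de, n_groups = 8L) {
  fc_cols <- grep("^fc_d", names(de), value = TRUE)
  rows <- if ("de" %in% names(de)) which(de$de) else seq_len(nrow(de))
  if (n_groups < 1 || length(rows) < n_groups) {
    abort_pistatus("`n_groups` must lie between 1 and the DE gene count.",
                   "pistatus_domain_error")
  }
  profiles <- log2(as.matrix(de[rows, fc_cols]))
  rownames(profiles) <- de$gene_id[rows]
  tree <- stats::hclust(correlation_distance(profiles), method = "average")
  cut <- stats::cutree(tree, k = n_groups)
  sizes <- sort(table(cut), decreasing = TRUE)
  relabel <- stats::setNames(as.character(utils::as.roman(seq_along(sizes))),
                             names(sizes))
  if (!"group" %in% names(de)) de$group <- NA_character_
  de$group[rows] <- relabel[as.character(cut)]
  attr(de, "tree") <- tree
  de
}

#' Symbolize an expression profile
#'
#' Converts per-day mean fold changes into the group-signature alphabet:
#' `↑` when the fold exceeds `fc_threshold`, `↓` when it falls below
#' `1/fc_threshold`, `-` otherwise.
#'
#' @param folds Positive numeric vector of per-day folds.
#' @param fc_threshold Fold threshold (default 1.5).
#' @return A compact pattern string, one symbol per day.
#' @export
#' @examples
#' symbolize_profile(c(1, 1, 1, 1, 1.8, 1.9, 1.2))  # Group I signature
symbolize_profile <- function(folds, fc_threshold = 1.5) {
  if (any(!is.finite(folds) | folds <= 0)) {
    abort_pistatus("Folds must be positive.", "pistatus_domain_error")
  }
  s <- ifelse(folds > fc_threshold, sym_up,
              ifelse(folds < 1 / fc_threshold, sym_down, sym_flat))
  paste(s, collapse = "")
}

#' Symbolize every group's mean profile
#'
#' @param de A clustered `pi_de` tibble.
#' @param fc_threshold Fold threshold (default 1.5).
#' @return Tibble `group`, `n_genes`, `pattern` (groups in Roman-numeral
#'   order), where `pattern` symbolizes the geometric mean fold profile of
#'   the group.
#' @export
group_signatures <- function(de, fc_threshold = 1.5) {
  fc_cols <- grep("^fc_d", names(de), value = TRUE)
  de |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      pattern = symbolize_profile(
        2^colMeans(log2(as.matrix(dplyr::pick(dplyr::all_of(fc_cols))))),
        fc_threshold
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$group, as.character(utils::as.roman(1:100))))
}

#' Term overrepresentation by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric test of whether each annotation term
#' appears more often in the selected gene set than expected by chance given
#' the universe, with Benjamini-Hochberg adjustment across terms.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param annotation Tibble with `gene_id` and `term` columns covering the
#'   universe (a gene may carry several terms).
#' @param universe Character vector of background gene ids.
#' @return Tibble `term`, `k` (selected genes with term), `K` (universe
#'   genes with term), `n` (selection size), `N` (universe size),
#'   `fold_enrichment`, `p`, `p_adj`, sorted by `p`.
#' @export
term_enrichment <- function(selected, annotation, universe) {
  if (!all(selected %in% universe)) {
    abort_pistatus("Every selected gene must belong to the universe.",
                   "pistatus_consistency_error")
  }
  if (length(selected) == 0) {
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(),
                          fold_enrichment = numeric(), p = numeric(),
                          p_adj = numeric()))
  }
  ann <- annotation |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$gene_id, .data$term)
  n_sel <- length(unique(selected))
  n_uni <- length(unique(universe))
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      k = sum(unique(.data$gene_id) %in% selected),
      K = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n_sel, N = n_uni,
      fold_enrichment = (.data$k / .data$n) / (.data$K / .data$N),
      p = stats::phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                        lower.tail = FALSE),
      p_adj = bh_adjust(.data$p)
    ) |>
    dplyr::arrange(.data$p, .data$term)
  res
}

#' Welch's two-sided t-test from summary statistics
#'
#' Computes the Welch statistic and Welch-Satterthwaite degrees of freedom
#' from group means, standard errors of the mean, and sample sizes, as used
#' to compare field summary statistics between fertilised and unfertilised
#' plots.
#'
#' @param mean1,sem1,n1 First group: mean, standard error, sample size.
#' @param mean2,sem2,n2 Second group.
#' @return Tibble `estimate` (mean1 - mean2), `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' welch_ttest(1.98, 0.10, 6, 5.13, 0.65, 3)
welch_ttest <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort_pistatus("Each group needs n >= 2.", "pistatus_domain_error")
  }
  if (sem1 <= 0 || sem2 <= 0) {
    abort_pistatus("Standard errors must be positive.",
                   "pistatus_domain_error")
  }
  se2 <- sem1^2 + sem2^2
  tstat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  tibble::tibble(
    estimate = mean1 - mean2,
    statistic = tstat,
    df = df,
    p_value = 2 * stats::pt(-abs(tstat), df)
  )
}
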