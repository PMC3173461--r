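#' Preprocessing parameters
#'
#' Parameters controlling two-channel normalization and the three-rule gene
#' pre-filter.
#'
#' @param lowess_span Fraction of the data used for each local Lowess fit
#'   (default 0.35).
#' @param control_floor Minimum control-channel value used in the ratio
#'   denominator (default 10).
#' @param raw_floor Low-signal threshold on raw intensities (default 50).
#' @param raw_floor_timepoints Number of time points at which the mean raw
#'   signal must fall below `raw_floor` to remove a gene (default 5 of 7).
#' @param flat_band Closed interval of normalized signal considered "no
#'   change" (default `c(0.8, 1.2)`).
#' @param absent_frac Fraction of measurements flagged absent above which a
#'   gene is removed (default 0.5).
#' @return A list of class `pi_preprocess_params`.
#' @export
preprocess_params <- function(lowess_span = 0.35, control_floor = 10,
                              raw_floor = 50, raw_floor_timepoints = 5L,
                              flat_band = c(0.8, 1.2), absent_frac = 0.5) {
  if (lowess_span <= 0 || lowess_span > 1) {
    abort_pistatus("`lowess_span` must lie in (0, 1].", "pistatus_design_error")
  }
  if (control_floor <= 0 || raw_floor < 0) {
    abort_pistatus("Floors must be positive.", "pistatus_design_error")
  }
  if (length(flat_band) != 2 || flat_band[1] > flat_band[2]) {
    abort_pistatus("`flat_band` must be an interval c(lower, upper).",
                   "pistatus_design_error")
  }
  structure(
    list(lowess_span = lowess_span, control_floor = control_floor,
         raw_floor = raw_floor,
         raw_floor_timepoints = as.integer(raw_floor_timepoints),
         flat_band = flat_band, absent_frac = absent_frac),
    class = "pi_preprocess_params"
  )
}

## Split two-channel metadata into per-array (experimental, control) channel
## ids; errors if any array lacks one of the two treatments.
array_channels <- function(meta) {
  arrays <- unique(meta$array_id)
  exp_id <- ctl_id <- character(length(arrays))
  for (i in seq_along(arrays)) {
    chans <- meta[meta$array_id == arrays[i], ]
    e <- chans$sample_id[chans$treatment == "minus_P"]
    c_ <- chans$sample_id[chans$treatment == "plus_P"]
    if (length(e) != 1 || length(c_) != 1) {
      abort_pistatus(
        sprintf("Array %s does not pair one minus_P with one plus_P channel.",
                arrays[i]),
        "pistatus_design_error"
      )
    }
    exp_id[i] <- e
    ctl_id[i] <- c_
  }
  tibble::tibble(array_id = arrays, experimental = exp_id, control = ctl_id)
}

## Core per-array Lowess correction. Returns corrected log2 ratios (M) given
## experimental and control intensity vectors.
lowess_correct <- function(e, c_, params) {
  cf <- pmax(c_, params$control_floor)
  e <- pmax(e, .Machine$double.eps)
  m <- log2(e / cf)
  a <- 0.5 * (log2(e) + log2(cf))
  fit <- stats::lowess(a, m, f = params$lowess_span, iter = 2)
  trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = "ordered")$y
  m - trend
}

#' Lowess-normalize a two-channel experiment
#'
#' For each array, computes the per-gene ratio experimental / max(control,
#' `control_floor`), fits a Lowess curve (local linear, tricube weights, two
#' robustness iterations, span `lowess_span`) to the log-ratio versus mean
#' log-intensity plot, and subtracts the fitted trend, removing
#' intensity-dependent dye bias. Ratios are strictly positive.
#'
#' @param raw Raw two-channel expression tibble (`gene_id` + channel
#'   columns).
#' @param meta Sample-channel metadata pairing channels into arrays.
#' @param params [preprocess_params()].
#' @return A ratio tibble: `gene_id` + one column per array holding the
#'   corrected experimental/control ratio.
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_design(n_genes = 200, seed = 1))
#' ratios <- lowess_normalize(sim$raw, sim$meta)
lowess_normalize <- function(raw, meta, params = preprocess_params()) {
  check_expr_tbl(raw, "raw")
  values <- expr_values(align_columns_to_meta(raw, meta, "raw"))
  if (any(values < 0)) {
    abort_pistatus("Raw intensities must be nonnegative.",
                   "pistatus_data_error")
  }
  ac <- array_channels(meta)
  out <- matrix(NA_real_, nrow = nrow(values), ncol = nrow(ac),
                dimnames = list(NULL, ac$array_id))
  for (i in seq_len(nrow(ac))) {
    m <- lowess_correct(values[, ac$experimental[i]], values[, ac$control[i]],
                        params)
    out[, i] <- 2^m
  }
  expr_tbl(out, raw$gene_id, "ratio")
}

#' Lowess-corrected per-channel signals
#'
#' Reconstructs two-channel signals after Lowess correction, so a dye-swap
#' experiment can be treated as one-colour data downstream: the control
#' channel is floored at `control_floor`, and the experimental channel is
#' set to `floored control x corrected ratio`, so the per-array ratio of the
#' returned channels equals the [lowess_normalize()] output.
#'
#' @inheritParams lowess_normalize
#' @return A tibble shaped like `raw` with corrected channel signals.
#' @export
normalized_channels <- function(raw, meta, params = preprocess_params()) {
  check_expr_tbl(raw, "raw")
  values <- expr_values(align_columns_to_meta(raw, meta, "raw"))
  ac <- array_channels(meta)
  out <- values[, meta$sample_id, drop = FALSE]
  for (i in seq_len(nrow(ac))) {
    cf <- pmax(values[, ac$control[i]], params$control_floor)
    m <- lowess_correct(values[, ac$experimental[i]], values[, ac$control[i]],
                        params)
    out[, ac$control[i]] <- cf
    out[, ac$experimental[i]] <- cf * 2^m
  }
  expr_tbl(out, raw$gene_id, "one_colour")
}

#' Median-scale each gene
#'
#' Divides every gene's measurements by the median of that gene's
#' measurements across all samples of the experiment, so each surviving
#' gene's per-gene median is 1. Genes whose values are all zero (or not
#' finite and positive) cannot be scaled; they are dropped with a warning
#' and recorded in the `"dropped"` attribute.
#'
#' @param x Expression tibble (`gene_id` + numeric columns).
#' @return A median-scaled tibble.
#' @export
#' @examples
#' median_scale(tibble::tibble(gene_id = "g1", s1 = 2, s2 = 4, s3 = 8))
median_scale <- function(x) {
  check_expr_tbl(x)
  values <- expr_values(x)
  med <- apply(values, 1, function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) == 0) NA_real_ else stats::median(v)
  })
  bad <- !is.finite(med) | med <= 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "Dropping %d gene(s) with no finite positive values to scale by.",
      sum(bad)
    ), class = "pistatus_degenerate_gene")
  }
  out <- expr_tbl(values[!bad, , drop = FALSE] / med[!bad],
                  x$gene_id[!bad], "median_scaled")
  attr(out, "dropped") <- x$gene_id[bad]
  out
}

#' Three-rule gene pre-filter
#'
#' Applies the pre-filter used before differential-expression analysis:
#' \enumerate{
#'   \item remove genes whose raw signal is below `raw_floor` in at least
#'     `raw_floor_timepoints` of the time points (evaluated on the mean raw
#'     signal across replicates and treatments within each time point);
#'   \item remove genes flagged absent in more than `absent_frac` of their
#'     measurements;
#'   \item remove genes whose normalized signal stays inside `flat_band` at
#'     all time points (evaluated on per-(day, treatment) means).
#' }
#' A gene may fire several rules; the removal report records each.
#'
#' @param x Median-scaled expression tibble (columns aligned to `meta`).
#' @param raw Raw expression tibble on the same genes (columns aligned to
#'   `raw_meta`, by default `meta`).
#' @param flags Logical absent-flag tibble shaped like `raw` (or `NULL`).
#' @param meta Metadata for `x`'s columns; must carry `day`.
#' @param params [preprocess_params()].
#' @param raw_meta Metadata for `raw`'s columns, if different from `meta`.
#' @return List with `matrix` (surviving genes) and `report` (tibble
#'   `gene_id`, `rule1`, `rule2`, `rule3`, `removed`).
#' @export
prefilter <- function(x, raw, flags, meta, params = preprocess_params(),
                      raw_meta = meta) {
  check_expr_tbl(x)
  check_expr_tbl(raw, "raw")
  if (!identical(x$gene_id, raw$gene_id)) {
    abort_pistatus("`x` and `raw` must cover the same genes in order.",
                   "pistatus_alignment_error")
  }
  if (any(is.na(meta$day)) || any(is.na(raw_meta$day))) {
    abort_pistatus("Metadata must assign a day to every sample.",
                   "pistatus_design_error")
  }
  raw_v <- expr_values(align_columns_to_meta(raw, raw_meta, "raw"))
  days <- sort(unique(raw_meta$day))

  ## Rule 1: dim in >= raw_floor_timepoints time points.
  day_mean <- vapply(days, function(d) {
    rowMeans(raw_v[, raw_meta$day == d, drop = FALSE])
  }, numeric(nrow(raw_v)))
  rule1 <- rowSums(day_mean < params$raw_floor) >= params$raw_floor_timepoints

  ## Rule 2: flagged absent in more than absent_frac of measurements.
  if (is.null(flags)) {
    rule2 <- rep(FALSE, nrow(raw_v))
  } else {
    check_expr_tbl(flags, "flags")
    if (!identical(flags$gene_id, raw$gene_id)) {
      abort_pistatus("`flags` must cover the same genes as `raw` in order.",
                     "pistatus_alignment_error")
    }
    flag_v <- expr_values(flags)
    rule2 <- rowMeans(flag_v) > params$absent_frac
  }

  ## Rule 3: normalized signal inside the flat band at every aggregate.
  x_al <- align_columns_to_meta(x, meta, "x")
  x_v <- expr_values(x_al)
  grp <- if ("treatment" %in% names(meta) && !anyNA(meta$treatment)) {
    interaction(meta$day, meta$treatment, drop = TRUE)
  } else {
    factor(meta$day)
  }
  agg <- vapply(levels(grp), function(g) {
    rowMeans(x_v[, grp == g, drop = FALSE])
  }, numeric(nrow(x_v)))
  rule3 <- rowSums(agg < params$flat_band[1] | agg > params$flat_band[2]) == 0

  removed <- rule1 | rule2 | rule3
  report <- tibble::tibble(
    gene_id = x$gene_id, rule1 = unname(rule1), rule2 = unname(rule2),
    rule3 = unname(rule3), removed = unname(removed)
  )
  list(matrix = x[!removed, , drop = FALSE], report = report)
}
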