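#' Simulate a dye-swap Pi-withdrawal time course
#'
#' Generates raw two-channel intensities for a full dye-swap time-course
#' experiment: at every (day, replicate) one Pi-starved (`minus_P`) and one
#' control (`plus_P`) biological sample are co-hybridised on an array, and
#' the pairing is repeated with dyes reversed. The default design yields 42
#' biological samples measured as 84 labelled sample-channels on 42 arrays.
#'
#' Signals are log-normal: each gene has a baseline log2 intensity drawn
#' once, responsive genes multiply the treated mean by `effect_fold` on the
#' days their pattern marks `↑` (divide on `↓`), and Gaussian noise of sd
#' `noise_sd` is added on the log2 scale per measurement. A fraction of
#' genes is generated dim (below the low-signal filter floor) and a fraction
#' of gene x array cells is flagged absent. Identical designs (including
#' seed) give bit-identical output.
#'
#' @param design A [sim_design()] object.
#' @return A list of class `pi_sim`:
#' \describe{
#'   \item{raw}{tibble of raw two-channel intensities, `gene_id` + one
#'     column per sample-channel.}
#'   \item{meta}{tibble with one row per sample-channel: `sample_id`,
#'     `array_id`, `dye`, `treatment`, `day`, `replicate`, `dataset`.}
#'   \item{flags}{logical tibble, same shape as `raw`; `TRUE` = absent.}
#'   \item{truth}{tibble `gene_id`, `pattern`, `is_diagnostic`,
#'     `planted_fold`, `direction`, `base_log2`, `low_signal`.}
#' }
#' @export
#' @examples
#' sim <- simulate_timecourse(sim_design(n_genes = 50, seed = 7))
#' nrow(sim$meta)  # 84 labelled sample-channels
simulate_timecourse <- function(design) {
  if (!inherits(design, "pi_design")) {
    abort_pistatus("`design` must be created by sim_design().",
                   "pistatus_design_error")
  }
  set.seed(derive_seed(design$seed, 1L))
  n <- design$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  ## Truth: planted patterns, baselines, low-signal genes.
  n_resp <- round(design$frac_responsive * n)
  responsive <- sort(sample.int(n, n_resp))
  pattern <- rep(strrep(sym_flat, length(design$days)), n)
  pattern[responsive] <- sample(design$patterns, n_resp, replace = TRUE)
  base_log2 <- stats::rnorm(n, mean = 10, sd = 1.5)
  n_low <- round(design$frac_low_signal * n)
  low_pool <- setdiff(seq_len(n), responsive)
  low_signal <- rep(FALSE, n)
  if (n_low > 0 && length(low_pool) > 0) {
    idx <- sort(sample(low_pool, min(n_low, length(low_pool))))
    low_signal[idx] <- TRUE
    base_log2[idx] <- stats::rnorm(length(idx),
                                   mean = log2(design$low_signal_level) - 0.5,
                                   sd = 0.3)
  }
  direction <- vapply(pattern, pattern_direction, numeric(1), USE.NAMES = FALSE)
  truth <- tibble::tibble(
    gene_id = gene_id,
    pattern = pattern,
    is_diagnostic = seq_len(n) %in% responsive,
    planted_fold = ifelse(seq_len(n) %in% responsive, design$effect_fold, 1),
    direction = direction,
    base_log2 = base_log2,
    low_signal = low_signal
  )

  ## Per-gene x per-day log2 fold applied to the treated channel.
  fold_log2 <- t(vapply(pattern, function(p) {
    log2(pattern_to_folds(p, design$effect_fold))
  }, numeric(length(design$days)), USE.NAMES = FALSE))

  n_swap <- if (design$dye_swap) 2L else 1L
  meta <- tidyr::expand_grid(
    day = design$days,
    replicate = seq_len(design$replicates),
    orientation = seq_len(n_swap),
    treatment = c("minus_P", "plus_P")
  )
  meta$array_id <- sprintf("d%02d_r%d_a%d", meta$day, meta$replicate,
                           meta$orientation)
  ## Orientation 1: treated labelled cy5; orientation 2: dyes reversed.
  meta$dye <- ifelse((meta$treatment == "minus_P") == (meta$orientation == 1L),
                     "cy5", "cy3")
  meta$sample_id <- sprintf("%s_%s_%s", meta$array_id,
                            sub("_P$", "P", meta$treatment), meta$dye)
  meta$dataset <- "timecourse"
  meta <- meta[, c("sample_id", "array_id", "dye", "treatment", "day",
                   "replicate", "dataset")]
  meta <- tibble::as_tibble(meta)

  day_index <- match(meta$day, design$days)
  mu <- matrix(base_log2, nrow = n, ncol = nrow(meta))
  treated <- meta$treatment == "minus_P"
  mu[, treated] <- mu[, treated] + fold_log2[, day_index[treated], drop = FALSE]
  noise <- matrix(stats::rnorm(n * nrow(meta), sd = design$noise_sd),
                  nrow = n)
  values <- 2^(mu + noise)
  colnames(values) <- meta$sample_id
  raw <- expr_tbl(values, gene_id, "raw_two_channel")

  ## Absent flags per gene x array, shared by the two channels of the array.
  arrays <- unique(meta$array_id)
  flag_arr <- matrix(stats::runif(n * length(arrays)) < design$frac_absent,
                     nrow = n, dimnames = list(NULL, arrays))
  flag_m <- flag_arr[, meta$array_id, drop = FALSE]
  colnames(flag_m) <- meta$sample_id
  flags <- expr_tbl(flag_m, gene_id)

  if (any(design$dye_bias != 0)) {
    raw <- inject_dye_bias(raw, meta, design$dye_bias)
  }
  structure(list(raw = raw, meta = meta, flags = flags, truth = truth),
            class = "pi_sim")
}

#' @export
print.pi_sim <- function(x, ...) {
  cat("<pi_sim> ", nrow(x$raw), " genes x ", nrow(x$meta),
      " sample-channels (", length(unique(x$meta$array_id)), " arrays); ",
      sum(x$truth$is_diagnostic), " responsive genes\n", sep = "")
  invisible(x)
}

#' Inject an intensity-dependent bias into two-channel data
#'
#' Adds a smooth polynomial function of the per-array mean log2 intensity to
#' the log-ratio of each array by multiplying the experimental (`minus_P`)
#' channel: with centred intensity `A`, the experimental channel is scaled
#' by `2^(c1*A + c2*A^2 + ...)`. This emulates the intensity-dependent dye
#' bias that Lowess normalization is designed to remove; the injected trend
#' is recoverable (and removable) by [lowess_normalize()]. The sign is kept
#' consistent across dye orientations so the trend is visible pooled over a
#' dye-swap design.
#'
#' @param raw Raw two-channel expression tibble.
#' @param meta Sample-channel metadata (see [simulate_timecourse()]).
#' @param coefficients Numeric polynomial coefficients, linear term first.
#' @return The biased raw tibble.
#' @export
inject_dye_bias <- function(raw, meta, coefficients) {
  check_expr_tbl(raw, "raw")
  kind <- value_kind(raw)
  two_channel <- all(table(meta$array_id[meta$sample_id %in% names(raw)]) == 2)
  if ((!is.na(kind) && kind != "raw_two_channel") || !two_channel) {
    abort_pistatus("Dye bias can only be injected into raw two-channel data.",
                   "pistatus_value_kind_error")
  }
  if (all(coefficients == 0)) {
    return(raw)
  }
  values <- expr_values(align_columns_to_meta(raw, meta, "raw"))
  for (arr in unique(meta$array_id)) {
    chans <- meta[meta$array_id == arr, ]
    e_id <- chans$sample_id[chans$treatment == "minus_P"]
    c_id <- chans$sample_id[chans$treatment == "plus_P"]
    a <- 0.5 * (log2(pmax(values[, e_id], .Machine$double.eps)) +
                log2(pmax(values[, c_id], .Machine$double.eps)))
    ac <- a - mean(a)
    bias <- rowSums(vapply(seq_along(coefficients),
                           function(k) coefficients[k] * ac^k,
                           numeric(length(ac))))
    values[, e_id] <- values[, e_id] * 2^bias
  }
  expr_tbl(values, raw$gene_id, "raw_two_channel")
}

#' Simulate a labelled one-colour field test set
#'
#' Generates a fertilised/unfertilised "field" test set on the same gene
#' universe as a simulated time course: `n_per_class` Pi-replete and
#' `n_per_class` Pi-deficient one-colour samples. Deficient samples shift
#' every diagnostic gene by `attenuation x log2(planted_fold)` in the gene's
#' planted direction; replete samples sit at baseline. Gaussian noise of sd
#' `noise_sd` is added on the log2 scale.
#'
#' @param truth Truth tibble from [simulate_timecourse()].
#' @param n_per_class Samples per class (default 15, i.e. 30 samples).
#' @param attenuation Fraction in (0, 1] of the planted glasshouse effect
#'   expressed in the field.
#' @param noise_sd Log2-scale noise sd.
#' @param seed Integer seed.
#' @return List of class `pi_field` with `expr` (one-colour tibble) and
#'   `meta` (with a `class` column, `"deficient"` or `"replete"`).
#' @export
generate_field_set <- function(truth, n_per_class = 15L, attenuation = 1,
                               noise_sd = 0.25, seed = 1L) {
  if (n_per_class < 1) {
    abort_pistatus("`n_per_class` must be at least 1.", "pistatus_design_error")
  }
  if (attenuation <= 0 || attenuation > 1) {
    abort_pistatus("`attenuation` must lie in (0, 1].", "pistatus_design_error")
  }
  if (!any(truth$is_diagnostic)) {
    abort_pistatus("`truth` must contain at least one diagnostic gene.",
                   "pistatus_design_error")
  }
  set.seed(derive_seed(seed, 2L))
  n <- nrow(truth)
  classes <- rep(c("deficient", "replete"), each = n_per_class)
  sample_id <- sprintf("field_%s_%02d", ifelse(classes == "deficient", "minusP",
                                               "plusP"),
                       rep(seq_len(n_per_class), times = 2))
  shift <- truth$direction * log2(truth$planted_fold) * attenuation
  mu <- matrix(truth$base_log2, nrow = n, ncol = length(sample_id))
  mu[, classes == "deficient"] <- mu[, classes == "deficient"] + shift
  noise <- matrix(stats::rnorm(n * length(sample_id), sd = noise_sd), nrow = n)
  values <- 2^(mu + noise)
  colnames(values) <- sample_id
  expr <- expr_tbl(values, truth$gene_id, "one_colour")
  meta <- tibble::tibble(
    sample_id = sample_id, array_id = sample_id, dye = "cy3",
    treatment = ifelse(classes == "deficient", "minus_P", "plus_P"),
    day = NA_integer_, replicate = rep(seq_len(n_per_class), times = 2),
    dataset = "field", class = classes
  )
  structure(list(expr = expr, meta = meta), class = "pi_field")
}
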