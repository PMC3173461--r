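#' Cluster-group expression-profile signatures
#'
#' Compact 7-symbol signatures (one symbol per sampling day) of the eight
#' canonical response groups seen after Pi withdrawal and re-supply:
#' `↑` = up-regulated more than the fold threshold on that day, `↓` =
#' down-regulated more than the fold threshold, `-` = no change. Days run
#' 0, 1, 3, 7, 17, 29, 31 relative to Pi withdrawal (re-supply after 28 d).
#'
#' @format Named character vector of length 8 (`I` ... `VIII`).
#' @export
pi_group_patterns <- c(
  I    = "----↑↑-",
  II   = "----↓↑-",
  III  = "↓------",
  IV   = "-------",
  V    = "----↓↓-",
  VI   = "--↑↑---",
  VII  = "---↑↑--",
  VIII = "---↑---"
)

## Sustained deficiency-marker patterns: responding on every day the
## starved plants are Pi deficient (all but the first day, before the
## starvation takes effect, and the last, after re-supply). These are the
## profile shapes usable as status markers; transient shapes (see
## pi_group_patterns) are available through the `patterns` argument.
default_responsive_patterns <- function(n_days = 7L) {
  mid_up <- strrep(sym_up, n_days - 2L)
  mid_dn <- strrep(sym_down, n_days - 2L)
  c(paste0(sym_flat, mid_up, sym_flat),
    paste0(sym_flat, mid_dn, sym_flat))
}

#' Describe a synthetic dye-swap time-course design
#'
#' Captures the design of the glasshouse Pi withdrawal/re-supply experiment
#' that the synthetic generator emulates: 7 sampling days (0, 1, 3, 7, 17,
#' 29, 31 relative to Pi withdrawal, with Pi re-supplied after 28 d), two
#' treatments (`plus_P` control, `minus_P` Pi-starved), 3 biological
#' replicates per cell, and a full dye swap, giving 42 biological samples
#' measured as 84 labelled sample-channels.
#'
#' @param days Strictly increasing integer vector of sampling days.
#' @param replicates Biological replicates per treatment x day cell.
#' @param dye_swap Duplicate each array pairing with dyes reversed?
#' @param n_genes Number of genes on the synthetic array.
#' @param frac_responsive Fraction of genes planted with a temporal response
#'   pattern (the rest are null).
#' @param effect_fold Multiplicative effect per pattern arrow; must be > 1.
#' @param noise_sd Standard deviation of additive Gaussian noise on the log2
#'   signal scale.
#' @param dye_bias Polynomial coefficients (linear term first) of a smooth
#'   log-intensity to log-ratio bias curve injected into the experimental
#'   channel; `0` disables the bias.
#' @param frac_absent Fraction of gene x array cells flagged absent.
#' @param frac_low_signal Fraction of genes generated with raw signal below
#'   the conventional low-signal filter floor.
#' @param low_signal_level Mean raw intensity (linear scale) of low-signal
#'   genes; default 20, below the conventional floor of 50.
#' @param patterns Character vector of response patterns (7-symbol strings
#'   over `↑`, `↓`, `-`) sampled for responsive genes. `NULL` (default)
#'   plants sustained deficiency markers: up- or down-regulated on every
#'   day the starved plants are Pi deficient (days 1-29) and back at
#'   baseline at day 0 (before starvation bites) and day 31 (after
#'   re-supply). Transient cluster signatures such as
#'   [pi_group_patterns] can be supplied instead.
#' @param seed Integer seed; identical designs generate bit-identical data.
#'
#' @return A list of class `pi_design`.
#' @export
#' @examples
#' d <- sim_design(n_genes = 100, seed = 1)
#' d$days
sim_design <- function(days = c(0L, 1L, 3L, 7L, 17L, 29L, 31L),
                       replicates = 3L,
                       dye_swap = TRUE,
                       n_genes = 2000L,
                       frac_responsive = 0.1,
                       effect_fold = 2,
                       noise_sd = 0.25,
                       dye_bias = 0,
                       frac_absent = 0.01,
                       frac_low_signal = 0.02,
                       low_signal_level = 20,
                       patterns = NULL,
                       seed = 1L) {
  days <- as.integer(days)
  if (length(days) < 2 || any(diff(days) <= 0)) {
    abort_pistatus("`days` must be a strictly increasing integer vector.",
                   "pistatus_design_error")
  }
  if (n_genes < 1 || replicates < 1) {
    abort_pistatus("`n_genes` and `replicates` must be positive.",
                   "pistatus_design_error")
  }
  if (effect_fold <= 1) {
    abort_pistatus("`effect_fold` must exceed 1.", "pistatus_design_error")
  }
  for (fr in c(frac_responsive, frac_absent, frac_low_signal)) {
    if (fr < 0 || fr > 1) {
      abort_pistatus("Fractions must lie in [0, 1].", "pistatus_design_error")
    }
  }
  if (noise_sd < 0) {
    abort_pistatus("`noise_sd` must be nonnegative.", "pistatus_design_error")
  }
  if (is.null(patterns)) {
    patterns <- default_responsive_patterns(length(days))
  }
  bad <- vapply(patterns, function(p) {
    s <- pattern_symbols(p)
    length(s) != length(days) || !all(s %in% c(sym_up, sym_down, sym_flat))
  }, logical(1))
  if (any(bad)) {
    abort_pistatus(
      sprintf("Patterns must be %d-symbol strings over {↑, ↓, -}.",
              length(days)),
      "pistatus_design_error"
    )
  }
  structure(
    list(
      days = days, treatments = c("plus_P", "minus_P"),
      replicates = as.integer(replicates), dye_swap = isTRUE(dye_swap),
      n_genes = as.integer(n_genes), frac_responsive = frac_responsive,
      effect_fold = effect_fold, noise_sd = noise_sd, dye_bias = dye_bias,
      frac_absent = frac_absent, frac_low_signal = frac_low_signal,
      low_signal_level = low_signal_level, patterns = patterns,
      seed = as.integer(seed)
    ),
    class = "pi_design"
  )
}

#' @export
print.pi_design <- function(x, ...) {
  cat("<pi_design> ", length(x$days), " days x 2 treatments x ",
      x$replicates, " replicates",
      if (x$dye_swap) " (full dye swap)", "; ",
      x$n_genes, " genes, ", round(100 * x$frac_responsive, 1),
      "% responsive at fold ", x$effect_fold, "\n", sep = "")
  invisible(x)
}

pattern_symbols <- function(pattern) {
  strsplit(pattern, "", fixed = FALSE)[[1]]
}

## Per-day multiplicative fold implied by a pattern string.
pattern_to_folds <- function(pattern, effect_fold) {
  s <- pattern_symbols(pattern)
  ifelse(s == sym_up, effect_fold, ifelse(s == sym_down, 1 / effect_fold, 1))
}

## Dominant direction of a pattern: +1 planted up, -1 planted down, 0 flat.
pattern_direction <- function(pattern) {
  s <- pattern_symbols(pattern)
  n_up <- sum(s == sym_up)
  n_dn <- sum(s == sym_down)
  if (n_up == 0 && n_dn == 0) 0 else if (n_up >= n_dn) 1 else -1
}
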