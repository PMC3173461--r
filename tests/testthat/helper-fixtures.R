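## Shared fixtures and independent oracles for the test suite.

up <- "↑"
dn <- "↓"

## Small default-design simulation, memoised per (n_genes, seed, ...) call.
small_sim <- function(n_genes = 300, seed = 1, ...) {
  simulate_timecourse(sim_design(n_genes = n_genes, seed = seed, ...))
}

## Tiny two-channel fixture built by hand: `n` genes on `n_arrays` arrays
## over the given days (one replicate, both dye orientations when swap).
toy_two_channel <- function(values_exp, values_ctl, days) {
  n_arr <- ncol(values_exp)
  meta <- tibble::tibble(
    sample_id = c(sprintf("a%d_exp", seq_len(n_arr)),
                  sprintf("a%d_ctl", seq_len(n_arr))),
    array_id = rep(sprintf("a%d", seq_len(n_arr)), 2),
    dye = rep(c("cy5", "cy3"), each = n_arr),
    treatment = rep(c("minus_P", "plus_P"), each = n_arr),
    day = rep(days, 2),
    replicate = 1L,
    dataset = "toy"
  )
  raw <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(nrow(values_exp))))
  for (i in seq_len(n_arr)) raw[[sprintf("a%d_exp", i)]] <- values_exp[, i]
  for (i in seq_len(n_arr)) raw[[sprintf("a%d_ctl", i)]] <- values_ctl[, i]
  list(raw = raw, meta = meta)
}

## Pooled correlation between log-ratio and mean log-intensity across all
## arrays of a two-channel experiment, given a ratio table; the oracle used
## to quantify residual intensity-dependent bias.
bias_correlation <- function(raw, meta, ratio) {
  ms <- c()
  as_ <- c()
  for (arr in unique(meta$array_id)) {
    chans <- meta[meta$array_id == arr, ]
    e <- raw[[chans$sample_id[chans$treatment == "minus_P"]]]
    ctl <- raw[[chans$sample_id[chans$treatment == "plus_P"]]]
    ms <- c(ms, log2(ratio[[arr]]))
    as_ <- c(as_, 0.5 * (log2(e) + log2(pmax(ctl, 10))))
  }
  stats::cor(ms, as_)
}

## Brute-force primal grid-search QP for the linear (order-1 dot product)
## soft-margin SVM: minimises 0.5||w||^2 + C * sum hinge over a refined
## grid; independent of the package's dual solver.
brute_force_linear_svm <- function(x, y, C = 1) {
  p <- ncol(x)
  obj <- function(wb) {
    w <- wb[seq_len(p)]
    b <- wb[p + 1]
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (x %*% w + b)))
  }
  centre <- rep(0, p + 1)
  width <- 5
  for (iter in 1:7) {
    axes <- lapply(seq_len(p + 1),
                   function(i) seq(centre[i] - width, centre[i] + width,
                                   length.out = 11))
    combos <- as.matrix(expand.grid(axes))
    vals <- apply(combos, 1, obj)
    centre <- combos[which.min(vals), ]
    width <- width / 2
  }
  ## derivative-free polish along the (possibly flat) valley of the convex
  ## piecewise-quadratic objective
  centre <- stats::optim(centre, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 20000))$par
  list(w = centre[seq_len(p)], b = centre[p + 1],
       margins = function(newx) drop(newx %*% centre[seq_len(p)] + centre[p + 1]))
}

## Feature tibble from a samples-in-columns numeric matrix.
feature_tbl <- function(m, gene_id = sprintf("g%02d", seq_len(nrow(m)))) {
  tb <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_id), tb)
}
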