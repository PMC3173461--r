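make_channel_meta <- function(days, reps_per_cell) {
  tidyr::expand_grid(day = days, treatment = c("minus_P", "plus_P"),
                     replicate = seq_len(reps_per_cell)) |>
    dplyr::mutate(sample_id = sprintf("d%d_%s_r%d", day, treatment, replicate),
                  dataset = "toy")
}

test_that("fold changes are ratios of treatment means per day", {
  meta <- tibble::tibble(
    sample_id = c("t1", "t2", "t3", "c1", "c2"),
    treatment = c(rep("minus_P", 3), rep("plus_P", 2)),
    day = 0
  )
  x <- tibble::tibble(gene_id = "g1",
                      t1 = 3.0, t2 = 3.2, t3 = 2.8, c1 = 1.0, c2 = 2.0)
  fc <- fold_changes(x, meta)
  expect_equal(fc$fc_d0, 2)
  ## identical treatment values give fold 1 at every day
  meta2 <- make_channel_meta(c(0, 1, 3), 2)
  x2 <- feature_tbl(matrix(5, nrow = 3, ncol = nrow(meta2),
                           dimnames = list(NULL, meta2$sample_id)))
  fc2 <- fold_changes(x2, meta2)
  expect_true(all(as.matrix(fc2[, -1]) == 1))
  ## a day missing one treatment is a design error
  meta3 <- meta[meta$treatment == "minus_P", ]
  expect_error(fold_changes(x[, c("gene_id", "t1", "t2", "t3")], meta3),
               class = "pistatus_design_error")
})

test_that("the treatment-response ANOVA behaves at the extremes", {
  meta <- make_channel_meta(c(0, 1, 3, 7, 17, 29, 31), 3)
  set.seed(10)
  n <- nrow(meta)
  ## gene 1 constant everywhere; gene 2 pure noise; gene 3 strong effect
  g1 <- rep(4, n)
  g2 <- 2^rnorm(n, 8, 0.3)
  g3 <- 2^(8 + ifelse(meta$treatment == "minus_P", log2(10), 0) +
             rnorm(n, 0, 0.1))
  x <- feature_tbl(rbind(g1, g2, g3))
  names(x)[-1] <- meta$sample_id
  p <- anova_pvalues(x, meta)
  expect_equal(p$p_raw[1], 1)
  expect_gt(p$p_raw[2], 1e-4)
  expect_lt(p$p_raw[3], 1e-4)
  ## all-degenerate input errors
  x_const <- feature_tbl(matrix(4, nrow = 2, ncol = n,
                                dimnames = list(NULL, meta$sample_id)))
  expect_error(anova_pvalues(x_const, meta),
               class = "pistatus_degenerate_anova_error")
  ## unreplicated cells error
  meta1 <- make_channel_meta(c(0, 1), 1)
  x1 <- feature_tbl(matrix(2^rnorm(4), nrow = 1,
                           dimnames = list(NULL, meta1$sample_id)))
  expect_error(anova_pvalues(x1, meta1), class = "pistatus_design_error")
})

test_that("null ANOVA p-values are approximately uniform", {
  sim <- small_sim(n_genes = 1000, seed = 31, frac_responsive = 0,
                   noise_sd = 0.2, frac_absent = 0, frac_low_signal = 0)
  x <- median_scale(sim$raw)
  p <- anova_pvalues(x, sim$meta)
  ks <- stats::ks.test(p$p_raw, "punif")$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  ## agrees with the reference implementation on random vectors
  set.seed(4)
  for (i in 1:5) {
    p <- stats::runif(50)^2
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  }
  ## monotone in sorted raw p and never below raw p
  p <- stats::runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "pistatus_domain_error")
})

test_that("DE calls combine significance with the fold rule", {
  fc <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    fc_d0 = c(2, 2, 1, 2), fc_d1 = c(2, 2, 1, 1),
    fc_d3 = c(1, 0.4, 1, 1), fc_d7 = c(1, 0.4, 1, 1),
    fc_d17 = c(1, 1, 1, 1), fc_d29 = c(1, 1, 1, 1), fc_d31 = c(1, 1, 1, 1)
  )
  p <- tibble::tibble(gene_id = fc$gene_id,
                      p_raw = c(0.001, 0.001, 0.001, 0.001),
                      p_adj = c(0.005, 0.005, 0.005, 0.005))
  de <- call_de(fc, p)
  expect_equal(de$up_call, c(TRUE, TRUE, FALSE, FALSE))   # g4: only 1 day
  expect_equal(de$down_call, c(FALSE, TRUE, FALSE, FALSE))
  ## a gene may be both up and down but counts once in the DE set
  expect_equal(sum(de$de),
               sum(de$up_call) + sum(de$down_call) -
                 sum(de$up_call & de$down_call))
  ## insignificant p blocks the call regardless of fold
  p2 <- dplyr::mutate(p, p_adj = 0.5)
  expect_false(any(call_de(fc, p2)$de))
})

test_that("DE counts shrink as thresholds tighten", {
  sim <- small_sim(n_genes = 400, seed = 32, frac_responsive = 0.2,
                   noise_sd = 0.2, frac_absent = 0, frac_low_signal = 0)
  x <- median_scale(sim$raw)
  fc <- fold_changes(x, sim$meta)
  p <- anova_pvalues(x, sim$meta)
  n_de <- function(fct, mtp) {
    sum(call_de(fc, p, de_params(fc_threshold = fct,
                                 min_timepoints = mtp))$de)
  }
  expect_gte(n_de(1.3, 2), n_de(1.5, 2))
  expect_gte(n_de(1.5, 2), n_de(2.5, 2))
  expect_gte(n_de(1.5, 2), n_de(1.5, 4))
})

test_that("hierarchical clustering separates opposite profile families", {
  set.seed(5)
  base <- c(0, 0, 1, 2, 2, 1, 0)
  profiles <- rbind(
    t(replicate(10, 2^(base + rnorm(7, 0, 0.05)))),
    t(replicate(10, 2^(-base + rnorm(7, 0, 0.05))))
  )
  fc <- feature_tbl(profiles)
  names(fc)[-1] <- sprintf("fc_d%d", c(0, 1, 3, 7, 17, 29, 31))
  out <- hierarchical_cluster(fc, 2)
  expect_equal(length(unique(out$group[1:10])), 1)
  expect_equal(length(unique(out$group[11:20])), 1)
  expect_false(out$group[1] == out$group[11])
  ## n_groups = 1 puts everything together
  one <- hierarchical_cluster(fc, 1)
  expect_equal(unique(one$group), "I")
  ## duplicate profiles always co-cluster
  fc_dup <- fc
  fc_dup[2, -1] <- fc_dup[1, -1]
  dup <- hierarchical_cluster(fc_dup, 8)
  expect_equal(dup$group[1], dup$group[2])
  ## too many groups error
  expect_error(hierarchical_cluster(fc, 21), class = "pistatus_domain_error")
})

test_that("profile symbolization applies the 1.5-fold thresholds", {
  expect_equal(symbolize_profile(c(1.0, 1.0, 1.0, 1.0, 1.8, 1.9, 1.2)),
               paste0("----", up, up, "-"))
  expect_equal(symbolize_profile(0.6), dn)  # 0.6 < 1/1.5
  expect_equal(symbolize_profile(rep(1, 7)), "-------")
  expect_equal(symbolize_profile(c(2, 0.5), fc_threshold = 2.5), "--")
  expect_error(symbolize_profile(c(1, -1)), class = "pistatus_domain_error")
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- sprintf("g%02d", 1:20)
  ann <- tibble::tibble(gene_id = universe,
                        term = rep(c("T1", "T2"), c(5, 15)))
  selected <- universe[1:10]  # contains all 5 genes of T1
  res <- term_enrichment(selected, ann, universe)
  t1 <- res[res$term == "T1", ]
  ## independent oracle: exact combinatorial arithmetic
  expect_equal(t1$p, choose(15, 5) / choose(20, 10))
  expect_equal(t1$p, 3003 / 184756)
  expect_equal(t1$fold_enrichment, (5 / 10) / (5 / 20))
  ## a term annotating every gene cannot be enriched
  all_term <- tibble::tibble(gene_id = universe, term = "ALL")
  res_all <- term_enrichment(selected, all_term, universe)
  expect_equal(res_all$p, 1)
  ## empty selection yields no rows; foreign genes error
  expect_equal(nrow(term_enrichment(character(), ann, universe)), 0)
  expect_error(term_enrichment("nope", ann, universe),
               class = "pistatus_consistency_error")
})

test_that("Welch's test from summary statistics matches t.test on raw data", {
  set.seed(6)
  a <- rnorm(8, 5, 2)
  b <- rnorm(5, 3, 1)
  ref <- stats::t.test(a, b)
  got <- welch_ttest(mean(a), stats::sd(a) / sqrt(8), 8,
                     mean(b), stats::sd(b) / sqrt(5), 5)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  ## equal means give p = 1; extreme separation is conclusive
  expect_equal(welch_ttest(5, 1, 4, 5, 1, 4)$p_value, 1)
  expect_lt(welch_ttest(0, 0.1, 4, 100, 0.1, 4)$p_value, 1e-6)
  expect_error(welch_ttest(1, 1, 1, 2, 1, 4), class = "pistatus_domain_error")
  expect_error(welch_ttest(1, 0, 4, 2, 1, 4), class = "pistatus_domain_error")
})
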