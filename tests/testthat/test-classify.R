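test_that("training labels implement the replete/deficient rule", {
  sim <- small_sim(n_genes = 10, seed = 41)
  labels <- build_training_labels(sim$meta)
  expect_equal(nrow(labels), 84)
  expect_equal(sum(labels$class == "replete"), 54)
  expect_equal(sum(labels$class == "deficient"), 30)
  ## a Pi-starved sample at day 0 is still replete
  d0 <- labels[labels$day == 0 & labels$treatment == "minus_P", ]
  expect_true(all(d0$class == "replete"))
  ## as is one at day 31, after re-supply
  d31 <- labels[labels$day == 31 & labels$treatment == "minus_P", ]
  expect_true(all(d31$class == "replete"))
  ## deficient samples are exactly minus_P at days 1-29
  def <- labels[labels$class == "deficient", ]
  expect_true(all(def$treatment == "minus_P"))
  expect_true(all(def$day %in% c(1, 3, 7, 17, 29)))
  bad <- sim$meta
  bad$day[3] <- NA
  expect_error(build_training_labels(bad), class = "pistatus_metadata_error")
})

test_that("Golub scores are signal-to-noise ratios", {
  d <- 0.25 * sqrt(2)
  x <- feature_tbl(rbind(
    c(2 - d, 2 + d, 1 - d, 1 + d),   # means 2 vs 1, both sd 0.5
    c(3, 3, 3, 3)                    # equal class means
  ))
  classes <- c("deficient", "deficient", "replete", "replete")
  s <- golub_scores(x, classes)
  expect_equal(s$score[1], 1)
  expect_equal(s$score[2], 0)
  expect_error(golub_scores(x, rep("replete", 4)),
               class = "pistatus_metadata_error")
})

test_that("balanced selection takes top-positive and top-negative scores", {
  scores <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                           score = c(3, -2, 1, -0.5))
  sel <- select_diagnostic(scores, 2)
  expect_setequal(sel$gene_id, c("a", "b"))
  expect_equal(nrow(select_diagnostic(scores, 4)), 4)
  ## ties break lexicographically, so selection is deterministic
  tied <- tibble::tibble(gene_id = c("z", "y", "x", "w"),
                         score = c(1, 1, -1, -1))
  expect_equal(select_diagnostic(tied, 2)$gene_id, c("y", "w"))
  expect_error(select_diagnostic(scores, 0), class = "pistatus_domain_error")
  expect_error(select_diagnostic(scores, 5), class = "pistatus_domain_error")
})

test_that("kernel values follow their definitions", {
  expect_equal(kernel_value(c(1, 2), c(3, 4), kernel_spec("poly_dot", 1)), 11)
  expect_equal(kernel_value(c(1, 2), c(3, 4), kernel_spec("poly_dot", 2)), 121)
  expect_equal(kernel_value(c(1, 2), c(3, 4), kernel_spec("poly_dot", 3)), 1331)
  for (g in c(0.1, 1, 7)) {
    expect_equal(kernel_value(c(1, 2), c(1, 2), kernel_spec("rbf", gamma = g)), 1)
  }
  expect_equal(kernel_value(0, 1, kernel_spec("rbf", gamma = 2)), exp(-2))
  expect_error(kernel_value(1:2, 1:3, kernel_spec("poly_dot", 1)),
               class = "pistatus_domain_error")
  expect_error(kernel_spec("poly_dot", degree = 4), class = "pistatus_design_error")
  expect_error(kernel_spec("rbf", degree = 2), class = "pistatus_design_error")
  expect_error(parse_kernel("poly9"), class = "pistatus_design_error")
})

test_that("the SVM solves a separable toy in closed form", {
  ## class -1 at x = 0 (twice), class +1 at x = 2 (twice): the maximal
  ## margin solution is w = 1, b = -1
  x <- feature_tbl(matrix(c(0, 0, 2, 2), nrow = 1))
  classes <- c("replete", "replete", "deficient", "deficient")
  fit <- svm_train(x, classes, "poly1")
  pred <- predict_margins(fit, feature_tbl(matrix(c(0, 2, 3), nrow = 1)))
  expect_equal(pred$margin, c(-1, 1, 2), tolerance = 1e-3)
  expect_equal(pred$predicted_class, c("replete", "deficient", "deficient"))
})

test_that("trained models satisfy the KKT conditions", {
  set.seed(7)
  for (kern in c("poly1", "rbf")) {
    x <- feature_tbl(rbind(c(rnorm(10, 0), rnorm(10, 3)),
                           c(rnorm(10, 0), rnorm(10, 3))))
    classes <- rep(c("replete", "deficient"), each = 10)
    fit <- svm_train(x, classes, kern, C = 10)
    expect_true(all(fit$alpha >= -1e-9 & fit$alpha <= 10 + 1e-9))
    expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
    ## support vectors of a separable problem sit on the margin
    m <- predict_margins(fit, x)$margin
    free <- fit$alpha > 1e-6 & fit$alpha < 10 - 1e-6
    expect_true(all(abs(abs(m[free]) - 1) < 1e-3))
    expect_true(all(abs(m[fit$sv_index]) >= 1 - 1e-3))
  }
})

test_that("flipping the labels negates every margin", {
  set.seed(8)
  x <- feature_tbl(matrix(rnorm(3 * 12), nrow = 3))
  classes <- rep(c("replete", "deficient"), 6)
  flipped <- ifelse(classes == "replete", "deficient", "replete")
  test <- feature_tbl(matrix(rnorm(3 * 5), nrow = 3))
  for (kern in c("poly1", "poly3", "rbf")) {
    m1 <- predict_margins(svm_train(x, classes, kern), test)$margin
    m2 <- predict_margins(svm_train(x, flipped, kern), test)$margin
    expect_equal(m1, -m2, tolerance = 1e-6)
  }
})

test_that("margins match an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- feature_tbl(rbind(c(rnorm(8, 0, 1), rnorm(8, 2, 1)),
                         c(rnorm(8, 0, 1), rnorm(8, 1.5, 1))))
  classes <- rep(c("replete", "deficient"), each = 8)
  test <- feature_tbl(matrix(rnorm(2 * 6, 1, 1.5), nrow = 2))
  xt <- t(as.matrix(x[, -1]))
  for (spec in list(kernel_spec("poly_dot", 1),
                    kernel_spec("rbf", gamma = 0.7))) {
    fit <- svm_train(x, classes, spec, C = 1)
    mine <- predict_margins(fit, test)$margin
    ref <- if (spec$family == "poly_dot") {
      e1071::svm(xt, factor(classes, c("deficient", "replete")),
                 kernel = "polynomial", degree = 1, gamma = 1, coef0 = 0,
                 cost = 1, scale = FALSE)
    } else {
      e1071::svm(xt, factor(classes, c("deficient", "replete")),
                 kernel = "radial", gamma = 0.7, cost = 1, scale = FALSE)
    }
    dv <- attr(stats::predict(ref, t(as.matrix(test[, -1])),
                              decision.values = TRUE), "decision.values")
    ## libsvm's positive side is the first class of its internal ordering;
    ## orient by the reported pair label before comparing
    ref_m <- if (startsWith(colnames(dv)[1], "deficient")) {
      dv[, 1]
    } else {
      -dv[, 1]
    }
    expect_equal(mine, unname(ref_m), tolerance = 1e-3)
  }
})

test_that("linear-kernel margins match a brute-force grid-search QP", {
  set.seed(10)
  for (rep in 1:3) {
    n <- sample(4:8, 1)
    xm <- matrix(rnorm(n * 2, 0, 1.5), ncol = 2)
    y <- c(rep(-1, floor(n / 2)), rep(1, ceiling(n / 2)))
    xm[y > 0, ] <- xm[y > 0, ] + 2
    x <- feature_tbl(t(xm))
    classes <- ifelse(y > 0, "deficient", "replete")
    fit <- svm_train(x, classes, "poly1", C = 1)
    oracle <- brute_force_linear_svm(xm, y, C = 1)
    test_m <- matrix(rnorm(10, 1, 2), ncol = 2)
    expect_equal(predict_margins(fit, feature_tbl(t(test_m)))$margin,
                 oracle$margins(test_m), tolerance = 1e-2)
  }
})

test_that("margins transform predictably under feature rescaling", {
  set.seed(11)
  x <- feature_tbl(rbind(c(rnorm(6, 1), rnorm(6, 3)),
                         c(rnorm(6, 1), rnorm(6, 2.5))))
  classes <- rep(c("replete", "deficient"), each = 6)
  test <- feature_tbl(matrix(rnorm(2 * 4, 2), nrow = 2))
  x_scaled <- x
  x_scaled[, -1] <- x[, -1] * 37
  test_scaled <- test
  test_scaled[, -1] <- test[, -1] * 37
  ## with L2 sample normalization margins are exactly scale-invariant
  for (kern in c("poly1", "poly2", "rbf")) {
    m1 <- predict_margins(svm_train(x, classes, kern, normalize = "l2"),
                          test)$margin
    m2 <- predict_margins(svm_train(x_scaled, classes, kern,
                                    normalize = "l2"), test_scaled)$margin
    expect_equal(m1, m2, tolerance = 1e-5)
  }
  ## without normalization, a hard-margin separable linear fit is also
  ## scale-invariant (w rescales by 1/c)
  m1 <- predict_margins(svm_train(x, classes, "poly1", C = 1e4), test)$margin
  m2 <- predict_margins(svm_train(x_scaled, classes, "poly1", C = 1e4),
                        test_scaled)$margin
  expect_equal(m1, m2, tolerance = 1e-3)
})

test_that("fitted models tidy, summarise and serialize faithfully", {
  set.seed(12)
  x <- feature_tbl(matrix(rnorm(4 * 10, 2), nrow = 4))
  classes <- rep(c("replete", "deficient"), 5)
  fit <- svm_train(x, classes, "poly2", C = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$sv_index))
  expect_equal(td$coef, fit$coef)
  gl <- glance(fit)
  expect_equal(gl$kernel, "poly2")
  expect_equal(gl$C, 2)
  path <- tempfile(fileext = ".json")
  write_svm_model(fit, path)
  back <- read_svm_model(path)
  test <- feature_tbl(matrix(rnorm(4 * 3, 2), nrow = 4))
  expect_equal(predict_margins(back, test)$margin,
               predict_margins(fit, test)$margin, tolerance = 1e-10)
  ## prediction on data missing a model gene is an alignment error
  expect_error(predict_margins(fit, test[-1, ]),
               class = "pistatus_alignment_error")
})

test_that("percent correct combines confusion counts to one decimal", {
  expect_equal(percent_correct(5, 7, 10, 8), 60.0)
  expect_equal(percent_correct(0, 0, 15, 15), 100.0)
  expect_equal(percent_correct(15, 15, 0, 0), 0.0)
  expect_equal(percent_correct(6, 2, 9, 13), 73.3)
  expect_error(percent_correct(0, 0, 0, 0), class = "pistatus_domain_error")
  expect_error(percent_correct(-1, 0, 1, 1), class = "pistatus_domain_error")
})

test_that("the evaluation grid is complete, conservative and deterministic", {
  sim <- small_sim(n_genes = 150, seed = 42, frac_responsive = 0.2)
  labels <- build_training_labels(sim$meta)
  train <- prepare_features(sim$raw)
  field <- generate_field_set(sim$truth, 5, attenuation = 0.8,
                              noise_sd = 0.25, seed = 43)
  test <- prepare_features(field$expr)
  sizes <- c(10, 50, 150)
  g1 <- evaluate_grid(train, labels$class, test, field$meta$class, sizes)
  expect_equal(nrow(g1), length(sizes) * 4)
  totals <- rowSums(g1[, c("n_replete_pred_deficient",
                           "n_deficient_pred_replete",
                           "n_replete_pred_replete",
                           "n_deficient_pred_deficient")])
  expect_true(all(totals == 10))
  g2 <- evaluate_grid(train, labels$class, test, field$meta$class, sizes)
  expect_identical(g1, g2)
  expect_error(evaluate_grid(train, labels$class, test, field$meta$class, 151),
               class = "pistatus_domain_error")
})

test_that("margins fade as the deficiency response decays", {
  ## re-supply analogue: planted effect at 100%, 50% and ~0% of full
  ## strength gives strictly decreasing median margins
  sim <- small_sim(n_genes = 500, seed = 44, frac_responsive = 0.1)
  labels <- build_training_labels(sim$meta)
  train <- prepare_features(sim$raw)
  scores <- golub_scores(pistatus:::log2_features(train), labels$class)
  genes <- select_diagnostic(scores, 50)$gene_id
  fit <- svm_train(train[match(genes, train$gene_id), ], labels$class,
                   "poly1", normalize = "l2")
  med <- vapply(c(1, 0.5, 1e-6), function(att) {
    f <- generate_field_set(sim$truth, 10, attenuation = att,
                            noise_sd = 0.2, seed = 45)
    feats <- prepare_features(f$expr)
    m <- predict_margins(fit, feats[match(genes, feats$gene_id), ])
    stats::median(m$margin[f$meta$class == "deficient"])
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
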