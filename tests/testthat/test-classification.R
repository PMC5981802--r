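# Edge vectorization, Lasso selection, RBF kernel, LOOCV pipeline,
# confusion/ROC metrics, discriminative edges, score correlation.

test_that("edge vectorization uses fixed upper-triangle order and inverts exactly", {
  labs3 <- c("a", "b", "c")
  W <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3,
              dimnames = list(labs3, labs3))
  F <- vectorize_edges(list(W, W), c(1, -1))
  expect_equal(ncol(F$X), 3L)
  expect_equal(F$edge_index$region_i, c("a", "a", "b"))
  expect_equal(F$edge_index$region_j, c("b", "c", "c"))
  expect_equal(unname(F$X[1, ]), c(.2, .3, .4))
  expect_equal(devectorize_edges(F$X[1, ], labs3), W)

  # 68 regions give the canonical 2278 edges
  labs <- dk_parcellation()$region_label
  set.seed(71)
  M <- matrix(runif(68 * 68), 68, dimnames = list(labs, labs))
  M <- (M + t(M)) / 2; diag(M) <- 1
  F68 <- vectorize_edges(list(M), NULL)
  expect_equal(ncol(F68$X), 2278L)
  expect_equal(devectorize_edges(F68$X[1, ], labs), M)

  expect_error(vectorize_edges(list(W, M), c(1, -1)), "dimension")
  expect_error(vectorize_edges(list(W, W), c(1, 2)), "labels")
})

test_that("lasso_select solves the L1 objective: soft-threshold, KKT zero, least-squares limit", {
  set.seed(72)
  n <- 30; m <- 30
  X <- qr.Q(qr(matrix(rnorm(n * m), n, m)))
  y <- rnorm(n)
  lam <- 0.25
  fit <- lasso_select(X, y, lam)
  expect_equal(unname(fit$w), soft_threshold_fit(X, y, lam),
               tolerance = 1e-8)
  expect_setequal(fit$selected, which(soft_threshold_fit(X, y, lam) != 0))

  # empty model at and above the critical penalty
  lam_max <- max(abs(crossprod(X, y)))
  expect_length(lasso_select(X, y, lam_max * 1.000001)$selected, 0L)

  # unpenalised limit = least squares
  fit0 <- lasso_select(X, y, 0)
  expect_equal(unname(fit0$w), drop(qr.coef(qr(X), y)), tolerance = 1e-10)

  # support is (weakly) monotone along an increasing penalty path
  Xr <- matrix(rnorm(40 * 25), 40)
  yr <- rnorm(40)
  path <- sort(runif(6, 0.05, 1)) * max(abs(crossprod(Xr, yr)))
  sizes <- vapply(path, function(l) length(lasso_select(Xr, yr, l)$selected),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))

  expect_error(lasso_select(X, y, -1), "lambda_reg")
  expect_error(lasso_select(matrix(c(1, NA), 1), 1, 0.1), "non-finite")
})

test_that("RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 0.5), 1)
  sg <- 1.3
  x1 <- c(0, 0); x2 <- c(sqrt(2) * sg, 0)  # ||x1-x2||^2 = 2 sigma^2
  expect_equal(rbf_kernel(x1, x2, sg), exp(-1))
  set.seed(73)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(rbf_kernel(a, b, 2.2),
               exp(-sum((a - b)^2) / (2 * 2.2^2)), tolerance = 1e-12)
  expect_equal(rbf_kernel(a, b, 2.2), rbf_kernel(b, a, 2.2))
  expect_error(rbf_kernel(a, b, 0), "sigma_rbf")
})

test_that("confusion metrics count the confusion table on the +1 class", {
  expect_equal(confusion_metrics(c(1, -1), c(1, -1)),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  y <- c(rep(1, 4), rep(-1, 4))
  p <- c(1, 1, 1, -1, 1, 1, -1, -1)  # TP=3 FN=1 FP=2 TN=2
  cm <- confusion_metrics(y, p)
  expect_equal(cm$accuracy, 0.625)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.5)
  cm2 <- confusion_metrics(y, rep(1, 8))
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 0)
  expect_warning(confusion_metrics(rep(1, 4), rep(1, 4)), "specificity")
})

test_that("ROC/AUC: sweep curve is valid and AUC equals pair counting", {
  r1 <- roc_auc(c(1, 1, -1, -1), c(5, 4, 2, 1))
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(c(1, 1, -1, -1), c(0.9, 0.4, 0.5, 0.1))
  expect_equal(r2$auc, 3 / 4)

  set.seed(74)
  for (rep in 1:20) {
    y <- sample(c(1, -1), 30, replace = TRUE, prob = c(.5, .5))
    if (length(unique(y)) < 2) next
    s <- rnorm(30) + 0.8 * y
    r <- roc_auc(y, s)
    # curve properties
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    # trapezoid area under the sweep curve equals pair counting
    area <- sum(diff(r$roc$fpr) *
                (head(r$roc$tpr, -1) + r$roc$tpr[-1]) / 2)
    expect_equal(area, r$auc, tolerance = 1e-12)
    # sign flip reverses the AUC
    expect_equal(roc_auc(y, -s)$auc, 1 - r$auc, tolerance = 1e-12)
  }
  expect_warning(rc <- roc_auc(c(1, -1), c(3, 3)), "constant")
  expect_equal(rc$auc, 0.5)
})

make_toy_edge_features <- function(n_per_group, shift, seed) {
  spec <- cohort_spec(V = 14, vertex_count_range = c(12, 24),
                      n_per_group = n_per_group,
                      group_effect = list(regions = 1:3, shift = shift),
                      seed = seed)
  coh <- generate_two_group_cohort(spec, seed = seed)
  nets <- lapply(coh$subjects, build_individual_network,
                 parcellation = spec_parcellation(spec))
  list(F = vectorize_edges(nets, coh$labels), coh = coh)
}

test_that("LOOCV pipeline separates a strong planted effect and records auditable folds", {
  toy <- make_toy_edge_features(8, shift = 2.5, seed = 81)
  rep <- loocv_classify(toy$F, lambda_reg = 0.5, C_grid = c(1, 8),
                        sigma_grid = c(2, 8))
  expect_gte(rep$accuracy, 0.9)
  expect_gte(rep$auc, 0.9)
  expect_length(rep$folds, 16L)
  expect_equal(rep$protocol, "literal")
  expect_true(all(vapply(rep$folds, function(f) length(f$selected) > 0,
                         logical(1))))
  # deterministic re-run
  rep2 <- loocv_classify(toy$F, lambda_reg = 0.5, C_grid = c(1, 8),
                         sigma_grid = c(2, 8))
  expect_equal(rep2$accuracy, rep$accuracy)
  expect_equal(vapply(rep2$folds, `[[`, numeric(1), "decision_value"),
               vapply(rep$folds, `[[`, numeric(1), "decision_value"))
  Fsmall <- toy$F
  Fsmall$X <- Fsmall$X[c(1, 2, 9), ]
  Fsmall$y <- Fsmall$y[c(1, 2, 9)]
  expect_error(loocv_classify(Fsmall), "subjects")
})

test_that("fold construction does not leak the held-out subject", {
  toy <- make_toy_edge_features(5, shift = 2, seed = 82)
  F <- toy$F
  rep <- loocv_classify(F, lambda_reg = 0.5, C_grid = 4, sigma_grid = 4)
  # corrupting the held-out row's features must not change that fold's
  # training-side selection
  i <- 3L
  F2 <- F
  set.seed(99)
  F2$X[i, ] <- F2$X[i, ] + rnorm(ncol(F2$X))
  rep2 <- loocv_classify(F2, lambda_reg = 0.5, C_grid = 4, sigma_grid = 4)
  expect_identical(rep$folds[[i]]$selected, rep2$folds[[i]]$selected)
})

test_that("accuracy increases with planted effect size", {
  accs <- vapply(c(0.3, 1.2, 3), function(shift)
    loocv_classify(make_toy_edge_features(6, shift, seed = 83)$F,
                   lambda_reg = 0.6, C_grid = 4, sigma_grid = 4)$accuracy,
    numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("discriminative edges are the strict intersection over folds with hemisphere tags", {
  report <- list(
    folds = list(list(selected = c(1L, 2L, 5L)),
                 list(selected = c(1L, 5L, 9L)),
                 list(selected = c(5L, 1L))),
    edge_index = data.frame(position = 1:10,
                            i = rep(1:4, length.out = 10),
                            j = rep(2:5, length.out = 10),
                            region_i = rep(c("lh_a", "rh_b"), 5),
                            region_j = rep(c("lh_c", "rh_d", "lh_a", "rh_b"),
                                           length.out = 10)))
  parc <- toy_parcellation(4, c("lh_a", "rh_b", "lh_c", "rh_d"))
  parc$hemisphere <- c("L", "R", "L", "R")
  de <- discriminative_edges(report, parc)
  expect_setequal(de$position, c(1L, 5L))  # edge 2 dropped: missed one fold
  expect_true(all(de$hemisphere_tag %in% c("intra-L", "intra-R", "inter")))
  expect_equal(sum(attr(de, "counts")), nrow(de))
})

test_that("edge-score correlations flag p < 0.05 and skip degenerate inputs", {
  toy <- make_toy_edge_features(6, shift = 0, seed = 84)
  F <- toy$F
  # score equal to an edge's values correlates perfectly
  res <- correlate_edges_with_scores(F, c(3L, 7L), F$X[, 3])
  expect_equal(res$r[res$position == 3], 1, tolerance = 1e-12)
  expect_true(res$significant[res$position == 3])

  # constant score: all skipped
  resc <- correlate_edges_with_scores(F, 1:5, rep(2, nrow(F$X)))
  expect_true(all(resc$skipped))

  # independent score: about 5% of edges flagged
  set.seed(85)
  score <- rnorm(nrow(F$X))
  resn <- correlate_edges_with_scores(F, seq_len(ncol(F$X)), score)
  frac <- mean(resn$significant, na.rm = TRUE)
  expect_lt(frac, 0.15)

  expect_error(correlate_edges_with_scores(F, 1:2, 1:3), "align")
})
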