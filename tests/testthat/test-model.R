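# well-separated two-cluster kernel: positives near e1, negatives near e2
separable_kernel <- function(n_pos = 20, n_neg = 20, noise = 0.05, seed = 1) {
  set.seed(seed)
  x <- rbind(cbind(1, matrix(rnorm(n_pos * 2, sd = noise), n_pos)),
             cbind(matrix(rnorm(n_neg, sd = noise), n_neg), 1,
                   matrix(rnorm(n_neg, sd = noise), n_neg)))
  K <- tcrossprod(x)
  K <- K / sqrt(outer(diag(K), diag(K)))
  list(K = K, labels = c(rep(1, n_pos), rep(-1, n_neg)), x = x)
}

test_that("the SVM separates a separable toy and is deterministic", {
  toy <- separable_kernel()
  m <- train_svm(toy$K, toy$labels, seed = 5)
  pred <- predict(m, toy$K)
  expect_equal(sign(pred$decision_value), toy$labels)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  # calibrated probability strictly increasing in decision value
  ord <- order(pred$decision_value)
  expect_true(all(diff(pred$probability[ord]) > 0))
  # retrain with the same seed: identical coefficients
  m2 <- train_svm(toy$K, toy$labels, seed = 5)
  expect_identical(m$coef, m2$coef)
  expect_identical(m$bias, m2$bias)
  # duplicate input rows give identical outputs
  rows <- toy$K[c(1, 1, 7, 7), , drop = FALSE]
  p2 <- predict(m, rows)
  expect_equal(p2[1, ], p2[2, ], ignore_attr = TRUE)
  expect_error(train_svm(toy$K, rep(1, nrow(toy$K))), "both classes")
})

test_that("precomputed-kernel and sparse-feature training routes agree", {
  set.seed(23)
  # sparse non-negative feature vectors, unit-normalized: their linear
  # kernel is exactly the normalized pair kernel
  n <- 60; d <- 300
  X <- Matrix::sparseMatrix(
    i = unlist(lapply(1:n, function(j) sample(d, 12))),
    j = rep(1:n, each = 12), x = 1, dims = c(d, n))
  lab <- rep(c(1, -1), each = n / 2)
  X[1:4, lab == 1] <- X[1:4, lab == 1] + 2
  X <- X %*% Matrix::Diagonal(x = 1 / sqrt(Matrix::colSums(X^2)))
  K <- as.matrix(Matrix::crossprod(X))
  m_kern <- train_svm(K, lab, seed = 1, tolerance = 1e-7)
  m_feat <- kernppi:::train_svm_sparse(Matrix::t(X), lab, seed = 1,
                                       tolerance = 1e-7)
  d_kern <- predict(m_kern, K)$decision_value
  d_feat <- predict(m_feat, K)$decision_value
  expect_equal(d_kern, d_feat, tolerance = 1e-6)
})

test_that("binomial error matches both closed forms", {
  expect_equal(binomial_error(0.5, 100, "as_printed"), 25)
  expect_equal(binomial_error(0.5, 100, "standard_error"), 0.05)
  expect_equal(binomial_error(0, 10, "as_printed"), 0)
  expect_equal(binomial_error(1, 10, "as_printed"), 0)
  expect_equal(binomial_error(0, 10, "standard_error"), 0)
  expect_equal(binomial_error(1, 10, "standard_error"), 0)
  expect_error(binomial_error(1.2, 10), "\\[0, 1\\]")
})

test_that("precision-recall curves follow the smallest-set definition", {
  # perfect ranking: precision 1 everywhere
  pc <- pr_curve(c(9, 8, 7, 1, 2), c(1, 1, 1, -1, -1))
  expect_equal(pc$precision, rep(1, 100))
  # hand-enumerated: scores .9 (+), .8 (-), .3 (+)
  pc <- pr_curve(c(0.9, 0.8, 0.3), c(1, -1, 1))
  expect_equal(pc$precision[pc$recall == 0.5], 1)
  expect_equal(pc$precision[pc$recall == 1.0], 2 / 3)
  expect_equal(pc$precision[pc$recall == 0.51], 2 / 3)
  # full-recall precision: bounded below by prevalence (the smallest full-
  # recall set drops trailing negatives), and close to it for random scores
  set.seed(24)
  for (i in 1:5) {
    n <- 220
    lab <- ifelse(runif(n) < 1 / 11, 1, -1)
    if (!any(lab == 1)) lab[1] <- 1
    pc <- pr_curve(runif(n), lab)
    expect_gte(pc$precision[100], mean(lab == 1))
    expect_equal(pc$precision[100], mean(lab == 1), tolerance = 0.25)
  }
  expect_error(pr_curve(1:3, c(-1, -1, -1)), "no positive")
})

test_that("random scores at 10:1 sampling hit the prevalence baseline", {
  set.seed(25)
  n <- 2200
  lab <- c(rep(1, 200), rep(-1, 2000))
  pc <- pr_curve(runif(n), lab, error = "standard_error")
  p_full <- pc$precision[100]
  sd_full <- binomial_error(1 / 11, n, "standard_error")
  expect_lt(abs(p_full - 1 / 11), 3 * sd_full)
})

test_that("the selection statistic averages early-recall precision", {
  curve <- structure(data.frame(recall = seq(0.01, 1, 0.01),
                                precision = 0.8, error = NA,
                                n_predictions = 1),
                     class = c("pr_curve", "data.frame"))
  expect_equal(selection_statistic(curve), 0.8)
  curve$precision <- c(1.0, 0.6, rep(0.1, 98))
  expect_equal(selection_statistic(curve, max_recall = 0.02), 0.8)
  # on a non-increasing curve the statistic cannot grow with the limit
  curve$precision <- sort(runif(100), decreasing = TRUE)
  stats <- vapply(c(0.1, 0.2, 0.5, 1), function(mr)
    selection_statistic(curve, mr), numeric(1))
  expect_true(all(diff(stats) <= 1e-12))
  expect_error(selection_statistic(curve, max_recall = 0.001), "no grid")
})

test_that("fold curves aggregate to mean and sd per recall point", {
  c1 <- pr_curve(c(3, 2, 1), c(1, 1, -1))
  c2 <- pr_curve(c(3, 1, 2), c(1, 1, -1))
  agg <- aggregate_pr_curves(list(c1, c2))
  expect_equal(agg$precision, (c1$precision + c2$precision) / 2)
  expect_equal(agg$error,
               apply(cbind(c1$precision, c2$precision), 1, sd))
})

test_that("cross-validation runs the full protocol and recovers signal", {
  set.seed(26)
  spec <- synthetic_spec(n_proteins = 70, len_range = c(60, 90),
                         n_positive = 12, motif_length = 3,
                         n_motif_pairs = 1, fraction_failing = 0, seed = 26)
  org <- simulate_organism(spec)
  pos <- org$interactions[, c("id_a", "id_b")]
  cv <- cross_validate(pos, org$proteome, org$profiles,
                       kernel_hyperparams(3, 4), folds = 3, repetitions = 2,
                       seed = 99)
  expect_equal(cv$n_models, 6)
  expect_length(cv$fold_curves, 6)
  expect_s3_class(cv$curve, "pr_curve")
  expect_true(all(cv$curve$precision >= 0 & cv$curve$precision <= 1))
  # planted shared motif is learnable: early precision beats prevalence
  expect_gt(selection_statistic(cv$curve), 2 * (1 / 11))
  # reproducible from the seed
  cv2 <- cross_validate(pos, org$proteome, org$profiles,
                        kernel_hyperparams(3, 4), folds = 3, repetitions = 2,
                        seed = 99)
  expect_equal(cv$curve, cv2$curve)
  expect_error(cross_validate(pos[1:2, ], org$proteome, org$profiles,
                              kernel_hyperparams(3, 4), folds = 5,
                              repetitions = 1, seed = 1),
               "fewer positives")
})

test_that("grid search picks the best combination with deterministic ties", {
  set.seed(27)
  spec <- synthetic_spec(n_proteins = 80, len_range = c(60, 90),
                         n_positive = 18, motif_length = 3,
                         n_motif_pairs = 1, fraction_failing = 0, seed = 27)
  org <- simulate_organism(spec)
  pos <- org$interactions[, c("id_a", "id_b")]
  # tiers below the grid-search cut are rejected with guidance
  expect_error(grid_search(pos, org$proteome, org$profiles,
                           tier = "fixed_hyperparams"),
               "cross_validate")
  gs <- grid_search(pos, org$proteome, org$profiles,
                    grid = expand.grid(k = c(3, 4), sigma = 4),
                    folds = 3, repetitions = 1, seed = 7,
                    tier = "grid_search")
  expect_equal(nrow(gs$report), 2)
  best <- gs$report[order(-gs$report$statistic,
                          gs$report$k, gs$report$sigma)[1], ]
  expect_equal(gs$chosen$k, best$k)
  expect_equal(gs$chosen$sigma, best$sigma)
  expect_s3_class(gs$final_model, "pair_kernel_model")
  expect_s3_class(gs$holdout_curve, "pr_curve")
  # hold-out errors are binomial standard errors (finite, non-negative)
  expect_true(all(gs$holdout_curve$error >= 0))
})

test_that("the default grid spans 4 k values by 8 sigma values", {
  g <- default_grid()
  expect_equal(nrow(g), 32)
  expect_setequal(unique(g$k), 3:6)
  expect_setequal(unique(g$sigma), 4:11)
})
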