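#' Train a pair-kernel SVM
#'
#' Fits a soft-margin C-SVM on a precomputed normalized pair-kernel matrix,
#' then fits a Platt-style sigmoid
#' \eqn{P(y = 1 \mid f) = 1 / (1 + e^{A f + B})} on the training decision
#' values with the usual smoothed targets, so the model outputs calibrated
#' probabilities. Decision values are oriented so that larger means more
#' likely to interact.
#'
#' Internally the kernel is factorized by symmetric eigendecomposition
#' (\eqn{K = F F^\top}, negative eigenvalues clipped at zero) and a linear
#' SVM is fitted on the rows of \eqn{F} with libsvm — an exact reformulation
#' of the precomputed-kernel problem that uses a well-tested optimizer.
#'
#' @param K Symmetric normalized kernel matrix over the training pairs.
#' @param labels Vector in \{-1, +1\}, both classes present.
#' @param C Soft-margin cost (default 1 on the normalized kernel).
#' @param seed Integer seed, stored with the model.
#' @param hp \code{\link{kernel_hyperparams}} used to build \code{K}.
#' @param pair_ids Optional data frame (\code{id_a}, \code{id_b}) of training
#'   pairs, stored for bookkeeping.
#' @param tolerance Termination tolerance of the SVM optimizer.
#' @return An object of class \code{pair_kernel_model} with support indices,
#'   signed support coefficients, bias, calibration parameters and metadata.
#'   Predictions are reproducible from this state alone.
#' @export
train_svm <- function(K, labels, C = 1, seed = 1,
                      hp = kernel_hyperparams(), pair_ids = NULL,
                      tolerance = 0.001) {
  stopifnot(nrow(K) == ncol(K), length(labels) == nrow(K))
  if (length(unique(labels)) < 2)
    stop("training labels must contain both classes")
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  set.seed(seed)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-6)
    warning("kernel matrix has eigenvalue ", min(eig$values),
            "; clipping to zero")
  F <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow(K))
  y <- factor(labels, levels = c(-1, 1))
  fit <- e1071::svm(F, y, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  svi <- fit$index
  cf <- as.vector(fit$coefs)
  b <- fit$rho
  dec <- as.vector(K[, svi, drop = FALSE] %*% cf) - b
  # libsvm's sign convention depends on which class it saw first; orient so
  # that positives score high.
  if (mean(dec[labels == 1]) < mean(dec[labels == -1])) {
    cf <- -cf
    b <- -b
    dec <- -dec
  }
  platt <- fit_platt(dec, labels)
  new_pair_kernel_model(svi, cf, b, platt, hp, C, seed, nrow(K), pair_ids)
}

new_pair_kernel_model <- function(svi, cf, b, platt, hp, C, seed, n_train,
                                  pair_ids) {
  structure(list(sv_index = svi, coef = cf, bias = b,
                 platt_a = platt[1], platt_b = platt[2],
                 hp = hp, C = C, seed = seed,
                 n_train = n_train,
                 pair_ids = pair_ids,
                 protein_ids = if (!is.null(pair_ids))
                   sort(unique(c(pair_ids$id_a, pair_ids$id_b))) else NULL),
            class = "pair_kernel_model")
}

# Equivalent training route on explicit pair features: because the
# normalized pair kernel is exactly the linear kernel on L2-normalized
# sparse pair vectors, a linear SVM on those vectors (libsvm via e1071)
# yields the same decision function as train_svm() on the precomputed
# kernel, and scales much better when the kernel is close to diagonal.
# X: pairs x k-mers sparse matrix with unit-norm rows.
train_svm_sparse <- function(X, labels, C = 1, seed = 1,
                             hp = kernel_hyperparams(), pair_ids = NULL,
                             tolerance = 0.001) {
  if (length(unique(labels)) < 2)
    stop("training labels must contain both classes")
  set.seed(seed)
  y <- factor(labels, levels = c(-1, 1))
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  svi <- fit$index
  cf <- as.vector(fit$coefs)
  b <- fit$rho
  dec <- as.vector(X %*% Matrix::t(X[svi, , drop = FALSE]) %*% cf) - b
  if (mean(dec[labels == 1]) < mean(dec[labels == -1])) {
    cf <- -cf
    b <- -b
    dec <- -dec
  }
  platt <- fit_platt(dec, labels)
  new_pair_kernel_model(svi, cf, b, platt, hp, C, seed, nrow(X), pair_ids)
}

# Sparse matrix of L2-normalized pair vectors (pairs x k-mers) from a
# normalized protein feature matrix M (k-mers x proteins).
pair_feature_matrix <- function(M, pairs) {
  P <- M[, pairs$id_a, drop = FALSE] + M[, pairs$id_b, drop = FALSE]
  nrm <- sqrt(Matrix::colSums(P^2))
  Matrix::t(P %*% Matrix::Diagonal(x = 1 / nrm))
}

# Platt sigmoid fit: minimize the calibrated NLL with smoothed targets
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2); returns c(A, B).
fit_platt <- function(dec, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == -1)
  t <- ifelse(labels == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * dec + par[2]
    sum(t * z + log1pexp(-z))
  }
  start <- c(-1, log((nn + 1) / (np + 1)))
  fit <- stats::optim(start, nll, method = "BFGS")
  fit$par
}

# Calibrated probability, clamped strictly inside (0, 1).
platt_probability <- function(model, dec) {
  p <- stats::plogis(-(model$platt_a * dec + model$platt_b))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Predict from a pair-kernel SVM
#'
#' @param object A \code{pair_kernel_model}.
#' @param kernel_rows Matrix of normalized kernel values between the new
#'   pairs (rows) and the training pairs (columns, in training order).
#' @param ... Ignored.
#' @return Data frame with \code{decision_value} and calibrated
#'   \code{probability}.
#' @export
predict.pair_kernel_model <- function(object, kernel_rows, ...) {
  kernel_rows <- as.matrix(kernel_rows)
  if (ncol(kernel_rows) != object$n_train)
    stop("kernel rows have ", ncol(kernel_rows), " columns; model was trained",
         " on ", object$n_train, " pairs")
  dec <- as.vector(kernel_rows[, object$sv_index, drop = FALSE] %*%
                     object$coef) - object$bias
  data.frame(decision_value = dec,
             probability = platt_probability(object, dec))
}

#' Binomial precision error
#'
#' Error bar attached to a hold-out precision estimate. Mode
#' \code{"as_printed"} is the literal count-scaled form \eqn{e = n\,p(1-p)};
#' mode \code{"standard_error"} is the binomial standard error
#' \eqn{\sqrt{p(1-p)/n}} and is the default for plots (see the methods
#' vignette for why both are provided).
#'
#' @param p Precision in [0, 1].
#' @param n Number of predictions at that point (>= 1).
#' @param mode \code{"standard_error"} or \code{"as_printed"}.
#' @return The error value (vectorized).
#' @export
binomial_error <- function(p, n, mode = c("standard_error", "as_printed")) {
  mode <- match.arg(mode)
  if (any(p < 0 | p > 1)) stop("precision must lie in [0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  switch(mode,
         as_printed = n * p * (1 - p),
         standard_error = sqrt(p * (1 - p) / n))
}

#' Precision-recall curve on a fixed recall grid
#'
#' Thresholds are swept from the highest score downwards; at each grid recall
#' the precision of the smallest prediction set achieving at least that
#' recall is reported (so with a perfect ranking the curve is 1 everywhere,
#' and at full recall the set ends at the lowest-ranked positive, making the
#' precision at least the positive prevalence and equal to it once trailing
#' negatives are included). Ties in score are broken by input order
#' (deterministic).
#'
#' @param scores Numeric prediction scores (finite).
#' @param labels Vector in \{-1, +1\} (or logical), at least one positive.
#' @param recall_grid Increasing recalls in (0, 1]; default 100 evenly spaced
#'   points 0.01..1.
#' @param error \code{"none"} (errors filled with NA; used inside
#'   cross-validation where the spread across folds is the error),
#'   \code{"standard_error"} or \code{"as_printed"} (binomial, for single
#'   hold-out curves).
#' @return Data frame of class \code{pr_curve} with columns \code{recall},
#'   \code{precision}, \code{error}, \code{n_predictions}.
#' @export
pr_curve <- function(scores, labels,
                     recall_grid = seq(0.01, 1, by = 0.01),
                     error = c("none", "standard_error", "as_printed")) {
  error <- match.arg(error)
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  P <- sum(labels == 1)
  if (P == 0) stop("no positive labels")
  if (is.unsorted(recall_grid, strictly = TRUE) ||
      any(recall_grid <= 0 | recall_grid > 1))
    stop("recall grid must be strictly increasing within (0, 1]")
  ord <- order(-scores)
  cpos <- cumsum(labels[ord] == 1)
  need <- pmax(1L, ceiling(recall_grid * P - 1e-9))
  n_at <- findInterval(need - 0.5, cpos) + 1L
  precision <- cpos[n_at] / n_at
  err <- switch(error,
                none = rep(NA_real_, length(recall_grid)),
                binomial_error(precision, n_at, error))
  structure(data.frame(recall = recall_grid, precision = precision,
                       error = err, n_predictions = n_at),
            class = c("pr_curve", "data.frame"))
}

#' Aggregate fold-level precision-recall curves
#'
#' Mean and standard deviation of precision across curves at each grid
#' recall, as used to summarize repeated cross-validation.
#'
#' @param curves List of \code{\link{pr_curve}} results on a common grid.
#' @return Data frame of class \code{pr_curve} with columns \code{recall},
#'   \code{precision} (mean), \code{error} (sd across curves),
#'   \code{n_predictions} (mean).
#' @export
aggregate_pr_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$recall
  for (cv in curves) stopifnot(identical(cv$recall, grid))
  prec <- sapply(curves, `[[`, "precision")
  npred <- sapply(curves, `[[`, "n_predictions")
  if (length(curves) == 1) prec <- cbind(prec)
  structure(data.frame(recall = grid,
                       precision = rowMeans(prec),
                       error = apply(prec, 1, stats::sd),
                       n_predictions = rowMeans(cbind(npred))),
            class = c("pr_curve", "data.frame"))
}

#' Model-selection statistic: mean precision up to a recall limit
#'
#' Condenses a precision-recall curve into one number by averaging the (mean)
#' precision over all grid points with recall at or below \code{max_recall}.
#'
#' @param curve A \code{\link{pr_curve}}.
#' @param max_recall Recall limit (default 0.2).
#' @return The mean precision over the early-recall grid points.
#' @export
selection_statistic <- function(curve, max_recall = 0.2) {
  sel <- curve$recall <= max_recall + 1e-12
  if (!any(sel)) stop("no grid points with recall <= ", max_recall)
  mean(curve$precision[sel])
}

# Shared kernel precomputation over a fixed protein set: k-mer features, the
# normalized sparse feature matrix M (k-mers x proteins) and the protein
# gram G = M'M.
build_kernel_state <- function(profiles, protein_ids, hp) {
  feats <- lapply(profiles[protein_ids], kmer_features, hp = hp)
  names(feats) <- protein_ids
  M <- feature_matrix(feats)
  G <- as.matrix(Matrix::crossprod(M))
  dimnames(G) <- list(protein_ids, protein_ids)
  list(features = feats, M = M, G = G)
}

#' Repeated cross-validation of a profile-kernel PPI model
#'
#' The protocol: per repetition, positives are split into \code{folds}
#' groups and a fresh negative set is sampled (10 per positive by default,
#' each negative protein dissimilar to every positive-set protein); per fold,
#' an SVM is trained on the remaining folds and scored on the held-out fold;
#' all \code{folds x repetitions} fold curves are aggregated into a mean
#' precision with a standard deviation per recall point. Because the
#' positives are redundancy-reduced, no protein similar to a held-out
#' positive's proteins can occur in the training positives; this is asserted
#' at run time.
#'
#' @param positives Redundancy-reduced positive interactions (\code{id_a},
#'   \code{id_b}).
#' @param proteome Data frame (\code{id}, \code{sequence}).
#' @param profiles Named list of \code{aa_profile} covering the proteome, as
#'   from \code{\link{load_profiles}}.
#' @param hp \code{\link{kernel_hyperparams}}.
#' @param folds Number of folds (default 5).
#' @param repetitions Full restarts, each with fresh fold split and fresh
#'   negatives (default 5).
#' @param seed Master seed; all sub-streams derive from it.
#' @param sampling \code{\link{sampling_config}} (its seed field is ignored;
#'   per-repetition seeds derive from \code{seed}).
#' @param C SVM cost.
#' @param recall_grid Grid for \code{\link{pr_curve}}.
#' @param cache Optional \code{\link{hval_cache}} shared across repetitions.
#' @return List of class \code{cv_result}: \code{curve} (aggregated
#'   \code{pr_curve}), \code{fold_curves}, \code{n_models}, \code{hp},
#'   \code{seed}.
#' @export
cross_validate <- function(positives, proteome, profiles, hp,
                           folds = 5, repetitions = 5, seed = 1,
                           sampling = sampling_config(), C = 1,
                           recall_grid = seq(0.01, 1, by = 0.01),
                           cache = NULL) {
  stopifnot(folds >= 2)
  if (nrow(positives) < folds)
    stop("fewer positives (", nrow(positives), ") than folds (", folds, ")")
  if (is.null(cache)) cache <- hval_cache()
  pos_prot <- c(positives$id_a, positives$id_b)
  if (anyDuplicated(pos_prot))
    stop("positives share proteins; redundancy-reduce before cross-validation")
  set.seed(seed)
  rep_seeds <- sample.int(2^30, repetitions)
  # Eligibility and the protein-level gram depend only on the positive set
  # and hp, so compute them once; negatives drawn later reuse the cache.
  pos_ids <- sort(unique(pos_prot))
  seqs <- stats::setNames(proteome$sequence, proteome$id)
  pool <- eligible_proteins(proteome, pos_ids, seqs[pos_ids],
                            sampling$hval_similar_cut, cache)
  ks <- build_kernel_state(profiles, sort(unique(c(pos_ids, pool))), hp)
  G <- ks$G
  fold_curves <- list()
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    neg_cfg <- sampling_config(sampling$negative_ratio,
                               sampling$hval_similar_cut,
                               seed = rep_seeds[r])
    negatives <- sample_negatives(positives, proteome, neg_cfg, cache)
    pairs <- rbind(positives[, c("id_a", "id_b")],
                   negatives[, c("id_a", "id_b")])
    labels <- c(rep(1, nrow(positives)), rep(-1, nrow(negatives)))
    self_k <- pair_self_kernel(G, pairs)
    K <- pair_kernel_block(G, pairs, pairs, self_k, self_k)
    P <- pair_feature_matrix(ks$M, pairs)
    fold_of_pos <- sample(rep(seq_len(folds), length.out = nrow(positives)))
    fold_of_neg <- sample(rep(seq_len(folds), length.out = nrow(negatives)))
    fold_of <- c(fold_of_pos, fold_of_neg)
    for (f in seq_len(folds)) {
      te <- which(fold_of == f)
      tr <- which(fold_of != f)
      # no protein of a held-out positive may occur in a training positive
      te_pos <- intersect(te, seq_len(nrow(positives)))
      tr_pos <- intersect(tr, seq_len(nrow(positives)))
      shared <- intersect(c(pairs$id_a[te_pos], pairs$id_b[te_pos]),
                          c(pairs$id_a[tr_pos], pairs$id_b[tr_pos]))
      stopifnot(length(shared) == 0)
      m <- train_svm_sparse(P[tr, , drop = FALSE], labels[tr], C = C,
                            seed = rep_seeds[r] + f, hp = hp,
                            pair_ids = pairs[tr, , drop = FALSE])
      pred <- predict(m, K[te, tr, drop = FALSE])
      fold_curves[[length(fold_curves) + 1]] <-
        pr_curve(pred$decision_value, labels[te], recall_grid, error = "none")
    }
  }
  structure(list(curve = aggregate_pr_curves(fold_curves),
                 fold_curves = fold_curves,
                 n_models = folds * repetitions,
                 hp = hp, folds = folds, repetitions = repetitions,
                 seed = seed),
            class = "cv_result")
}

#' Hyperparameter grid search with held-out evaluation
#'
#' For organisms with enough non-redundant positives: positives are split
#' two-thirds / one-third (seeded); every (k, sigma) combination is scored by
#' repeated cross-validation on the training two-thirds using the
#' early-recall mean-precision statistic; the winner (ties to smaller k, then
#' smaller sigma) is retrained on the full training split and evaluated once
#' on the held-out third.
#'
#' @inheritParams cross_validate
#' @param grid Data frame of \code{k}, \code{sigma} combinations (default
#'   \code{\link{default_grid}}).
#' @param config \code{\link{curation_config}} supplying the tier thresholds.
#' @param tier Tier of this data set from
#'   \code{\link{select_model_organisms}}; only \code{"grid_search"} is
#'   accepted.
#' @return List of class \code{grid_search_result}: \code{report} (one row
#'   per combination with its selection statistic), \code{chosen} (hp),
#'   \code{cv_results}, \code{final_model}, \code{holdout_curve},
#'   \code{holdout_statistic}.
#' @export
grid_search <- function(positives, proteome, profiles,
                        grid = default_grid(), folds = 5, repetitions = 5,
                        seed = 1, sampling = sampling_config(), C = 1,
                        recall_grid = seq(0.01, 1, by = 0.01),
                        config = curation_config(),
                        tier = select_model_organisms(
                          stats::setNames(nrow(positives), "this"),
                          config)[[1]],
                        cache = NULL) {
  if (!identical(tier, "grid_search"))
    stop("data set tier is '", tier, "', not 'grid_search'; use ",
         "cross_validate() with the fixed default hyperparameters ",
         "(k = 5, sigma = 11)")
  if (is.null(cache)) cache <- hval_cache()
  set.seed(seed)
  n <- nrow(positives)
  train_idx <- sort(sample(n, round(2 * n / 3)))
  test_idx <- setdiff(seq_len(n), train_idx)
  train_pos <- positives[train_idx, , drop = FALSE]
  test_pos <- positives[test_idx, , drop = FALSE]
  cv_results <- vector("list", nrow(grid))
  stat <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- kernel_hyperparams(grid$k[g], grid$sigma[g])
    cv_results[[g]] <- cross_validate(train_pos, proteome, profiles, hp,
                                      folds, repetitions, seed = seed + g,
                                      sampling = sampling, C = C,
                                      recall_grid = recall_grid,
                                      cache = cache)
    stat[g] <- selection_statistic(cv_results[[g]]$curve)
  }
  ord <- order(-stat, grid$k, grid$sigma)
  best <- ord[1]
  chosen <- kernel_hyperparams(grid$k[best], grid$sigma[best])
  final <- fit_final_model(train_pos, proteome, profiles, chosen,
                           seed = seed, sampling = sampling, C = C,
                           cache = cache)
  holdout <- evaluate_holdout(final, test_pos, proteome, profiles,
                              seed = seed + 10000L, sampling = sampling,
                              recall_grid = recall_grid, cache = cache)
  structure(list(report = cbind(grid, statistic = stat),
                 chosen = chosen,
                 cv_results = cv_results,
                 final_model = final,
                 holdout_curve = holdout,
                 holdout_statistic = selection_statistic(holdout)),
            class = "grid_search_result")
}

#' Train the final model on a full positive set
#'
#' Samples negatives against the full positive set, builds the pair kernel
#' and trains one SVM. The returned model carries the normalized per-protein
#' feature vectors and pair self-kernels needed to score new pairs.
#'
#' @inheritParams cross_validate
#' @return A \code{pair_kernel_model} with kernel state attached
#'   (\code{train_features}, \code{train_self_kernel}, \code{train_pairs}).
#' @export
fit_final_model <- function(positives, proteome, profiles, hp, seed = 1,
                            sampling = sampling_config(), C = 1,
                            cache = NULL) {
  if (is.null(cache)) cache <- hval_cache()
  neg_cfg <- sampling_config(sampling$negative_ratio,
                             sampling$hval_similar_cut, seed = seed)
  negatives <- sample_negatives(positives, proteome, neg_cfg, cache)
  pairs <- rbind(positives[, c("id_a", "id_b")],
                 negatives[, c("id_a", "id_b")])
  labels <- c(rep(1, nrow(positives)), rep(-1, nrow(negatives)))
  ids <- sort(unique(c(pairs$id_a, pairs$id_b)))
  ks <- build_kernel_state(profiles, ids, hp)
  self_k <- pair_self_kernel(ks$G, pairs)
  P <- pair_feature_matrix(ks$M, pairs)
  m <- train_svm_sparse(P, labels, C = C, seed = seed, hp = hp,
                        pair_ids = pairs)
  m$train_features <- ks$features
  m$train_self_kernel <- self_k
  m$train_pairs <- pairs
  m
}

# Score new pairs against a final model: kernel rows from the cross-gram
# between new-pair proteins and the model's training proteins.
score_pairs <- function(model, pairs, profiles) {
  ids <- sort(unique(c(pairs$id_a, pairs$id_b)))
  feats <- lapply(profiles[ids], kmer_features, hp = model$hp)
  names(feats) <- ids
  G_nn <- protein_gram(feats)
  G_nt <- protein_cross_gram(feats, model$train_features)
  self_new <- pair_self_kernel(G_nn, pairs)
  raw <- G_nt[pairs$id_a, model$train_pairs$id_a, drop = FALSE] +
         G_nt[pairs$id_a, model$train_pairs$id_b, drop = FALSE] +
         G_nt[pairs$id_b, model$train_pairs$id_a, drop = FALSE] +
         G_nt[pairs$id_b, model$train_pairs$id_b, drop = FALSE]
  K <- raw / outer(sqrt(self_new), sqrt(model$train_self_kernel))
  predict(model, K)
}

# Hold-out evaluation of a final model: fresh negatives for the held-out
# positives, scored in one batch.
evaluate_holdout <- function(model, test_pos, proteome, profiles, seed,
                             sampling = sampling_config(),
                             recall_grid = seq(0.01, 1, by = 0.01),
                             cache = NULL) {
  neg_cfg <- sampling_config(sampling$negative_ratio,
                             sampling$hval_similar_cut, seed = seed)
  negatives <- sample_negatives(test_pos, proteome, neg_cfg, cache)
  pairs <- rbind(test_pos[, c("id_a", "id_b")],
                 negatives[, c("id_a", "id_b")])
  labels <- c(rep(1, nrow(test_pos)), rep(-1, nrow(negatives)))
  pred <- score_pairs(model, pairs, profiles)
  pr_curve(pred$decision_value, labels, recall_grid,
           error = "standard_error")
}
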