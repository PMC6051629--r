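#' Number of unordered pairs among n proteins
#' @param n Number of proteins.
#' @return \code{n (n - 1) / 2}, as a double to avoid integer overflow.
#' @export
candidate_pair_count <- function(n) as.numeric(n) * (n - 1) / 2

#' Enumerate interactome candidate proteins and pairs
#'
#' Eligible proteins are those whose HVAL stays strictly below
#' \code{hval_cut} against every protein of the positive training set, i.e.
#' proteins for which no homology shortcut to the training data exists. The
#' candidate pairs are all unordered pairs of eligible proteins; the pair set
#' itself is never materialized here, only counted.
#'
#' @param proteome Data frame (\code{id}, \code{sequence}).
#' @param positive_proteins Data frame (\code{id}, \code{sequence}) of the
#'   positive-set proteins, or a character vector of ids resolved against
#'   \code{proteome}.
#' @param hval_cut Similarity cut (default 20).
#' @param cache Optional \code{\link{hval_cache}}.
#' @return List of class \code{candidate_set}: \code{eligible} (ids),
#'   \code{n_pairs}, \code{excluded} (named character vector id -> reason).
#' @export
candidate_pairs <- function(proteome, positive_proteins, hval_cut = 20,
                            cache = NULL) {
  stopifnot(nrow(proteome) >= 1)
  if (is.character(positive_proteins)) {
    idx <- match(positive_proteins, proteome$id)
    if (anyNA(idx)) stop("positive protein id(s) missing from proteome")
    positive_proteins <- proteome[idx, , drop = FALSE]
  }
  eligible <- eligible_proteins(proteome, positive_proteins$id,
                                positive_proteins$sequence, hval_cut, cache)
  excluded <- setdiff(proteome$id, eligible)
  structure(list(eligible = sort(eligible),
                 n_pairs = candidate_pair_count(length(eligible)),
                 excluded = stats::setNames(
                   rep("similar to a positive-set protein", length(excluded)),
                   excluded)),
            class = "candidate_set")
}

#' Score every candidate pair with a trained model
#'
#' Per-protein feature vectors are computed once; pairs are enumerated in
#' index batches (never materialized as a whole), scored, and merged into a
#' single ranking sorted by descending probability with ties broken by
#' (\code{id_a}, \code{id_b}). Output is identical for any batch size.
#'
#' @param model A final \code{pair_kernel_model} from
#'   \code{\link{fit_final_model}}.
#' @param candidates A \code{\link{candidate_pairs}} result (or character
#'   vector of eligible ids).
#' @param profiles Named list of \code{aa_profile} covering the candidates.
#' @param batch_size Pairs scored per batch (default 10000).
#' @return Data frame of prediction records: \code{rank}, \code{id_a},
#'   \code{id_b}, \code{decision_value}, \code{probability}.
#' @export
predict_all <- function(model, candidates, profiles, batch_size = 10000) {
  ids <- if (inherits(candidates, "candidate_set")) candidates$eligible
         else sort(candidates)
  n <- length(ids)
  if (n < 2) stop("need at least two eligible proteins")
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop("no profile for candidate protein(s): ",
         paste(missing, collapse = ", "))
  feats <- lapply(profiles[ids], kmer_features, hp = model$hp)
  names(feats) <- ids
  G_nn <- protein_gram(feats)
  G_nt <- protein_cross_gram(feats, model$train_features)
  total <- candidate_pair_count(n)
  chunks <- split(seq_len(total),
                  ceiling(seq_len(total) / max(1, batch_size)))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    ij <- unrank_pairs(chunks[[ci]], n)
    pairs <- data.frame(id_a = ids[ij$i], id_b = ids[ij$j],
                        stringsAsFactors = FALSE)
    self_new <- pair_self_kernel(G_nn, pairs)
    raw <- G_nt[pairs$id_a, model$train_pairs$id_a, drop = FALSE] +
           G_nt[pairs$id_a, model$train_pairs$id_b, drop = FALSE] +
           G_nt[pairs$id_b, model$train_pairs$id_a, drop = FALSE] +
           G_nt[pairs$id_b, model$train_pairs$id_b, drop = FALSE]
    K <- raw / outer(sqrt(self_new), sqrt(model$train_self_kernel))
    pred <- predict(model, K)
    out[[ci]] <- cbind(pairs, pred)
  }
  out <- do.call(rbind, out)
  ord <- order(-out$probability, out$id_a, out$id_b)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "id_a", "id_b", "decision_value", "probability")]
}

#' Select the published top set
#'
#' Keeps the globally most reliable predictions up to a budget of
#' \code{per_protein} records per proteome protein (about 10 per protein by
#' default). An optional rounding granularity mimics round published set
#' sizes.
#'
#' @param predictions Prediction records sorted by descending probability.
#' @param n_proteins Number of proteins in the organism's proteome.
#' @param per_protein Predictions budgeted per protein (default 10).
#' @param round_to Optional granularity; the budget is rounded down to a
#'   multiple of it.
#' @return The top records (all records when the budget exceeds the input).
#' @export
select_top <- function(predictions, n_proteins, per_protein = 10,
                       round_to = NULL) {
  stopifnot(per_protein >= 1)
  budget <- per_protein * n_proteins
  if (!is.null(round_to)) budget <- floor(budget / round_to) * round_to
  ord <- order(-predictions$probability, predictions$id_a, predictions$id_b)
  out <- predictions[ord[seq_len(min(budget, nrow(predictions)))], ,
                     drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare predictions against an external reference set
#'
#' Counts how many predictions have any call in the reference (evidenced) and
#' how many of those are classified consistently: a prediction's class is
#' positive when its calibrated probability is at least 0.5, and it is
#' correct when that class equals the reference's interact/not-interact call.
#' Accuracy is \code{100 * n_correct / n_evidence}, reported to two decimals,
#' and undefined (NA) when nothing is evidenced.
#'
#' @param predictions Prediction records (\code{id_a}, \code{id_b},
#'   \code{probability}).
#' @param reference Data frame (\code{id_a}, \code{id_b}, \code{interacts}
#'   logical).
#' @return A \code{\link{comparison_report}}.
#' @export
compare_with_reference <- function(predictions, reference) {
  cp <- canonical_pair(reference$id_a, reference$id_b)
  ref_key <- pair_key(cp$id_a, cp$id_b)
  if (anyDuplicated(ref_key)) stop("duplicate pairs in reference")
  key <- pair_key(predictions$id_a, predictions$id_b)
  hit <- match(key, ref_key)
  evid <- !is.na(hit)
  pred_class <- predictions$probability >= 0.5
  correct <- evid & (pred_class == reference$interacts[hit])
  comparison_report(n_pred = nrow(predictions),
                    n_evidence = sum(evid),
                    n_correct = sum(correct, na.rm = TRUE))
}

#' Prediction-vs-reference comparison report
#'
#' @param n_pred Predictions checked.
#' @param n_evidence Predictions with any reference call.
#' @param n_correct Evidenced predictions classified consistently.
#' @return List of class \code{comparison_report} with the three counts and
#'   \code{accuracy} (percent, two decimals; NA when \code{n_evidence} is 0).
#' @export
comparison_report <- function(n_pred, n_evidence, n_correct) {
  stopifnot(n_correct <= n_evidence, n_evidence <= n_pred)
  structure(list(n_pred = n_pred, n_evidence = n_evidence,
                 n_correct = n_correct,
                 accuracy = if (n_evidence > 0)
                   round(100 * n_correct / n_evidence, 2) else NA_real_),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("predictions checked: ", x$n_pred, "\n",
      "with reference evidence: ", x$n_evidence, "\n",
      "correctly classified: ", x$n_correct, "\n",
      "accuracy: ", if (is.na(x$accuracy)) "undefined"
      else paste0(sprintf("%.2f", x$accuracy), "%"), "\n", sep = "")
  invisible(x)
}
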