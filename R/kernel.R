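#' Profile-kernel hyperparameters
#'
#' @param k k-mer length in residues (>= 1). Default 5.
#' @param sigma Conservation threshold in nats (> 0): a k-mer belongs to a
#'   window's mutation neighborhood when the summed \code{-log p} of its
#'   residues under the profile stays strictly below \code{sigma}. Default
#'   11. For orientation, a fully uninformative position costs
#'   \code{-log(1/20) = 3.0} nats.
#' @return A list of class \code{kernel_hyperparams}.
#' @export
kernel_hyperparams <- function(k = 5, sigma = 11) {
  stopifnot(k >= 1, sigma > 0)
  structure(list(k = as.integer(k), sigma = sigma),
            class = "kernel_hyperparams")
}

#' Default hyperparameter grid
#'
#' The grid searched per organism: k in 3..6 crossed with sigma in 4..11
#' (32 combinations).
#'
#' @return Data frame with columns \code{k} and \code{sigma}.
#' @export
default_grid <- function() expand.grid(k = 3:6, sigma = 4:11)

#' Mutation neighborhood of one profile window
#'
#' All k-mers whose conservation score \eqn{\sum_{j} -\log
#' p_{i+j}(\beta_j)} under the profile is strictly below \code{sigma}.
#' Explored breadth-first with running-score pruning, so only viable
#' prefixes are ever expanded.
#'
#' @param profile An \code{aa_profile}.
#' @param position Window start (1-based); \code{position + k - 1} must not
#'   exceed the profile length.
#' @param hp \code{\link{kernel_hyperparams}}.
#' @return Character vector of k-mers (sorted).
#' @export
neighborhood <- function(profile, position, hp) {
  L <- nrow(profile$probs)
  if (position < 1 || position + hp$k - 1 > L)
    stop("window [", position, ", ", position + hp$k - 1,
         "] out of range for length ", L)
  S <- -log(profile$probs)
  sort(expand_window(S, position, hp$k, hp$sigma)$kmers)
}

# BFS with pruning over one window; returns kmers and their scores.
expand_window <- function(S, position, k, sigma) {
  scores <- 0
  kmers <- ""
  for (j in seq_len(k)) {
    cand <- outer(scores, S[position + j - 1, ], `+`)
    keep <- which(cand < sigma)
    if (length(keep) == 0) return(list(kmers = character(0), scores = numeric(0)))
    row <- ((keep - 1) %% length(scores)) + 1
    col <- ((keep - 1) %/% length(scores)) + 1
    scores <- cand[keep]
    kmers <- paste0(kmers[row], AA20[col])
  }
  list(kmers = kmers, scores = scores)
}

#' Sparse profile k-mer feature vector
#'
#' For each of the \code{L - k + 1} windows of the profile, every k-mer in
#' the window's mutation neighborhood gains count 1. The result is the sparse
#' feature map of the profile kernel. With a delta profile this reduces to
#' the classic k-mer spectrum counts of the query sequence.
#'
#' @param profile An \code{aa_profile}.
#' @param hp \code{\link{kernel_hyperparams}}.
#' @return Named numeric vector of k-mer counts, with attribute \code{owner}
#'   (protein id). Empty (with a message) when the profile is shorter than k.
#' @export
kmer_features <- function(profile, hp) {
  L <- nrow(profile$probs)
  if (L < hp$k) {
    message("profile ", profile$id, " shorter than k = ", hp$k,
            "; empty feature vector")
    return(structure(stats::setNames(numeric(0), character(0)),
                     owner = profile$id))
  }
  S <- -log(profile$probs)
  all_kmers <- vector("list", L - hp$k + 1)
  for (pos in seq_len(L - hp$k + 1))
    all_kmers[[pos]] <- expand_window(S, pos, hp$k, hp$sigma)$kmers
  counts <- table(unlist(all_kmers))
  structure(stats::setNames(as.numeric(counts), names(counts)),
            owner = profile$id)
}

#' Brute-force oracle for \code{kmer_features}
#'
#' Literal enumeration of all \code{20^k} k-mers at every window, applying
#' the neighborhood inequality directly. Exponential in k (guarded at
#' k <= 4); exists purely to verify the pruned traversal.
#'
#' @inheritParams kmer_features
#' @return Named numeric vector of k-mer counts.
#' @export
kmer_features_oracle <- function(profile, hp) {
  if (hp$k > 4) stop("oracle enumeration guarded at k <= 4")
  L <- nrow(profile$probs)
  if (L < hp$k)
    return(structure(stats::setNames(numeric(0), character(0)),
                     owner = profile$id))
  S <- -log(profile$probs)
  idx <- as.matrix(expand.grid(rep(list(1:20), hp$k)))[, hp$k:1, drop = FALSE]
  kmers <- apply(idx, 1, function(r) paste(AA20[r], collapse = ""))
  acc <- list()
  for (pos in seq_len(L - hp$k + 1)) {
    sc <- rowSums(matrix(S[cbind(rep(pos:(pos + hp$k - 1), each = nrow(idx)),
                                 as.vector(idx))],
                         nrow = nrow(idx)))
    acc[[pos]] <- kmers[sc < hp$sigma]
  }
  counts <- table(unlist(acc))
  structure(stats::setNames(as.numeric(counts), names(counts)),
            owner = profile$id)
}

# L2-normalize a named count vector.
l2_normalize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot normalize a zero feature vector")
  v / nrm
}

#' Combine two protein feature vectors into a pair vector
#'
#' Each input is L2-normalized, then the two are summed key-wise. The result
#' is independent of argument order and keeps the induced pair kernel
#' positive semidefinite.
#'
#' @param vec_a,vec_b Named numeric feature vectors (non-empty).
#' @return Named numeric pair vector.
#' @export
pair_vector <- function(vec_a, vec_b) {
  if (length(vec_a) == 0 || length(vec_b) == 0)
    stop("pair_vector requires non-empty feature vectors")
  a <- l2_normalize(vec_a)
  b <- l2_normalize(vec_b)
  keys <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Normalized kernel matrix from pair vectors
#'
#' Dot products of the pair vectors followed by cosine normalization
#' \eqn{K'(x, y) = K(x, y) / \sqrt{K(x, x) K(y, y)}}. The result is
#' symmetric, unit-diagonal and positive semidefinite.
#'
#' @param pair_vectors Named list (>= 2) of pair vectors from
#'   \code{\link{pair_vector}}.
#' @return Symmetric matrix with the list names as dimnames.
#' @export
kernel_matrix <- function(pair_vectors) {
  stopifnot(length(pair_vectors) >= 2)
  keys <- unique(unlist(lapply(pair_vectors, names)))
  M <- Matrix::sparseMatrix(
    i = match(unlist(lapply(pair_vectors, names)), keys),
    j = rep(seq_along(pair_vectors), lengths(pair_vectors)),
    x = unlist(pair_vectors),
    dims = c(length(keys), length(pair_vectors)))
  K <- as.matrix(Matrix::crossprod(M))
  d <- sqrt(diag(K))
  if (any(d == 0)) stop("zero-norm pair vector")
  K <- K / outer(d, d)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(names(pair_vectors), names(pair_vectors))
  K
}

# Sparse feature matrix (k-mers x proteins) with L2-normalized columns.
feature_matrix <- function(features) {
  keys <- unique(unlist(lapply(features, names)))
  M <- Matrix::sparseMatrix(
    i = match(unlist(lapply(features, names)), keys),
    j = rep(seq_along(features), lengths(features)),
    x = unlist(lapply(features, unname)),
    dims = c(length(keys), length(features)),
    dimnames = list(keys, names(features)))
  nrm <- sqrt(Matrix::colSums(M^2))
  if (any(nrm == 0))
    stop("zero feature vector for protein(s): ",
         paste(names(features)[nrm == 0], collapse = ", "))
  out <- M %*% Matrix::Diagonal(x = 1 / nrm)
  dimnames(out) <- dimnames(M)
  out
}

# Gram matrix of normalized per-protein feature vectors.
protein_gram <- function(features) {
  M <- feature_matrix(features)
  G <- as.matrix(Matrix::crossprod(M))
  dimnames(G) <- list(names(features), names(features))
  G
}

# Cross-gram between two normalized feature sets, aligning k-mer keys.
protein_cross_gram <- function(features_a, features_b) {
  keys <- unique(c(unlist(lapply(features_a, names)),
                   unlist(lapply(features_b, names))))
  mk <- function(fs) {
    M <- Matrix::sparseMatrix(
      i = match(unlist(lapply(fs, names)), keys),
      j = rep(seq_along(fs), lengths(fs)),
      x = unlist(lapply(fs, unname)),
      dims = c(length(keys), length(fs)),
      dimnames = list(keys, names(fs)))
    nrm <- sqrt(Matrix::colSums(M^2))
    if (any(nrm == 0)) stop("zero feature vector")
    M %*% Matrix::Diagonal(x = 1 / nrm)
  }
  G <- as.matrix(Matrix::crossprod(mk(features_a), mk(features_b)))
  dimnames(G) <- list(names(features_a), names(features_b))
  G
}

# Normalized pair kernel between two pair lists, from protein-level grams.
# G_aa: gram among proteins of `pairs_a`; G_bb among `pairs_b`; G_ab across.
# pairs_* are data.frames with id_a, id_b indexing the gram dimnames.
pair_kernel_block <- function(G_ab, pairs_a, pairs_b, self_a, self_b) {
  raw <- G_ab[pairs_a$id_a, pairs_b$id_a, drop = FALSE] +
         G_ab[pairs_a$id_a, pairs_b$id_b, drop = FALSE] +
         G_ab[pairs_a$id_b, pairs_b$id_a, drop = FALSE] +
         G_ab[pairs_a$id_b, pairs_b$id_b, drop = FALSE]
  raw / outer(sqrt(self_a), sqrt(self_b))
}

# Unnormalized self-kernel K(x, x) = 2 + 2 G(a, b) for each pair.
pair_self_kernel <- function(G, pairs) {
  2 + 2 * G[cbind(pairs$id_a, pairs$id_b)]
}
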