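#' Global alignment percent identity
#'
#' Aligns two sequences with the Needleman-Wunsch algorithm (BLOSUM62, gap
#' open 10, gap extend 0.5) and summarizes the alignment as percent identity
#' over all alignment columns (gapped columns included) plus the alignment
#' length. One deterministic aligner serves both reference-proteome mapping
#' and the HSSP-curve distance, so the two stages can never disagree on what
#' "similar" means.
#'
#' @param seq_a,seq_b Amino-acid sequences (non-empty strings).
#' @return A list with \code{pide} (percent identity in [0, 100]) and
#'   \code{length} (alignment columns, >= 1).
#' @export
align_identity <- function(seq_a, seq_b) {
  res <- align_identity_many(seq_a, seq_b)
  list(pide = res$pide[1], length = res$length[1])
}

# Vectorized core: elementwise alignment of two recycled sequence vectors.
# Alignment length in columns is len_a + len_b - (matches + mismatches),
# i.e. every gap column counts once.
align_identity_pairs <- function(seqs_a, seqs_b) {
  if (any(!nzchar(seqs_a)) || any(!nzchar(seqs_b))) stop("empty sequence")
  n <- max(length(seqs_a), length(seqs_b))
  a <- rep_len(seqs_a, n)
  b <- rep_len(seqs_b, n)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  ident <- Biostrings::nmatch(aln)
  len <- nchar(a) + nchar(b) - ident - Biostrings::nmismatch(aln)
  list(pide = 100 * ident / len, length = len)
}

# One query against many subjects.
align_identity_many <- function(query, subjects) {
  align_identity_pairs(rep(query, length(subjects)), subjects)
}

#' HSSP-curve identity threshold
#'
#' Length-dependent percent-identity threshold separating reliably homologous
#' alignments from the twilight zone: 100 for alignments of at most 11
#' columns, \eqn{480 L^{-0.32 (1 + e^{-L/1000})}} for 11 < L <= 450, and the
#' 19.5 plateau beyond 450 columns.
#'
#' @param length Alignment length(s) in columns (positive).
#' @return Threshold percent identity, vectorized over \code{length}.
#' @export
hssp_threshold <- function(length) {
  if (any(length <= 0)) stop("alignment length must be positive")
  ifelse(length <= 11, 100,
  ifelse(length <= 450, 480 * length^(-0.32 * (1 + exp(-length / 1000))),
         19.5))
}

#' HSSP-curve distance (HVAL) between two sequences
#'
#' Percent identity of the global alignment minus the HSSP-curve threshold at
#' the alignment's length. HVAL > 20 marks a clearly homologous pair; at
#' alignment length 250 that corresponds to roughly 40.7\% identity.
#'
#' @param seq_a,seq_b Amino-acid sequences.
#' @return HVAL in identity percentage points.
#' @export
hval <- function(seq_a, seq_b) {
  s <- align_identity(seq_a, seq_b)
  s$pide - hssp_threshold(s$length)
}

# One query vs many subjects; returns numeric vector of HVALs.
hval_many <- function(query, subjects) {
  s <- align_identity_many(query, subjects)
  s$pide - hssp_threshold(s$length)
}

#' Create an HVAL memoization cache
#'
#' Pairwise HVALs are expensive (one global alignment each); a cache shared
#' across curation, redundancy reduction, negative sampling and candidate
#' enumeration avoids recomputation. Results are identical with or without a
#' cache.
#'
#' @return An environment usable as the \code{cache} argument of the
#'   similarity operations.
#' @export
hval_cache <- function() new.env(parent = emptyenv())

# HVALs of id-labelled sequence pairs (elementwise, recycled), memoized by
# unordered id pair when a cache is given. ids must be stable within a run.
hval_pairs_cached <- function(ids_a, seqs_a, ids_b, seqs_b, cache = NULL) {
  n <- max(length(ids_a), length(ids_b))
  ids_a <- rep_len(ids_a, n); seqs_a <- rep_len(seqs_a, n)
  ids_b <- rep_len(ids_b, n); seqs_b <- rep_len(seqs_b, n)
  if (is.null(cache)) {
    r <- align_identity_pairs(seqs_a, seqs_b)
    return(r$pide - hssp_threshold(r$length))
  }
  keys <- ifelse(ids_b < ids_a, paste(ids_b, ids_a, sep = "\r"),
                 paste(ids_a, ids_b, sep = "\r"))
  out <- unlist(mget(keys, envir = cache, ifnotfound = NA_real_),
                use.names = FALSE)
  miss <- which(is.na(out))
  if (length(miss)) {
    mkeys <- keys[miss]
    first <- miss[!duplicated(mkeys)]
    r <- align_identity_pairs(seqs_a[first], seqs_b[first])
    fresh <- r$pide - hssp_threshold(r$length)
    list2env(as.list(stats::setNames(fresh, keys[first])), envir = cache)
    out[miss] <- fresh[match(mkeys, keys[first])]
  }
  out
}

# HVALs of one protein against a block of proteins.
hval_vs_set <- function(id, seq, set_ids, set_seqs, cache = NULL) {
  if (length(set_ids) == 0) return(numeric(0))
  hval_pairs_cached(id, seq, set_ids, set_seqs, cache)
}

#' Negative-sampling configuration
#'
#' @param negative_ratio Negatives sampled per positive (default 10, the
#'   10:1 design ratio).
#' @param hval_similar_cut HVAL above which two proteins count as similar
#'   (default 20).
#' @param seed Integer seed for the sampling stream; recorded on all sampled
#'   outputs.
#' @return A list of class \code{sampling_config}.
#' @export
sampling_config <- function(negative_ratio = 10, hval_similar_cut = 20,
                            seed = 1) {
  stopifnot(negative_ratio >= 1)
  structure(list(negative_ratio = negative_ratio,
                 hval_similar_cut = hval_similar_cut,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Redundancy-reduce an interaction set
#'
#' Greedy single pass: interactions are visited in a deterministic order
#' (descending evidence score, then lexicographic pair id) and retained only
#' if both of their proteins have HVAL at or below \code{hval_cut} to every
#' protein of every interaction already retained. The output therefore
#' contains no two interactions linked by a homologous protein, and each
#' protein occurs in at most one retained interaction.
#'
#' @param interactions Interaction data frame (with \code{evidence} if
#'   evidence-ranked ordering is wanted; otherwise pair order alone is used).
#' @param proteome Data frame (\code{id}, \code{sequence}) covering every
#'   interaction partner.
#' @param hval_cut Similarity cut in HVAL units (default 20; exactly 20 is
#'   retained).
#' @param cache Optional \code{\link{hval_cache}}.
#' @return The retained interactions (original rows, visit order).
#' @export
reduce_redundancy <- function(interactions, proteome, hval_cut = 20,
                              cache = NULL) {
  if (nrow(interactions) == 0) return(interactions)
  seqs <- stats::setNames(proteome$sequence, proteome$id)
  partners <- unique(c(interactions$id_a, interactions$id_b))
  missing <- setdiff(partners, names(seqs))
  if (length(missing))
    stop("no sequence for interaction partner(s): ",
         paste(missing, collapse = ", "))
  ev <- if ("evidence" %in% names(interactions))
    evidence_scores(interactions) else rep(0, nrow(interactions))
  ord <- order(-ev, interactions$id_a, interactions$id_b)
  kept_ids <- character(0)
  keep_rows <- integer(0)
  for (i in ord) {
    pa <- interactions$id_a[i]; pb <- interactions$id_b[i]
    p <- unique(c(pa, pb))
    ok <- length(kept_ids) == 0 ||
      all(hval_pairs_cached(rep(p, each = length(kept_ids)),
                            rep(seqs[p], each = length(kept_ids)),
                            rep.int(kept_ids, length(p)),
                            rep.int(seqs[kept_ids], length(p)),
                            cache) <= hval_cut)
    if (ok) {
      keep_rows <- c(keep_rows, i)
      kept_ids <- c(kept_ids, setdiff(unique(c(pa, pb)), kept_ids))
    }
  }
  out <- interactions[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Protein ids of a proteome whose HVAL stays strictly below `cut` against
# every protein in `anchor_ids`; used for negative pools and interactome
# candidates. All candidate-anchor pairs are aligned in large elementwise
# batches (chunked to bound memory).
eligible_proteins <- function(proteome, anchor_ids, anchor_seqs, cut,
                              cache = NULL, chunk = 25000L) {
  m <- length(anchor_ids)
  if (m == 0) return(proteome$id)
  n <- nrow(proteome)
  ci <- rep(seq_len(n), each = m)
  aj <- rep.int(seq_len(m), n)
  hv <- numeric(length(ci))
  for (at in split(seq_along(ci), ceiling(seq_along(ci) / chunk))) {
    hv[at] <- hval_pairs_cached(proteome$id[ci[at]],
                                proteome$sequence[ci[at]],
                                anchor_ids[aj[at]], anchor_seqs[aj[at]],
                                cache)
  }
  worst <- apply(matrix(hv, nrow = m), 2, max)
  proteome$id[worst < cut]
}

#' Sample negative interaction pairs
#'
#' Draws \code{negative_ratio x nrow(positives)} distinct unordered protein
#' pairs uniformly from all pairs of eligible proteins, where a protein is
#' eligible only if its HVAL stays strictly below \code{hval_similar_cut}
#' against every protein of the positive set. No sampled pair equals a
#' positive pair. Sampling is reproducible from \code{config$seed}, which is
#' recorded on the result.
#'
#' @param positives Positive interaction data frame (\code{id_a},
#'   \code{id_b}).
#' @param proteome Data frame (\code{id}, \code{sequence}).
#' @param config A \code{\link{sampling_config}}.
#' @param cache Optional \code{\link{hval_cache}}.
#' @return Data frame (\code{id_a}, \code{id_b}) of negative pairs with
#'   attributes \code{seed} and \code{eligible} (pool ids).
#' @export
sample_negatives <- function(positives, proteome, config = sampling_config(),
                             cache = NULL) {
  stopifnot(nrow(positives) >= 1)
  pos_ids <- sort(unique(c(positives$id_a, positives$id_b)))
  seqs <- stats::setNames(proteome$sequence, proteome$id)
  missing <- setdiff(pos_ids, names(seqs))
  if (length(missing))
    stop("positive-set protein(s) missing from proteome: ",
         paste(missing, collapse = ", "))
  pool <- eligible_proteins(proteome, pos_ids, seqs[pos_ids],
                            config$hval_similar_cut, cache)
  pool <- sort(pool)
  n <- length(pool)
  n_needed <- config$negative_ratio * nrow(positives)
  pos_keys <- pair_key(positives$id_a, positives$id_b)
  total <- n * (n - 1) / 2
  if (total < n_needed)
    stop("eligible pool supports only ", total, " pairs; ", n_needed,
         " negatives requested (shortfall ", n_needed - total, ")")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  # Rejection-free draw of distinct pair ranks, then unrank to (i < j);
  # re-draw only the few that collide with positive pairs.
  taken <- character(0)
  out_a <- character(0); out_b <- character(0)
  while (length(out_a) < n_needed) {
    m <- n_needed - length(out_a)
    ranks <- sample(total, min(m + 32, total))
    ij <- unrank_pairs(ranks, n)
    a <- pool[ij$i]; b <- pool[ij$j]
    key <- pair_key(a, b)
    ok <- !(key %in% pos_keys) & !(key %in% taken) & !duplicated(key)
    a <- a[ok][seq_len(min(m, sum(ok)))]
    b <- b[ok][seq_len(min(m, sum(ok)))]
    taken <- c(taken, pair_key(a, b))
    out_a <- c(out_a, a); out_b <- c(out_b, b)
  }
  out <- data.frame(id_a = out_a, id_b = out_b, stringsAsFactors = FALSE)
  attr(out, "seed") <- config$seed
  attr(out, "eligible") <- pool
  out
}

# Unrank 1-based pair ranks into (i < j) indices over n items, lexicographic
# by i.
unrank_pairs <- function(ranks, n) {
  cum <- cumsum((n - 1):1)
  i <- findInterval(ranks - 1, cum) + 1L
  offset <- c(0, cum)[i]
  j <- i + (ranks - offset)
  list(i = i, j = as.integer(j))
}
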