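#' Curation configuration
#'
#' Thresholds of the data-quality pipeline: the minimum experimental-evidence
#' reliability an interaction must reach on the 1-10 scale, the minimum
#' percent sequence identity for mapping interaction partners onto a
#' reference proteome, and the non-redundant PPI counts that decide how an
#' organism's model is trained.
#'
#' @param min_evidence_score Keep interactions whose best evidence reaches at
#'   least this score (inclusive; default 5).
#' @param min_mapping_identity Minimum percent identity for mapping a protein
#'   onto a reference (inclusive; default 95).
#' @param min_ppis_per_organism Minimum non-redundant PPI count to model an
#'   organism at all (inclusive; default 200).
#' @param grid_search_min_ppis Above this count (exclusive) hyperparameters
#'   are grid-searched; between the two counts the fixed default
#'   hyperparameters are used (default 500).
#' @return A list of class \code{curation_config}.
#' @export
curation_config <- function(min_evidence_score = 5,
                            min_mapping_identity = 95,
                            min_ppis_per_organism = 200,
                            grid_search_min_ppis = 500) {
  stopifnot(min_evidence_score >= 1, min_evidence_score <= 10,
            min_mapping_identity > 0, min_mapping_identity <= 100,
            min_ppis_per_organism <= grid_search_min_ppis)
  structure(list(min_evidence_score = min_evidence_score,
                 min_mapping_identity = min_mapping_identity,
                 min_ppis_per_organism = min_ppis_per_organism,
                 grid_search_min_ppis = grid_search_min_ppis),
            class = "curation_config")
}

#' Reliability score of one interaction
#'
#' An interaction's reliability is the maximum score over its experimental
#' evidence entries: a single strong assay outweighs any number of weak ones.
#'
#' @param evidence Data frame with columns \code{method} and \code{score}
#'   (one interaction's evidence), or an interaction data frame row's
#'   \code{evidence[[i]]}.
#' @return The maximum reliability score.
#' @export
evidence_score <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0)
    stop("cannot score an interaction without evidence")
  max(evidence$score)
}

#' Reliability scores for a collection of interactions
#' @param interactions Interaction data frame with list-column
#'   \code{evidence}.
#' @return Numeric vector of per-interaction maximum scores.
#' @export
evidence_scores <- function(interactions) {
  vapply(interactions$evidence, evidence_score, numeric(1))
}

#' Filter interactions by experimental-evidence reliability
#'
#' Retains interactions with at least one evidence entry scoring at or above
#' \code{config$min_evidence_score}. Input order is preserved.
#'
#' @param interactions Interaction data frame.
#' @param config A \code{\link{curation_config}}.
#' @return The retained subset.
#' @export
filter_by_evidence <- function(interactions, config = curation_config()) {
  if (nrow(interactions) == 0) return(interactions)
  keep <- evidence_scores(interactions) >= config$min_evidence_score
  out <- interactions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a protein onto a reference proteome
#'
#' Aligns the query against every reference sequence and returns the
#' reference id with the highest percent identity, provided that identity
#' reaches \code{config$min_mapping_identity} (inclusive). Ties go to the
#' lexicographically smallest reference id, which makes the result invariant
#' under reference-proteome shuffling.
#'
#' @param protein One-row data frame (or list) with \code{id} and
#'   \code{sequence}.
#' @param reference Reference proteome data frame (\code{id},
#'   \code{sequence}).
#' @param config A \code{\link{curation_config}}.
#' @return The matched reference id, or \code{NA_character_} if no reference
#'   reaches the identity threshold.
#' @export
map_to_reference <- function(protein, reference, config = curation_config()) {
  stopifnot(nrow(reference) >= 1)
  if (!nzchar(protein$sequence)) stop("empty query sequence")
  aln <- align_identity_many(protein$sequence, reference$sequence)
  best <- max(aln$pide)
  if (best < config$min_mapping_identity) return(NA_character_)
  cand <- reference$id[aln$pide == best]
  sort(cand)[1]
}

#' Assign organisms to modelling tiers by non-redundant PPI count
#'
#' Organisms below \code{min_ppis_per_organism} (exclusive) are not modelled;
#' organisms with counts in \code{[min_ppis_per_organism,
#' grid_search_min_ppis]} are trained with the fixed default hyperparameters;
#' organisms above \code{grid_search_min_ppis} (exclusive) get a full
#' hyperparameter grid search.
#'
#' @param counts Named integer vector of non-redundant PPI counts.
#' @param config A \code{\link{curation_config}}.
#' @return Named character vector over \code{c("none", "fixed_hyperparams",
#'   "grid_search")}.
#' @export
select_model_organisms <- function(counts, config = curation_config()) {
  if (any(counts < 0)) stop("negative PPI count")
  tier <- ifelse(counts < config$min_ppis_per_organism, "none",
          ifelse(counts > config$grid_search_min_ppis, "grid_search",
                 "fixed_hyperparams"))
  stats::setNames(tier, names(counts))
}
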