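#' Default miniature reliability score table
#'
#' Bundled experimental-method scores used by the synthetic evidence model:
#' blue native page (3), pull down (2.5), enzyme linked immunosorbent assay
#' (5), x-ray crystallography (10).
#'
#' @return A \code{\link{score_table}}.
#' @export
mini_score_table <- function() {
  score_table(c("blue native page" = 3,
                "pull down" = 2.5,
                "enzyme linked immunosorbent assay" = 5,
                "x-ray crystallography" = 10))
}

#' Specification for a synthetic organism
#'
#' Defines proteome size and composition, homolog-family structure,
#' interaction signal and evidence model. The defaults emulate the study
#' conditions the pipeline assumes: sequences of 150-250 residues,
#' within-family per-residue substitution rate 0.15 (keeping within-family
#' HVAL comfortably above 20 at these lengths while unrelated sequences stay
#' far below), and interacting partners sharing a planted k-mer motif pair,
#' which is the learnable signal the kernel is built to pick up.
#'
#' @param n_proteins Proteome size.
#' @param len_range Integer range of founder/singleton sequence lengths.
#' @param n_families Number of homolog families (0 = all singletons).
#' @param family_size Members per family.
#' @param mutation_rate Per-residue substitution probability within a family.
#' @param n_positive Planted positive interactions.
#' @param motif_length Length of each planted motif k-mer.
#' @param n_motif_pairs Number of distinct motif pairs; positives draw theirs
#'   uniformly from this set.
#' @param fraction_failing Fraction of positives whose evidence is entirely
#'   below the reliability threshold of 5 (they should be removed by
#'   curation).
#' @param scores \code{\link{score_table}} for the evidence model.
#' @param seed Master seed; every sub-stream derives from it.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_proteins = 600, len_range = c(150, 250),
                           n_families = 0, family_size = 3,
                           mutation_rate = 0.15,
                           n_positive = 200, motif_length = 4,
                           n_motif_pairs = 3, fraction_failing = 0.25,
                           scores = mini_score_table(), seed = 1) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            fraction_failing >= 0, fraction_failing <= 1,
            n_families * family_size <= n_proteins,
            motif_length <= len_range[1],
            len_range[1] >= 1, len_range[2] >= len_range[1])
  structure(list(n_proteins = n_proteins, len_range = len_range,
                 n_families = n_families, family_size = family_size,
                 mutation_rate = mutation_rate, n_positive = n_positive,
                 motif_length = motif_length, n_motif_pairs = n_motif_pairs,
                 fraction_failing = fraction_failing, scores = scores,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_sequence <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

mutate_sequence <- function(seq, rate) {
  res <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(res)) < rate
  if (any(hit)) {
    # substitute to a uniformly chosen *different* residue
    res[hit] <- vapply(res[hit],
                       function(r) sample(setdiff(AA20, r), 1), character(1))
  }
  paste(res, collapse = "")
}

#' Simulate a proteome with homolog families
#'
#' Family founders are drawn i.i.d. uniform over the 20 residues; members are
#' derived from their founder by independent per-residue substitution at the
#' family mutation rate; the remaining proteins are independent singletons.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Data frame (\code{id}, \code{sequence}, \code{family}; family 0 =
#'   singleton). Reproducible from \code{spec$seed}.
#' @export
simulate_proteome <- function(spec) {
  set.seed(spec$seed)
  n_members <- spec$n_families * spec$family_size
  ids <- sprintf("SP%04d", seq_len(spec$n_proteins))
  seqs <- character(spec$n_proteins)
  family <- integer(spec$n_proteins)
  i <- 1L
  for (f in seq_len(spec$n_families)) {
    len <- sample(spec$len_range[1]:spec$len_range[2], 1)
    founder <- random_sequence(len)
    for (m in seq_len(spec$family_size)) {
      seqs[i] <- if (m == 1) founder else
        mutate_sequence(founder, spec$mutation_rate)
      family[i] <- f
      i <- i + 1L
    }
  }
  while (i <= spec$n_proteins) {
    seqs[i] <- random_sequence(
      sample(spec$len_range[1]:spec$len_range[2], 1))
    i <- i + 1L
  }
  data.frame(id = ids, sequence = seqs, family = family,
             stringsAsFactors = FALSE)
}

#' Plant interactions with shared motif pairs into a proteome
#'
#' Draws \code{2 n_positive} distinct proteins (at most one member per
#' family, so redundancy reduction keeps one interaction per family), writes
#' a motif pair (m1 into one partner, m2 into the other, at random positions)
#' into each interacting pair, and attaches evidence: a fraction
#' \code{fraction_failing} of positives receives only weak-method evidence
#' (scores below 5), the rest at least one strong method.
#'
#' @param proteome From \code{\link{simulate_proteome}}.
#' @param spec The same \code{\link{synthetic_spec}}.
#' @return List: \code{proteome} (sequences now carry the motifs),
#'   \code{interactions} (with \code{evidence} list-column and logical
#'   \code{strong} ground truth), \code{motifs} (data frame m1, m2).
#' @export
plant_interactions <- function(proteome, spec) {
  set.seed(spec$seed + 1L)
  need <- 2L * spec$n_positive
  # at most one protein per family, plus all singletons
  cand <- unlist(lapply(split(seq_len(nrow(proteome)), proteome$family),
                        function(ix) if (proteome$family[ix[1]] == 0) ix
                                     else sample(ix, 1)))
  if (length(cand) < need)
    stop("spec supports only ", length(cand),
         " interaction partners; need ", need)
  partners <- sample(cand, need)
  motifs <- data.frame(
    m1 = replicate(spec$n_motif_pairs, random_sequence(spec$motif_length)),
    m2 = replicate(spec$n_motif_pairs, random_sequence(spec$motif_length)),
    stringsAsFactors = FALSE)
  k <- spec$motif_length
  implant <- function(i, motif) {
    s <- proteome$sequence[i]
    pos <- sample(nchar(s) - k + 1, 1)
    proteome$sequence[i] <<- paste0(substr(s, 1, pos - 1), motif,
                                    substr(s, pos + k, nchar(s)))
  }
  ia <- partners[seq_len(spec$n_positive)]
  ib <- partners[spec$n_positive + seq_len(spec$n_positive)]
  motif_of <- sample(spec$n_motif_pairs, spec$n_positive, replace = TRUE)
  for (p in seq_len(spec$n_positive)) {
    implant(ia[p], motifs$m1[motif_of[p]])
    implant(ib[p], motifs$m2[motif_of[p]])
  }
  sc <- unclass(spec$scores)
  weak <- names(sc)[sc < 5]
  strong <- names(sc)[sc >= 5]
  fails <- stats::runif(spec$n_positive) < spec$fraction_failing
  evidence <- lapply(seq_len(spec$n_positive), function(p) {
    m <- if (fails[p]) sample(weak, sample(1:2, 1), replace = FALSE)
         else unique(c(sample(strong, 1), sample(names(sc), 1)))
    data.frame(method = m, score = unname(sc[m]), stringsAsFactors = FALSE)
  })
  cp <- canonical_pair(proteome$id[ia], proteome$id[ib])
  interactions <- data.frame(id_a = cp$id_a, id_b = cp$id_b,
                             self = FALSE, stringsAsFactors = FALSE)
  interactions$evidence <- I(evidence)
  interactions$strong <- !fails
  list(proteome = proteome, interactions = interactions, motifs = motifs)
}

#' Simulate a complete synthetic organism
#'
#' Convenience wrapper: proteome, planted interactions, score table and
#' profiles (delta-like pseudo-profiles by default) in one call.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param profile_alpha \code{alpha} for the pseudo-profiles (0 = delta
#'   profiles).
#' @param verify If \code{TRUE}, assert the family HVAL structure (within
#'   family > 20, across families < 20) on a sample of pairs; quadratic in
#'   proteome size, so meant for small specs.
#' @return List: \code{proteome}, \code{interactions}, \code{motifs},
#'   \code{profiles}, \code{scores}, \code{spec}.
#' @export
simulate_organism <- function(spec, profile_alpha = 0, verify = FALSE) {
  proteome <- simulate_proteome(spec)
  planted <- plant_interactions(proteome, spec)
  proteome <- planted$proteome
  if (verify) verify_family_structure(proteome)
  profiles <- lapply(seq_len(nrow(proteome)), function(i)
    pseudo_profile(proteome[i, ], profile_alpha))
  names(profiles) <- proteome$id
  list(proteome = proteome, interactions = planted$interactions,
       motifs = planted$motifs, profiles = profiles, scores = spec$scores,
       spec = spec)
}

verify_family_structure <- function(proteome) {
  fams <- unique(proteome$family[proteome$family > 0])
  for (f in fams) {
    ix <- which(proteome$family == f)
    first <- ix[1]
    others <- ix[-1]
    if (length(others)) {
      hv <- hval_many(proteome$sequence[first], proteome$sequence[others])
      if (any(hv <= 20))
        stop("within-family HVAL <= 20 for family ", f)
    }
    out_ix <- which(proteome$family != f)
    if (length(out_ix)) {
      probe <- out_ix[seq_len(min(5, length(out_ix)))]
      hv <- hval_many(proteome$sequence[first], proteome$sequence[probe])
      if (any(hv >= 20))
        stop("cross-family HVAL >= 20 for family ", f)
    }
  }
  invisible(TRUE)
}

#' Write a synthetic organism to disk
#'
#' Emits FASTA (proteome), interaction TSV, score-table TSV and one PSSM per
#' protein (integer percentages derived from the profiles), i.e. exactly the
#' external formats the readers consume.
#'
#' @param organism From \code{\link{simulate_organism}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic <- function(organism, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(organism$proteome, file.path(dir, "proteome.fasta"))
  write_interactions(organism$interactions,
                     file.path(dir, "interactions.tsv"))
  write_score_table(organism$scores, file.path(dir, "scores.tsv"))
  pdir <- file.path(dir, "profiles")
  dir.create(pdir, showWarnings = FALSE)
  for (pr in organism$profiles)
    write_pssm(pr$query, round(pr$probs * 100),
               file.path(pdir, paste0(pr$id, ".pssm")))
  invisible(dir)
}
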