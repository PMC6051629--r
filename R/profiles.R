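#' Construct a per-protein evolutionary profile
#'
#' A profile is a per-position probability distribution over the 20 standard
#' residues. Every row is floored at \code{1e-4} and renormalized to sum to
#' one, so \code{-log p} (the kernel's conservation score) is always finite.
#'
#' @param id Protein id.
#' @param query Residue string of length L.
#' @param probs L x 20 matrix of probabilities, columns in canonical
#'   (alphabetical) residue order.
#' @return An object of class \code{aa_profile}.
#' @export
aa_profile <- function(id, query, probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 20, nrow(probs) == nchar(query))
  colnames(probs) <- AA20
  probs <- floor_renormalize(probs)
  structure(list(id = id, query = query, probs = probs),
            class = "aa_profile")
}

# Pin entries below the floor to exactly eps and rescale the remaining mass
# so each row sums to one. Idempotent (a floored row passes through
# unchanged), so profiles survive write/read cycles bit-for-bit to text
# precision. The low set only grows across iterations, so this terminates.
floor_renormalize <- function(p) {
  eps <- PROFILE_EPS
  p <- p / rowSums(p)
  repeat {
    low <- p <= eps
    k <- rowSums(low)
    rest <- rowSums(p * !low)
    scale <- (1 - k * eps) / pmax(rest, .Machine$double.xmin)
    pnew <- p * scale
    pnew[low] <- eps
    done <- max(abs(pnew - p)) < 1e-14
    p <- pnew
    if (done) break
  }
  p
}

#' Convert a raw PSSM percentage table to a profile
#'
#' Divides the weighted-observed percentage columns of a PSI-BLAST ASCII PSSM
#' by 100 and applies the profile floor-and-renormalize rule. Positions whose
#' percentage row is all zero (PSI-BLAST emits these when a position has no
#' aligned homologs) fall back to a delta distribution on the query residue,
#' with a message.
#'
#' @param pssm A list as returned by \code{\link{read_pssm}}.
#' @param id Protein id to attach.
#' @return An \code{aa_profile}.
#' @export
pssm_to_profile <- function(pssm, id) {
  p <- pssm$percent / 100
  zero <- rowSums(p) == 0
  if (any(zero)) {
    message(sum(zero), " all-zero PSSM row(s) replaced by query-residue delta")
    res <- strsplit(pssm$query, "")[[1]]
    for (i in which(zero)) {
      r <- res[i]
      p[i, ] <- if (r %in% AA20) ifelse(AA20 == r, 1, 0) else 1 / 20
    }
  }
  aa_profile(id, pssm$query, p)
}

#' Sequence-only pseudo-profile
#'
#' Fallback when no PSSM exists: each position mixes a point mass on the
#' query residue with the BLOSUM62 conditional substitution distribution of
#' that residue, \eqn{p_i = (1 - \alpha)\,\delta(q_i) + \alpha\, q(\cdot \mid
#' q_i)}. Positions holding the nonstandard residue \code{X} get a uniform
#' row, so uninformative positions cannot manufacture conserved k-mers.
#' Deterministic: the same sequence and \code{alpha} always give the same
#' table.
#'
#' @param protein One-row data frame or list with \code{id} and
#'   \code{sequence}.
#' @param alpha Mixing weight in [0, 1]; 0 gives a delta profile (up to the
#'   probability floor), 1 gives pure substitution-conditional rows. Default
#'   0.1 keeps the query residue dominant while admitting conservative
#'   substitutions.
#' @return An \code{aa_profile}.
#' @export
pseudo_profile <- function(protein, alpha = 0.1) {
  stopifnot(alpha >= 0, alpha <= 1)
  res <- strsplit(protein$sequence, "")[[1]]
  L <- length(res)
  q <- blosum62_conditional()
  p <- matrix(1 / 20, L, 20, dimnames = list(NULL, AA20))
  std <- res %in% AA20
  if (any(std)) {
    delta <- diag(20)[match(res[std], AA20), , drop = FALSE]
    p[std, ] <- (1 - alpha) * delta + alpha * q[res[std], , drop = FALSE]
  }
  aa_profile(protein$id, protein$sequence, p)
}

#' Write a profile to the plain-text cache format
#'
#' One TSV per protein: columns \code{position}, \code{residue}, then the 20
#' residue probabilities in canonical order.
#'
#' @param profile An \code{aa_profile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  tab <- data.frame(position = seq_len(nrow(profile$probs)),
                    residue = strsplit(profile$query, "")[[1]],
                    profile$probs, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile from the plain-text cache format
#' @param path Input path.
#' @param id Protein id to attach (defaults to the file name without
#'   extension).
#' @return An \code{aa_profile}.
#' @export
read_profile <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, check.names = FALSE)
  aa_profile(id, paste(tab$residue, collapse = ""),
             as.matrix(tab[, AA20, drop = FALSE]))
}

#' Load or synthesize profiles for a set of proteins
#'
#' For each protein, looks for \code{<id>.tsv} (profile cache format) then
#' \code{<id>.pssm} (PSI-BLAST ASCII) under \code{dir}; proteins without
#' either file fall back to \code{\link{pseudo_profile}} when
#' \code{fallback_alpha} is not \code{NULL}, and raise an error otherwise.
#'
#' @param proteome Data frame (\code{id}, \code{sequence}).
#' @param dir Profile directory, or \code{NULL} to use the fallback for all
#'   proteins.
#' @param fallback_alpha \code{alpha} for \code{\link{pseudo_profile}}, or
#'   \code{NULL} to forbid the fallback.
#' @return Named list of \code{aa_profile} objects.
#' @export
load_profiles <- function(proteome, dir = NULL, fallback_alpha = 0.1) {
  out <- vector("list", nrow(proteome))
  names(out) <- proteome$id
  for (i in seq_len(nrow(proteome))) {
    id <- proteome$id[i]
    tsv <- if (!is.null(dir)) file.path(dir, paste0(id, ".tsv")) else ""
    pssm <- if (!is.null(dir)) file.path(dir, paste0(id, ".pssm")) else ""
    out[[i]] <- if (nzchar(tsv) && file.exists(tsv)) {
      read_profile(tsv, id)
    } else if (nzchar(pssm) && file.exists(pssm)) {
      pssm_to_profile(read_pssm(pssm), id)
    } else if (!is.null(fallback_alpha)) {
      pseudo_profile(proteome[i, ], fallback_alpha)
    } else {
      stop("no profile found for protein ", id)
    }
  }
  out
}
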