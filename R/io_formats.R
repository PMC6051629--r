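#' Read a proteome from a FASTA file
#'
#' Reads amino-acid sequences and normalizes them to the package's internal
#' convention: sequences are upper-cased and every letter outside the 20
#' standard residues (including \code{*}, \code{B}, \code{Z}, \code{U},
#' \code{O}) is mapped to \code{X}.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns \code{id} (first whitespace-delimited
#'   token of the header) and \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty header in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- sanitize_sequence(as.character(set))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    stop("empty sequence for record(s): ", paste(bad, collapse = ", "))
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a proteome to a FASTA file
#'
#' @param proteome Data frame with columns \code{id} and \code{sequence}.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(proteome)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    writeLines(paste0(">", proteome$id[i]), con)
    s <- proteome$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the \code{-out_ascii_pssm} layout: a header naming the 20 residues
#' twice (log-odds block, then weighted observed percentages), followed by one
#' row per query position. Only the percentage block and the query residue
#' string are retained; columns are re-ordered into the package's canonical
#' alphabetical residue order.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A list with \code{query} (residue string of length L) and
#'   \code{percent} (L x 20 numeric matrix, columns named by residue).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- grepl("^\\s*[0-9]+\\s+[A-Z]\\s", lines)
  if (!any(is_data)) stop("no PSSM data rows found in ", path)
  rows <- strsplit(trimws(lines[is_data]), "\\s+")
  nfield <- lengths(rows)
  if (any(nfield < 42))
    stop("truncated PSSM row (", min(nfield), " fields, need >= 42) in ", path)
  pos <- as.integer(vapply(rows, `[`, character(1), 1))
  if (anyNA(pos) || !identical(pos, seq_along(pos)))
    stop("non-contiguous position column in ", path)
  query <- paste(vapply(rows, `[`, character(1), 2), collapse = "")
  pct <- t(vapply(rows, function(r) as.numeric(r[23:42]), numeric(20)))
  if (anyNA(pct)) stop("non-numeric percentage cell in ", path)
  colnames(pct) <- PSSM_AA_ORDER
  pct <- pct[, AA20, drop = FALSE]
  if (nrow(pct) != nchar(query))
    stop("row count does not match query length in ", path)
  list(query = sanitize_sequence(query), percent = pct)
}

#' Write a profile as a PSI-BLAST ASCII PSSM file
#'
#' Emits the \code{-out_ascii_pssm} dialect so that synthetic profiles
#' round-trip through \code{\link{read_pssm}}. Percentages are written as
#' integers; log-odds are filled with zeros (they are never consumed).
#'
#' @param query Residue string.
#' @param percent L x 20 matrix of integer percentages, columns in canonical
#'   (alphabetical) residue order.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pssm <- function(query, percent, path) {
  stopifnot(nchar(query) == nrow(percent), ncol(percent) == 20)
  pct <- round(percent)[, match(PSSM_AA_ORDER, AA20), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("         ", paste(sprintf("%3s", PSSM_AA_ORDER), collapse = ""),
           "  ", paste(sprintf("%3s", PSSM_AA_ORDER), collapse = ""))), con)
  res <- strsplit(query, "")[[1]]
  for (i in seq_len(nrow(pct))) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", rep(0L, 20)), collapse = ""), "  ",
                      paste(sprintf("%3d", pct[i, ]), collapse = ""),
                      sprintf("  %5.2f %9.2f", 0, 0)), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read an experimental-method reliability score table
#'
#' Two-column TSV (header \code{method}, \code{score}) mapping experimental
#' detection-method names to reliability scores on a 1 (lowest) to 10
#' (highest) scale. Lookup is case-insensitive after whitespace
#' normalization.
#'
#' @param path Path to the TSV.
#' @return A named numeric vector (names normalized), class
#'   \code{score_table}.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("method", "score") %in% names(tab)))
    stop("score table needs columns 'method' and 'score': ", path)
  score_table(stats::setNames(as.numeric(tab$score), tab$method))
}

#' Construct a reliability score table
#'
#' @param scores Named numeric vector: method name -> score in [1, 10].
#' @return Named numeric vector with normalized names, class
#'   \code{score_table}.
#' @export
score_table <- function(scores) {
  if (any(is.na(scores)) || any(scores < 1 | scores > 10))
    stop("reliability scores must lie in [1, 10]")
  names(scores) <- normalize_method(names(scores))
  if (anyDuplicated(names(scores)))
    stop("duplicate method names after normalization")
  structure(scores, class = c("score_table", "numeric"))
}

normalize_method <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Write a score table as TSV
#' @param scores A \code{score_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(
    data.frame(method = names(scores), score = as.numeric(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read evidence-annotated interaction records
#'
#' Supports two dialects. \code{tsv}: a header line then columns \code{id_a},
#' \code{id_b}, \code{method}; repeated lines for the same unordered pair
#' accumulate evidence. \code{mitab}: MITAB 2.5, of which only columns 1 and 2
#' (interactor ids, the text after the last \code{:}) and column 7 (detection
#' method; the free-text name inside parentheses) are used.
#'
#' Pairs are canonicalized at read time (smaller id first). Methods are
#' resolved against \code{scores}; methods absent from the table receive
#' \code{default_score} (lowest reliability by default) with a warning, so
#' missing annotation quality can never promote an interaction past the
#' evidence filter. Self-pairs are parsed but flagged in column \code{self}.
#'
#' @param path Input path.
#' @param dialect \code{"tsv"} or \code{"mitab"}.
#' @param scores A \code{score_table}.
#' @param default_score Score for methods missing from \code{scores}.
#' @return A data frame with columns \code{id_a}, \code{id_b}, \code{self},
#'   and a list-column \code{evidence} of data frames
#'   (\code{method}, \code{score}).
#' @export
read_interactions <- function(path, dialect = c("tsv", "mitab"), scores,
                              default_score = 1) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(scores, "score_table"))
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("id_a", "id_b", "method") %in% names(tab)))
      stop("tsv interaction file needs columns id_a, id_b, method: ", path)
    ids_a <- tab$id_a; ids_b <- tab$id_b; methods <- tab$method
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 7)
    if (length(short))
      stop("MITAB line ", short[1], " has fewer than 7 columns")
    strip_db <- function(x) sub(".*:", "", x)
    ids_a <- strip_db(vapply(fields, `[`, character(1), 1))
    ids_b <- strip_db(vapply(fields, `[`, character(1), 2))
    raw_m <- vapply(fields, `[`, character(1), 7)
    methods <- ifelse(grepl("\\(([^)]*)\\)", raw_m),
                      sub(".*\\(([^)]*)\\).*", "\\1", raw_m), raw_m)
  }
  bad <- which(!nzchar(ids_a) | !nzchar(ids_b) | is.na(ids_a) | is.na(ids_b))
  if (length(bad)) stop("unreadable interaction record at line ", bad[1] + 1)
  mnorm <- normalize_method(methods)
  sc <- unname(unclass(scores)[mnorm])
  unknown <- unique(methods[is.na(sc)])
  if (length(unknown)) {
    warning("method(s) not in score table, using default score ",
            default_score, ": ", paste(unknown, collapse = ", "))
    sc[is.na(sc)] <- default_score
  }
  cp <- canonical_pair(ids_a, ids_b)
  key <- pair_key(cp$id_a, cp$id_b)
  idx <- split(seq_along(key), key)
  keys1 <- vapply(idx, `[`, integer(1), 1)
  out <- data.frame(id_a = cp$id_a[keys1], id_b = cp$id_b[keys1],
                    stringsAsFactors = FALSE)
  out$self <- out$id_a == out$id_b
  out$evidence <- I(lapply(idx, function(i)
    data.frame(method = mnorm[i], score = sc[i], stringsAsFactors = FALSE)))
  ord <- order(out$id_a, out$id_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write interactions in the TSV dialect
#'
#' One line per evidence entry, so \code{\link{read_interactions}} re-groups
#' them into the same records.
#'
#' @param interactions Interaction data frame (see
#'   \code{\link{read_interactions}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(interactions)), function(i) {
    ev <- interactions$evidence[[i]]
    data.frame(id_a = interactions$id_a[i], id_b = interactions$id_b[i],
               method = ev$method, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked interaction predictions
#'
#' TSV with header \code{rank}, \code{id_a}, \code{id_b},
#' \code{decision_value}, \code{probability}; probabilities are printed with
#' six decimals. Records must already be sorted by descending probability
#' with ties broken by (\code{id_a}, \code{id_b}).
#'
#' @param predictions Data frame with columns \code{rank}, \code{id_a},
#'   \code{id_b}, \code{decision_value}, \code{probability}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("rank", "id_a", "id_b", "decision_value", "probability")
  stopifnot(all(cols %in% names(predictions)))
  p <- predictions$probability
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  if (is.unsorted(rev(p))) stop("predictions must be sorted by descending probability")
  out <- data.frame(rank = predictions$rank,
                    id_a = predictions$id_a, id_b = predictions$id_b,
                    decision_value = sprintf("%.6g", predictions$decision_value),
                    probability = sprintf("%.6f", p),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction file written by \code{write_predictions}
#' @param path Input path.
#' @return Data frame with the five prediction columns.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(rank = "integer",
                                          id_a = "character",
                                          id_b = "character",
                                          decision_value = "numeric",
                                          probability = "numeric"))
  tab
}
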