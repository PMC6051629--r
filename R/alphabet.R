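# Internal constants shared across modules.

# Canonical residue order used for all profile / feature tables.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order of PSI-BLAST ASCII PSSM files.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

# Robinson & Robinson amino-acid background frequencies, in AA20 order.
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)

# Probability floor applied to every profile cell so that -log p stays finite.
PROFILE_EPS <- 1e-4

#' @importFrom utils data
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

# Conditional substitution distribution q(b | a) over AA20, derived from
# BLOSUM62 half-bit scores and background frequencies:
# q(b | a) proportional to f(b) * 2^(s(a, b) / 2), rows renormalized.
blosum62_conditional <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- blosum62_matrix()[AA20, AA20]
      q <- sweep(2^(s / 2), 2, AA_BACKGROUND, `*`)
      cache <<- q / rowSums(q)
    }
    cache
  }
})

# Uppercase a sequence and map anything outside the 20 standard residues to X.
sanitize_sequence <- function(x) {
  x <- toupper(x)
  gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "X", x)
}

# Canonical unordered-pair orientation: lexicographically smaller id first.
canonical_pair <- function(id_a, id_b) {
  swap <- id_b < id_a
  data.frame(id_a = ifelse(swap, id_b, id_a),
             id_b = ifelse(swap, id_a, id_b),
             stringsAsFactors = FALSE)
}

pair_key <- function(id_a, id_b) paste(id_a, id_b, sep = "\r")

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 35
  out[hi] <- x[hi]
  out[!hi] <- log1p(exp(x[!hi]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
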