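AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(len) paste(sample(AA, len, TRUE), collapse = "")

rand_proteome <- function(n, len = 100, prefix = "Q") {
  data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
             sequence = replicate(n, rand_seq(len)),
             stringsAsFactors = FALSE)
}

# interaction record with explicit evidence entries
make_interaction <- function(id_a, id_b, methods, scores) {
  cp <- if (id_b < id_a) c(id_b, id_a) else c(id_a, id_b)
  out <- data.frame(id_a = cp[1], id_b = cp[2], self = cp[1] == cp[2],
                    stringsAsFactors = FALSE)
  out$evidence <- I(list(data.frame(method = methods, score = scores,
                                    stringsAsFactors = FALSE)))
  out
}

make_interactions <- function(...) do.call(rbind, list(...))

# independent spectrum-kmer counter for the delta-profile limit
spectrum_counts <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(stats::setNames(numeric(0), character(0)))
  kmers <- substring(seq, 1:n, k:(k + n - 1))
  tab <- table(kmers)
  stats::setNames(as.numeric(tab), names(tab))
}

# random profile with a mix of sharp and flat positions
rand_profile <- function(id, len, sharpness = 5) {
  seq <- rand_seq(len)
  p <- matrix(stats::rgamma(len * 20, shape = 1 / sharpness), len, 20)
  ridx <- match(strsplit(seq, "")[[1]], AA)
  p[cbind(seq_len(len), ridx)] <- p[cbind(seq_len(len), ridx)] + sharpness
  aa_profile(id, seq, p / rowSums(p))
}

sort_named <- function(v) v[order(names(v))]
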