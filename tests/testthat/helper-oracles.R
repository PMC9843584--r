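# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: enumeration via expand.grid, ranks via
# sorting, confusion matrices via explicit loops, edit distance via textbook
# dynamic programming.

# All distinct synonymous nucleotide sequences of `aa` by exhaustive
# cartesian enumeration (keep capacities small in tests).
oracle_enumerate_synonyms <- function(aa, table) {
  residues <- strsplit(aa, "")[[1]]
  lists <- table$mapping[residues]
  grid <- do.call(expand.grid, c(lists, stringsAsFactors = FALSE))
  unique(apply(as.matrix(grid), 1, paste, collapse = ""))
}

# Spearman's rho from scratch: average ranks by sorting, then the Pearson
# formula evaluated term by term.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (val in unique(v)) {
      pos <- which(v == val)
      n_less <- sum(v < val)
      r[pos] <- mean(n_less + seq_along(pos))
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_mcc <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Textbook Wagner-Fischer Levenshtein distance.
oracle_levenshtein <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(s) + 1L, length(t) + 1L)
  d[, 1] <- 0:length(s)
  d[1, ] <- 0:length(t)
  for (i in seq_along(s)) {
    for (j in seq_along(t)) {
      cost <- if (s[i] == t[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[length(s) + 1L, length(t) + 1L]
}

# Codon-level Hamming distance between two equal-length nucleotide strings.
codon_hamming <- function(a, b) {
  starts <- seq(1, nchar(a), by = 3)
  sum(substring(a, starts, starts + 2) != substring(b, starts, starts + 2))
}

random_aa <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(ntaug:::AA_LETTERS, len, replace = TRUE),
                           collapse = ""),
         character(1))
}

all_tables <- function(seed = 3L) {
  list(natural = natural_codon_table(),
       balanced = balanced_codon_table(seed),
       shuffled = shuffled_codon_table(seed))
}
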