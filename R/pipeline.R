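#' Levenshtein edit distance between sequences
#'
#' Substitutions, insertions and deletions each cost 1. Vectorized over the
#' longer argument with the usual recycling of the shorter one.
#'
#' @param a,b Character vectors of sequences.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("ACDE", "ACDF") # 1
#' @export
edit_distance <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1 && length(b) > 1) return(as.integer(d[1, ]))
  if (length(b) == 1 && length(a) > 1) return(as.integer(d[, 1]))
  if (length(a) == length(b)) return(as.integer(diag(as.matrix(d))))
  as.integer(d)
}

# Quantile bins on a numeric label (duplicate edges merged); classification
# labels stratify by class directly.
label_bins <- function(labels, task, n_bins) {
  if (task == "classification") {
    return(as.integer(labels))
  }
  edges <- unique(stats::quantile(labels, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 2) return(rep(1L, length(labels)))
  as.integer(cut(labels, breaks = edges, include.lowest = TRUE))
}

# Largest-remainder apportionment of `total` draws across strata of sizes
# `sizes`, proportional to size, never exceeding any stratum's size.
largest_remainder_quota <- function(sizes, total) {
  raw <- sizes / sum(sizes) * total
  quota <- floor(raw)
  rem <- total - sum(quota)
  if (rem > 0) {
    ord <- order(raw - quota, decreasing = TRUE)
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1L
  }
  over <- quota > sizes
  while (any(over)) {
    excess <- sum(quota[over] - sizes[over])
    quota[over] <- sizes[over]
    room <- which(quota < sizes)
    if (!length(room) || excess == 0) break
    ord <- room[order(sizes[room] - quota[room], decreasing = TRUE)]
    for (i in seq_len(excess)) {
      j <- ord[(i - 1L) %% length(ord) + 1L]
      quota[j] <- quota[j] + 1L
    }
    over <- quota > sizes
  }
  as.integer(quota)
}

#' Split a dataset by edit distance from wild type
#'
#' Records at edit distance `<= ed_threshold` from the wild-type sequence
#' form the train/validation pool; records beyond it form the test set. A
#' `valid_fraction` share of the pool is allocated to validation, stratified
#' by label quantile bin (regression) or class (classification).
#'
#' @param dataset Amino-acid labeled dataset.
#' @param wild_type Wild-type amino-acid sequence.
#' @param ed_threshold Maximum edit distance from wild type for train/valid.
#' @param valid_fraction Fraction of the pool used for validation (default
#'   0.2).
#' @param n_bins Number of label quantile bins for stratification.
#' @param seed Integer seed.
#' @return The dataset with `set` tags assigned.
#' @export
split_by_edit_distance <- function(dataset, wild_type, ed_threshold,
                                   valid_fraction = 0.2, n_bins = 10, seed = 0L) {
  stopifnot(ed_threshold >= 1, valid_fraction > 0, valid_fraction < 1)
  meta <- dataset_meta(dataset)
  ed <- edit_distance(dataset$sequence, wild_type)
  pool <- which(ed <= ed_threshold)
  test <- which(ed > ed_threshold)
  if (!length(pool) || !length(test)) {
    abort_ntaug(
      sprintf("Edit-distance threshold %d leaves an empty %s partition.",
              ed_threshold, if (length(pool)) "test" else "train"),
      "degenerate_split"
    )
  }
  set_tag <- rep("train", nrow(dataset))
  set_tag[test] <- "test"
  bins <- label_bins(dataset$label[pool], meta$task, n_bins)
  n_valid <- round(valid_fraction * length(pool))
  sizes <- as.integer(table(bins))
  quota <- largest_remainder_quota(sizes, n_valid)
  valid_idx <- with_seed(seed, {
    unlist(mapply(function(b, q) {
      members <- pool[bins == b]
      sample_exact(members, q)
    }, sort(unique(bins)), quota, SIMPLIFY = FALSE))
  })
  set_tag[valid_idx] <- "valid"
  dataset$set <- set_tag
  as_labeled_dataset(dataset, alphabet = meta$alphabet, task = meta$task)
}

#' Stratified truncation of a regression training set
#'
#' Returns a subset of roughly `fraction * n` records whose label-bin
#' proportions match the input's (largest-remainder quotas over quantile
#' bins). `fraction = 1` returns the input unchanged.
#'
#' @param dataset Regression labeled dataset.
#' @param fraction Fraction in `(0, 1]` of records to keep.
#' @param n_bins Number of quantile bins (default 10).
#' @param seed Integer seed.
#' @return The truncated dataset.
#' @export
stratified_truncate <- function(dataset, fraction, n_bins = 10, seed = 0L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(dataset)
  meta <- dataset_meta(dataset)
  n <- nrow(dataset)
  total <- ceiling(fraction * n)
  bins <- label_bins(dataset$label, meta$task, n_bins)
  sizes <- as.integer(table(bins))
  quota <- largest_remainder_quota(sizes, total)
  keep <- with_seed(seed, {
    unlist(mapply(function(b, q) {
      members <- which(bins == b)
      sample_exact(members, q)
    }, sort(unique(bins)), quota, SIMPLIFY = FALSE))
  })
  out <- dataset[sort(keep), ]
  as_labeled_dataset(out, alphabet = meta$alphabet, task = meta$task)
}

#' Impose class imbalance by down-sampling positives
#'
#' Negatives are untouched; positives are down-sampled without replacement to
#' `round(positive_ratio * n_negatives)`. A ratio of 1 on balanced input is
#' the identity.
#'
#' @param dataset Classification labeled dataset.
#' @param positive_ratio Target positive:negative ratio in `(0, 1]`.
#' @param seed Integer seed.
#' @return The imbalanced dataset (input order preserved).
#' @export
impose_class_imbalance <- function(dataset, positive_ratio, seed = 0L) {
  stopifnot(positive_ratio > 0, positive_ratio <= 1)
  meta <- dataset_meta(dataset)
  if (meta$task != "classification") {
    abort_ntaug("Class imbalance applies to classification datasets.", "config_error")
  }
  pos <- which(dataset$label == 1)
  neg <- which(dataset$label == 0)
  if (!length(pos) || !length(neg)) {
    abort_ntaug("Both classes must be present.", "config_error")
  }
  n_target <- round(positive_ratio * length(neg))
  if (n_target > length(pos)) {
    abort_ntaug(
      sprintf("Ratio %.2f requests %d positives but only %d are available.",
              positive_ratio, n_target, length(pos)),
      "infeasible_ratio"
    )
  }
  keep_pos <- with_seed(seed, sample_exact(pos, n_target))
  out <- dataset[sort(c(keep_pos, neg)), ]
  as_labeled_dataset(out, alphabet = meta$alphabet, task = meta$task)
}

#' Augment only the minority class of a classification set
#'
#' The minority class (by count) is augmented `n_aug`-fold per record; the
#' majority class is reverse translated once per record without augmentation
#' (random codon sampling, seeded). Labels are preserved. A tie in class
#' counts is ambiguous and must be resolved via `minority_class`.
#'
#' @param dataset Amino-acid classification dataset.
#' @param cfg An [aug_config()].
#' @param minority_class Optional explicit minority class (0 or 1).
#' @return A nucleotide classification dataset with provenance columns.
#' @export
augment_minority_class <- function(dataset, cfg, minority_class = NULL) {
  stopifnot(inherits(cfg, "aug_config"))
  meta <- dataset_meta(dataset)
  if (meta$task != "classification" || meta$alphabet != "amino_acid") {
    abort_ntaug("Minority-class augmentation needs an amino-acid classification dataset.",
                "config_error")
  }
  n_pos <- sum(dataset$label == 1)
  n_neg <- sum(dataset$label == 0)
  if (is.null(minority_class)) {
    if (n_pos == n_neg) {
      abort_ntaug("Class counts are tied; pass `minority_class` explicitly.",
                  "ambiguous_minority")
    }
    minority_class <- if (n_pos < n_neg) 1 else 0
  }
  minority <- dataset[dataset$label == minority_class, ]
  majority <- dataset[dataset$label != minority_class, ]
  minority <- as_labeled_dataset(minority, meta$alphabet, meta$task)
  majority <- as_labeled_dataset(majority, meta$alphabet, meta$task)
  aug_min <- augment_dataset_offline(minority, cfg)
  plain_cfg <- aug_config(1L, method = "random", table = cfg$table,
                          seed = cfg$seed + nrow(dataset))
  aug_maj <- suppressWarnings(augment_dataset_offline(majority, plain_cfg))
  out <- rbind(aug_min, aug_maj)
  as_labeled_dataset(out, alphabet = "nucleotide", task = "classification")
}

#' Reverse translate a test set into replicated nucleotide versions
#'
#' Produces `k` nucleotide datasets with identical amino-acid identities and
#' ordering, differing only in codon realization. Replicate `i` uses seed
#' `base_seed + i`. With `mode = "deterministic"` (mirroring iterative
#' training setups) all replicates are identical; with `mode = "random"`
#' codons are drawn independently per replicate.
#'
#' @param dataset Amino-acid labeled dataset (typically the test split).
#' @param table A [codon_table].
#' @param mode `"deterministic"` or `"random"` codon sampling.
#' @param base_seed Integer base seed.
#' @param k Number of replicates (default 5).
#' @return A list of class `nta_test_replicates` holding `k` nucleotide
#'   datasets.
#' @export
make_test_replicates <- function(dataset, table = natural_codon_table(),
                                 mode = c("deterministic", "random"),
                                 base_seed = 0L, k = 5L) {
  mode <- match.arg(mode)
  meta <- dataset_meta(dataset)
  if (meta$alphabet != "amino_acid") {
    abort_ntaug("Test replication expects an amino-acid dataset.", "config_error")
  }
  reps <- lapply(seq_len(k), function(i) {
    nts <- if (nrow(dataset) == 0) {
      character()
    } else if (mode == "deterministic") {
      vapply(dataset$sequence, reverse_translate, character(1),
             table = table, USE.NAMES = FALSE)
    } else {
      with_seed(base_seed + i, vapply(
        dataset$sequence,
        function(s) reverse_translate(s, table, mode = "random"),
        character(1), USE.NAMES = FALSE
      ))
    }
    out <- dataset
    out$sequence <- nts
    as_labeled_dataset(out, alphabet = "nucleotide", task = meta$task)
  })
  structure(list(replicates = reps, base_seed = as.integer(base_seed),
                 mode = mode),
            class = "nta_test_replicates")
}
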