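#' Offline augmentation configuration
#'
#' @param n_aug Augmentation factor: number of nucleotide sequences emitted
#'   per amino-acid training sequence (>= 1).
#' @param method `"iterative"` (deterministic cartesian-product enumeration)
#'   or `"random"` (independent uniform codon draws).
#' @param table A [codon_table].
#' @param seed Integer seed driving the random method.
#' @return An `aug_config` list.
#' @export
aug_config <- function(n_aug, method = c("iterative", "random"),
                       table = natural_codon_table(), seed = 0L) {
  method <- match.arg(method)
  if (!is.numeric(n_aug) || length(n_aug) != 1 || n_aug < 1 || n_aug != floor(n_aug)) {
    abort_ntaug("`n_aug` must be a positive integer.", "config_error")
  }
  stopifnot(inherits(table, "codon_table"))
  structure(
    list(n_aug = as.integer(n_aug), method = method, table = table,
         seed = as.integer(seed)),
    class = "aug_config"
  )
}

#' Online augmentation configuration
#'
#' Per mini-batch sequence, a modification probability `p_aug ~ Uniform(0,1)`
#' is drawn; when `p_aug` strictly exceeds the threshold `t_aug` the sequence
#' is modified by substituting at most `floor(num_subs * L)` codons (L = codon
#' count) with synonymous alternatives.
#'
#' @param t_aug Threshold in `[0, 1]`; 0.5 by default.
#' @param num_subs Maximum fraction of codon positions substituted per
#'   modified sequence, in `(0, 1]`; 0.25 by default.
#' @param table A [codon_table].
#' @param seed Integer seed for the augmentation RNG stream.
#' @return An `online_aug_config` list.
#' @export
online_aug_config <- function(t_aug = 0.5, num_subs = 0.25,
                              table = natural_codon_table(), seed = 0L) {
  if (!is.numeric(t_aug) || t_aug < 0 || t_aug > 1) {
    abort_ntaug("`t_aug` must lie in [0, 1].", "config_error")
  }
  if (!is.numeric(num_subs) || num_subs <= 0 || num_subs > 1) {
    abort_ntaug("`num_subs` must lie in (0, 1].", "config_error")
  }
  stopifnot(inherits(table, "codon_table"))
  structure(
    list(t_aug = t_aug, num_subs = num_subs, table = table,
         seed = as.integer(seed)),
    class = "online_aug_config"
  )
}

# Mixed-radix enumeration of per-position codon choices, leftmost position
# varying fastest, starting from the all-first (deterministic) sequence.
# Returns up to n sequences.
enumerate_synonyms <- function(aa, table, n) {
  check_aa(aa)
  residues <- strsplit(aa, "")[[1]]
  lists <- table$mapping[residues]
  radix <- lengths(lists)
  capacity <- prod(radix)
  n_out <- min(n, capacity)
  digits <- rep(0L, length(radix))
  out <- character(n_out)
  for (i in seq_len(n_out)) {
    out[i] <- paste(
      mapply(function(l, d) l[[d + 1L]], lists, digits),
      collapse = ""
    )
    # increment: leftmost digit fastest
    j <- 1L
    while (j <= length(digits)) {
      digits[j] <- digits[j] + 1L
      if (digits[j] < radix[j]) break
      digits[j] <- 0L
      j <- j + 1L
    }
  }
  out
}

#' Offline iterative augmentation of one sequence
#'
#' Emits the deterministic reverse translation first, then walks the
#' cartesian product of per-position codon choices in a fixed order (leftmost
#' position varying fastest), so early augmentations differ from the base
#' sequence only near the sequence start. Output is capped at the synonym
#' capacity, with a warning when `n_aug` exceeds it.
#'
#' @param aa Amino-acid string.
#' @param n_aug Number of augmentations requested.
#' @param table A [codon_table].
#' @return Character vector of distinct synonymous nucleotide sequences, of
#'   length `min(n_aug, synonym_capacity(aa, table))`.
#' @examples
#' augment_offline_iterative("KK", 3, natural_codon_table())
#' @export
augment_offline_iterative <- function(aa, n_aug, table = natural_codon_table()) {
  stopifnot(inherits(table, "codon_table"))
  capacity <- synonym_capacity(aa, table)
  if (n_aug > capacity) {
    warning(sprintf(
      "n_aug = %d exceeds the synonym capacity %.0f of '%s'; output capped.",
      n_aug, capacity, aa
    ), call. = FALSE)
  }
  enumerate_synonyms(aa, table, n_aug)
}

#' Offline random augmentation of one sequence
#'
#' Draws `n_aug` independent random reverse translations (each residue's
#' codon uniform over its codon list). Duplicates are permitted and trigger
#' a warning, as does `n_aug` above the synonym capacity.
#'
#' @inheritParams augment_offline_iterative
#' @param seed Integer seed; output is deterministic in it.
#' @return Character vector of length `n_aug`.
#' @export
augment_offline_random <- function(aa, n_aug, table = natural_codon_table(),
                                   seed = 0L) {
  stopifnot(inherits(table, "codon_table"))
  capacity <- synonym_capacity(aa, table)
  out <- with_seed(seed, vapply(
    seq_len(n_aug),
    function(i) reverse_translate(aa, table, mode = "random"),
    character(1)
  ))
  if (n_aug > capacity) {
    warning(sprintf(
      "n_aug = %d exceeds the synonym capacity %.0f of '%s'; duplicates are inevitable.",
      n_aug, capacity, aa
    ), call. = FALSE)
  } else if (anyDuplicated(out)) {
    warning(sprintf("Random augmentation of '%s' produced duplicate sequences.", aa),
            call. = FALSE)
  }
  out
}

#' Offline augmentation of a labeled dataset
#'
#' Applies [augment_offline_iterative()] or [augment_offline_random()] to
#' every record, concatenating results in input order with provenance
#' columns. Labels are copied unchanged from each parent record. For the
#' random method, record `i` uses seed `cfg$seed + i - 1`, so the expansion
#' is reproducible and records are independent.
#'
#' @param dataset Amino-acid labeled dataset (see [labeled_dataset()]).
#' @param cfg An [aug_config()].
#' @return A nucleotide labeled dataset with columns `id`, `sequence`,
#'   `label`, `set`, `parent_id`, `aug_index` (0-based).
#' @export
augment_dataset_offline <- function(dataset, cfg) {
  stopifnot(inherits(cfg, "aug_config"))
  meta <- dataset_meta(dataset)
  if (meta$alphabet != "amino_acid") {
    abort_ntaug("Offline augmentation expects an amino-acid dataset.", "config_error")
  }
  if (nrow(dataset) == 0) {
    out <- tibble::tibble(
      id = character(), sequence = character(), label = numeric(),
      set = character(), parent_id = character(), aug_index = integer()
    )
    return(as_labeled_dataset(out, alphabet = "nucleotide", task = meta$task))
  }
  pieces <- vector("list", nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    rec <- dataset[i, ]
    nts <- withCallingHandlers(
      if (cfg$method == "iterative") {
        augment_offline_iterative(rec$sequence, cfg$n_aug, cfg$table)
      } else {
        augment_offline_random(rec$sequence, cfg$n_aug, cfg$table,
                               seed = cfg$seed + i - 1L)
      },
      error = function(e) {
        abort_ntaug(
          sprintf("Augmentation failed for record '%s': %s", rec$id,
                  conditionMessage(e)),
          "augmentation_error", parent = e
        )
      }
    )
    pieces[[i]] <- tibble::tibble(
      id = paste0(rec$id, "_aug", seq_along(nts) - 1L),
      sequence = nts,
      label = rep(rec$label, length(nts)),
      set = rep(rec$set, length(nts)),
      parent_id = rep(rec$id, length(nts)),
      aug_index = seq_along(nts) - 1L
    )
  }
  out <- do.call(rbind, pieces)
  as_labeled_dataset(out, alphabet = "nucleotide", task = meta$task)
}

#' Online probabilistic augmentation of a mini-batch
#'
#' For each nucleotide sequence a fresh `p_aug ~ Uniform(0,1)` is drawn; when
#' `p_aug > t_aug` the sequence is modified: `k` codon positions are chosen
#' uniformly without replacement among positions with degeneracy > 1, with
#' `k` uniform on `{1, ..., max(1, floor(num_subs * L))}` (capped at the
#' number of eligible positions), and each chosen codon is replaced by a
#' uniform draw over its synonymous alternatives excluding itself. Batch
#' size, order and labels are untouched; every output translates to the same
#' amino-acid sequence as its input. Randomness is consumed from the current
#' RNG state of the caller (wrap in a stream for isolation; see
#' [train_model()]).
#'
#' @param nt Character vector of codon-structured nucleotide sequences.
#' @param cfg An [online_aug_config()].
#' @return Character vector of the same length.
#' @export
augment_online_batch <- function(nt, cfg) {
  stopifnot(inherits(cfg, "online_aug_config"))
  table <- cfg$table
  vapply(nt, function(s) {
    aa <- translate_nt(s, table) # validates translatability
    p_aug <- stats::runif(1)
    if (p_aug <= cfg$t_aug) return(s)
    residues <- strsplit(aa, "")[[1]]
    deg <- vapply(table$mapping[residues], length, integer(1))
    eligible <- which(deg > 1L)
    if (!length(eligible)) return(s)
    l_codons <- length(residues)
    k_max <- max(1L, floor(cfg$num_subs * l_codons))
    k <- sample.int(k_max, 1L)
    k <- min(k, length(eligible))
    pos <- sample_exact(eligible, k)
    starts <- seq(1L, nchar(s), by = 3L)
    codons <- substring(s, starts, starts + 2L)
    for (p in pos) {
      alts <- setdiff(table$mapping[[residues[p]]], codons[p])
      codons[p] <- alts[sample.int(length(alts), 1L)]
    }
    paste(codons, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
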