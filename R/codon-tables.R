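#' Amino-acid-to-codon tables
#'
#' A codon table maps each of the 20 canonical amino acids to a non-empty,
#' lexicographically sorted set of sense codons, with every codon assigned to
#' at most one amino acid. Three constructions are provided: the natural
#' standard genetic code ([natural_codon_table()]), a balanced table assigning
#' exactly three codons per residue ([balanced_codon_table()]), and a table
#' that permutes codon identities while conserving the natural degeneracy
#' spectrum ([shuffled_codon_table()]). Stop codons (TAA, TAG, TGA) are never
#' assigned: augmentation operates on coding sequence only.
#'
#' @param mapping Named list, one entry per canonical amino acid letter, each
#'   a character vector of distinct codons over `{A,C,G,T}`.
#' @param name Identifier for the table (`"natural"`, `"balanced"`,
#'   `"shuffled"`, or a custom label).
#' @param seed Integer seed recorded for the seeded constructions, or `NULL`.
#' @return An object of class `codon_table`: a list with elements `name`,
#'   `mapping` (codon lists sorted lexicographically), `seed`, and `reverse`
#'   (codon -> amino acid lookup).
#' @name codon_table
NULL

#' @rdname codon_table
#' @export
codon_table <- function(mapping, name = "custom", seed = NULL) {
  if (!is.list(mapping) || is.null(names(mapping))) {
    abort_ntaug("`mapping` must be a named list of codon vectors.", "config_error")
  }
  keys <- sort(names(mapping))
  if (!identical(keys, AA_LETTERS)) {
    abort_ntaug(
      "Codon table must have exactly the 20 canonical amino-acid keys.",
      "config_error"
    )
  }
  mapping <- lapply(mapping[AA_LETTERS], function(x) sort(unique(as.character(x))))
  all_codons <- unlist(mapping, use.names = FALSE)
  if (length(all_codons) != length(unique(all_codons))) {
    abort_ntaug("A codon is assigned to more than one amino acid.", "config_error")
  }
  if (any(!grepl("^[ACGT]{3}$", all_codons))) {
    abort_ntaug("Codons must be 3-letter strings over {A,C,G,T}.", "config_error")
  }
  if (any(lengths(mapping) == 0)) {
    abort_ntaug("Every amino acid needs at least one codon.", "config_error")
  }
  rev_lookup <- rep(names(mapping), lengths(mapping))
  names(rev_lookup) <- all_codons
  structure(
    list(name = name, mapping = mapping, seed = seed, reverse = rev_lookup),
    class = "codon_table"
  )
}

#' @export
print.codon_table <- function(x, ...) {
  cat(
    sprintf(
      "<codon_table '%s'>: 20 amino acids, %d sense codons%s\n",
      x$name, length(x$reverse),
      if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)
    )
  )
  invisible(x)
}

# 61 sense codons of the standard genetic code, keyed by amino acid.
natural_mapping <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}

#' @rdname codon_table
#' @export
natural_codon_table <- function() {
  codon_table(natural_mapping(), name = "natural")
}

#' @rdname codon_table
#' @param seed Non-negative integer; the construction is deterministic in it.
#' @details The balanced table keeps, for residues with three or more natural
#'   codons, the three lexicographically smallest; residues with fewer keep
#'   all of theirs and are topped up to three from a seeded shuffle of the
#'   then-unassigned sense codons. 60 of the 61 sense codons end up in use.
#' @export
balanced_codon_table <- function(seed) {
  nat <- natural_mapping()
  kept <- lapply(nat, function(cods) sort(cods)[seq_len(min(3L, length(cods)))])
  pool <- setdiff(unlist(nat, use.names = FALSE), unlist(kept, use.names = FALSE))
  pool <- with_seed(seed, sample_exact(sort(pool), length(pool)))
  for (aa in AA_LETTERS) {
    need <- 3L - length(kept[[aa]])
    if (need > 0) {
      kept[[aa]] <- c(kept[[aa]], pool[seq_len(need)])
      pool <- pool[-seq_len(need)]
    }
  }
  codon_table(kept, name = "balanced", seed = as.integer(seed))
}

#' @rdname codon_table
#' @details The shuffled table applies a seeded permutation to the 61 sense
#'   codons and deals them back out in the natural per-residue counts,
#'   iterating residues alphabetically, so the degeneracy spectrum is
#'   conserved while codon identities are scrambled.
#' @export
shuffled_codon_table <- function(seed) {
  nat <- natural_mapping()[AA_LETTERS]
  codons <- sort(unlist(nat, use.names = FALSE))
  perm <- with_seed(seed, sample_exact(codons, length(codons)))
  counts <- lengths(nat)
  out <- vector("list", 20L)
  names(out) <- AA_LETTERS
  at <- 0L
  for (aa in AA_LETTERS) {
    out[[aa]] <- perm[at + seq_len(counts[[aa]])]
    at <- at + counts[[aa]]
  }
  codon_table(out, name = "shuffled", seed = as.integer(seed))
}

#' Per-amino-acid codon counts of a table
#'
#' @param table A [codon_table].
#' @return Named integer vector of codon-list lengths, one per amino acid.
#' @export
codon_degeneracy <- function(table) {
  stopifnot(inherits(table, "codon_table"))
  lengths(table$mapping)
}

check_aa <- function(aa) {
  if (length(aa) != 1 || !is.character(aa) || is.na(aa)) {
    abort_ntaug("Amino-acid sequence must be a single string.", "unsupported_residue")
  }
  bad <- setdiff(strsplit(aa, "")[[1]], AA_LETTERS)
  if (length(bad)) {
    abort_ntaug(
      sprintf(
        "Unsupported residue(s) %s: only the 20 canonical amino acids can be reverse translated.",
        paste(sQuote(unique(bad)), collapse = ", ")
      ),
      "unsupported_residue"
    )
  }
  invisible(aa)
}

#' Translate a codon-structured nucleotide sequence
#'
#' Reverse-lookup translation, codon by codon, under an arbitrary
#' amino-acid-to-codon table. Codons not assigned in the table (stop codons
#' under the natural table, or unassigned codons under a balanced table)
#' raise an untranslatable-codon error.
#'
#' @param nt Nucleotide string over `{A,C,G,T}`, length a multiple of 3.
#' @param table A [codon_table].
#' @return The translated amino-acid string.
#' @examples
#' translate_nt("ATGTGG", natural_codon_table()) # "MW"
#' @export
translate_nt <- function(nt, table) {
  stopifnot(inherits(table, "codon_table"), is.character(nt), length(nt) == 1)
  n <- nchar(nt)
  if (n == 0 || n %% 3 != 0) {
    abort_ntaug(
      sprintf("Sequence length %d is not a positive multiple of 3.", n),
      "malformed_sequence"
    )
  }
  starts <- seq(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(table$reverse[codons])
  if (anyNA(aa)) {
    i <- which(is.na(aa))[1]
    abort_ntaug(
      sprintf(
        "Codon '%s' at codon position %d is not assigned in table '%s'.",
        codons[i], i, table$name
      ),
      "untranslatable_codon"
    )
  }
  paste(aa, collapse = "")
}

#' Reverse translate an amino-acid sequence
#'
#' Deterministic mode always picks the lexicographically first codon of each
#' residue; random mode draws each residue's codon uniformly and
#' independently from its codon list. In both modes the result translates
#' back to `aa` under the same table.
#'
#' @param aa Amino-acid string over the 20 canonical letters.
#' @param table A [codon_table].
#' @param mode `"deterministic"` or `"random"`.
#' @param seed Integer seed, required for random mode (ignored otherwise).
#' @return A nucleotide string of length `3 * nchar(aa)`.
#' @examples
#' reverse_translate("MW", natural_codon_table()) # "ATGTGG"
#' @export
reverse_translate <- function(aa, table, mode = c("deterministic", "random"),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "codon_table"))
  check_aa(aa)
  residues <- strsplit(aa, "")[[1]]
  if (mode == "deterministic") {
    codons <- vapply(table$mapping[residues], `[[`, character(1), 1L)
  } else {
    if (is.null(seed)) {
      codons <- vapply(
        table$mapping[residues],
        function(cods) cods[sample.int(length(cods), 1L)],
        character(1)
      )
    } else {
      codons <- with_seed(seed, vapply(
        table$mapping[residues],
        function(cods) cods[sample.int(length(cods), 1L)],
        character(1)
      ))
    }
  }
  paste(codons, collapse = "")
}

#' Number of distinct synonymous nucleotide sequences
#'
#' The product over residues of their codon-list sizes; returned as a double
#' because the count grows geometrically in sequence length.
#'
#' @inheritParams reverse_translate
#' @return A double: the count of distinct synonymous nucleotide sequences.
#' @examples
#' synonym_capacity("MS", natural_codon_table()) # 6
#' @export
synonym_capacity <- function(aa, table) {
  stopifnot(inherits(table, "codon_table"))
  check_aa(aa)
  residues <- strsplit(aa, "")[[1]]
  prod(vapply(table$mapping[residues], length, integer(1)))
}

#' Read or write a codon table as plain text
#'
#' The on-disk format is one residue per line: the amino-acid letter, a tab,
#' and its codons comma-separated — so externally published tables can be
#' supplied verbatim.
#'
#' @param table A [codon_table].
#' @param path File path.
#' @param name Name for the table read from disk.
#' @return `read_codon_table()` returns a [codon_table];
#'   `write_codon_table()` returns `path` invisibly.
#' @export
write_codon_table <- function(table, path) {
  stopifnot(inherits(table, "codon_table"))
  lines <- vapply(
    AA_LETTERS,
    function(aa) paste0(aa, "\t", paste(table$mapping[[aa]], collapse = ",")),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_codon_table
#' @export
read_codon_table <- function(path, name = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort_ntaug("Each line must be '<residue>\\t<codon,codon,...>'.", "parse_error")
  }
  mapping <- lapply(parts, function(p) strsplit(p[[2]], ",", fixed = TRUE)[[1]])
  names(mapping) <- vapply(parts, `[[`, character(1), 1L)
  codon_table(mapping, name = name)
}
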