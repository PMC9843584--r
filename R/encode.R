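#' ngram vocabularies
#'
#' Vocabularies are closed and alphabet-derived, never fitted from data:
#' 4 nucleotide unigrams, 64 codon trigrams, their 68-element concatenation,
#' or the 21 amino-acid unigrams (20 canonical + UNK). Content tokens are
#' ordered lexicographically (UNK last for amino acids) and assigned ids
#' `1..content_size`; the padding token PAD holds the reserved id 0.
#'
#' @param scheme One of `"aa_unigram"`, `"nt_unigram"`, `"nt_trigram"`,
#'   `"nt_tri_unigram"`.
#' @return An object of class `nta_vocabulary`: list with `scheme`, `tokens`
#'   (content tokens in id order), `content_size`, `pad_id = 0`.
#' @examples
#' build_vocabulary("nt_trigram")$content_size # 64
#' @export
build_vocabulary <- function(scheme = c("aa_unigram", "nt_unigram",
                                        "nt_trigram", "nt_tri_unigram")) {
  scheme <- match.arg(scheme)
  trigrams <- sort(apply(expand.grid(NT_LETTERS, NT_LETTERS, NT_LETTERS),
                         1L, paste, collapse = ""))
  tokens <- switch(scheme,
    aa_unigram = c(AA_LETTERS, "UNK"),
    nt_unigram = NT_LETTERS,
    nt_trigram = trigrams,
    nt_tri_unigram = c(trigrams, NT_LETTERS)
  )
  structure(
    list(scheme = scheme, tokens = tokens, content_size = length(tokens),
         pad_id = 0L),
    class = "nta_vocabulary"
  )
}

#' @export
print.nta_vocabulary <- function(x, ...) {
  cat(sprintf("<nta_vocabulary '%s'>: %d content tokens + PAD\n",
              x$scheme, x$content_size))
  invisible(x)
}

#' Tokenize a sequence into ngrams
#'
#' Unigram schemes emit per-character tokens; `nt_trigram` emits consecutive
#' non-overlapping triplets; `nt_tri_unigram` emits the trigram tokens
#' followed by the unigram tokens of the same sequence (token count
#' `L/3 + L`). Out-of-alphabet characters map to UNK for `aa_unigram` and
#' are errors for nucleotide schemes.
#'
#' @param seq A single sequence string.
#' @inheritParams build_vocabulary
#' @return An object of class `nta_tokens`: list with `tokens`, `scheme`,
#'   `source_length`.
#' @examples
#' tokenize("ATGTGG", "nt_trigram")$tokens # "ATG" "TGG"
#' @export
tokenize <- function(seq, scheme = c("aa_unigram", "nt_unigram",
                                     "nt_trigram", "nt_tri_unigram")) {
  scheme <- match.arg(scheme)
  stopifnot(is.character(seq), length(seq) == 1, !is.na(seq))
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  if (scheme == "aa_unigram") {
    toks <- ifelse(chars %in% AA_LETTERS, chars, "UNK")
  } else {
    bad <- setdiff(chars, NT_LETTERS)
    if (length(bad)) {
      abort_ntaug(
        sprintf("Non-nucleotide character(s) %s in sequence.",
                paste(sQuote(unique(bad)), collapse = ", ")),
        "malformed_sequence"
      )
    }
    if (scheme %in% c("nt_trigram", "nt_tri_unigram") && n %% 3 != 0) {
      abort_ntaug(
        sprintf("Length %d is not a multiple of 3; trigram schemes need codon-aligned input.", n),
        "malformed_sequence"
      )
    }
    toks <- switch(scheme,
      nt_unigram = chars,
      nt_trigram = substring(seq, seq(1L, n, 3L), seq(3L, n, 3L)),
      nt_tri_unigram = c(substring(seq, seq(1L, n, 3L), seq(3L, n, 3L)), chars)
    )
  }
  structure(list(tokens = toks, scheme = scheme, source_length = n),
            class = "nta_tokens")
}

#' Categorical (token-id) encoding of a batch
#'
#' Sequences are tokenized, mapped to vocabulary ids, and right-padded with
#' PAD (id 0) to the batch maximum token count. The returned mask is `TRUE`
#' at PAD positions.
#'
#' @param seqs Character vector of sequences (or a list of `nta_tokens`).
#' @param vocab An [build_vocabulary()] vocabulary.
#' @return An object of class `nta_encoded_batch`: list with `token_ids`
#'   (batch x max_len integer matrix), `mask` (logical matrix, `TRUE` = PAD),
#'   `lengths` (token counts), `vocab`.
#' @export
encode_categorical <- function(seqs, vocab) {
  stopifnot(inherits(vocab, "nta_vocabulary"))
  tok_lists <- if (is.list(seqs) && all(vapply(seqs, inherits, logical(1), "nta_tokens"))) {
    lapply(seqs, `[[`, "tokens")
  } else {
    lapply(seqs, function(s) tokenize(s, vocab$scheme)$tokens)
  }
  b <- length(tok_lists)
  lens <- vapply(tok_lists, length, integer(1))
  max_len <- if (b) max(lens) else 0L
  ids <- matrix(vocab$pad_id, nrow = b, ncol = max_len)
  for (i in seq_len(b)) {
    m <- match(tok_lists[[i]], vocab$tokens)
    if (anyNA(m)) {
      j <- which(is.na(m))[1]
      abort_ntaug(
        sprintf("Token '%s' at position %d of sequence %d is not in the '%s' vocabulary.",
                tok_lists[[i]][j], j, i, vocab$scheme),
        "encoding_error"
      )
    }
    if (lens[i]) ids[i, seq_len(lens[i])] <- m
  }
  mask <- matrix(rep(seq_len(max_len), each = b) > lens, nrow = b, ncol = max_len)
  structure(
    list(token_ids = ids, mask = mask, lengths = lens, vocab = vocab),
    class = "nta_encoded_batch"
  )
}

#' One-hot encoding of a categorical batch
#'
#' Adds a `one_hot` array of dimension batch x max_len x content_size:
#' non-PAD positions are unit rows, PAD positions are all-zero rows.
#'
#' @param encoded An `nta_encoded_batch` from [encode_categorical()].
#' @param vocab The vocabulary used for encoding (defaults to the one stored
#'   in the batch).
#' @return The batch with a `one_hot` element added.
#' @export
encode_one_hot <- function(encoded, vocab = encoded$vocab) {
  if (!inherits(encoded, "nta_encoded_batch") || is.null(encoded$token_ids)) {
    abort_ntaug("`encoded` must carry token_ids from encode_categorical().",
                "config_error")
  }
  ids <- encoded$token_ids
  b <- nrow(ids)
  max_len <- ncol(ids)
  v <- vocab$content_size
  oh <- array(0, dim = c(b, max_len, v))
  nonpad <- which(ids != vocab$pad_id, arr.ind = TRUE)
  if (nrow(nonpad)) {
    oh[cbind(nonpad[, 1], nonpad[, 2], ids[nonpad])] <- 1
  }
  encoded$one_hot <- oh
  encoded
}

#' Export an encoded batch as a portable JSON bundle
#'
#' Writes `token_ids`, `mask`, `lengths` and (when present) `one_hot` with
#' their dimensions, so downstream consumers in any language can reload the
#' arrays.
#'
#' @param encoded An `nta_encoded_batch`.
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
write_encoded_batch <- function(encoded, path) {
  stopifnot(inherits(encoded, "nta_encoded_batch"))
  bundle <- list(
    scheme = encoded$vocab$scheme,
    tokens = encoded$vocab$tokens,
    dim_token_ids = dim(encoded$token_ids),
    token_ids = as.vector(encoded$token_ids),
    mask = as.vector(encoded$mask),
    lengths = encoded$lengths
  )
  if (!is.null(encoded$one_hot)) {
    bundle$dim_one_hot <- dim(encoded$one_hot)
    bundle$one_hot <- as.vector(encoded$one_hot)
  }
  jsonlite::write_json(bundle, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
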