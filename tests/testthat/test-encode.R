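test_that("vocabularies are closed with the documented sizes", {
  expect_identical(build_vocabulary("nt_unigram")$content_size, 4L)
  expect_identical(build_vocabulary("nt_trigram")$content_size, 64L)
  expect_identical(build_vocabulary("nt_tri_unigram")$content_size, 68L)
  expect_identical(build_vocabulary("aa_unigram")$content_size, 21L)
  for (s in c("aa_unigram", "nt_unigram", "nt_trigram", "nt_tri_unigram")) {
    v <- build_vocabulary(s)
    expect_identical(anyDuplicated(v$tokens), 0L) # token <-> id bijection
    expect_identical(v$pad_id, 0L)
  }
  expect_identical(utils::tail(build_vocabulary("aa_unigram")$tokens, 1), "UNK")
})

test_that("tokenization follows the scheme-specific closed forms", {
  expect_identical(tokenize("ATGTGG", "nt_trigram")$tokens, c("ATG", "TGG"))
  expect_identical(tokenize("ACDEF", "aa_unigram")$tokens,
                   c("A", "C", "D", "E", "F"))
  tk <- tokenize("ATGTGGAAA", "nt_tri_unigram")
  expect_length(tk$tokens, 12) # L/3 + L for L = 9
  expect_identical(tk$tokens[1:3], c("ATG", "TGG", "AAA"))
  expect_identical(tokenize("ACDEFXZ", "aa_unigram")$tokens[6:7], c("UNK", "UNK"))
  expect_error(tokenize("ATGT", "nt_trigram"), class = "ntaug_malformed_sequence")
  expect_error(tokenize("ATGU", "nt_unigram"), class = "ntaug_malformed_sequence")
  # closed forms over a range of lengths
  set.seed(8)
  for (len in seq(3, 300, by = 51)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    expect_length(tokenize(s, "nt_unigram")$tokens, len)
    expect_length(tokenize(s, "nt_trigram")$tokens, len / 3)
    expect_length(tokenize(s, "nt_tri_unigram")$tokens, len / 3 + len)
  }
})

test_that("detokenization reconstructs the source sequence", {
  set.seed(9)
  for (i in 1:5) {
    len <- sample(c(3, 9, 30), 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    expect_identical(paste(tokenize(s, "nt_unigram")$tokens, collapse = ""), s)
    expect_identical(paste(tokenize(s, "nt_trigram")$tokens, collapse = ""), s)
    tu <- tokenize(s, "nt_tri_unigram")$tokens
    expect_identical(paste(tu[seq_len(len / 3)], collapse = ""), s)
    expect_identical(paste(tu[-seq_len(len / 3)], collapse = ""), s)
  }
})

test_that("categorical encoding pads to batch maximum and masks PAD", {
  v <- build_vocabulary("nt_trigram")
  enc <- encode_categorical(c("ATGTGG", "ATGTGGAAA"), v)
  expect_identical(dim(enc$token_ids), c(2L, 3L))
  expect_identical(sum(enc$token_ids == 0), 1L)
  expect_identical(enc$mask[1, ], c(FALSE, FALSE, TRUE))
  expect_identical(enc$mask[2, ], c(FALSE, FALSE, FALSE))
  # equal lengths -> no padding
  eq <- encode_categorical(c("ATGTGG", "AAACCC"), v)
  expect_false(any(eq$mask))
  # empty batch keeps consistent dimensions
  e0 <- encode_categorical(character(0), v)
  expect_identical(dim(e0$token_ids), c(0L, 0L))
  expect_identical(dim(e0$mask), c(0L, 0L))
  # ids are stable across calls
  expect_identical(encode_categorical("ATGTGG", v)$token_ids,
                   encode_categorical("ATGTGG", v)$token_ids)
})

test_that("one-hot shapes follow the scheme closed forms for a 9-nt sequence", {
  nine <- "ATGTGGAAA"
  u <- encode_one_hot(encode_categorical(nine, build_vocabulary("nt_unigram")))
  expect_identical(dim(u$one_hot)[2:3], c(9L, 4L))
  tr <- encode_one_hot(encode_categorical(nine, build_vocabulary("nt_trigram")))
  expect_identical(dim(tr$one_hot)[2:3], c(3L, 64L))
  tu <- encode_one_hot(encode_categorical(nine, build_vocabulary("nt_tri_unigram")))
  expect_identical(dim(tu$one_hot)[2:3], c(12L, 68L))
  # amino acids: 21 columns, support restricted to the 20 canonical ones
  aa <- encode_one_hot(encode_categorical("ACDEFGHIKL", build_vocabulary("aa_unigram")))
  expect_identical(dim(aa$one_hot)[2:3], c(10L, 21L))
  expect_identical(sum(aa$one_hot[1, , 21]), 0) # no UNK column activity
})

test_that("one-hot rows are unit at content positions and zero at PAD", {
  v <- build_vocabulary("nt_unigram")
  set.seed(10)
  seqs <- vapply(sample(2:12, 6, replace = TRUE), function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  enc <- encode_one_hot(encode_categorical(seqs, v))
  row_sums <- apply(enc$one_hot, c(1, 2), sum)
  expect_identical(unname(row_sums[!enc$mask]), rep(1, sum(!enc$mask)))
  expect_identical(unname(row_sums[enc$mask]), rep(0, sum(enc$mask)))
  # argmax of each non-PAD one-hot row equals its token id
  for (i in seq_along(seqs)) {
    for (t in seq_len(enc$lengths[i])) {
      expect_identical(which.max(enc$one_hot[i, t, ]),
                       as.integer(enc$token_ids[i, t]))
    }
  }
})

test_that("encoding rejects tokens outside the vocabulary", {
  v <- build_vocabulary("nt_unigram")
  expect_error(encode_categorical("ATGN", v), class = "ntaug_malformed_sequence")
  expect_error(encode_one_hot(structure(list(), class = "nta_encoded_batch")),
               class = "ntaug_config_error")
})

test_that("encoded batches export to a reloadable JSON bundle", {
  v <- build_vocabulary("nt_unigram")
  enc <- encode_one_hot(encode_categorical(c("ATG", "ATGAAA"), v))
  path <- withr::local_tempfile(fileext = ".json")
  write_encoded_batch(enc, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(array(as.integer(back$token_ids), back$dim_token_ids),
                   array(as.integer(enc$token_ids), dim(enc$token_ids)))
  expect_identical(array(as.numeric(back$one_hot), back$dim_one_hot), enc$one_hot)
  expect_identical(as.integer(back$lengths), enc$lengths)
})
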