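test_that("iterative augmentation enumerates the cartesian product leftmost-first", {
  nat <- natural_codon_table()
  expect_warning(one <- augment_offline_iterative("M", 5, nat), "capacity")
  expect_identical(one, "ATG")
  expect_identical(augment_offline_iterative("KK", 3, nat),
                   c("AAAAAA", "AAGAAA", "AAAAAG"))
  out <- augment_offline_iterative("MS", 6, nat)
  expect_length(out, 6)
  expect_identical(anyDuplicated(out), 0L)
  expect_setequal(out, oracle_enumerate_synonyms("MS", nat))
  expect_true(all(vapply(out, translate_nt, character(1), table = nat) == "MS"))
  # first record is the deterministic reverse translation
  expect_identical(out[1], reverse_translate("MS", nat))
})

test_that("iterative output at capacity equals brute-force enumeration as a set", {
  for (tab in all_tables(seed = 9)) {
    for (s in c("MS", "ACD", "KLM")) {
      cap <- synonym_capacity(s, tab)
      out <- augment_offline_iterative(s, cap, tab)
      expect_setequal(out, oracle_enumerate_synonyms(s, tab))
    }
  }
})

test_that("iterative augmentation caps at capacity with a warning", {
  nat <- natural_codon_table()
  expect_warning(out <- augment_offline_iterative("MS", 10, nat),
                 "capacity")
  expect_length(out, 6)
})

test_that("random augmentation is seeded, synonymous, and warns on duplicates", {
  nat <- natural_codon_table()
  expect_warning(out <- augment_offline_random("M", 4, nat, seed = 1), "capacity")
  expect_identical(out, rep("ATG", 4))
  a <- suppressWarnings(augment_offline_random("MS", 3, nat, seed = 5))
  b <- suppressWarnings(augment_offline_random("MS", 3, nat, seed = 5))
  expect_identical(a, b)
  expect_warning(big <- augment_offline_random("MS", 100, nat, seed = 2),
                 "capacity")
  expect_length(big, 100)
  expect_true(all(unique(big) %in% oracle_enumerate_synonyms("MS", nat)))
})

test_that("dataset-level offline augmentation preserves labels and provenance", {
  ds <- labeled_dataset(c("KLMW", "ACDE"), c(1.5, -0.2),
                        alphabet = "amino_acid", task = "regression")
  cfg <- aug_config(5, method = "random", seed = 3)
  # duplicate draws among the 5 random reverse translations are legitimate
  out <- suppressWarnings(augment_dataset_offline(ds, cfg))
  expect_identical(nrow(out), 10L)
  expect_identical(out$parent_id, rep(ds$id, each = 5))
  expect_identical(out$aug_index, rep(0:4, 2))
  expect_identical(out$label, rep(ds$label, each = 5))
  nat <- natural_codon_table()
  expect_identical(vapply(out$sequence, translate_nt, character(1), table = nat,
                          USE.NAMES = FALSE),
                   rep(ds$sequence, each = 5))
  # empty input -> empty output
  empty <- ds[0, ]
  empty <- as_labeled_dataset(empty, "amino_acid", "regression")
  expect_identical(nrow(augment_dataset_offline(empty, cfg)), 0L)
  # iterative past capacity warns and caps
  one <- labeled_dataset("MS", 1, alphabet = "amino_acid", task = "regression")
  expect_warning(capped <- augment_dataset_offline(one, aug_config(10, "iterative")),
                 "capacity")
  expect_identical(nrow(capped), 6L)
})

test_that("synonymy holds for all augmentation variants over all table types", {
  seqs <- random_aa(5, 8, seed = 21)
  for (tab in all_tables(seed = 17)) {
    for (s in seqs) {
      it <- suppressWarnings(augment_offline_iterative(s, 4, tab))
      rd <- suppressWarnings(augment_offline_random(s, 4, tab, seed = 23))
      expect_true(all(vapply(it, translate_nt, character(1), table = tab) == s))
      expect_true(all(vapply(rd, translate_nt, character(1), table = tab) == s))
    }
    nts <- vapply(seqs, function(s) reverse_translate(s, tab, "random", seed = 29),
                  character(1), USE.NAMES = FALSE)
    cfg <- online_aug_config(t_aug = 0.2, num_subs = 0.5, table = tab)
    set.seed(31)
    out <- augment_online_batch(nts, cfg)
    expect_identical(vapply(out, translate_nt, character(1), table = tab,
                            USE.NAMES = FALSE), unname(seqs))
  }
})

test_that("online augmentation is the identity at t_aug = 1 and on degenerate input", {
  nat <- natural_codon_table()
  nts <- c("ATGAGTAAA", "TGGTACAAA")
  set.seed(1)
  expect_identical(augment_online_batch(nts, online_aug_config(t_aug = 1.0)), nts)
  all_met <- rep("ATGATGATG", 5)
  set.seed(2)
  expect_identical(augment_online_batch(all_met, online_aug_config(t_aug = 0.0)),
                   all_met)
})

test_that("online modification rate tracks t_aug and respects the codon cap", {
  base <- reverse_translate("KLMWSACDE", natural_codon_table()) # 9 codons
  batch <- rep(base, 1000)
  cfg <- online_aug_config(t_aug = 0.5, num_subs = 0.25)
  set.seed(41)
  out <- augment_online_batch(batch, cfg)
  modified <- out != batch
  # P(modify) = P(U > 0.5) = 0.5; binomial(1000, 0.5) 4-sigma band
  expect_gt(mean(modified), 0.5 - 4 * sqrt(0.25 / 1000))
  expect_lt(mean(modified), 0.5 + 4 * sqrt(0.25 / 1000))
  dists <- mapply(codon_hamming, out[modified], batch[modified])
  expect_true(all(dists >= 1))
  expect_true(all(dists <= floor(0.25 * 9))) # <= 2 codons
})

test_that("augmentation configs validate their hyperparameters", {
  expect_error(aug_config(0), class = "ntaug_config_error")
  expect_error(online_aug_config(t_aug = 1.5), class = "ntaug_config_error")
  expect_error(online_aug_config(num_subs = 0), class = "ntaug_config_error")
})
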