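test_that("natural table matches the standard genetic code", {
  nat <- natural_codon_table()
  expect_identical(nat$mapping$M, "ATG")
  expect_identical(nat$mapping$W, "TGG")
  expect_length(nat$mapping$S, 6)
  expect_length(nat$mapping$L, 6)
  expect_length(nat$mapping$R, 6)
  # sense-codon count by independent enumeration: 64 triplets minus stops
  triplets <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = "")
  n_sense <- length(setdiff(triplets, c("TAA", "TAG", "TGA")))
  expect_identical(sum(lengths(nat$mapping)), n_sense)
  expect_identical(sum(lengths(nat$mapping)), 61L)
  # codon lists sorted, duplicate-free, reverse lookup is a function
  for (aa in names(nat$mapping)) {
    expect_identical(nat$mapping[[aa]], sort(unique(nat$mapping[[aa]])))
  }
  all_codons <- unlist(nat$mapping, use.names = FALSE)
  expect_identical(length(all_codons), length(unique(all_codons)))
})

test_that("balanced table allocates exactly three codons per residue", {
  bal <- balanced_codon_table(0)
  expect_true(all(codon_degeneracy(bal) == 3))
  codons <- unlist(bal$mapping, use.names = FALSE)
  expect_identical(length(unique(codons)), 60L)
  expect_false(any(c("TAA", "TAG", "TGA") %in% codons))
  expect_identical(balanced_codon_table(0), balanced_codon_table(0))
  b0 <- balanced_codon_table(0)$mapping
  b1 <- balanced_codon_table(1)$mapping
  expect_false(identical(b0, b1))
})

test_that("shuffled table conserves the natural degeneracy spectrum", {
  sh <- shuffled_codon_table(0)
  expect_length(sh$mapping$S, 6)
  expect_length(sh$mapping$M, 1)
  expected_spectrum <- sort(c(6, 6, 6, 4, 4, 4, 4, 4, 3,
                              2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 1))
  expect_identical(sort(unname(codon_degeneracy(sh))), as.integer(expected_spectrum))
  expect_identical(shuffled_codon_table(0), shuffled_codon_table(0))
})

test_that("shuffled-table degeneracy conservation holds across many seeds", {
  nat_deg <- sort(unname(codon_degeneracy(natural_codon_table())))
  for (seed in 0:99) {
    sh <- shuffled_codon_table(seed)
    expect_identical(sort(unname(codon_degeneracy(sh))), nat_deg)
    codons <- unlist(sh$mapping, use.names = FALSE)
    expect_identical(length(unique(codons)), 61L)
  }
})

test_that("translate performs codon-wise reverse lookup with clear errors", {
  nat <- natural_codon_table()
  expect_identical(translate_nt("ATGTGG", nat), "MW")
  expect_error(translate_nt("ATGT", nat), class = "ntaug_malformed_sequence")
  expect_error(translate_nt("ATGTAA", nat), class = "ntaug_untranslatable_codon")
  expect_error(translate_nt("ATGTAA", nat), "TAA")
  bal <- balanced_codon_table(0)
  unassigned <- setdiff(names(nat$reverse), names(bal$reverse))
  expect_length(unassigned, 1)
  expect_error(translate_nt(unassigned, bal), class = "ntaug_untranslatable_codon")
})

test_that("reverse translation is synonymous and mode-faithful", {
  nat <- natural_codon_table()
  expect_identical(reverse_translate("MW", nat), "ATGTGG")
  expect_identical(reverse_translate("K", nat), "AAA") # lexicographic first of AAA/AAG
  r <- reverse_translate("MS", nat, mode = "random", seed = 7)
  expect_identical(nchar(r), 6L)
  expect_identical(translate_nt(r, nat), "MS")
  expect_identical(reverse_translate("MS", nat, "random", seed = 7),
                   reverse_translate("MS", nat, "random", seed = 7))
  expect_error(reverse_translate("MX", nat), class = "ntaug_unsupported_residue")
})

test_that("round trip holds for every table and mode", {
  tabs <- all_tables(seed = 11)
  seqs <- random_aa(8, 12, seed = 5)
  for (tab in tabs) {
    for (s in seqs) {
      expect_identical(translate_nt(reverse_translate(s, tab), tab), s)
      r <- reverse_translate(s, tab, mode = "random", seed = 13)
      expect_identical(translate_nt(r, tab), s)
    }
  }
})

test_that("synonym capacity equals exhaustive enumeration", {
  nat <- natural_codon_table()
  expect_identical(synonym_capacity("M", nat), 1)
  expect_identical(synonym_capacity("MS", nat), 6)
  expect_identical(synonym_capacity("AC", balanced_codon_table(4)), 9)
  for (s in c("MS", "KLM", "ACD", "WYV", "SSP")) {
    for (tab in all_tables(seed = 2)) {
      syn <- oracle_enumerate_synonyms(s, tab)
      expect_identical(synonym_capacity(s, tab), as.numeric(length(syn)))
      expect_true(all(vapply(syn, translate_nt, character(1), table = tab) == s))
    }
  }
})

test_that("codon tables survive a plain-text round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  sh <- shuffled_codon_table(5)
  write_codon_table(sh, path)
  back <- read_codon_table(path, name = "shuffled")
  expect_identical(back$mapping, sh$mapping)
  expect_identical(back$reverse, sh$reverse)
})
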