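# ntaug — nucleotide augmentation for protein sequence–function learning

Labeled protein sequence–function data is expensive: every fitness value or
binder/non-binder label costs wet-lab time, so training sets for
machine-learning-guided protein engineering are often small or heavily
class-imbalanced. `ntaug` implements **nucleotide augmentation (NTA)**: it
expands a labeled amino-acid dataset by reverse translating each sequence
into multiple *synonymous* nucleotide sequences via codon degeneracy, with
every augmented sequence inheriting its parent's label. Because synonymy is
exact at the protein level, the augmentation never corrupts labels — it is
the sequence analogue of synonym replacement in NLP.

For a protein of length *L* with residues *a₁…a_L*, the number of distinct
nucleotide encodings is ∏ᵢ d(aᵢ), where d(a) ∈ {1,…,6} is the codon
degeneracy of residue *a* in the standard genetic code. NTA samples from
this space with a user-chosen augmentation factor *n*_aug, either

* **offline iterative** — deterministic cartesian-product enumeration of
  codon choices starting from the lexicographically first reverse
  translation,
* **offline random** — *n*_aug independent uniform codon draws per
  sequence, or
* **online probabilistic** — constant dataset size; each mini-batch
  sequence is modified with probability P(*p*_aug > *t*_aug), substituting
  at most ⌊NumSubs·L⌋ codons with synonymous alternatives before each
  gradient step.

The package is a complete workbench around that idea: natural / balanced /
shuffled codon tables, ngram encoders (unigram, trigram, tri+unigram;
vocabularies 4/64/68, amino acids 21), edit-distance train/test splitting,
stratified truncation, class-imbalance and minority-class-augmentation
protocols, five-fold replicated test-set reverse translation, synthetic
combinatorial-landscape and binder-library generators, native CNN and
transformer-encoder reference models trained by SGD with momentum, and
Spearman-rho / MCC evaluation with replicate- and seed-level aggregation.

## Worked example

```r
library(ntaug)

nat <- natural_codon_table()
synonym_capacity("MS", nat)            # 6 — Met has 1 codon, Ser has 6
augment_offline_iterative("KK", 3, nat)
# [1] "AAAAAA" "AAGAAA" "AAAAAG"       Lys codons {AAA, AAG}, leftmost varies first

# a desk-scale experiment on the synthetic saturation-mutagenesis landscape
cfg <- list(
  dataset = list(preset = "gb1_like", n_variants = 3000, max_ed = 4),
  split = list(ed_threshold = 3, valid_fraction = 0.2),
  fraction = 0.1,                       # keep 10% of the training pool
  scheme = "nt_trigram",
  model = list(family = "cnn", preset = "desk"),
  train = list(epochs = 30, patience = 5, batch_size = 32, lr = 0.01),
  seed = 1
)
cfg$condition <- list(type = "dna_baseline", method = "random")
baseline <- run_experiment(cfg)
cfg$condition <- list(type = "offline", method = "random", n_aug = 10)
nta <- run_experiment(cfg)
compare_runs(baseline$metric, list(nta_n10 = nta$metric))
```

With seed 1 this prints (test-set Spearman rho over the 5 reverse-translated
test replicates):

```
# A tibble: 2 × 6
  condition metric        mean    sd n_seeds delta_vs_baseline
  <chr>     <chr>        <dbl> <dbl>   <int>             <dbl>
1 baseline  spearman_rho 0.193     0       1             0
2 nta_n10   spearman_rho 0.916     0       1             0.723
```

(the sd column summarizes across seeds and this example uses one; the
per-replicate values behind the means are 0.200/0.215/0.199/0.169/0.181 for
the baseline and 0.919/0.913/0.918/0.914/0.916 for NTA).

The unaugmented DNA baseline collapses because random codon sampling makes
train and test codon usage disagree; augmentation repairs exactly that while
also multiplying the training set, lifting rho from ~0.2 to ~0.9 at this
training-set size (~190 sequences). A thin command-line wrapper for the
common steps lives at `inst/cli/nta.R`
(`Rscript nta.R simulate|augment|split|evaluate --help`).

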