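# Finite-difference validation of the hand-derived backpropagation, plus the
# forward contracts (shapes, masking, determinism) and training behaviour.

gradcheck_family <- function(family, scheme, task, n_checks = 25) {
  vocab <- build_vocabulary(scheme)
  cfg <- model_config(family, task, "desk", scheme)
  cfg$dropout <- 0 # deterministic loss for the finite-difference probe
  model <- build_model(cfg, vocab, seed = 1)
  seqs <- if (scheme == "aa_unigram") {
    c("MSKG", "KLVING", "ACDEF")
  } else {
    c("ATGAGTAAA", "AAACTGGTTATTAACGGT", "GCATGTGAC")
  }
  y <- if (task == "regression") c(0.5, -1.2, 2.0) else c(1, 0, 1)
  enc <- ntaug:::encode_for_model(model, seqs)
  lg <- ntaug:::model_loss_grads(model, enc, y, train = TRUE)
  g_analytic <- ntaug:::flatten_params(lg$grads)
  flat <- ntaug:::flatten_params(model$params)
  set.seed(42)
  idx <- sample(length(flat), n_checks)
  eps <- 1e-5
  g_num <- vapply(idx, function(i) {
    m1 <- model
    f <- flat
    f[i] <- f[i] + eps
    m1$params <- ntaug:::assign_flat(model$params, f)
    l1 <- ntaug:::model_loss_grads(m1, enc, y, train = TRUE)$loss
    f[i] <- f[i] - 2 * eps
    m1$params <- ntaug:::assign_flat(model$params, f)
    l2 <- ntaug:::model_loss_grads(m1, enc, y, train = TRUE)$loss
    (l1 - l2) / (2 * eps)
  }, numeric(1))
  max(abs(g_num - g_analytic[idx]) / pmax(1, abs(g_num)))
}

test_that("analytic gradients match finite differences for both families", {
  expect_lt(gradcheck_family("cnn", "nt_trigram", "regression"), 1e-6)
  expect_lt(gradcheck_family("cnn", "nt_unigram", "classification"), 1e-6)
  expect_lt(gradcheck_family("transformer", "nt_trigram", "regression"), 1e-6)
  expect_lt(gradcheck_family("transformer", "aa_unigram", "classification"), 1e-6)
})

test_that("the forward contract yields one output per sequence", {
  vocab <- build_vocabulary("nt_trigram")
  seqs <- vapply(1:7, function(i) {
    reverse_translate(random_aa(1, 6, seed = i), natural_codon_table())
  }, character(1))
  for (family in c("cnn", "transformer")) {
    m <- build_model(model_config(family, "regression", "desk", "nt_trigram"),
                     vocab, seed = 2)
    p <- predict_model(m, seqs)
    expect_length(p, 7)
    expect_true(all(is.finite(p)))
  }
  # classification outputs pass through a sigmoid
  mc <- build_model(model_config("cnn", "classification", "desk", "nt_unigram"),
                    build_vocabulary("nt_unigram"), seed = 3)
  pr <- predict_model(mc, c("ATGAAA", "TGGCCC"))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(
    build_model(model_config("cnn", "regression", "desk", "nt_trigram"),
                build_vocabulary("nt_unigram")),
    class = "ntaug_config_error"
  )
})

test_that("predictions are invariant to the amount of right padding", {
  # the same sequence encoded alone vs alongside a much longer one must
  # score identically: padded positions carry no information
  long <- reverse_translate(random_aa(1, 18, seed = 4), natural_codon_table())
  short <- reverse_translate(random_aa(1, 6, seed = 5), natural_codon_table())
  for (family in c("cnn", "transformer")) {
    for (scheme in c("nt_unigram", "nt_trigram")) {
      m <- build_model(model_config(family, "regression", "desk", scheme),
                       build_vocabulary(scheme), seed = 6)
      alone <- predict_model(m, short)
      padded <- predict_model(m, c(short, long))[1]
      expect_equal(alone, padded, tolerance = 1e-10)
    }
  }
})

test_that("prediction is deterministic in eval mode and empty-safe", {
  m <- build_model(model_config("cnn", "regression", "desk", "nt_trigram"),
                   build_vocabulary("nt_trigram"), seed = 7)
  seqs <- c("ATGAAATGG", "CCCGGGTTT")
  expect_identical(predict_model(m, seqs), predict_model(m, seqs))
  expect_identical(predict_model(m, character(0)), numeric(0))
})

small_landscape_sets <- function(n = 600, seed = 7, noise_sd = 0.05) {
  spec <- gb1_like_spec(seed = seed, noise_sd = noise_sd)
  ds <- generate_landscape(spec, n, 4)
  ds <- split_by_edit_distance(ds, spec$wild_type, 3, seed = 1)
  list(
    train = as_labeled_dataset(ds[ds$set == "train", ], "amino_acid", "regression"),
    valid = as_labeled_dataset(ds[ds$set == "valid", ], "amino_acid", "regression")
  )
}

test_that("training reduces the loss and the CNN learns the landscape", {
  sets <- small_landscape_sets()
  nat <- natural_codon_table()
  tr <- ntaug:::reverse_translate_dataset(sets$train, nat, "deterministic", 0)
  va <- ntaug:::reverse_translate_dataset(sets$valid, nat, "deterministic", 0)
  m <- build_model(model_config("cnn", "regression", "desk", "nt_trigram"),
                   build_vocabulary("nt_trigram"), seed = 8)
  res <- train_model(m, tr, va, train_config("offline", epochs = 25,
                                             patience = 25, batch_size = 32,
                                             lr = 0.01, seed = 9))
  expect_lt(utils::tail(res$history$train_loss, 1), res$history$train_loss[1])
  expect_gt(max(res$history$valid_metric, na.rm = TRUE), 0.5)
})

test_that("transformer training also reduces the loss", {
  sets <- small_landscape_sets(n = 300)
  m <- build_model(model_config("transformer", "regression", "desk", "aa_unigram"),
                   build_vocabulary("aa_unigram"), seed = 10)
  res <- train_model(m, sets$train, sets$valid,
                     train_config("offline", epochs = 8, patience = 8,
                                  batch_size = 32, lr = 0.005, seed = 11))
  expect_lt(utils::tail(res$history$train_loss, 1), res$history$train_loss[1])
})

test_that("early stopping with zero patience halts at the first non-improvement", {
  sets <- small_landscape_sets(n = 300)
  nat <- natural_codon_table()
  tr <- ntaug:::reverse_translate_dataset(sets$train, nat, "deterministic", 0)
  va <- ntaug:::reverse_translate_dataset(sets$valid, nat, "deterministic", 0)
  m <- build_model(model_config("cnn", "regression", "desk", "nt_trigram"),
                   build_vocabulary("nt_trigram"), seed = 12)
  res <- train_model(m, tr, va, train_config("offline", epochs = 50,
                                             patience = 0, batch_size = 32,
                                             lr = 0.01, seed = 13))
  h <- res$history$valid_metric
  expect_lt(nrow(res$history), 50)
  # the run ends exactly one epoch after the last improvement
  expect_identical(res$stopped_epoch, res$best_epoch + 1L)
})

test_that("online training with augmentation disabled equals the plain run", {
  sets <- small_landscape_sets(n = 300)
  nat <- natural_codon_table()
  tr <- ntaug:::reverse_translate_dataset(sets$train[1:80, ], nat, "random", 5)
  va <- ntaug:::reverse_translate_dataset(sets$valid, nat, "random", 6)
  m <- build_model(model_config("cnn", "regression", "desk", "nt_trigram"),
                   build_vocabulary("nt_trigram"), seed = 14)
  on_cfg <- train_config("online", epochs = 4, batch_size = 16, lr = 0.01,
                         seed = 15,
                         online_cfg = online_aug_config(t_aug = 1.0, seed = 99))
  off_cfg <- train_config("offline", epochs = 4, patience = 10, batch_size = 16,
                          lr = 0.01, seed = 15)
  h_on <- train_model(m, tr, va, on_cfg)$history
  h_off <- train_model(m, tr, va, off_cfg)$history
  expect_identical(h_on$train_loss, h_off$train_loss)
  expect_identical(h_on$valid_loss, h_off$valid_loss)
  expect_identical(h_on$valid_metric, h_off$valid_metric)
})

test_that("class-weighted sampling balances mini-batches on average", {
  spec <- cdrh3_like_spec(seed = 16)
  ds <- generate_binder_dataset(spec, 400, 7)
  ds$set <- "train"
  ds <- as_labeled_dataset(ds, "amino_acid", "classification")
  imb <- impose_class_imbalance(ds, 0.2, seed = 17)
  m <- build_model(model_config("cnn", "classification", "desk", "aa_unigram"),
                   build_vocabulary("aa_unigram"), seed = 18)
  res <- train_model(m, imb, imb,
                     train_config("offline", epochs = 3, patience = 3,
                                  batch_size = 16, lr = 0.01, seed = 19,
                                  class_weighted_sampling = TRUE))
  expect_identical(nrow(res$history), 3L)
  expect_error(
    train_model(m, imb, imb,
                train_config("offline", epochs = 1, batch_size = 16,
                             seed = 1, class_weighted_sampling = TRUE)),
    NA
  )
  # weighted sampling demands a classification task
  reg <- small_landscape_sets(n = 300)$train
  mr <- build_model(model_config("cnn", "regression", "desk", "aa_unigram"),
                    build_vocabulary("aa_unigram"), seed = 20)
  expect_error(
    train_model(mr, reg, reg,
                train_config("offline", epochs = 1,
                             class_weighted_sampling = TRUE)),
    class = "ntaug_config_error"
  )
})

test_that("training configuration enforces the mode contract", {
  expect_error(
    train_config("offline", online_cfg = online_aug_config()),
    class = "ntaug_config_error"
  )
  m <- build_model(model_config("cnn", "regression", "desk", "nt_trigram"),
                   build_vocabulary("nt_trigram"), seed = 21)
  empty <- labeled_dataset(character(0), numeric(0), alphabet = "nucleotide")
  expect_error(train_model(m, empty, empty, train_config("offline", epochs = 1)),
               class = "ntaug_config_error")
})
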