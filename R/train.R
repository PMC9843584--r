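#' Training configuration
#'
#' Offline mode uses early stopping on the validation metric (Spearman's rho
#' or MCC) with the given patience and restores the best epoch's weights.
#' Online mode forgoes early stopping and runs exactly `epochs` epochs,
#' applying [augment_online_batch()] to every mini-batch before the gradient
#' step (so augmented and baseline runs see the same number of data points).
#' The optimizer is stochastic gradient descent with momentum 0.9.
#'
#' @param mode `"offline"` or `"online"`.
#' @param epochs Maximum (offline) or exact (online) number of epochs.
#' @param patience Early-stopping patience in epochs (offline only);
#'   default 10.
#' @param batch_size Mini-batch size.
#' @param lr Learning rate (default 1e-3).
#' @param momentum SGD momentum (default 0.9).
#' @param seed Integer seed for shuffling, dropout and initialization
#'   ordering.
#' @param online_cfg An [online_aug_config()] or `NULL` for no online
#'   augmentation.
#' @param class_weighted_sampling Draw mini-batches with per-class weights
#'   inversely proportional to class frequency (classification only).
#' @param clip_norm Optional global gradient-norm cap (`NULL` disables;
#'   1 is a conventional value when enabled).
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("offline", "online"), epochs = 30L,
                         patience = 10L, batch_size = 32L, lr = 1e-3,
                         momentum = 0.9, seed = 0L, online_cfg = NULL,
                         class_weighted_sampling = FALSE, clip_norm = NULL) {
  mode <- match.arg(mode)
  if (!is.null(online_cfg) && !inherits(online_cfg, "online_aug_config")) {
    abort_ntaug("`online_cfg` must come from online_aug_config().", "config_error")
  }
  if (mode == "offline" && !is.null(online_cfg)) {
    abort_ntaug("Offline training cannot carry an online augmentation config.",
                "config_error")
  }
  structure(
    list(mode = mode, epochs = as.integer(epochs), patience = as.integer(patience),
         batch_size = as.integer(batch_size), lr = lr, momentum = momentum,
         seed = as.integer(seed), online_cfg = online_cfg,
         class_weighted_sampling = class_weighted_sampling,
         clip_norm = clip_norm),
    class = "train_config"
  )
}

validation_metric <- function(model, valid_seqs, valid_y) {
  pred <- predict_model(model, valid_seqs)
  if (model$cfg$task == "regression") {
    if (length(unique(pred)) < 2 || length(unique(valid_y)) < 2) return(NA_real_)
    spearman_rho(pred, valid_y)
  } else {
    mcc(as.numeric(pred > 0.5), valid_y)
  }
}

eval_loss <- function(model, seqs, y, batch_size = 256L) {
  n <- length(seqs)
  total <- 0
  starts <- seq(1L, n, by = batch_size)
  loss_fn <- if (model$cfg$task == "regression") mse_loss else bce_logit_loss
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    enc <- encode_for_model(model, seqs[idx])
    fwd <- model_forward(model, enc, train = FALSE)
    total <- total + loss_fn(fwd$z, y[idx])$loss * length(idx)
  }
  total / n
}

#' Train a reference model
#'
#' Runs seeded mini-batch SGD with momentum. Training sequences must already
#' be in the model's alphabet (nucleotide for `nt_*` schemes, amino acid for
#' `aa_unigram`); online augmentation additionally requires codon-structured
#' nucleotide input. Online augmentation randomness is drawn from a
#' dedicated RNG stream, so a run with augmentation disabled is bit-identical
#' to a plain fixed-epoch run under the same seed.
#'
#' @param model An [build_model()] model.
#' @param train_data,valid_data Labeled datasets in the model's alphabet.
#' @param tc A [train_config()].
#' @return A list of class `nta_train_result`: `model` (best weights for
#'   offline, final for online), `history` (per-epoch tibble of train loss,
#'   validation loss and validation metric), `best_epoch`, `stopped_epoch`,
#'   `config`.
#' @export
train_model <- function(model, train_data, valid_data, tc) {
  stopifnot(inherits(model, "nta_model"), inherits(tc, "train_config"))
  seqs <- train_data$sequence
  y <- train_data$label
  if (!length(seqs)) abort_ntaug("Training set is empty.", "config_error")
  valid_seqs <- valid_data$sequence
  valid_y <- valid_data$label
  n <- length(seqs)
  bs <- min(tc$batch_size, n)
  weights <- NULL
  if (tc$class_weighted_sampling) {
    if (model$cfg$task != "classification") {
      abort_ntaug("Class-weighted sampling needs a classification task.",
                  "config_error")
    }
    freq <- table(y)
    weights <- as.numeric(1 / freq[as.character(y)])
  }
  aug_stream <- if (!is.null(tc$online_cfg)) {
    new_rng_stream(tc$online_cfg$seed)
  } else {
    NULL
  }
  velocity <- numeric(length(flatten_params(model$params)))
  history <- vector("list", tc$epochs)
  best_metric <- -Inf
  best_epoch <- 0L
  best_params <- model$params
  best_bn <- model$bn_stats
  wait <- 0L
  stopped <- tc$epochs
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      order_idx <- if (is.null(weights)) {
        sample.int(n, n)
      } else {
        sample.int(n, n, replace = TRUE, prob = weights)
      }
      n_batches <- ceiling(n / bs)
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        idx <- order_idx[((bi - 1L) * bs + 1L):min(bi * bs, n)]
        batch_seqs <- seqs[idx]
        if (!is.null(aug_stream)) {
          batch_seqs <- stream_eval(
            aug_stream,
            augment_online_batch(batch_seqs, tc$online_cfg)
          )
        }
        enc <- encode_for_model(model, batch_seqs)
        lg <- model_loss_grads(model, enc, y[idx], train = TRUE)
        if (!is.finite(lg$loss)) {
          abort_ntaug(sprintf("Non-finite loss at epoch %d.", epoch),
                      "training_error")
        }
        g <- flatten_params(lg$grads)
        if (!is.null(tc$clip_norm)) {
          nrm <- sqrt(sum(g^2))
          if (nrm > tc$clip_norm) g <- g * (tc$clip_norm / nrm)
        }
        velocity <- tc$momentum * velocity - tc$lr * g
        model$params <- assign_flat(
          model$params,
          flatten_params(model$params) + velocity
        )
        model$bn_stats <- lg$bn_stats
        epoch_loss <- epoch_loss + lg$loss * length(idx)
      }
      train_loss <- epoch_loss / n
      valid_loss <- eval_loss(model, valid_seqs, valid_y)
      metric <- validation_metric(model, valid_seqs, valid_y)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, valid_loss = valid_loss,
        valid_metric = metric
      )
      if (tc$mode == "offline") {
        improved <- !is.na(metric) && metric > best_metric
        if (improved) {
          best_metric <- metric
          best_epoch <- epoch
          best_params <- model$params
          best_bn <- model$bn_stats
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait > tc$patience) {
            stopped <- epoch
            break
          }
        }
      }
    }
  })
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  if (tc$mode == "offline" && best_epoch > 0L) {
    model$params <- best_params
    model$bn_stats <- best_bn
  } else {
    best_epoch <- nrow(history)
  }
  stopped <- min(stopped, nrow(history))
  structure(
    list(model = model, history = history, best_epoch = best_epoch,
         stopped_epoch = stopped, config = tc),
    class = "nta_train_result"
  )
}

#' @export
print.nta_train_result <- function(x, ...) {
  cat(sprintf(
    "<nta_train_result>: %d epoch(s), best epoch %d, final valid metric %.4f\n",
    x$stopped_epoch, x$best_epoch,
    x$history$valid_metric[nrow(x$history)]
  ))
  invisible(x)
}
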