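#' Model configuration for the reference CNN and Transformer
#'
#' The `"full"` preset carries the full-scale reference widths (Transformer-R:
#' embedding 256, 8 heads, feed-forward 1024, linear 1024; Transformer-C:
#' embedding 32, 2 heads, feed-forward 128, linear 512; CNN-R: kernels 5 and
#' 3 with 1024 and 512 filters; CNN-C: kernel 5 with 64 filters; linear 512;
#' dropout 0.3 throughout). The `"desk"` preset preserves the layer
#' structure but shrinks every width so the full pipeline trains in minutes
#' on one CPU.
#'
#' @param family `"cnn"` or `"transformer"`.
#' @param task `"regression"` or `"classification"`.
#' @param preset `"desk"` or `"full"`.
#' @param scheme Encoding scheme the model consumes (see
#'   [build_vocabulary()]); the CNN takes one-hot input, the Transformer
#'   token ids.
#' @return A `model_config` list.
#' @export
model_config <- function(family = c("cnn", "transformer"),
                         task = c("regression", "classification"),
                         preset = c("desk", "full"),
                         scheme = "nt_trigram") {
  family <- match.arg(family)
  task <- match.arg(task)
  preset <- match.arg(preset)
  cfg <- list(family = family, task = task, preset = preset, scheme = scheme,
              dropout = 0.3)
  if (family == "cnn") {
    if (task == "regression") {
      cfg$kernels <- c(5L, 3L)
      cfg$filters <- if (preset == "full") c(1024L, 512L) else c(32L, 16L)
    } else {
      cfg$kernels <- 5L
      cfg$filters <- if (preset == "full") 64L else 16L
    }
    cfg$linear_dim <- if (preset == "full") 512L else 32L
  } else {
    if (task == "regression") {
      if (preset == "full") {
        cfg$d_model <- 256L; cfg$n_heads <- 8L
        cfg$ffn_dim <- 1024L; cfg$linear_dim <- 1024L
      } else {
        cfg$d_model <- 16L; cfg$n_heads <- 2L
        cfg$ffn_dim <- 32L; cfg$linear_dim <- 32L
      }
    } else {
      if (preset == "full") {
        cfg$d_model <- 32L; cfg$n_heads <- 2L
        cfg$ffn_dim <- 128L; cfg$linear_dim <- 512L
      } else {
        cfg$d_model <- 16L; cfg$n_heads <- 2L
        cfg$ffn_dim <- 32L; cfg$linear_dim <- 32L
      }
    }
  }
  structure(cfg, class = "model_config")
}

#' Build a reference model
#'
#' Initializes parameters (Glorot-scaled Gaussian, seeded). The forward
#' contract: a padded batch with mask in, a `B x 1` output out (fitness for
#' regression, pre-sigmoid logit for classification); padded positions never
#' influence the output.
#'
#' @param cfg A [model_config()].
#' @param vocab The [build_vocabulary()] vocabulary matching `cfg$scheme`.
#' @param seed Integer seed for initialization.
#' @return An object of class `nta_model`.
#' @export
build_model <- function(cfg, vocab, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"), inherits(vocab, "nta_vocabulary"))
  if (!identical(cfg$scheme, vocab$scheme)) {
    abort_ntaug(sprintf("Model scheme '%s' does not match vocabulary '%s'.",
                        cfg$scheme, vocab$scheme), "config_error")
  }
  v <- vocab$content_size
  params <- with_seed(seed, {
    if (cfg$family == "cnn") {
      chans <- c(v, cfg$filters)
      convs <- lapply(seq_along(cfg$filters), function(l) {
        list(
          w = glorot(cfg$kernels[l] * chans[l], chans[l + 1]),
          b = numeric(chans[l + 1]),
          gamma = rep(1, chans[l + 1]),
          beta = numeric(chans[l + 1])
        )
      })
      list(
        convs = convs,
        wh = glorot(cfg$filters[length(cfg$filters)], cfg$linear_dim),
        bh = numeric(cfg$linear_dim),
        wo = glorot(cfg$linear_dim, 1L),
        bo = 0
      )
    } else {
      d <- cfg$d_model
      list(
        e = glorot(v, d),
        wq = glorot(d, d), bq = numeric(d),
        wk = glorot(d, d), bk = numeric(d),
        wv = glorot(d, d), bv = numeric(d),
        wa = glorot(d, d), ba = numeric(d),
        g1 = rep(1, d), be1 = numeric(d),
        w1 = glorot(d, cfg$ffn_dim), b1 = numeric(cfg$ffn_dim),
        w2 = glorot(cfg$ffn_dim, d), b2 = numeric(d),
        g2 = rep(1, d), be2 = numeric(d),
        wh = glorot(d, cfg$linear_dim), bh = numeric(cfg$linear_dim),
        wo = glorot(cfg$linear_dim, 1L), bo = 0
      )
    }
  })
  bn_stats <- if (cfg$family == "cnn") {
    lapply(cfg$filters, function(f) list(mean = numeric(f), var = rep(1, f)))
  } else {
    NULL
  }
  structure(
    list(cfg = cfg, vocab = vocab, params = params, bn_stats = bn_stats,
         seed = as.integer(seed)),
    class = "nta_model"
  )
}

#' @export
print.nta_model <- function(x, ...) {
  cat(sprintf("<nta_model %s-%s (%s preset, scheme %s)>: %d parameters\n",
              x$cfg$family, substr(x$cfg$task, 1, 1), x$cfg$preset,
              x$cfg$scheme, length(flatten_params(x$params))))
  invisible(x)
}

## ---- CNN network ----

cnn_forward <- function(model, oh, lens, train = FALSE, dmask = NULL) {
  p <- model$params
  cfg <- model$cfg
  x <- oh
  cur_lens <- lens
  caches <- vector("list", length(p$convs))
  for (l in seq_along(p$convs)) {
    d <- dim(x)
    bsz <- d[1]; t_max <- d[2]; chan <- d[3]
    cv <- p$convs[[l]]
    conv <- conv1d_forward(x, cv$w, cv$b, cfg$kernels[l])
    vr <- valid_rows(cur_lens, t_max)
    bn <- bn_forward(conv$y, cv$gamma, cv$beta, vr, train, model$bn_stats[[l]])
    act <- pmax(bn$out, 0)
    aarr <- as_arr3(act, bsz, t_max)
    pool <- maxpool2_forward(aarr, cur_lens)
    caches[[l]] <- list(conv = conv, bn = bn, relu_in = bn$out, vr = vr,
                        pool = pool, bsz = bsz, t_max = t_max, chan = chan)
    x <- pool$out
    cur_lens <- pool$lens_p
  }
  gm <- globalmax_forward(x, cur_lens)
  pre_h <- add_bias(gm$g %*% p$wh, p$bh)
  h1 <- pmax(pre_h, 0)
  dm <- if (train && cfg$dropout > 0) {
    if (is.null(dmask)) dropout_mask(dim(h1), cfg$dropout) else dmask
  } else {
    NULL
  }
  h1d <- if (is.null(dm)) h1 else h1 * dm
  z <- drop(h1d %*% p$wo) + p$bo
  list(z = z, caches = caches, gm = gm, g = gm$g, pre_h = pre_h, h1d = h1d,
       dm = dm, final = x, final_lens = cur_lens)
}

cnn_backward <- function(model, fwd, dz) {
  p <- model$params
  cfg <- model$cfg
  bsz <- length(dz)
  dout <- matrix(dz, ncol = 1)
  gr <- list()
  gr$wo <- crossprod(fwd$h1d, dout)
  gr$bo <- sum(dout)
  dh1d <- dout %*% t(p$wo)
  dh1 <- if (is.null(fwd$dm)) dh1d else dh1d * fwd$dm
  dpre_h <- dh1 * (fwd$pre_h > 0)
  gr$wh <- crossprod(fwd$g, dpre_h)
  gr$bh <- colSums(dpre_h)
  dg <- dpre_h %*% t(p$wh)
  d_final <- dim(fwd$final)
  dx <- globalmax_backward(dg, fwd$gm, d_final[1], d_final[2], d_final[3])
  gr$convs <- vector("list", length(p$convs))
  for (l in rev(seq_along(p$convs))) {
    ca <- caches_l <- fwd$caches[[l]]
    f <- ncol(ca$conv$y)
    dact <- maxpool2_backward(dx, ca$pool, NULL, f)
    dact_m <- as_mat3(dact)
    dbn_out <- dact_m * (ca$relu_in > 0)
    bnb <- bn_backward(dbn_out, ca$bn, p$convs[[l]]$gamma, ca$vr)
    cvb <- conv1d_backward(bnb$dx, ca$conv, p$convs[[l]]$w, cfg$kernels[l],
                           ca$bsz, ca$t_max, ca$chan)
    gr$convs[[l]] <- list(w = cvb$dw, b = cvb$db, gamma = bnb$dgamma,
                          beta = bnb$dbeta)
    dx <- cvb$dx
  }
  # reorder to match params layout (convs first)
  list(convs = gr$convs, wh = gr$wh, bh = gr$bh, wo = gr$wo, bo = gr$bo)
}

## ---- Transformer network ----

pe_matrix <- function(t_max, d) {
  pos <- seq_len(t_max) - 1
  i <- seq_len(d)
  freq <- 1 / 10000^((2 * ((i - 1) %/% 2)) / d)
  ang <- outer(pos, freq)
  pe <- matrix(0, t_max, d)
  odd_cols <- seq(1, d, by = 2)
  even_cols <- seq(2, d, by = 2)
  pe[, odd_cols] <- sin(ang[, odd_cols, drop = FALSE])
  pe[, even_cols] <- cos(ang[, even_cols, drop = FALSE])
  pe
}

tf_seq_forward <- function(p, cfg, ids, pe, train, masks = NULL) {
  len <- length(ids)
  d <- cfg$d_model
  nh <- cfg$n_heads
  dh <- d %/% nh
  x0 <- p$e[ids, , drop = FALSE] + pe[seq_len(len), , drop = FALSE]
  q <- add_bias(x0 %*% p$wq, p$bq)
  k <- add_bias(x0 %*% p$wk, p$bk)
  v <- add_bias(x0 %*% p$wv, p$bv)
  attn <- vector("list", nh)
  o <- matrix(0, len, d)
  for (h in seq_len(nh)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    s <- (q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE])) / sqrt(dh)
    a <- softmax_rows(s)
    o[, idx] <- a %*% v[, idx, drop = FALSE]
    attn[[h]] <- a
  }
  o2 <- add_bias(o %*% p$wa, p$ba)
  m_attn <- if (train && cfg$dropout > 0) {
    if (is.null(masks)) dropout_mask(dim(o2), cfg$dropout) else masks$attn
  } else {
    NULL
  }
  o2d <- if (is.null(m_attn)) o2 else o2 * m_attn
  r1 <- x0 + o2d
  ln1 <- ln_forward(r1, p$g1, p$be1)
  x1 <- ln1$out
  pre_f <- add_bias(x1 %*% p$w1, p$b1)
  f1 <- pmax(pre_f, 0)
  f2 <- add_bias(f1 %*% p$w2, p$b2)
  m_ffn <- if (train && cfg$dropout > 0) {
    if (is.null(masks)) dropout_mask(dim(f2), cfg$dropout) else masks$ffn
  } else {
    NULL
  }
  f2d <- if (is.null(m_ffn)) f2 else f2 * m_ffn
  r2 <- x1 + f2d
  ln2 <- ln_forward(r2, p$g2, p$be2)
  g <- colMeans(ln2$out)
  list(g = g, x0 = x0, q = q, k = k, v = v, attn = attn, o = o, o2 = o2,
       m_attn = m_attn, ln1 = ln1, x1 = x1, pre_f = pre_f, f1 = f1,
       m_ffn = m_ffn, ln2 = ln2, ids = ids, len = len)
}

tf_seq_backward <- function(p, cfg, cache, dg, gr) {
  len <- cache$len
  d <- cfg$d_model
  nh <- cfg$n_heads
  dh <- d %/% nh
  dx2 <- matrix(dg / len, nrow = len, ncol = d, byrow = TRUE)
  ln2b <- ln_backward(dx2, cache$ln2, p$g2)
  gr$g2 <- gr$g2 + ln2b$dgamma
  gr$be2 <- gr$be2 + ln2b$dbeta
  dr2 <- ln2b$dx
  dx1 <- dr2
  df2 <- if (is.null(cache$m_ffn)) dr2 else dr2 * cache$m_ffn
  gr$w2 <- gr$w2 + crossprod(cache$f1, df2)
  gr$b2 <- gr$b2 + colSums(df2)
  df1 <- df2 %*% t(p$w2)
  dpre_f <- df1 * (cache$pre_f > 0)
  gr$w1 <- gr$w1 + crossprod(cache$x1, dpre_f)
  gr$b1 <- gr$b1 + colSums(dpre_f)
  dx1 <- dx1 + dpre_f %*% t(p$w1)
  ln1b <- ln_backward(dx1, cache$ln1, p$g1)
  gr$g1 <- gr$g1 + ln1b$dgamma
  gr$be1 <- gr$be1 + ln1b$dbeta
  dr1 <- ln1b$dx
  dx0 <- dr1
  do2 <- if (is.null(cache$m_attn)) dr1 else dr1 * cache$m_attn
  gr$wa <- gr$wa + crossprod(cache$o, do2)
  gr$ba <- gr$ba + colSums(do2)
  do_ <- do2 %*% t(p$wa)
  dq <- matrix(0, len, d)
  dk <- matrix(0, len, d)
  dv <- matrix(0, len, d)
  for (h in seq_len(nh)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    a <- cache$attn[[h]]
    doh <- do_[, idx, drop = FALSE]
    da <- doh %*% t(cache$v[, idx, drop = FALSE])
    dv[, idx] <- crossprod(a, doh)
    ds <- a * (da - rowSums(da * a))
    dq[, idx] <- (ds %*% cache$k[, idx, drop = FALSE]) / sqrt(dh)
    dk[, idx] <- (crossprod(ds, cache$q[, idx, drop = FALSE])) / sqrt(dh)
  }
  gr$wq <- gr$wq + crossprod(cache$x0, dq)
  gr$bq <- gr$bq + colSums(dq)
  gr$wk <- gr$wk + crossprod(cache$x0, dk)
  gr$bk <- gr$bk + colSums(dk)
  gr$wv <- gr$wv + crossprod(cache$x0, dv)
  gr$bv <- gr$bv + colSums(dv)
  dx0 <- dx0 + dq %*% t(p$wq) + dk %*% t(p$wk) + dv %*% t(p$wv)
  de <- rowsum(dx0, group = cache$ids)
  rows <- as.integer(rownames(de))
  gr$e[rows, ] <- gr$e[rows, , drop = FALSE] + de
  gr
}

tf_forward <- function(model, ids, lens, train = FALSE, dmask = NULL) {
  p <- model$params
  cfg <- model$cfg
  bsz <- nrow(ids)
  pe <- pe_matrix(max(lens), cfg$d_model)
  seq_caches <- vector("list", bsz)
  g <- matrix(0, bsz, cfg$d_model)
  for (b in seq_len(bsz)) {
    sc <- tf_seq_forward(p, cfg, ids[b, seq_len(lens[b])], pe, train)
    seq_caches[[b]] <- sc
    g[b, ] <- sc$g
  }
  pre_h <- add_bias(g %*% p$wh, p$bh)
  h1 <- pmax(pre_h, 0)
  dm <- if (train && cfg$dropout > 0) {
    if (is.null(dmask)) dropout_mask(dim(h1), cfg$dropout) else dmask
  } else {
    NULL
  }
  h1d <- if (is.null(dm)) h1 else h1 * dm
  z <- drop(h1d %*% p$wo) + p$bo
  list(z = z, seq_caches = seq_caches, g = g, pre_h = pre_h, h1d = h1d,
       dm = dm)
}

tf_backward <- function(model, fwd, dz) {
  p <- model$params
  cfg <- model$cfg
  dout <- matrix(dz, ncol = 1)
  gr <- lapply(p, function(x) {
    z <- x
    z[] <- 0
    z
  })
  gr$wo <- crossprod(fwd$h1d, dout)
  gr$bo <- sum(dout)
  dh1d <- dout %*% t(p$wo)
  dh1 <- if (is.null(fwd$dm)) dh1d else dh1d * fwd$dm
  dpre_h <- dh1 * (fwd$pre_h > 0)
  gr$wh <- crossprod(fwd$g, dpre_h)
  gr$bh <- colSums(dpre_h)
  dg_all <- dpre_h %*% t(p$wh)
  for (b in seq_along(fwd$seq_caches)) {
    gr <- tf_seq_backward(p, cfg, fwd$seq_caches[[b]], dg_all[b, ], gr)
  }
  gr
}

## ---- unified forward / loss / gradients ----

encode_for_model <- function(model, seqs) {
  enc <- encode_categorical(seqs, model$vocab)
  if (model$cfg$family == "cnn") enc <- encode_one_hot(enc)
  enc
}

model_forward <- function(model, enc, train = FALSE) {
  if (model$cfg$family == "cnn") {
    cnn_forward(model, enc$one_hot, enc$lengths, train = train)
  } else {
    tf_forward(model, enc$token_ids, enc$lengths, train = train)
  }
}

# Loss and parameter gradients for one encoded batch; returns the new BN
# running stats alongside so the training loop can commit them.
model_loss_grads <- function(model, enc, y, train = TRUE) {
  fwd <- model_forward(model, enc, train = train)
  loss_fn <- if (model$cfg$task == "regression") mse_loss else bce_logit_loss
  lo <- loss_fn(fwd$z, y)
  gr <- if (model$cfg$family == "cnn") {
    cnn_backward(model, fwd, lo$dz)
  } else {
    tf_backward(model, fwd, lo$dz)
  }
  bn_new <- model$bn_stats
  if (train && model$cfg$family == "cnn") {
    for (l in seq_along(bn_new)) {
      bn <- fwd$caches[[l]]$bn
      bn_new[[l]]$mean <- 0.9 * bn_new[[l]]$mean + 0.1 * bn$mu
      bn_new[[l]]$var <- 0.9 * bn_new[[l]]$var + 0.1 * bn$var
    }
  }
  list(loss = lo$loss, grads = gr, bn_stats = bn_new, z = fwd$z)
}

#' Predict with a trained model
#'
#' Deterministic evaluation-mode forward pass (dropout off, batch-norm
#' running statistics). Output order is aligned with the input.
#'
#' @param model An `nta_model`.
#' @param newdata A labeled dataset, or a character vector of sequences in
#'   the model's alphabet.
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector: predicted fitness (regression) or sigmoid
#'   probability of the positive class (classification).
#' @export
predict_model <- function(model, newdata, batch_size = 256L) {
  seqs <- if (is.character(newdata)) newdata else newdata$sequence
  n <- length(seqs)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    enc <- encode_for_model(model, seqs[idx])
    fwd <- model_forward(model, enc, train = FALSE)
    out[idx] <- fwd$z
  }
  if (model$cfg$task == "classification") 1 / (1 + exp(-out)) else out
}
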