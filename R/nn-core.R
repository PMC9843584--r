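# Native neural-network core: array helpers, layer forward/backward passes,
# and losses. Written against base R matrix algebra; gradients are
# hand-derived and validated by finite-difference checks in the test suite.

BN_EPS <- 1e-5
LN_EPS <- 1e-5

# (B,T,C) array <-> (B*T, C) matrix, rows ordered batch-fastest.
as_mat3 <- function(a) {
  d <- dim(a)
  matrix(a, nrow = d[1] * d[2], ncol = d[3])
}
as_arr3 <- function(m, b, t) {
  array(as.vector(m), dim = c(b, t, ncol(m)))
}

add_bias <- function(m, b) {
  m + matrix(b, nrow = nrow(m), ncol = length(b), byrow = TRUE)
}

# Logical vector over (B*T) rows marking positions within each sequence.
valid_rows <- function(lens, t_max) {
  rep(lens, times = t_max) >= rep(seq_len(t_max), each = length(lens))
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nrow = nin)
}

## ---- 1-D convolution (same padding, odd kernel) ----

conv1d_forward <- function(x, w, b, k) {
  d <- dim(x)
  bsz <- d[1]; t_max <- d[2]; chan <- d[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(bsz, t_max + 2L * pad, chan))
  xp[, pad + seq_len(t_max), ] <- x
  m <- matrix(0, bsz * t_max, k * chan)
  for (o in seq_len(k)) {
    m[, (o - 1L) * chan + seq_len(chan)] <-
      as_mat3(xp[, o:(o + t_max - 1L), , drop = FALSE])
  }
  y <- add_bias(m %*% w, b)
  list(y = y, m = m)
}

conv1d_backward <- function(dy, cache, w, k, bsz, t_max, chan) {
  pad <- (k - 1L) %/% 2L
  dw <- crossprod(cache$m, dy)
  db <- colSums(dy)
  dm <- dy %*% t(w)
  dxp <- array(0, dim = c(bsz, t_max + 2L * pad, chan))
  for (o in seq_len(k)) {
    dxp[, o:(o + t_max - 1L), ] <- dxp[, o:(o + t_max - 1L), , drop = FALSE] +
      as_arr3(dm[, (o - 1L) * chan + seq_len(chan), drop = FALSE], bsz, t_max)
  }
  list(dx = dxp[, pad + seq_len(t_max), , drop = FALSE], dw = dw, db = db)
}

## ---- batch normalization over valid (batch x position) rows ----

bn_forward <- function(y, gamma, beta, valid, train, stats) {
  if (train) {
    yv <- y[valid, , drop = FALSE]
    mu <- colMeans(yv)
    xc <- sweep(y, 2, mu)
    va <- colMeans(xc[valid, , drop = FALSE]^2)
  } else {
    mu <- stats$mean
    va <- stats$var
    xc <- sweep(y, 2, mu)
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- add_bias(sweep(xhat, 2, gamma, `*`), beta)
  out[!valid, ] <- 0
  list(out = out, xhat = xhat, inv = inv, mu = mu, var = va)
}

bn_backward <- function(dout, cache, gamma, valid) {
  dout[!valid, ] <- 0
  n <- sum(valid)
  xhat <- cache$xhat
  xhat[!valid, ] <- 0
  dxhat <- sweep(dout, 2, gamma, `*`)
  sum_dxhat <- colSums(dxhat[valid, , drop = FALSE])
  sum_dxhat_xhat <- colSums((dxhat * xhat)[valid, , drop = FALSE])
  dx <- sweep(
    dxhat - matrix(sum_dxhat / n, nrow(dout), ncol(dout), byrow = TRUE) -
      sweep(xhat, 2, sum_dxhat_xhat / n, `*`),
    2, cache$inv, `*`
  )
  dx[!valid, ] <- 0
  list(dx = dx, dgamma = colSums((dout * xhat)[valid, , drop = FALSE]),
       dbeta = colSums(dout[valid, , drop = FALSE]))
}

## ---- max pooling, width 2 stride 2 (ceiling semantics) ----

maxpool2_forward <- function(a, lens) {
  d <- dim(a)
  bsz <- d[1]; t_max <- d[2]; f <- d[3]
  am <- as_mat3(a)
  vr <- valid_rows(lens, t_max)
  am[!vr, ] <- -Inf
  a2 <- as_arr3(am, bsz, t_max)
  t_p <- as.integer(ceiling(t_max / 2))
  odd <- seq(1L, by = 2L, length.out = t_p)
  even <- odd + 1L
  a_odd <- a2[, odd, , drop = FALSE]
  a_even <- array(-Inf, dim = c(bsz, t_p, f))
  in_range <- even <= t_max
  if (any(in_range)) {
    a_even[, which(in_range), ] <- a2[, even[in_range], , drop = FALSE]
  }
  take_odd <- a_odd >= a_even
  pooled <- pmax(a_odd, a_even)
  pooled[!is.finite(pooled)] <- 0
  lens_p <- as.integer(ceiling(lens / 2))
  list(out = pooled, take_odd = take_odd, lens_p = lens_p,
       t_max = t_max, t_p = t_p)
}

maxpool2_backward <- function(dp, cache, lens, f) {
  bsz <- dim(dp)[1]
  t_p <- cache$t_p
  t_max <- cache$t_max
  vrp <- valid_rows(cache$lens_p, t_p)
  dpm <- as_mat3(dp)
  dpm[!vrp, ] <- 0
  dp <- as_arr3(dpm, bsz, t_p)
  da <- array(0, dim = c(bsz, t_max, f))
  odd <- seq(1L, by = 2L, length.out = t_p)
  even <- odd + 1L
  da[, odd, ] <- dp * cache$take_odd
  in_range <- which(even <= t_max)
  if (length(in_range)) {
    da[, even[in_range], ] <-
      dp[, in_range, , drop = FALSE] * !cache$take_odd[, in_range, , drop = FALSE]
  }
  da
}

## ---- global max pooling over valid positions ----

globalmax_forward <- function(a, lens) {
  d <- dim(a)
  bsz <- d[1]; t_max <- d[2]; f <- d[3]
  am <- as_mat3(a)
  am[!valid_rows(lens, t_max), ] <- -Inf
  m <- matrix(aperm(as_arr3(am, bsz, t_max), c(1, 3, 2)), nrow = bsz * f,
              ncol = t_max)
  arg <- max.col(m, ties.method = "first")
  g <- matrix(m[cbind(seq_len(bsz * f), arg)], nrow = bsz, ncol = f)
  list(g = g, arg = arg)
}

globalmax_backward <- function(dg, cache, bsz, t_max, f) {
  dm <- matrix(0, bsz * f, t_max)
  dm[cbind(seq_len(bsz * f), cache$arg)] <- as.vector(dg)
  aperm(array(dm, dim = c(bsz, f, t_max)), c(1, 3, 2))
}

## ---- layer normalization (per row) ----

ln_forward <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + LN_EPS)
  xhat <- xc * inv
  out <- add_bias(sweep(xhat, 2, gamma, `*`), beta)
  list(out = out, xhat = xhat, inv = inv)
}

ln_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = colSums(dout * xhat), dbeta = colSums(dout))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

## ---- losses ----

mse_loss <- function(z, y) {
  n <- length(y)
  list(loss = mean((z - y)^2), dz = 2 * (z - y) / n)
}

bce_logit_loss <- function(z, y) {
  n <- length(y)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  list(loss = loss, dz = (p - y) / n)
}

## ---- parameter bookkeeping ----

# Flatten a nested list of numeric arrays to one vector and back; used by
# the SGD update and the finite-difference gradient checks.
flatten_params <- function(p) {
  unlist(rapply(p, as.vector, how = "unlist"), use.names = FALSE)
}

assign_flat <- function(p, v) {
  idx <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- v[idx + seq_len(n)]
    idx <<- idx + n
    dim(out) <- dim(x)
    out
  }
  walk(p)
}

dropout_mask <- function(dims, rate) {
  keep <- 1 - rate
  array((stats::runif(prod(dims)) < keep) / keep, dim = dims)
}
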