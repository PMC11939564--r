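# 1D neural-network primitives with analytic forward/backward passes.
# Activations are arrays of dim (C, L, B): channel x length x batch.
# Every *_fwd returns list(out, cache); every *_bwd takes the upstream
# gradient and the cache and returns gradients w.r.t. inputs and parameters.
# Gradients are verified against central finite differences in the tests.

conv_out_len <- function(L, k, stride, pad) {
  (L + 2L * pad - k) %/% stride + 1L
}

pad_lr <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1], d[2] + 2L * pad, d[3]))
  xp[, (pad + 1L):(pad + d[2]), ] <- x
  xp
}

# im2col: (C, Lp, B) -> matrix (K*C, L_out*B), k fastest within c.
im2col <- function(xp, k, stride, L_out) {
  d <- dim(xp)
  C <- d[1]; Lp <- d[2]; B <- d[3]
  M <- matrix(xp, C, Lp * B)
  base <- outer(1:k, (0:(L_out - 1L)) * stride, `+`)        # k x L_out
  off <- rep((0:(B - 1L)) * Lp, each = k * L_out)
  idx <- rep(as.vector(base), B) + off                      # k*L_out*B
  A <- M[, idx, drop = FALSE]                               # C x (k*L_out*B)
  dim(A) <- c(C, k, L_out * B)
  A <- aperm(A, c(2, 1, 3))
  dim(A) <- c(k * C, L_out * B)
  A
}

conv1d_init <- function(c_in, c_out, k, seed_scale = 1) {
  fan_in <- k * c_in
  list(W = matrix(stats::rnorm(c_out * k * c_in, 0,
                               seed_scale * sqrt(2 / fan_in)),
                  c_out, k * c_in),
       b = numeric(c_out))
}

conv1d_fwd <- function(x, par, stride = 1L, pad = 0L) {
  d <- dim(x)
  k <- ncol(par$W) / d[1]
  L_out <- conv_out_len(d[2], k, stride, pad)
  xp <- pad_lr(x, pad)
  cols <- im2col(xp, k, stride, L_out)
  Y <- par$W %*% cols + par$b
  out <- array(Y, c(nrow(par$W), L_out, d[3]))
  list(out = out,
       cache = list(cols = cols, x_dim = d, k = k, stride = stride,
                    pad = pad, L_out = L_out))
}

conv1d_bwd <- function(dout, cache, par) {
  d <- cache$x_dim
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  L_out <- cache$L_out
  dY <- matrix(dout, nrow(par$W), L_out * d[3])
  dW <- dY %*% t(cache$cols)
  db <- rowSums(dY)
  dcols <- crossprod(par$W, dY)                             # (k*C) x (L_out*B)
  dim(dcols) <- c(k, d[1], L_out * d[3])
  dxp <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
  pos0 <- (0:(L_out - 1L)) * stride
  for (kk in 1:k) {
    blk <- array(dcols[kk, , ], c(d[1], L_out, d[3]))
    p <- pos0 + kk
    dxp[, p, ] <- dxp[, p, ] + blk
  }
  dx <- if (pad > 0L) dxp[, (pad + 1L):(pad + d[2]), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

bn_fwd <- function(x, par, train = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1], d[2] * d[3])
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * v
  } else {
    mu <- par$run_mean
    v <- par$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * ivar
  y <- array(par$gamma * xhat + par$beta, d)
  list(out = y, par = par,
       cache = list(xhat = xhat, ivar = ivar, d = d, train = train))
}

bn_bwd <- function(dout, cache, par) {
  d <- cache$d
  N <- d[2] * d[3]
  dy <- matrix(dout, d[1], N)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  if (!cache$train) {
    dx <- array(dy * par$gamma * cache$ivar, d)
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  dxhat <- dy * par$gamma
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (cache$ivar / N) * (N * dxhat - s1 - cache$xhat * s2)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}

relu_bwd <- function(dout, mask) dout * mask

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  L_out <- conv_out_len(d[2], k, stride, pad)
  xp <- pad_lr(x, pad, value = -Inf)
  Mp <- matrix(aperm(xp, c(1, 3, 2)), d[1] * d[3], d[2] + 2L * pad)
  best <- matrix(-Inf, d[1] * d[3], L_out)
  argk <- matrix(1L, d[1] * d[3], L_out)
  pos0 <- (0:(L_out - 1L)) * stride
  for (kk in 1:k) {
    cand <- Mp[, pos0 + kk, drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    argk[upd] <- kk
  }
  out <- array(best, c(d[1], d[3], L_out))
  out <- aperm(out, c(1, 3, 2))
  list(out = out,
       cache = list(argk = argk, d = d, k = k, stride = stride, pad = pad,
                    L_out = L_out))
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$d
  L_out <- cache$L_out
  dy <- matrix(aperm(dout, c(1, 3, 2)), d[1] * d[3], L_out)
  dxp <- matrix(0, d[1] * d[3], d[2] + 2L * cache$pad)
  pos0 <- (0:(L_out - 1L)) * cache$stride
  for (kk in 1:cache$k) {
    sel <- cache$argk == kk
    if (!any(sel)) next
    contrib <- dy * sel
    p <- pos0 + kk
    dxp[, p] <- dxp[, p] + contrib
  }
  if (cache$pad > 0L) {
    dxp <- dxp[, (cache$pad + 1L):(cache$pad + d[2]), drop = FALSE]
  }
  aperm(array(dxp, c(d[1], d[3], d[2])), c(1, 3, 2))
}

gap_fwd <- function(x) {
  d <- dim(x)
  out <- colMeans(aperm(x, c(2, 1, 3)))                     # (C, B)
  list(out = out, cache = d)
}

gap_bwd <- function(dout, d) {
  dx <- array(0, d)
  for (b in seq_len(d[3])) dx[, , b] <- matrix(dout[, b], d[1], d[2]) / d[2]
  dx
}

linear_init <- function(d_in, d_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / d_in)
  list(W = matrix(stats::rnorm(d_out * d_in, 0, scale), d_out, d_in),
       b = numeric(d_out))
}

# x: (d_in, B) -> (d_out, B)
linear_fwd <- function(x, par) {
  list(out = par$W %*% x + par$b, cache = x)
}

linear_bwd <- function(dout, x, par) {
  list(dx = crossprod(par$W, dout),
       dW = dout %*% t(x),
       db = rowSums(dout))
}
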