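#' Stage-2 transformer configuration
#'
#' Sequence regressor over consecutive fused feature vectors: linear input
#' embedding, sine-cosine positional encoding, an encoder stack of
#' multi-head self-attention + feed-forward sublayers, and a decoder stack
#' with masked self-attention and cross-attention to the encoder output,
#' finishing in a linear head that emits per-position systolic/diastolic
#' estimates.
#'
#' @param d_model embedding width (default 64).
#' @param n_heads attention heads H; must divide `d_model` (default 4).
#' @param encoder_layers,decoder_layers stack depths (default 2 and 2).
#' @param d_ff feed-forward inner width (default 128).
#' @param sequence_len windows per sequence T (default 8).
#' @return list of class `transformer_config` (with `d_k = d_model/H`).
#' @export
transformer_config <- function(d_model = 64L, n_heads = 4L,
                               encoder_layers = 2L, decoder_layers = 2L,
                               d_ff = 128L, sequence_len = 8L) {
  stopifnot(d_model >= 1, n_heads >= 1, d_ff >= 1, sequence_len >= 1,
            encoder_layers >= 1, decoder_layers >= 1)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_k = as.integer(d_model / n_heads),
                 encoder_layers = as.integer(encoder_layers),
                 decoder_layers = as.integer(decoder_layers),
                 d_ff = as.integer(d_ff),
                 sequence_len = as.integer(sequence_len)),
            class = "transformer_config")
}

#' Sine-cosine positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d_model))` and
#' `PE(pos, 2i + 1) = cos(pos / 10000^(2i/d_model))`, with `pos` and `i`
#' zero-based.
#'
#' @param pos zero-based position index (>= 0).
#' @param d_model encoding width.
#' @return numeric vector of length `d_model`.
#' @export
positional_encoding <- function(pos, d_model) {
  stopifnot(pos >= 0, d_model >= 1)
  j <- seq_len(d_model)
  i <- (j - 1L) %/% 2L
  ang <- pos / 10000^(2 * i / d_model)
  ifelse(j %% 2L == 1L, sin(ang), cos(ang))
}

pe_matrix <- function(T_len, d_model) {
  t(vapply(seq_len(T_len) - 1L, positional_encoding, numeric(d_model),
           d_model = d_model))
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with row-wise softmax; each row of the
#' attention matrix sums to 1.
#'
#' @param Q,K,V matrices with rows as positions; `Q` and `K` share width
#'   `d_k`, `V` has the value width.
#' @param d_k key width used in the scaling (defaults to `ncol(K)`).
#' @param mask optional additive mask matrix (`-Inf`/0) applied to the score
#'   matrix before the softmax.
#' @return list with `out` (attended values) and `weights` (the softmax
#'   attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K), mask = NULL) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(d_k)
  if (!is.null(mask)) S <- S + mask
  A <- softmax_rows(S)
  list(out = A %*% V, weights = A)
}

causal_mask <- function(T_len) {
  M <- matrix(0, T_len, T_len)
  M[upper.tri(M)] <- -1e30
  M
}

mha_init <- function(d_model, seed_scale = 1) {
  s <- seed_scale / sqrt(d_model)
  list(Wq = matrix(stats::rnorm(d_model^2, 0, s), d_model, d_model),
       Wk = matrix(stats::rnorm(d_model^2, 0, s), d_model, d_model),
       Wv = matrix(stats::rnorm(d_model^2, 0, s), d_model, d_model),
       Wo = matrix(stats::rnorm(d_model^2, 0, s), d_model, d_model))
}

# Multi-head attention forward. Xq: (Tq x d), Xkv: (Tk x d).
mha_fwd <- function(Xq, Xkv, par, n_heads, mask = NULL) {
  d <- ncol(par$Wq)
  d_k <- d %/% n_heads
  Q <- Xq %*% par$Wq
  K <- Xkv %*% par$Wk
  V <- Xkv %*% par$Wv
  heads <- vector("list", n_heads)
  O <- matrix(0, nrow(Xq), d)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1L) * d_k + 1L):(h * d_k)
    S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(d_k)
    if (!is.null(mask)) S <- S + mask
    A <- softmax_rows(S)
    O[, ix] <- A %*% V[, ix, drop = FALSE]
    heads[[h]] <- A
  }
  out <- O %*% par$Wo
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, O = O,
                    A = heads, n_heads = n_heads, d_k = d_k, mask = mask))
}

mha_bwd <- function(dout, cache, par) {
  d <- ncol(par$Wq)
  n_heads <- cache$n_heads
  d_k <- cache$d_k
  dWo <- t(cache$O) %*% dout
  dO <- dout %*% t(par$Wo)
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1L) * d_k + 1L):(h * d_k)
    A <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    Vh <- cache$V[, ix, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, ix] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))           # softmax backward, row-wise
    dS <- dS / sqrt(d_k)
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE]
    dK[, ix] <- t(dS) %*% cache$Q[, ix, drop = FALSE]
  }
  list(dXq = dQ %*% t(par$Wq),
       dXkv = dK %*% t(par$Wk) + dV %*% t(par$Wv),
       dWq = t(cache$Xq) %*% dQ,
       dWk = t(cache$Xkv) %*% dK,
       dWv = t(cache$Xkv) %*% dV,
       dWo = dWo)
}

#' Multi-head attention
#'
#' Per-head learned projections of query, key and value, scaled dot-product
#' attention in each subspace, concatenation and output projection.
#'
#' @param Q,K,V source matrices (rows = positions, width `d_model`). `K` and
#'   `V` must share their source (`K` is used as the key/value source).
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`d_model x d_model`).
#' @param n_heads head count dividing `d_model`.
#' @param mask optional additive score mask (e.g. causal).
#' @return the attended output matrix (`nrow(Q) x d_model`).
#' @export
multi_head_attention <- function(Q, K, V, params, n_heads, mask = NULL) {
  if (ncol(params$Wq) %% n_heads != 0) {
    stop("d_model must be divisible by n_heads")
  }
  if (!identical(dim(K), dim(V))) stop("K and V must share their source")
  mha_fwd(Q, K, params, n_heads, mask)$out
}

ln_init <- function(d) list(gamma = rep(1, d), beta = numeric(d))

#' Layer normalization
#'
#' Normalizes each row (sample) to zero mean and unit variance, then applies
#' the learned affine `gamma * xhat + beta`.
#'
#' @param x matrix, rows are samples.
#' @param gamma,beta numeric vectors of length `ncol(x)`.
#' @param eps variance floor.
#' @return normalized matrix.
#' @export
layer_norm <- function(x, gamma = rep(1, ncol(x)), beta = numeric(ncol(x)),
                       eps = 1e-5) {
  ln_fwd(x, list(gamma = gamma, beta = beta), eps)$out
}

ln_fwd <- function(x, par, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  ivar <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * ivar
  out <- sweep(xhat, 2, par$gamma, `*`)
  out <- sweep(out, 2, par$beta, `+`)
  list(out = out, cache = list(xhat = xhat, ivar = ivar))
}

ln_bwd <- function(dout, cache, par) {
  D <- ncol(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, par$gamma, `*`)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (cache$ivar / D) * (D * dxhat - s1 - cache$xhat * s2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dense_init <- function(d_in, d_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / d_in)
  list(W = matrix(stats::rnorm(d_in * d_out, 0, scale), d_in, d_out),
       b = numeric(d_out))
}

dense_fwd <- function(x, par) {
  list(out = sweep(x %*% par$W, 2, par$b, `+`), cache = x)
}

dense_bwd <- function(dout, x, par) {
  list(dx = dout %*% t(par$W), dW = t(x) %*% dout, db = colSums(dout))
}

ffn_fwd <- function(x, par) {
  h1 <- dense_fwd(x, par$fc1)
  r <- relu_fwd(h1$out)
  h2 <- dense_fwd(r$out, par$fc2)
  list(out = h2$out, cache = list(x = x, mask = r$cache, h = r$out))
}

ffn_bwd <- function(dout, cache, par) {
  d2 <- dense_bwd(dout, cache$h, par$fc2)
  dr <- relu_bwd(d2$dx, cache$mask)
  d1 <- dense_bwd(dr, cache$x, par$fc1)
  list(dx = d1$dx,
       grads = list(fc1 = list(W = d1$dW, b = d1$db),
                    fc2 = list(W = d2$dW, b = d2$db)))
}

#' Initialize stage-2 transformer parameters
#'
#' One transformer instance serves one pressure stream (systolic on the
#' `X_S` sequences or diastolic on `X_D`); the pipeline trains one instance
#' per stream and pairs their outputs.
#'
#' @param cfg a [transformer_config()].
#' @param input_dim width of the fused input vectors (feature_dim + 1, or
#'   feature_dim in no-fusion mode).
#' @param seed integer seed.
#' @return named list of parameter groups.
#' @export
transformer_init <- function(cfg = transformer_config(), input_dim,
                             seed = 1L) {
  with_local_seed(seed, {
    d <- cfg$d_model
    p <- list()
    p$embed <- dense_init(input_dim, d)
    p$dec_embed <- dense_init(1L, d)
    p$start_token <- stats::rnorm(d, 0, 0.02)
    for (l in seq_len(cfg$encoder_layers)) {
      p[[paste0("enc", l, "_mha")]] <- mha_init(d)
      p[[paste0("enc", l, "_ln1")]] <- ln_init(d)
      p[[paste0("enc", l, "_ffn")]] <- list(fc1 = dense_init(d, cfg$d_ff),
                                            fc2 = dense_init(cfg$d_ff, d))
      p[[paste0("enc", l, "_ln2")]] <- ln_init(d)
    }
    for (l in seq_len(cfg$decoder_layers)) {
      p[[paste0("dec", l, "_self")]] <- mha_init(d)
      p[[paste0("dec", l, "_ln1")]] <- ln_init(d)
      p[[paste0("dec", l, "_cross")]] <- mha_init(d)
      p[[paste0("dec", l, "_ln2")]] <- ln_init(d)
      p[[paste0("dec", l, "_ffn")]] <- list(fc1 = dense_init(d, cfg$d_ff),
                                            fc2 = dense_init(cfg$d_ff, d))
      p[[paste0("dec", l, "_ln3")]] <- ln_init(d)
    }
    p$out_head <- dense_init(d, 1L)
    p
  })
}

# Scale applied to mmHg values entering embeddings, so their magnitude
# matches unit-norm features.
BP_SCALE <- 1 / 200

#' Stage-2 forward pass (one pressure stream)
#'
#' Encoder input: fused vectors of `sequence_len` consecutive windows,
#' linearly embedded plus positional encoding. Decoder input: a learned
#' start token followed by the stream's own embedded stage-1 preliminary
#' estimates, shifted right one position, under a causal mask (ground-truth
#' teacher forcing is never used, so no label leaks into prediction).
#' Deterministic under fixed weights.
#'
#' @param params parameters from [transformer_init()].
#' @param X matrix `T x input_dim` of fused vectors, time-ordered.
#' @param prelim length-T vector of this stream's stage-1 preliminary
#'   estimates in mmHg.
#' @param cfg the matching [transformer_config()].
#' @return list with `Y` (length-T refined estimates, mmHg) and `cache`.
#' @export
stage2_forward <- function(params, X, prelim, cfg = transformer_config()) {
  T_len <- nrow(X)
  if (T_len != cfg$sequence_len) stop("sequence length mismatch")
  prelim <- matrix(as.numeric(prelim), ncol = 1)
  stopifnot(nrow(prelim) == T_len)
  PE <- pe_matrix(T_len, cfg$d_model)
  cache <- list(T_len = T_len)

  emb <- dense_fwd(X, params$embed)
  h <- emb$out + PE
  cache$embed <- emb$cache
  for (l in seq_len(cfg$encoder_layers)) {
    a <- mha_fwd(h, h, params[[paste0("enc", l, "_mha")]], cfg$n_heads)
    l1 <- ln_fwd(h + a$out, params[[paste0("enc", l, "_ln1")]])
    f <- ffn_fwd(l1$out, params[[paste0("enc", l, "_ffn")]])
    l2 <- ln_fwd(l1$out + f$out, params[[paste0("enc", l, "_ln2")]])
    cache[[paste0("enc", l)]] <- list(mha = a$cache, ln1 = l1$cache,
                                      ffn = f$cache, ln2 = l2$cache)
    h <- l2$out
  }
  enc_out <- h

  dec_tokens <- prelim * BP_SCALE
  demb <- dense_fwd(dec_tokens, params$dec_embed)
  D_in <- rbind(params$start_token,
                demb$out[-T_len, , drop = FALSE]) + PE
  if (T_len == 1L) D_in <- matrix(params$start_token, 1) + PE
  cache$dec_embed <- demb$cache
  mask <- causal_mask(T_len)
  g <- D_in
  for (l in seq_len(cfg$decoder_layers)) {
    a <- mha_fwd(g, g, params[[paste0("dec", l, "_self")]], cfg$n_heads, mask)
    l1 <- ln_fwd(g + a$out, params[[paste0("dec", l, "_ln1")]])
    cx <- mha_fwd(l1$out, enc_out, params[[paste0("dec", l, "_cross")]],
                  cfg$n_heads)
    l2 <- ln_fwd(l1$out + cx$out, params[[paste0("dec", l, "_ln2")]])
    f <- ffn_fwd(l2$out, params[[paste0("dec", l, "_ffn")]])
    l3 <- ln_fwd(l2$out + f$out, params[[paste0("dec", l, "_ln3")]])
    cache[[paste0("dec", l)]] <- list(self = a$cache, ln1 = l1$cache,
                                      cross = cx$cache, ln2 = l2$cache,
                                      ffn = f$cache, ln3 = l3$cache)
    g <- l3$out
  }
  outh <- dense_fwd(g, params$out_head)
  cache$out_head <- outh$cache
  list(Y = as.numeric(outh$out), cache = cache, enc_out = enc_out)
}

#' Stage-2 backward pass
#'
#' @param params,cfg as in [stage2_forward()].
#' @param cache cache from [stage2_forward()].
#' @param dY gradient of the loss w.r.t. the length-T output.
#' @return named list of parameter gradients.
#' @export
stage2_backward <- function(params, cfg, cache, dY) {
  grads <- list()
  dY <- matrix(as.numeric(dY), ncol = 1)
  oh <- dense_bwd(dY, cache$out_head, params$out_head)
  grads$out_head <- list(W = oh$dW, b = oh$db)
  dg <- oh$dx
  denc <- 0
  for (l in rev(seq_len(cfg$decoder_layers))) {
    cc <- cache[[paste0("dec", l)]]
    l3 <- ln_bwd(dg, cc$ln3, params[[paste0("dec", l, "_ln3")]])
    grads[[paste0("dec", l, "_ln3")]] <- list(gamma = l3$dgamma, beta = l3$dbeta)
    fb <- ffn_bwd(l3$dx, cc$ffn, params[[paste0("dec", l, "_ffn")]])
    grads[[paste0("dec", l, "_ffn")]] <- fb$grads
    d2 <- l3$dx + fb$dx
    l2 <- ln_bwd(d2, cc$ln2, params[[paste0("dec", l, "_ln2")]])
    grads[[paste0("dec", l, "_ln2")]] <- list(gamma = l2$dgamma, beta = l2$dbeta)
    cb <- mha_bwd(l2$dx, cc$cross, params[[paste0("dec", l, "_cross")]])
    grads[[paste0("dec", l, "_cross")]] <- list(Wq = cb$dWq, Wk = cb$dWk,
                                                Wv = cb$dWv, Wo = cb$dWo)
    denc <- denc + cb$dXkv
    d1 <- l2$dx + cb$dXq
    l1 <- ln_bwd(d1, cc$ln1, params[[paste0("dec", l, "_ln1")]])
    grads[[paste0("dec", l, "_ln1")]] <- list(gamma = l1$dgamma, beta = l1$dbeta)
    sb <- mha_bwd(l1$dx, cc$self, params[[paste0("dec", l, "_self")]])
    grads[[paste0("dec", l, "_self")]] <- list(Wq = sb$dWq, Wk = sb$dWk,
                                               Wv = sb$dWv, Wo = sb$dWo)
    dg <- l1$dx + sb$dXq + sb$dXkv
  }
  # decoder input: start token + shifted embedded prelims (+ PE)
  grads$start_token <- dg[1, ]
  T_len <- cache$T_len
  ddemb <- rbind(dg[-1, , drop = FALSE], matrix(0, 1, ncol(dg)))
  de <- dense_bwd(ddemb, cache$dec_embed, params$dec_embed)
  grads$dec_embed <- list(W = de$dW, b = de$db)

  dh <- denc
  for (l in rev(seq_len(cfg$encoder_layers))) {
    cc <- cache[[paste0("enc", l)]]
    l2 <- ln_bwd(dh, cc$ln2, params[[paste0("enc", l, "_ln2")]])
    grads[[paste0("enc", l, "_ln2")]] <- list(gamma = l2$dgamma, beta = l2$dbeta)
    fb <- ffn_bwd(l2$dx, cc$ffn, params[[paste0("enc", l, "_ffn")]])
    grads[[paste0("enc", l, "_ffn")]] <- fb$grads
    d1 <- l2$dx + fb$dx
    l1 <- ln_bwd(d1, cc$ln1, params[[paste0("enc", l, "_ln1")]])
    grads[[paste0("enc", l, "_ln1")]] <- list(gamma = l1$dgamma, beta = l1$dbeta)
    ab <- mha_bwd(l1$dx, cc$mha, params[[paste0("enc", l, "_mha")]])
    grads[[paste0("enc", l, "_mha")]] <- list(Wq = ab$dWq, Wk = ab$dWk,
                                              Wv = ab$dWv, Wo = ab$dWo)
    dh <- l1$dx + ab$dXq + ab$dXkv
  }
  eb <- dense_bwd(dh, cache$embed, params$embed)
  grads$embed <- list(W = eb$dW, b = eb$db)
  grads
}
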