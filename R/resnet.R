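#' Stage-1 residual network configuration
#'
#' A 1D adaptation of the 18-layer residual network: stem convolution
#' (kernel 7, stride 2) with max pooling, four stages of basic blocks with
#' identity skip connections (`y = F(x, W) + x`), global average pooling,
#' and two regression heads. Each head produces a feature vector (`F_S` for
#' systolic, `F_D` for diastolic) and a dense preliminary pressure estimate.
#'
#' @param in_channels input channels (2: micro-vibration + derivative).
#' @param stem_width stem channel width; stages use 1x/2x/4x/8x. Default 64.
#' @param stage_blocks integer vector of blocks per stage; the default
#'   `c(2, 2, 2, 2)` is the 18-layer configuration.
#' @param feature_dim length n of the per-head feature vectors. Default 512.
#' @return list of class `resnet_config`.
#' @export
resnet_config <- function(in_channels = 2L, stem_width = 64L,
                          stage_blocks = c(2L, 2L, 2L, 2L),
                          feature_dim = 512L) {
  stopifnot(in_channels >= 1, stem_width >= 1, length(stage_blocks) == 4L,
            all(stage_blocks >= 1), feature_dim >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 stem_width = as.integer(stem_width),
                 stage_blocks = as.integer(stage_blocks),
                 feature_dim = as.integer(feature_dim)),
            class = "resnet_config")
}

stage_widths <- function(cfg) cfg$stem_width * c(1L, 2L, 4L, 8L)

#' Initialize stage-1 network parameters
#'
#' He-normal initialization for convolutions and linear layers, unit
#' batch-norm scale. Deterministic given the seed.
#'
#' @param cfg a [resnet_config()].
#' @param seed integer seed.
#' @return named list of parameter groups.
#' @export
resnet_init <- function(cfg = resnet_config(), seed = 1L) {
  with_local_seed(seed, {
    widths <- stage_widths(cfg)
    p <- list()
    p$stem_conv <- conv1d_init(cfg$in_channels, cfg$stem_width, 7L)
    p$stem_bn <- bn_init(cfg$stem_width)
    c_in <- cfg$stem_width
    for (s in 1:4) {
      for (b in seq_len(cfg$stage_blocks[s])) {
        pre <- sprintf("s%db%d", s, b)
        stride <- if (s > 1 && b == 1) 2L else 1L
        c_out <- widths[s]
        p[[paste0(pre, "_conv1")]] <- conv1d_init(c_in, c_out, 3L)
        p[[paste0(pre, "_bn1")]] <- bn_init(c_out)
        p[[paste0(pre, "_conv2")]] <- conv1d_init(c_out, c_out, 3L)
        p[[paste0(pre, "_bn2")]] <- bn_init(c_out)
        if (stride != 1L || c_in != c_out) {
          p[[paste0(pre, "_down")]] <- conv1d_init(c_in, c_out, 1L)
          p[[paste0(pre, "_down_bn")]] <- bn_init(c_out)
        }
        c_in <- c_out
      }
    }
    p$head_s_f <- linear_init(widths[4], cfg$feature_dim)
    p$head_s_y <- linear_init(cfg$feature_dim, 1L)
    p$head_d_f <- linear_init(widths[4], cfg$feature_dim)
    p$head_d_y <- linear_init(cfg$feature_dim, 1L)
    p
  })
}

block_fwd <- function(x, params, pre, stride, train) {
  has_down <- !is.null(params[[paste0(pre, "_down")]])
  c1 <- conv1d_fwd(x, params[[paste0(pre, "_conv1")]], stride, pad = 1L)
  b1 <- bn_fwd(c1$out, params[[paste0(pre, "_bn1")]], train)
  params[[paste0(pre, "_bn1")]] <- b1$par
  r1 <- relu_fwd(b1$out)
  c2 <- conv1d_fwd(r1$out, params[[paste0(pre, "_conv2")]], 1L, pad = 1L)
  b2 <- bn_fwd(c2$out, params[[paste0(pre, "_bn2")]], train)
  params[[paste0(pre, "_bn2")]] <- b2$par
  if (has_down) {
    cd <- conv1d_fwd(x, params[[paste0(pre, "_down")]], stride, pad = 0L)
    bd <- bn_fwd(cd$out, params[[paste0(pre, "_down_bn")]], train)
    params[[paste0(pre, "_down_bn")]] <- bd$par
    xs <- bd$out
    down_cache <- list(conv = cd$cache, bn = bd$cache)
  } else {
    xs <- x
    down_cache <- NULL
  }
  r2 <- relu_fwd(b2$out + xs)
  list(out = r2$out, params = params,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    down = down_cache, has_down = has_down))
}

block_bwd <- function(dout, cache, params, pre, grads) {
  dsum <- relu_bwd(dout, cache$r2)
  # main branch
  db2 <- bn_bwd(dsum, cache$b2, params[[paste0(pre, "_bn2")]])
  grads[[paste0(pre, "_bn2")]] <- list(gamma = db2$dgamma, beta = db2$dbeta)
  dc2 <- conv1d_bwd(db2$dx, cache$c2, params[[paste0(pre, "_conv2")]])
  grads[[paste0(pre, "_conv2")]] <- list(W = dc2$dW, b = dc2$db)
  dr1 <- relu_bwd(dc2$dx, cache$r1)
  db1 <- bn_bwd(dr1, cache$b1, params[[paste0(pre, "_bn1")]])
  grads[[paste0(pre, "_bn1")]] <- list(gamma = db1$dgamma, beta = db1$dbeta)
  dc1 <- conv1d_bwd(db1$dx, cache$c1, params[[paste0(pre, "_conv1")]])
  grads[[paste0(pre, "_conv1")]] <- list(W = dc1$dW, b = dc1$db)
  dx <- dc1$dx
  # skip branch
  if (cache$has_down) {
    dbd <- bn_bwd(dsum, cache$down$bn, params[[paste0(pre, "_down_bn")]])
    grads[[paste0(pre, "_down_bn")]] <- list(gamma = dbd$dgamma, beta = dbd$dbeta)
    dcd <- conv1d_bwd(dbd$dx, cache$down$conv, params[[paste0(pre, "_down")]])
    grads[[paste0(pre, "_down")]] <- list(W = dcd$dW, b = dcd$db)
    dx <- dx + dcd$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

#' Stage-1 forward pass
#'
#' Runs a batch of dual-channel windows through the shared residual trunk
#' and both regression heads. Deterministic under fixed weights.
#'
#' @param params parameters from [resnet_init()].
#' @param x numeric array `C x L x B` (or `window_set` channels slice
#'   reshaped by [windows_to_batch()]).
#' @param cfg the matching [resnet_config()].
#' @param train logical; `TRUE` uses batch statistics in batch norm and
#'   stores caches for the backward pass.
#' @return list with `F_S`, `F_D` (`feature_dim x B`), `y_S`, `y_D`
#'   (length-B preliminary estimates in mmHg), `params` (running statistics
#'   updated when training) and `cache`.
#' @export
resnet_forward <- function(params, x, cfg = resnet_config(), train = FALSE) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == cfg$in_channels)
  cache <- list()
  st <- conv1d_fwd(x, params$stem_conv, stride = 2L, pad = 3L)
  sb <- bn_fwd(st$out, params$stem_bn, train)
  params$stem_bn <- sb$par
  sr <- relu_fwd(sb$out)
  mp <- maxpool_fwd(sr$out)
  cache$stem <- list(conv = st$cache, bn = sb$cache, relu = sr$cache,
                     pool = mp$cache)
  h <- mp$out
  for (s in 1:4) {
    for (b in seq_len(cfg$stage_blocks[s])) {
      pre <- sprintf("s%db%d", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      bl <- block_fwd(h, params, pre, stride, train)
      params <- bl$params
      cache[[pre]] <- bl$cache
      h <- bl$out
    }
  }
  gp <- gap_fwd(h)
  cache$gap <- gp$cache
  g <- gp$out
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)  # B = 1
  fs <- linear_fwd(g, params$head_s_f); frs <- relu_fwd(fs$out)
  fd <- linear_fwd(g, params$head_d_f); frd <- relu_fwd(fd$out)
  ys <- linear_fwd(frs$out, params$head_s_y)
  yd <- linear_fwd(frd$out, params$head_d_y)
  cache$heads <- list(g = g, fs = fs$cache, frs = frs$cache, fd = fd$cache,
                      frd = frd$cache, ys = ys$cache, yd = yd$cache)
  list(F_S = frs$out, F_D = frd$out,
       y_S = as.numeric(ys$out), y_D = as.numeric(yd$out),
       params = params, cache = cache)
}

#' Stage-1 backward pass
#'
#' @param params,cfg as in [resnet_forward()].
#' @param cache cache from a `train = TRUE` forward pass.
#' @param dy_S,dy_D length-B gradients of the loss w.r.t. the preliminary
#'   estimates.
#' @return named list of parameter gradients (same nesting as `params`).
#' @export
resnet_backward <- function(params, cfg, cache, dy_S, dy_D) {
  grads <- list()
  hd <- cache$heads
  B <- length(dy_S)
  dys <- matrix(dy_S, 1, B); dyd <- matrix(dy_D, 1, B)
  lys <- linear_bwd(dys, hd$ys, params$head_s_y)
  grads$head_s_y <- list(W = lys$dW, b = lys$db)
  lyd <- linear_bwd(dyd, hd$yd, params$head_d_y)
  grads$head_d_y <- list(W = lyd$dW, b = lyd$db)
  dfs <- relu_bwd(lys$dx, hd$frs)
  dfd <- relu_bwd(lyd$dx, hd$frd)
  lfs <- linear_bwd(dfs, hd$g, params$head_s_f)
  grads$head_s_f <- list(W = lfs$dW, b = lfs$db)
  lfd <- linear_bwd(dfd, hd$g, params$head_d_f)
  grads$head_d_f <- list(W = lfd$dW, b = lfd$db)
  dg <- lfs$dx + lfd$dx
  dh <- gap_bwd(dg, cache$gap)
  for (s in 4:1) {
    for (b in rev(seq_len(cfg$stage_blocks[s]))) {
      pre <- sprintf("s%db%d", s, b)
      bl <- block_bwd(dh, cache[[pre]], params, pre, grads)
      grads <- bl$grads
      dh <- bl$dx
    }
  }
  dp <- maxpool_bwd(dh, cache$stem$pool)
  dr <- relu_bwd(dp, cache$stem$relu)
  db <- bn_bwd(dr, cache$stem$bn, params$stem_bn)
  grads$stem_bn <- list(gamma = db$dgamma, beta = db$dbeta)
  dc <- conv1d_bwd(db$dx, cache$stem$conv, params$stem_conv)
  grads$stem_conv <- list(W = dc$dW, b = dc$db)
  grads
}

#' Reshape window-set channels into a network batch
#'
#' @param ws a `window_set`.
#' @param idx window indices to include (default all).
#' @return array `2 x L x length(idx)`.
#' @export
windows_to_batch <- function(ws, idx = seq_len(n_windows(ws))) {
  aperm(ws$channels[idx, , , drop = FALSE], c(2, 3, 1))
}
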