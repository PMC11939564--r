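test_that("a residual block with zeroed residual branch is the identity map", {
  cfg <- tiny_resnet_cfg()
  params <- resnet_init(cfg, seed = 1)
  for (leaf in c("s1b1_conv1", "s1b1_conv2")) {
    params[[leaf]]$W[] <- 0
    params[[leaf]]$b[] <- 0
  }
  params$s1b1_bn1$beta[] <- 0
  params$s1b1_bn2$beta[] <- 0
  x <- array(abs(stats::rnorm(cfg$stem_width * 20 * 2)),
             c(cfg$stem_width, 20, 2))  # non-negative input
  out <- radbp:::block_fwd(x, params, "s1b1", stride = 1L, train = TRUE)$out
  expect_close(out, x, tol = 1e-9)
})

test_that("stage-1 forward obeys shape and determinism contracts", {
  cfg <- tiny_resnet_cfg()
  params <- resnet_init(cfg, seed = 2)
  B <- 5L
  x <- array(stats::rnorm(2 * 64 * B), c(2, 64, B))
  fw1 <- resnet_forward(params, x, cfg, train = FALSE)
  fw2 <- resnet_forward(params, x, cfg, train = FALSE)
  expect_identical(fw1$y_S, fw2$y_S)
  expect_identical(fw1$F_D, fw2$F_D)
  expect_identical(dim(fw1$F_S), c(cfg$feature_dim, B))
  expect_length(fw1$y_S, B)
  expect_true(all(is.finite(fw1$F_S)))
  # all-zero input still yields finite outputs
  z <- resnet_forward(params, array(0, c(2, 64, 3)), cfg, train = FALSE)
  expect_true(all(is.finite(c(z$F_S, z$F_D, z$y_S, z$y_D))))
  expect_error(resnet_forward(params, array(0, c(3, 64, 2)), cfg), "")
  # deterministic re-initialization
  expect_identical(resnet_init(cfg, seed = 2)$stem_conv$W, params$stem_conv$W)
})

test_that("stage-1 backward matches finite differences", {
  cfg <- tiny_resnet_cfg()
  params <- resnet_init(cfg, seed = 3)
  set.seed(4)
  B <- 3L
  x <- array(stats::rnorm(2 * 40 * B), c(2, 40, B))
  sbp <- stats::runif(B, 100, 140)
  dbp <- stats::runif(B, 60, 90)
  lossf <- function(p) {
    fw <- resnet_forward(p, x, cfg, train = TRUE)
    mean(pseudo_huber(sbp - fw$y_S, 5)) + mean(pseudo_huber(dbp - fw$y_D, 5))
  }
  fw <- resnet_forward(params, x, cfg, train = TRUE)
  lg <- radbp:::stage1_loss_grads(fw, sbp, dbp, 5)
  gr <- resnet_backward(fw$params, cfg, fw$cache, lg$dy_S, lg$dy_D)
  probes <- list(c("stem_conv", "W", 5), c("s1b1_conv1", "W", 7),
                 c("s2b1_down", "W", 3), c("s3b2_bn2", "gamma", 2),
                 c("head_d_y", "W", 3), c("head_s_y", "b", 1))
  eps <- 1e-5
  for (pr in probes) {
    i <- as.integer(pr[3])
    p1 <- params; p2 <- params
    p1[[pr[1]]][[pr[2]]][i] <- p1[[pr[1]]][[pr[2]]][i] + eps
    p2[[pr[1]]][[pr[2]]][i] <- p2[[pr[1]]][[pr[2]]][i] - eps
    num <- (lossf(p1) - lossf(p2)) / (2 * eps)
    ana <- gr[[pr[1]]][[pr[2]]][i]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-3,
              label = paste(pr, collapse = "$"))
  }
})

test_that("positional encoding matches its closed form", {
  # pos 0: sin(0) = 0, cos(0) = 1, alternating
  expect_close(positional_encoding(0, 6), c(0, 1, 0, 1, 0, 1))
  # pos 1, d_model 4: [sin(1), cos(1), sin(1e-2), cos(1e-2)]
  expect_close(positional_encoding(1, 4),
               c(sin(1), cos(1), sin(0.01), cos(0.01)), tol = 1e-12)
  expect_close(positional_encoding(1, 4),
               c(0.84147, 0.54030, 0.01000, 0.99995), tol = 1e-5)
  # each adjacent (sin, cos) pair lies on the unit circle
  for (pos in c(0, 3, 17)) {
    pe <- positional_encoding(pos, 8)
    pairs <- matrix(pe, nrow = 2)
    expect_close(colSums(pairs^2), rep(1, 4), tol = 1e-12)
  }
})

test_that("scaled dot-product attention matches hand-computed cases", {
  # sequence length 1: softmax over one element, output = V
  V <- matrix(c(2, -1), 1)
  out1 <- scaled_dot_attention(matrix(1, 1, 1), matrix(1, 1, 1), V, d_k = 1)
  expect_close(out1$out, V)
  # Q = K = V = I2, d_k = 2: row-0 weights softmax([1/sqrt(2), 0])
  I2 <- diag(2)
  res <- scaled_dot_attention(I2, I2, I2, d_k = 2)
  w <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + exp(0))
  expect_close(res$weights[1, ], c(w, 1 - w), tol = 1e-12)
  expect_close(res$weights[1, ], c(0.6698, 0.3302), tol = 1e-4)
  expect_close(res$out[1, ], c(w, 1 - w), tol = 1e-12)
  # softmax rows sum to 1 for arbitrary inputs
  set.seed(5)
  r <- scaled_dot_attention(matrix(rnorm(12), 4), matrix(rnorm(12), 4),
                            matrix(rnorm(8), 4), d_k = 3)
  expect_close(rowSums(r$weights), rep(1, 4), tol = 1e-6)
})

test_that("multi-head attention degenerates to single-head and keeps width", {
  set.seed(6)
  d <- 4L
  X <- matrix(rnorm(3 * d), 3, d)
  id <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
  mh <- multi_head_attention(X, X, X, id, n_heads = 1)
  sd1 <- scaled_dot_attention(X, X, X, d_k = d)
  expect_close(mh, sd1$out, tol = 1e-12)
  # output width is d_model for any head count
  par <- radbp:::mha_init(d)
  for (h in c(1L, 2L, 4L)) {
    expect_identical(dim(multi_head_attention(X, X, X, par, h)),
                     c(3L, d))
  }
  expect_error(multi_head_attention(X, X, X, par, n_heads = 3), "divisible")
})

test_that("causal masking blocks information flow from future positions", {
  set.seed(7)
  d <- 8L
  par <- radbp:::mha_init(d)
  X <- matrix(rnorm(5 * d), 5, d)
  mask <- radbp:::causal_mask(5)
  base <- radbp:::mha_fwd(X, X, par, n_heads = 2, mask = mask)$out
  X2 <- X
  X2[4:5, ] <- X2[4:5, ] + rnorm(2 * d)
  pert <- radbp:::mha_fwd(X2, X2, par, n_heads = 2, mask = mask)$out
  expect_close(pert[1:3, ], base[1:3, ], tol = 1e-12)
  expect_false(isTRUE(all.equal(pert[4, ], base[4, ])))
})

test_that("layer normalization produces the prescribed moments", {
  set.seed(8)
  x <- matrix(rnorm(6 * 32, mean = 3, sd = 4), 6, 32)
  y <- layer_norm(x)
  expect_close(rowMeans(y), rep(0, 6), tol = 1e-5)
  expect_close(apply(y, 1, function(r) mean(r^2)), rep(1, 6), tol = 1e-4)
  # affine parameters shift and scale
  y2 <- layer_norm(x, gamma = rep(2, 32), beta = rep(5, 32))
  expect_close(rowMeans(y2), rep(5, 6), tol = 1e-4)
})

test_that("fusion concatenates the cross preliminary estimate", {
  bundle <- list(F_S = matrix(c(.1, .2, .3, .4), 4),
                 F_D = matrix(c(.5, .6, .7, .8), 4),
                 y_S = 120, y_D = 70)
  fx <- fuse(bundle)
  expect_identical(dim(fx$X_S), c(5L, 1L))
  expect_equal(fx$X_S[5, 1], 70 / 200)   # DBP estimate closes the SBP vector
  expect_equal(fx$X_D[5, 1], 120 / 200)  # SBP estimate closes the DBP vector
  expect_close(fx$X_S[1:4, 1], c(.1, .2, .3, .4))
  # n = 512 gives 513-dimensional fused vectors
  big <- list(F_S = matrix(0, 512, 2), F_D = matrix(0, 512, 2),
              y_S = c(120, 121), y_D = c(70, 71))
  expect_identical(nrow(fuse(big)$X_S), 513L)
  # no-fusion ablation: plain features
  nf <- fuse(bundle, fusion = FALSE)
  expect_identical(dim(nf$X_S), c(4L, 1L))
  expect_error(fuse(list(F_S = bundle$F_S, F_D = bundle$F_D)), "missing")
})

test_that("stage-2 forward is deterministic, causal, and degenerates at T = 1", {
  cfg <- transformer_config(d_model = 8, n_heads = 2, encoder_layers = 1,
                            decoder_layers = 1, d_ff = 12, sequence_len = 4)
  params <- transformer_init(cfg, input_dim = 5, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(20), 4, 5)
  prelim <- runif(4, 90, 140)
  a <- stage2_forward(params, X, prelim, cfg)
  b <- stage2_forward(params, X, prelim, cfg)
  expect_identical(a$Y, b$Y)
  expect_length(a$Y, 4L)
  # decoder causality: perturbing the preliminary estimate at position k
  # leaves outputs up to k unchanged (the decoder stream is shifted right)
  p2 <- prelim; p2[3] <- p2[3] + 25
  c_ <- stage2_forward(params, X, p2, cfg)
  expect_close(c_$Y[1:3], a$Y[1:3], tol = 1e-12)
  expect_false(isTRUE(all.equal(c_$Y[4], a$Y[4])))
  expect_error(stage2_forward(params, X[1:3, ], prelim[1:3], cfg),
               "length mismatch")
  # T = 1: attention collapses to a single unit weight; still finite
  cfg1 <- transformer_config(d_model = 8, n_heads = 2, encoder_layers = 1,
                             decoder_layers = 1, d_ff = 12, sequence_len = 1)
  p1 <- transformer_init(cfg1, input_dim = 5, seed = 9)
  out1 <- stage2_forward(p1, matrix(rnorm(5), 1), 120, cfg1)
  expect_length(out1$Y, 1L)
  expect_true(is.finite(out1$Y))
})

test_that("stage-2 backward matches finite differences", {
  cfg <- transformer_config(d_model = 8, n_heads = 2, encoder_layers = 2,
                            decoder_layers = 2, d_ff = 12, sequence_len = 5)
  params <- transformer_init(cfg, input_dim = 7, seed = 4)
  set.seed(3)
  X <- matrix(rnorm(35), 5, 7)
  prelim <- runif(5, 60, 140)
  labels <- runif(5, 60, 140)
  lossf <- function(p) {
    radbp:::stage2_loss_grads(stage2_forward(p, X, prelim, cfg)$Y, labels,
                              5)$loss
  }
  fw <- stage2_forward(params, X, prelim, cfg)
  lg <- radbp:::stage2_loss_grads(fw$Y, labels, 5)
  gr <- stage2_backward(params, cfg, fw$cache, lg$dY)
  probes <- list(c("embed", "W", 3), c("dec_embed", "W", 4),
                 c("enc1_mha", "Wq", 5), c("dec2_cross", "Wo", 12),
                 c("enc2_ln2", "gamma", 4), c("out_head", "W", 2))
  eps <- 1e-5
  for (pr in probes) {
    i <- as.integer(pr[3])
    p1 <- params; p2 <- params
    p1[[pr[1]]][[pr[2]]][i] <- p1[[pr[1]]][[pr[2]]][i] + eps
    p2[[pr[1]]][[pr[2]]][i] <- p2[[pr[1]]][[pr[2]]][i] - eps
    num <- (lossf(p1) - lossf(p2)) / (2 * eps)
    ana <- gr[[pr[1]]][[pr[2]]][i]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4,
              label = paste(pr, collapse = "$"))
  }
  st1 <- params; st1$start_token[2] <- st1$start_token[2] + eps
  st2 <- params; st2$start_token[2] <- st2$start_token[2] - eps
  num <- (lossf(st1) - lossf(st2)) / (2 * eps)
  expect_lt(abs(num - gr$start_token[2]) /
              max(1e-8, abs(num) + abs(gr$start_token[2])), 1e-4)
})
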