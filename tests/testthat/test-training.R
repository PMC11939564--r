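test_that("pseudo-huber loss matches its closed form and asymptotics", {
  expect_equal(pseudo_huber(0, 5), 0)
  # a = delta = 1: sqrt(2) - 1
  expect_equal(pseudo_huber(1, 1), sqrt(2) - 1, tolerance = 1e-12)
  # quadratic regime: loss ~ a^2/2 within 1% for |a| <= delta/10
  for (a in c(0.1, 0.5, -0.5)) {
    expect_lt(abs(pseudo_huber(a, 5) - a^2 / 2) / (a^2 / 2), 0.01)
  }
  # linear regime: loss / (delta * |a|) -> 1 for |a| >> delta
  expect_equal(pseudo_huber(5000, 5) / (5 * 5000), 1, tolerance = 1e-3)
  # monotone non-decreasing in |a|
  grid <- seq(0, 50, by = 0.25)
  expect_true(all(diff(pseudo_huber(grid, 5)) >= 0))
  expect_error(pseudo_huber(1, 0), "positive")
})

test_that("plateau scheduler halves the rate after the patience window", {
  sched <- plateau_scheduler(0.001, factor = 0.5, patience = 5)
  # constant validation stream: LR is 0.0005 after six epochs
  for (k in 1:6) sched <- scheduler_step(sched, 1.0)
  expect_equal(sched$lr, 0.0005)
  # five further constant epochs halve again
  for (k in 1:5) sched <- scheduler_step(sched, 1.0)
  expect_equal(sched$lr, 0.00025)
  # an improvement resets the counter
  sched2 <- plateau_scheduler(0.001, 0.5, 5)
  for (k in 1:4) sched2 <- scheduler_step(sched2, 1.0)
  sched2 <- scheduler_step(sched2, 0.5)  # improvement
  for (k in 1:4) sched2 <- scheduler_step(sched2, 0.5)
  expect_equal(sched2$lr, 0.001)
})

test_that("adam with decoupled decay shrinks weights but not biases", {
  params <- list(lin = list(W = matrix(1, 2, 2), b = c(1, 1)))
  grads <- list(lin = list(W = matrix(0, 2, 2), b = c(0, 0)))
  state <- radbp:::adam_init_like(params)
  upd <- radbp:::adam_update(params, grads, state, t = 1, lr = 0.1,
                             weight_decay = 0.1)
  expect_true(all(upd$params$lin$W < 1))       # decayed
  expect_identical(upd$params$lin$b, c(1, 1))  # zero grad, no decay
})

test_that("training losses decrease on a learnable toy problem", {
  # 50 optimizer steps on a tiny batch must strictly reduce the loss for
  # both stages (trainability sanity)
  cfg <- tiny_resnet_cfg()
  params <- resnet_init(cfg, seed = 5)
  set.seed(6)
  B <- 8L
  x <- array(rnorm(2 * 48 * B), c(2, 48, B))
  sbp <- runif(B, 100, 140); dbp <- runif(B, 60, 90)
  params$head_s_y$b <- mean(sbp); params$head_d_y$b <- mean(dbp)
  state <- radbp:::adam_init_like(params)
  losses <- numeric(50)
  for (it in 1:50) {
    fw <- resnet_forward(params, x, cfg, train = TRUE)
    params <- fw$params
    lg <- radbp:::stage1_loss_grads(fw, sbp, dbp, 5)
    losses[it] <- lg$loss
    gr <- resnet_backward(params, cfg, fw$cache, lg$dy_S, lg$dy_D)
    upd <- radbp:::adam_update(params, gr, state, it, 0.001, 0.002)
    params <- upd$params; state <- upd$state
  }
  expect_lt(losses[50], losses[1])
  expect_lt(min(losses), 0.5 * losses[1])

  tcfg2 <- transformer_config(d_model = 8, n_heads = 2, encoder_layers = 1,
                              decoder_layers = 1, d_ff = 16,
                              sequence_len = 4)
  tp <- transformer_init(tcfg2, input_dim = 5, seed = 7)
  X <- matrix(rnorm(20), 4, 5)
  prelim <- runif(4, 90, 130)
  labels <- runif(4, 90, 130)
  tp$out_head$b <- mean(labels)
  tstate <- radbp:::adam_init_like(tp)
  tlosses <- numeric(50)
  for (it in 1:50) {
    fw <- stage2_forward(tp, X, prelim, tcfg2)
    lg <- radbp:::stage2_loss_grads(fw$Y, labels, 5)
    tlosses[it] <- lg$loss
    gr <- stage2_backward(tp, tcfg2, fw$cache, lg$dY)
    upd <- radbp:::adam_update(tp, gr, tstate, it, 0.001, 0.002)
    tp <- upd$params; tstate <- upd$state
  }
  expect_lt(tlosses[50], tlosses[1])
})

test_that("stage-1 fitting is seeded, improves on the baseline, and exports features", {
  ws <- coupled_windows()
  sp <- make_splits(ws, split_spec(seed = 2))
  rcfg <- tiny_resnet_cfg()
  tcfg <- train_config(epochs = 4, seed = 11)
  m <- fit_stage1(sp$train, sp$val, rcfg, tcfg)
  m2 <- fit_stage1(sp$train, sp$val, rcfg, tcfg)
  expect_equal(m$best_val, m2$best_val, tolerance = 1e-12)
  expect_identical(nrow(m$history) <= 4, TRUE)
  # features exported with frozen weights are reproducible
  b1 <- export_features(m, sp$test)
  b2 <- export_features(m, sp$test)
  expect_identical(b1$y_S, b2$y_S)
  expect_identical(dim(b1$F_S), c(rcfg$feature_dim, n_windows(sp$test)))
  expect_error(fit_stage1(window_subset(ws, integer()), sp$val, rcfg, tcfg),
               "empty")
})

test_that("stage-2 fitting consumes frozen features and supports ablations", {
  ws <- coupled_windows()
  sp <- make_splits(ws, split_spec(seed = 2))
  rcfg <- tiny_resnet_cfg()
  tcfg <- train_config(epochs = 2, seed = 12)
  m1 <- fit_stage1(sp$train, sp$val, rcfg, tcfg)
  cfg2 <- transformer_config(d_model = 8, n_heads = 2, encoder_layers = 1,
                             decoder_layers = 1, d_ff = 16, sequence_len = 4)
  pair <- fit_stage2_pair(sp$train, sp$val, m1, cfg2, tcfg, fusion = TRUE)
  expect_identical(pair$sbp$input_dim, rcfg$feature_dim + 1L)
  pred <- predict_pipeline(m1, pair, sp$test, mode = "full")
  expect_identical(nrow(pred), n_windows(sp$test))
  expect_true(all(is.finite(pred$sbp_pred)))
  # no-fusion ablation narrows the input width by one and still trains
  pair_nf <- fit_stage2_pair(sp$train, sp$val, m1, cfg2, tcfg,
                             fusion = FALSE)
  expect_identical(pair_nf$sbp$input_dim, rcfg$feature_dim)
  pred_nf <- predict_pipeline(m1, pair_nf, sp$test, mode = "no-fusion")
  expect_true(all(is.finite(pred_nf$dbp_pred)))
  # fusion mismatch between training and prediction is refused
  expect_error(predict_pipeline(m1, pair_nf, sp$test, mode = "full"),
               "fusion")
  # stage-1-only path bypasses stage 2 entirely
  p1 <- predict_pipeline(m1, NULL, sp$test, mode = "stage1-only")
  b <- export_features(m1, sp$test)
  expect_identical(p1$sbp_pred, b$y_S)
  # seeded reproducibility of the stage-2 fit
  pair2 <- fit_stage2_pair(sp$train, sp$val, m1, cfg2, tcfg, fusion = TRUE)
  expect_equal(pair$sbp$best_val, pair2$sbp$best_val, tolerance = 1e-12)
})

test_that("sequence assembly keeps subjects separate and pads for prediction", {
  ws <- coupled_windows()
  sp <- make_splits(ws, split_spec(mode = "subject", seed = 3))
  rcfg <- tiny_resnet_cfg()
  m1 <- fit_stage1(sp$train, sp$val, rcfg, train_config(epochs = 1, seed = 1))
  b <- export_features(m1, sp$train)
  cfg2 <- transformer_config(d_model = 8, n_heads = 2, sequence_len = 4)
  seqs <- build_sequences(sp$train, b, cfg2, "sbp", fusion = TRUE)
  for (sq in seqs) {
    expect_length(unique(sp$train$subject_id[sq$idx]), 1L)
    expect_identical(nrow(sq$X), 4L)
    # time-ordered within the sequence
    expect_true(all(diff(sp$train$window_start_s[sq$idx]) > 0))
  }
  padded <- build_sequences(sp$train, b, cfg2, "sbp", fusion = TRUE,
                            pad = TRUE)
  covered <- sort(unique(unlist(lapply(padded, function(s) {
    s$idx[seq_len(s$n_eff)]
  }))))
  expect_identical(covered, seq_len(n_windows(sp$train)))
})
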