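#' Training configuration
#'
#' Optimization regime shared by both stages: Adam with decoupled weight
#' decay, plateau learning-rate scheduling, early stopping and a robust
#' Pseudo-Huber objective.
#'
#' @param lr initial learning rate (default 0.001).
#' @param plateau_factor multiplicative LR reduction on plateau (default 0.5).
#' @param plateau_patience epochs without validation improvement before the
#'   LR is reduced (default 5).
#' @param weight_decay decoupled L2 coefficient applied to weight matrices
#'   (default 0.002).
#' @param epochs maximum epochs (default 60).
#' @param batch_stage1,batch_stage2 minibatch sizes (defaults 32 and 4).
#' @param delta Pseudo-Huber scale in mmHg (default 5, the scale of the
#'   clinically tolerated mean error).
#' @param early_stop_patience epochs without validation improvement before
#'   training stops (default 10).
#' @param seed integer seed for initialization and shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, plateau_factor = 0.5,
                         plateau_patience = 5L, weight_decay = 0.002,
                         epochs = 60L, batch_stage1 = 32L, batch_stage2 = 4L,
                         delta = 5, early_stop_patience = 10L, seed = 1L) {
  stopifnot(lr > 0, plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1, weight_decay >= 0, epochs >= 1,
            batch_stage1 >= 1, batch_stage2 >= 1, delta > 0,
            early_stop_patience >= 1)
  structure(list(lr = lr, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_stage1 = as.integer(batch_stage1),
                 batch_stage2 = as.integer(batch_stage2), delta = delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Pseudo-Huber loss
#'
#' `delta^2 * (sqrt(1 + (a/delta)^2) - 1)`: quadratic (`a^2/2`) for errors
#' well below `delta`, linear (`delta * |a|`) far above it, with continuous
#' curvature in between.
#'
#' @param a error(s) in mmHg (prediction minus truth or vice versa).
#' @param delta positive scale in mmHg.
#' @return loss value(s), elementwise.
#' @export
pseudo_huber <- function(a, delta = 5) {
  if (!is.numeric(delta) || delta <= 0) stop("delta must be positive")
  delta^2 * (sqrt(1 + (a / delta)^2) - 1)
}

# d/da of pseudo_huber
pseudo_huber_grad <- function(a, delta = 5) {
  a / sqrt(1 + (a / delta)^2)
}

# ---------------------------------------------------------------------------
# AdamW over arbitrarily nested parameter lists. Decoupled weight decay is
# applied to weight matrices (names starting with "W"); biases, norm affine
# parameters and the start token are not decayed. Batch-norm running
# statistics are carried through untouched.

DECAY_NAMES <- c("W", "Wq", "Wk", "Wv", "Wo")

adam_init_like <- function(params) {
  rec <- function(p) {
    if (is.list(p)) lapply(p, rec)
    else list(m = p * 0, v = p * 0)
  }
  lapply(params, rec)
}

adam_update <- function(params, grads, state, t, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, s, name) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% c("run_mean", "run_var")) next
        if (is.null(g[[nm]])) next
        r <- rec(p[[nm]], g[[nm]], s[[nm]], nm)
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    step <- lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    if (name %in% DECAY_NAMES) step <- step + lr * weight_decay * p
    list(p = p - step, s = s)
  }
  out <- rec(params, grads, state, "")
  list(params = out$p, state = out$s)
}

# ---------------------------------------------------------------------------
# Plateau scheduler and early stopping

#' Create a plateau learning-rate scheduler
#'
#' Tracks the best validation loss; when `patience` consecutive epochs fail
#' to improve it, the learning rate is multiplied by `factor` and the
#' counter resets. With patience 5 and a constant validation stream, the
#' first reduction happens at the sixth epoch.
#'
#' @param lr initial learning rate.
#' @param factor multiplicative reduction in (0, 1).
#' @param patience consecutive non-improving epochs tolerated.
#' @return scheduler state list (fields `lr`, `best`, `count`).
#' @export
plateau_scheduler <- function(lr, factor = 0.5, patience = 5L) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       best = Inf, count = 0L)
}

#' Advance a plateau scheduler by one epoch
#'
#' @param sched scheduler state from [plateau_scheduler()].
#' @param val_loss this epoch's validation loss.
#' @return updated scheduler state.
#' @export
scheduler_step <- function(sched, val_loss) {
  if (val_loss < sched$best) {
    sched$best <- val_loss
    sched$count <- 0L
  } else {
    sched$count <- sched$count + 1L
    if (sched$count >= sched$patience) {
      sched$lr <- sched$lr * sched$factor
      sched$count <- 0L
    }
  }
  sched
}

batch_indices <- function(n, batch_size, shuffle_seed = NULL) {
  ord <- if (is.null(shuffle_seed)) seq_len(n)
         else with_local_seed(shuffle_seed, sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

stage1_loss_grads <- function(fw, sbp, dbp, delta) {
  a_s <- sbp - fw$y_S
  a_d <- dbp - fw$y_D
  loss <- mean(pseudo_huber(a_s, delta)) + mean(pseudo_huber(a_d, delta))
  n <- length(a_s)
  list(loss = loss,
       dy_S = -pseudo_huber_grad(a_s, delta) / n,
       dy_D = -pseudo_huber_grad(a_d, delta) / n)
}

#' Fit the stage-1 residual network
#'
#' Adam with decoupled weight decay, plateau LR scheduling, early stopping
#' on validation loss, Pseudo-Huber objective (systolic and diastolic terms
#' summed unweighted). The output-head biases are initialized to the
#' training label means so optimization starts from an unbiased predictor.
#' The parameters achieving the best validation loss are returned.
#'
#' @param train_ws,val_ws training/validation `window_set`s (disjoint).
#' @param rcfg a [resnet_config()].
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `stage1_model`: `params`, `rcfg`, `tcfg`,
#'   `history` (epoch, train/val loss, lr), `best_val`.
#' @export
fit_stage1 <- function(train_ws, val_ws, rcfg = resnet_config(),
                       tcfg = train_config(), verbose = FALSE) {
  if (!n_windows(train_ws) || !n_windows(val_ws)) stop("empty split")
  params <- resnet_init(rcfg, seed = tcfg$seed)
  params$head_s_y$b <- mean(train_ws$sbp)
  params$head_d_y$b <- mean(train_ws$dbp)
  state <- adam_init_like(params)
  sched <- plateau_scheduler(tcfg$lr, tcfg$plateau_factor,
                             tcfg$plateau_patience)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame()
  t_adam <- 0L
  stall <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    batches <- batch_indices(n_windows(train_ws), tcfg$batch_stage1,
                             shuffle_seed = tcfg$seed + 1000L * epoch)
    tr_loss <- 0
    for (bi in batches) {
      x <- windows_to_batch(train_ws, bi)
      fw <- resnet_forward(params, x, rcfg, train = TRUE)
      params <- fw$params   # running BN statistics
      lg <- stage1_loss_grads(fw, train_ws$sbp[bi], train_ws$dbp[bi],
                              tcfg$delta)
      grads <- resnet_backward(params, rcfg, fw$cache, lg$dy_S, lg$dy_D)
      t_adam <- t_adam + 1L
      upd <- adam_update(params, grads, state, t_adam, sched$lr,
                         tcfg$weight_decay)
      params <- upd$params; state <- upd$state
      tr_loss <- tr_loss + lg$loss * length(bi)
    }
    tr_loss <- tr_loss / n_windows(train_ws)
    val_loss <- stage1_eval_loss(params, rcfg, val_ws, tcfg)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss, lr = sched$lr))
    if (verbose) {
      message(sprintf("stage1 epoch %d train %.4f val %.4f lr %.5f",
                      epoch, tr_loss, val_loss, sched$lr))
    }
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    sched <- scheduler_step(sched, val_loss)
    if (stall >= tcfg$early_stop_patience) break
  }
  structure(list(params = best$params, rcfg = rcfg, tcfg = tcfg,
                 history = hist, best_val = best$val,
                 best_epoch = best$epoch),
            class = "stage1_model")
}

stage1_eval_loss <- function(params, rcfg, ws, tcfg) {
  pr <- stage1_predict_raw(params, rcfg, ws, tcfg$batch_stage1)
  mean(pseudo_huber(ws$sbp - pr$y_S, tcfg$delta)) +
    mean(pseudo_huber(ws$dbp - pr$y_D, tcfg$delta))
}

stage1_predict_raw <- function(params, rcfg, ws, batch_size = 64L) {
  n <- n_windows(ws)
  F_S <- matrix(0, rcfg$feature_dim, n)
  F_D <- matrix(0, rcfg$feature_dim, n)
  y_S <- numeric(n); y_D <- numeric(n)
  for (bi in batch_indices(n, batch_size)) {
    fw <- resnet_forward(params, windows_to_batch(ws, bi), rcfg,
                         train = FALSE)
    F_S[, bi] <- fw$F_S; F_D[, bi] <- fw$F_D
    y_S[bi] <- fw$y_S; y_D[bi] <- fw$y_D
  }
  list(F_S = F_S, F_D = F_D, y_S = y_S, y_D = y_D)
}

#' Extract stage-1 feature bundles with frozen weights
#'
#' @param model a `stage1_model`.
#' @param ws a `window_set`.
#' @return list with `F_S`, `F_D` (`feature_dim x N`) and preliminary
#'   estimates `y_S`, `y_D` (length N, mmHg).
#' @export
export_features <- function(model, ws) {
  stopifnot(inherits(model, "stage1_model"))
  stage1_predict_raw(model$params, model$rcfg, ws)
}

# ---------------------------------------------------------------------------
# Sequence assembly for stage 2

#' Assemble stage-2 sequences for one pressure stream
#'
#' Windows are ordered in time within each subject and chunked into
#' consecutive runs of `sequence_len`. The systolic stream carries the
#' `X_S` fused vectors (systolic features + scaled diastolic preliminary
#' estimate), its own preliminary estimates and systolic labels; the
#' diastolic stream mirrors this. In training mode the trailing partial
#' chunk is dropped; in prediction mode it is padded by repeating the last
#' window so every window receives a stage-2 estimate.
#'
#' @param ws a `window_set`.
#' @param bundle feature bundle from [export_features()].
#' @param cfg a [transformer_config()].
#' @param stream `"sbp"` or `"dbp"`.
#' @param fusion logical, cross-coupled fusion on (default) or off.
#' @param pad pad the trailing partial chunk (prediction mode).
#' @return list of sequences, each with `X` (`T x input_dim`), `prelim`
#'   (length T), `labels` (length T), `idx` (window indices) and `n_eff`
#'   (positions that are real windows, `<= T` when padded).
#' @export
build_sequences <- function(ws, bundle, cfg = transformer_config(),
                            stream = c("sbp", "dbp"), fusion = TRUE,
                            pad = FALSE) {
  stream <- match.arg(stream)
  fused <- fuse(bundle, fusion)
  X_all <- if (stream == "sbp") fused$X_S else fused$X_D
  prelim_all <- if (stream == "sbp") bundle$y_S else bundle$y_D
  label_all <- if (stream == "sbp") ws$sbp else ws$dbp
  T_len <- cfg$sequence_len
  seqs <- list()
  for (sid in unique(ws$subject_id)) {
    widx <- which(ws$subject_id == sid)
    widx <- widx[order(ws$window_start_s[widx])]
    nfull <- length(widx) %/% T_len
    rem <- length(widx) %% T_len
    take <- if (pad && rem > 0) nfull + 1L else nfull
    for (k in seq_len(take)) {
      idx <- widx[((k - 1L) * T_len + 1L):min(k * T_len, length(widx))]
      n_eff <- length(idx)
      if (n_eff < T_len) idx <- c(idx, rep(idx[n_eff], T_len - n_eff))
      seqs[[length(seqs) + 1L]] <- list(
        X = t(X_all[, idx, drop = FALSE]),
        prelim = prelim_all[idx],
        labels = label_all[idx],
        idx = idx, n_eff = n_eff)
    }
  }
  seqs
}

seq_input_dim <- function(seqs) ncol(seqs[[1]]$X)

stage2_loss_grads <- function(Y, labels, delta) {
  a <- labels - Y
  list(loss = mean(pseudo_huber(a, delta)),
       dY = -pseudo_huber_grad(a, delta) / length(a))
}

#' Fit a stage-2 transformer stream
#'
#' Same optimizer regime as stage 1 (Adam with decoupled weight decay,
#' plateau scheduler, early stopping, Pseudo-Huber loss over every sequence
#' position), at the stage-2 batch size. Stage-1 weights are frozen; only
#' sequences of its exported features are consumed. The pipeline fits one
#' stream for systolic and one for diastolic pressure (see
#' [fit_stage2_pair()]).
#'
#' @param seqs_train,seqs_val sequence lists from [build_sequences()].
#' @param cfg a [transformer_config()].
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `stage2_model`: `params`, `cfg`, `tcfg`,
#'   `history`, `best_val`, `input_dim`.
#' @export
fit_stage2 <- function(seqs_train, seqs_val, cfg = transformer_config(),
                       tcfg = train_config(), verbose = FALSE) {
  if (!length(seqs_train) || !length(seqs_val)) stop("empty sequence split")
  input_dim <- seq_input_dim(seqs_train)
  if (!all(vapply(seqs_train, function(s) ncol(s$X), integer(1)) == input_dim)) {
    stop("inconsistent sequence input widths")
  }
  params <- transformer_init(cfg, input_dim, seed = tcfg$seed)
  params$out_head$b <- mean(unlist(lapply(seqs_train, `[[`, "labels")))
  state <- adam_init_like(params)
  sched <- plateau_scheduler(tcfg$lr, tcfg$plateau_factor,
                             tcfg$plateau_patience)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame()
  t_adam <- 0L
  stall <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    batches <- batch_indices(length(seqs_train), tcfg$batch_stage2,
                             shuffle_seed = tcfg$seed + 2000L * epoch)
    tr_loss <- 0
    for (bi in batches) {
      grads_acc <- NULL
      loss_b <- 0
      for (si in bi) {
        sq <- seqs_train[[si]]
        fw <- stage2_forward(params, sq$X, sq$prelim, cfg)
        lg <- stage2_loss_grads(fw$Y, sq$labels, tcfg$delta)
        g <- stage2_backward(params, cfg, fw$cache, lg$dY / length(bi))
        grads_acc <- if (is.null(grads_acc)) g else add_grads(grads_acc, g)
        loss_b <- loss_b + lg$loss
      }
      t_adam <- t_adam + 1L
      upd <- adam_update(params, grads_acc, state, t_adam, sched$lr,
                         tcfg$weight_decay)
      params <- upd$params; state <- upd$state
      tr_loss <- tr_loss + loss_b
    }
    tr_loss <- tr_loss / length(seqs_train)
    val_loss <- stage2_eval_loss(params, cfg, seqs_val, tcfg)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss, lr = sched$lr))
    if (verbose) {
      message(sprintf("stage2 epoch %d train %.4f val %.4f lr %.5f",
                      epoch, tr_loss, val_loss, sched$lr))
    }
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    sched <- scheduler_step(sched, val_loss)
    if (stall >= tcfg$early_stop_patience) break
  }
  structure(list(params = best$params, cfg = cfg, tcfg = tcfg,
                 history = hist, best_val = best$val,
                 best_epoch = best$epoch, input_dim = input_dim),
            class = "stage2_model")
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) add_grads(a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

stage2_eval_loss <- function(params, cfg, seqs, tcfg) {
  tot <- 0
  for (sq in seqs) {
    fw <- stage2_forward(params, sq$X, sq$prelim, cfg)
    tot <- tot + stage2_loss_grads(fw$Y, sq$labels, tcfg$delta)$loss
  }
  tot / length(seqs)
}

# ---------------------------------------------------------------------------
# Pipeline prediction

#' Fit both stage-2 streams
#'
#' Trains one transformer on the systolic (`X_S`) sequences and one on the
#' diastolic (`X_D`) sequences, sharing the training regime.
#'
#' @param train_ws,val_ws training/validation `window_set`s.
#' @param stage1 a fitted `stage1_model` (frozen).
#' @param cfg a [transformer_config()].
#' @param tcfg a [train_config()].
#' @param fusion cross-coupled fusion on (default) or off.
#' @param verbose print per-epoch progress.
#' @return list of class `stage2_pair`: `sbp`, `dbp` (`stage2_model`s),
#'   `fusion`, `cfg`.
#' @export
fit_stage2_pair <- function(train_ws, val_ws, stage1,
                            cfg = transformer_config(),
                            tcfg = train_config(), fusion = TRUE,
                            verbose = FALSE) {
  btr <- export_features(stage1, train_ws)
  bva <- export_features(stage1, val_ws)
  models <- lapply(c("sbp", "dbp"), function(st) {
    fit_stage2(build_sequences(train_ws, btr, cfg, st, fusion),
               build_sequences(val_ws, bva, cfg, st, fusion),
               cfg, tcfg, verbose = verbose)
  })
  structure(list(sbp = models[[1]], dbp = models[[2]], fusion = fusion,
                 cfg = cfg),
            class = "stage2_pair")
}

#' Predict blood pressure for a window set
#'
#' @param stage1 a `stage1_model`.
#' @param stage2 a `stage2_pair` from [fit_stage2_pair()], or `NULL` for
#'   the stage-1-only ablation.
#' @param ws a `window_set`.
#' @param mode `"full"` (cross-coupled fusion + transformer), `"no-fusion"`
#'   (transformer on plain features) or `"stage1-only"`.
#' @return data.frame with `sbp_pred` and `dbp_pred` (mmHg), one row per
#'   window of `ws`.
#' @export
predict_pipeline <- function(stage1, stage2 = NULL, ws,
                             mode = c("full", "no-fusion", "stage1-only")) {
  mode <- match.arg(mode)
  bundle <- export_features(stage1, ws)
  if (mode == "stage1-only") {
    return(data.frame(sbp_pred = bundle$y_S, dbp_pred = bundle$y_D))
  }
  if (is.null(stage2)) stop("stage-2 model required for mode ", mode)
  fusion <- (mode == "full")
  if (!identical(stage2$fusion, fusion)) {
    stop("stage-2 pair was trained with a different fusion setting")
  }
  out <- list()
  for (st in c("sbp", "dbp")) {
    model <- stage2[[st]]
    seqs <- build_sequences(ws, bundle, model$cfg, st, fusion, pad = TRUE)
    pred <- numeric(n_windows(ws))
    for (sq in seqs) {
      fw <- stage2_forward(model$params, sq$X, sq$prelim, model$cfg)
      eff <- seq_len(sq$n_eff)
      pred[sq$idx[eff]] <- fw$Y[eff]
    }
    out[[st]] <- pred
  }
  data.frame(sbp_pred = out$sbp, dbp_pred = out$dbp)
}

#' Training-mean baseline predictor
#'
#' Predicts the training-set mean systolic/diastolic values for every
#' window: the no-information reference any learned model must beat.
#'
#' @param train_ws training `window_set`.
#' @param ws target `window_set`.
#' @return data.frame with constant `sbp_pred`, `dbp_pred`.
#' @export
mean_baseline <- function(train_ws, ws) {
  data.frame(sbp_pred = rep(mean(train_ws$sbp), n_windows(ws)),
             dbp_pred = rep(mean(train_ws$dbp), n_windows(ws)))
}
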