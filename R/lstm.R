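#' @title Recurrent forecasters
#' @description
#' A single-layer LSTM over the 12-period input sequence with either a
#' rank-consistent ordinal output head or a single sigmoid output. The
#' ordinal head follows the conditional ordinal-regression decomposition:
#' the 4-class task becomes 3 binary exceedance tasks (>0, >1, >2), the
#' k-th trained only on examples already exceeding k-1, and unconditional
#' exceedance probabilities are chained products of the conditional ones, so
#' P(y>0) >= P(y>1) >= P(y>2) holds structurally. The network (default 1
#' layer, 128 hidden units, 10% dropout, 150 epochs) is trained with Adam
#' after a short automated range test over learning rate and batch size;
#' the epoch with the best validation metric is kept by default.
#' @name forecast_models_rnn
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(n_in, hidden, n_out, seed) {
  set.seed(seed)
  sc_x <- sqrt(1 / n_in)
  sc_h <- sqrt(1 / hidden)
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias
  list(Wx = matrix(stats::rnorm(n_in * 4 * hidden, 0, sc_x), n_in, 4 * hidden),
       Wh = matrix(stats::rnorm(hidden * 4 * hidden, 0, sc_h), hidden, 4 * hidden),
       b = b,
       Wo = matrix(stats::rnorm(hidden * n_out, 0, sc_h), hidden, n_out),
       bo = rep(0, n_out))
}

lstm_forward <- function(params, X, keep_cache = FALSE) {
  d <- dim(X)  # n x T x F
  H <- nrow(params$Wh)
  h <- matrix(0, d[1], H)
  cc <- matrix(0, d[1], H)
  cache <- if (keep_cache) vector("list", d[2]) else NULL
  for (t in seq_len(d[2])) {
    xt <- matrix(X[, t, ], d[1], d[3])
    A <- xt %*% params$Wx + h %*% params$Wh +
      matrix(params$b, d[1], 4 * H, byrow = TRUE)
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    if (keep_cache)
      cache[[t]] <- list(x = xt, i = i, f = f, g = g, o = o,
                         c_prev = cc, tc = tc, h_prev = h)
    h <- o * tc
    cc <- c_new
  }
  list(h = h, cache = cache)
}

lstm_backward <- function(params, cache, dh_last) {
  H <- nrow(params$Wh)
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dh <- dh_last
  dc <- dh * 0
  for (t in rev(seq_along(cache))) {
    ch <- cache[[t]]
    do_ <- dh * ch$tc
    dc <- dc + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g
    df <- dc * ch$c_prev
    dg <- dc * ch$i
    dA <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do_ * ch$o * (1 - ch$o))
    dWx <- dWx + crossprod(ch$x, dA)
    dWh <- dWh + crossprod(ch$h_prev, dA)
    db <- db + colSums(dA)
    dh <- dA %*% t(params$Wh)
    dc <- dc * ch$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# conditional ordinal loss: task k trained on the subset already exceeding
# class k-1, target = exceeds class k
corn_loss_grad <- function(logits, y) {
  n <- nrow(logits)
  M <- cbind(rep(1, n), y >= 1, y >= 2)
  Tg <- cbind(y > 0, y > 1, y > 2)
  p <- sigmoid(logits)
  ntot <- sum(M)
  eps <- 1e-12
  loss <- -sum(M * (Tg * log(p + eps) + (1 - Tg) * log(1 - p + eps))) / ntot
  list(loss = loss, dlogits = M * (p - Tg) / ntot)
}

bce_loss_grad <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  n <- nrow(logits)
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - y) / n)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(grads)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

rnn_batch_grads <- function(params, X, y, loss_fn, dropout, rng_dropout) {
  fw <- lstm_forward(params, X, keep_cache = TRUE)
  h <- fw$h
  if (dropout > 0 && rng_dropout) {
    mask <- matrix(stats::rbinom(length(h), 1, 1 - dropout), nrow(h)) /
      (1 - dropout)
  } else mask <- 1
  hd <- h * mask
  logits <- hd %*% params$Wo + matrix(params$bo, nrow(h), ncol(params$Wo),
                                      byrow = TRUE)
  lg <- loss_fn(logits, y)
  dWo <- crossprod(hd, lg$dlogits)
  dbo <- colSums(lg$dlogits)
  dh <- (lg$dlogits %*% t(params$Wo)) * mask
  back <- lstm_backward(params, fw$cache, dh)
  list(loss = lg$loss,
       grads = list(Wx = back$Wx, Wh = back$Wh, b = back$b,
                    Wo = dWo, bo = dbo))
}

rnn_logits <- function(params, X) {
  h <- lstm_forward(params, X)$h
  h %*% params$Wo + matrix(params$bo, nrow(h), ncol(params$Wo), byrow = TRUE)
}

#' Exceedance probabilities to ordinal class
#'
#' The predicted class is the number of cumulative exceedance probabilities
#' strictly above 0.5.
#'
#' @param cumprobs Matrix (n x 3) of P(y>0), P(y>1), P(y>2).
#' @return Integer classes in `{0,1,2,3}`.
#' @export
#' @examples
#' exceedance_to_class(rbind(c(0.9, 0.6, 0.2)))  # 2
exceedance_to_class <- function(cumprobs) {
  as.integer(rowSums(cumprobs > 0.5))
}

rnn_cumprobs <- function(params, X) {
  p <- sigmoid(rnn_logits(params, X))
  cp <- t(apply(p, 1, cumprod))
  if (any(cp[, -1, drop = FALSE] - cp[, -ncol(cp), drop = FALSE] > 1e-12))
    stop("rank-consistency assertion failed: exceedance probabilities increase")
  cp
}

run_epochs <- function(params, opt, Xtr, ytr, loss_fn, epochs, batch_size,
                       lr, dropout, eval_fn = NULL) {
  n <- dim(Xtr)[1]
  best <- NULL
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    bl <- 0
    for (start in seq(1, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1, n)]
      out <- rnn_batch_grads(params, Xtr[b, , , drop = FALSE], ytr[b],
                             loss_fn, dropout, TRUE)
      st <- adam_step(params, out$grads, opt, lr)
      params <- st$params; opt <- st$state
      bl <- bl + out$loss * length(b)
    }
    losses[ep] <- bl / n
    if (!is.null(eval_fn)) {
      score <- eval_fn(params)
      if (is.null(best) || score < best$score)
        best <- list(params = params, score = score, epoch = ep)
    }
  }
  list(params = params, opt = opt, losses = losses, best = best)
}

range_test <- function(init, Xtr, ytr, loss_fn, dropout, n_train) {
  lrs <- c(0.03, 0.01, 0.003, 0.001)
  batches <- unique(pmin(c(32L, 64L), n_train))
  best <- NULL
  for (lr in lrs) for (bs in batches) {
    res <- run_epochs(init, adam_new(init), Xtr, ytr, loss_fn,
                      epochs = 2, batch_size = bs, lr = lr, dropout = dropout)
    fl <- res$losses[length(res$losses)]
    if (is.finite(fl) && (is.null(best) || fl < best$loss))
      best <- list(lr = lr, batch_size = bs, loss = fl)
  }
  if (is.null(best)) best <- list(lr = 0.003, batch_size = batches[1])
  best
}

train_rnn_core <- function(examples, y, loss_fn, n_out, eval_builder,
                           hidden, epochs, dropout, lr, batch_size, seed,
                           model_selection, refit_final) {
  s <- examples$meta$split
  tr <- which(s == "train"); va <- which(s == "val")
  Xtr <- examples$X[tr, , , drop = FALSE]
  Xva <- examples$X[va, , , drop = FALSE]
  init <- lstm_init(dim(Xtr)[3], hidden, n_out, seed)
  set.seed(seed + 1L)
  if (is.null(lr) || is.null(batch_size)) {
    rt <- range_test(init, Xtr, y[tr], loss_fn, dropout, length(tr))
    if (is.null(lr)) lr <- rt$lr
    if (is.null(batch_size)) batch_size <- rt$batch_size
  }
  eval_fn <- if (model_selection) eval_builder(Xva, y[va]) else NULL
  set.seed(seed + 2L)
  res <- run_epochs(init, adam_new(init), Xtr, y[tr], loss_fn, epochs,
                    batch_size, lr, dropout, eval_fn)
  params <- res$params
  n_epochs_used <- epochs
  if (model_selection && !is.null(res$best)) {
    params <- res$best$params
    n_epochs_used <- res$best$epoch
  }
  if (refit_final) {
    all_idx <- c(tr, va)
    set.seed(seed + 3L)
    res2 <- run_epochs(init, adam_new(init),
                       examples$X[all_idx, , , drop = FALSE], y[all_idx],
                       loss_fn, n_epochs_used, batch_size, lr, dropout)
    params <- res2$params
  }
  list(params = params, lr = lr, batch_size = batch_size,
       epochs_used = n_epochs_used, Xva = Xva, yva = y[va])
}

#' Train a recurrent ordinal forecaster
#'
#' @param examples Standardized `forecast_examples` (ordinal labels).
#' @param hidden Hidden units in the single LSTM layer (default 128).
#' @param epochs Training epochs (default 150).
#' @param dropout Dropout rate on the final hidden state (default 0.10).
#' @param lr,batch_size Learning rate and batch size; `NULL` (default) runs
#'   a short automated range test before training.
#' @param seed Integer seed (initialization, batching, dropout).
#' @param model_selection Keep the epoch with the best validation MAMAE
#'   (default); `FALSE` keeps the final epoch.
#' @param refit_final Refit on train+validation for the selected number of
#'   epochs (default).
#' @return Object of class `rnn_ordinal`.
#' @export
train_rnn_ordinal <- function(examples, hidden = 128, epochs = 150,
                              dropout = 0.10, lr = NULL, batch_size = NULL,
                              seed = 1, model_selection = TRUE,
                              refit_final = TRUE) {
  eval_builder <- function(Xva, yva) {
    function(params) mamae(yva, exceedance_to_class(rnn_cumprobs(params, Xva)))
  }
  core <- train_rnn_core(examples, examples$y, corn_loss_grad, 3L,
                         eval_builder, hidden, epochs, dropout, lr,
                         batch_size, seed, model_selection, refit_final)
  structure(list(params = core$params, lr = core$lr,
                 batch_size = core$batch_size, epochs_used = core$epochs_used,
                 item = examples$item, horizon = examples$horizon,
                 task = "ordinal", algorithm = "rnn"),
            class = c("rnn_ordinal", "phenocast_model"))
}

#' Train a recurrent binary forecaster
#'
#' Labels are binarized with the item's recoding rule; training uses binary
#' cross-entropy, epoch selection the validation balanced accuracy, and the
#' decision threshold maximizes validation balanced accuracy unless fixed.
#'
#' @inheritParams train_rnn_ordinal
#' @param fixed_threshold Optional fixed probability cutoff (e.g., 0.5).
#' @return Object of class `rnn_binary`.
#' @export
train_rnn_binary <- function(examples, hidden = 128, epochs = 150,
                             dropout = 0.10, lr = NULL, batch_size = NULL,
                             seed = 1, model_selection = TRUE,
                             refit_final = TRUE, fixed_threshold = NULL) {
  y <- binarize(examples$y, examples$item)
  s <- examples$meta$split
  if (length(unique(y[s == "train"])) < 2L)
    stop("single-class training labels: binary task is degenerate")
  eval_builder <- function(Xva, yva) {
    if (length(unique(yva)) < 2L)
      function(params) 1 - accuracy(yva, as.integer(sigmoid(rnn_logits(params, Xva)) >= 0.5))
    else
      function(params) 1 - bacc(yva, as.integer(sigmoid(rnn_logits(params, Xva)) >= 0.5))
  }
  core <- train_rnn_core(examples, y, bce_loss_grad, 1L, eval_builder,
                         hidden, epochs, dropout, lr, batch_size, seed,
                         model_selection, refit_final)
  prob_val <- as.numeric(sigmoid(rnn_logits(core$params, core$Xva)))
  th <- if (is.null(fixed_threshold)) best_bacc_threshold(prob_val, core$yva)
        else fixed_threshold
  structure(list(params = core$params, prob_threshold = th, lr = core$lr,
                 batch_size = core$batch_size, epochs_used = core$epochs_used,
                 item = examples$item, horizon = examples$horizon,
                 task = "binary", algorithm = "rnn"),
            class = c("rnn_binary", "phenocast_model"))
}

#' Predict on a split of examples
#'
#' @param model A trained `phenocast_model` (gbt/rnn x ordinal/binary).
#' @param examples The `forecast_examples` the model was built from (features
#'   already standardized with the stored parameters).
#' @param split Which split to score, default `"test"`.
#' @return A `prediction_set`: list with `truth`, `pred`, optional
#'   probabilities, and condition metadata.
#' @export
predict_forecast <- function(model, examples, split = "test") {
  stopifnot(inherits(model, "phenocast_model"))
  if (!identical(model$item, examples$item) ||
      !identical(model$horizon, examples$horizon))
    stop("feature-schema mismatch: model and examples disagree on condition")
  idx <- which(examples$meta$split == split)
  truth <- examples$y[idx]
  out <- list(item = model$item, horizon = model$horizon, task = model$task,
              algorithm = model$algorithm, split = split,
              meta = examples$meta[idx, , drop = FALSE])
  if (model$algorithm == "gbt") {
    tab <- to_tabular(examples)[idx, , drop = FALSE]
    if (model$task == "ordinal") {
      sc <- stats::predict(model$model, tab)
      out$scores <- sc
      out$pred <- apply_thresholds(sc, model$thresholds)
      out$truth <- truth
    } else {
      prob <- stats::predict(model$model, tab)
      out$prob <- prob
      out$pred <- as.integer(prob >= model$prob_threshold)
      out$truth <- binarize(truth, model$item)
    }
  } else {
    X <- examples$X[idx, , , drop = FALSE]
    if (model$task == "ordinal") {
      cp <- rnn_cumprobs(model$params, X)
      out$cumprobs <- cp
      out$pred <- exceedance_to_class(cp)
      out$truth <- truth
    } else {
      prob <- as.numeric(sigmoid(rnn_logits(model$params, X)))
      out$prob <- prob
      out$pred <- as.integer(prob >= model$prob_threshold)
      out$truth <- binarize(truth, model$item)
    }
  }
  if (length(unique(out$pred)) == 1L && length(out$pred) > 1L)
    attr(out, "single_class_prediction") <- TRUE
  structure(out, class = "prediction_set")
}
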