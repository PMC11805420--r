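numeric_grad <- function(f, params, key, eps = 1e-5) {
  g <- params[[key]] * 0
  for (i in seq_along(g)) {
    up <- params; up[[key]][i] <- up[[key]][i] + eps
    dn <- params; dn[[key]][i] <- dn[[key]][i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

test_that("analytic LSTM+CORN gradients match finite differences", {
  set.seed(5)
  n <- 7; T_ <- 4; F_ <- 3; H <- 5
  X <- array(rnorm(n * T_ * F_), c(n, T_, F_))
  y <- sample(0:3, n, replace = TRUE)
  params <- phenocast:::lstm_init(F_, H, 3L, seed = 2)
  loss_of <- function(p) {
    fw <- phenocast:::lstm_forward(p, X)
    logits <- fw$h %*% p$Wo + matrix(p$bo, n, 3, byrow = TRUE)
    phenocast:::corn_loss_grad(logits, y)$loss
  }
  out <- phenocast:::rnn_batch_grads(params, X, y,
                                     phenocast:::corn_loss_grad,
                                     dropout = 0, rng_dropout = FALSE)
  for (key in c("Wx", "Wh", "b", "Wo", "bo")) {
    num <- numeric_grad(loss_of, params, key)
    expect_lt(max(abs(out$grads[[key]] - num)), 1e-6)
  }
})

test_that("analytic gradients also hold for the binary head", {
  set.seed(6)
  n <- 6; X <- array(rnorm(n * 3 * 2), c(n, 3, 2))
  y <- rep(c(0, 1), 3)
  params <- phenocast:::lstm_init(2, 4, 1L, seed = 3)
  loss_of <- function(p) {
    fw <- phenocast:::lstm_forward(p, X)
    logits <- fw$h %*% p$Wo + matrix(p$bo, n, 1, byrow = TRUE)
    phenocast:::bce_loss_grad(logits, y)$loss
  }
  out <- phenocast:::rnn_batch_grads(params, X, y,
                                     phenocast:::bce_loss_grad,
                                     dropout = 0, rng_dropout = FALSE)
  for (key in c("Wx", "Wh", "b", "Wo", "bo")) {
    expect_lt(max(abs(out$grads[[key]] - numeric_grad(loss_of, params, key))),
              1e-6)
  }
})

test_that("exceedance probabilities map to classes by counting > 0.5", {
  expect_equal(exceedance_to_class(rbind(c(0.9, 0.6, 0.2))), 2L)
  expect_equal(exceedance_to_class(rbind(c(0.4, 0.3, 0.1))), 0L)
  expect_equal(exceedance_to_class(rbind(c(0.9, 0.8, 0.7))), 3L)
  expect_equal(exceedance_to_class(rbind(c(0.5, 0.5, 0.5))), 0L)
})

test_that("the conditional ordinal head is structurally rank-consistent", {
  set.seed(8)
  params <- phenocast:::lstm_init(4, 6, 3L, seed = 4)
  X <- array(rnorm(50 * 5 * 4, sd = 2), c(50, 5, 4))
  cp <- phenocast:::rnn_cumprobs(params, X)
  expect_true(all(cp >= 0 & cp <= 1))
  expect_true(all(cp[, 1] >= cp[, 2]))
  expect_true(all(cp[, 2] >= cp[, 3]))
})

test_that("recurrent learners are deterministic given a seed and learn signal", {
  ex <- tiny_examples("Depressed", 0)
  m1 <- train_rnn_ordinal(ex, hidden = 12, epochs = 8, lr = 0.01,
                          batch_size = 32, seed = 9)
  m2 <- train_rnn_ordinal(ex, hidden = 12, epochs = 8, lr = 0.01,
                          batch_size = 32, seed = 9)
  p1 <- predict_forecast(m1, ex)
  p2 <- predict_forecast(m2, ex)
  expect_identical(p1$pred, p2$pred)
  expect_equal(m1$params$Wx, m2$params$Wx)
  expect_true(all(p1$pred %in% 0:3))
  expect_lt(mamae(p1$truth, p1$pred), 1.3)

  mb <- train_rnn_binary(ex, hidden = 12, epochs = 8, lr = 0.01,
                         batch_size = 32, seed = 9)
  pb <- predict_forecast(mb, ex)
  expect_true(all(pb$pred %in% 0:1))
  expect_gt(bacc(pb$truth, pb$pred), 0.5)
})

test_that("condition mismatch between model and examples is rejected", {
  ex <- tiny_examples("Depressed", 0)
  other <- tiny_examples("Calm", 0)
  m <- train_gbt_ordinal(ex, n_trials = 2, seed = 1)
  expect_error(predict_forecast(m, other), "mismatch")
})
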