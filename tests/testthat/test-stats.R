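test_that("Monte Carlo baseline draws from the training label distribution", {
  # degenerate sampler: single-class training labels -> zero variance
  bl <- monte_carlo_baseline(rep(2L, 50), c(0L, 1L, 2L, 3L), "mamae",
                             n_draws = 200, seed = 1)
  expect_equal(sd(bl$samples), 0)
  expect_equal(bl$samples[1], mean(c(2, 1, 0, 1)))

  # uniform binary training labels on a balanced test -> centered on 0.5
  set.seed(2)
  bl2 <- monte_carlo_baseline(rep(0:1, 500), rep(0:1, 40), "bacc",
                              n_draws = 1000, seed = 2)
  expect_lt(abs(mean(bl2$samples) - 0.5), 0.02)

  # determinism
  a <- monte_carlo_baseline(c(0, 1, 2, 3, 0, 0), rep(0:3, 5), "mamae",
                            n_draws = 100, seed = 7)
  b <- monte_carlo_baseline(c(0, 1, 2, 3, 0, 0), rep(0:3, 5), "mamae",
                            n_draws = 100, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_error(monte_carlo_baseline(rep(1L, 10), rep(1L, 5), "bacc"),
               "single-class")
})

test_that("significance calls use the corrected quantile with a strict tie rule", {
  bl <- monte_carlo_baseline(rep(0:3, 25), rep(0:3, 10), "mamae",
                             n_draws = 12000, seed = 3)
  call <- significance_call(bl, value = min(bl$samples) - 0.01)
  expect_equal(call$alpha_corrected, 0.05 / 120)
  expect_false(call$resolution_limited)
  expect_true(call$is_significant)
  # a value exactly at the threshold is not significant
  tied <- significance_call(bl, value = call$threshold)
  expect_false(tied$is_significant)
  # 1,000 draws cannot resolve 4.2e-4: annotated, extreme order statistic
  bl1k <- monte_carlo_baseline(rep(0:3, 25), rep(0:3, 10), "mamae",
                               n_draws = 1000, seed = 3)
  lim <- significance_call(bl1k, value = 1)
  expect_true(lim$resolution_limited)
  expect_equal(lim$threshold, min(bl1k$samples))
  # higher-is-better metrics use the upper tail
  blb <- monte_carlo_baseline(rep(0:1, 50), rep(0:1, 20), "bacc",
                              n_draws = 12000, seed = 4)
  cb <- significance_call(blb, value = 0.99)
  expect_true(cb$is_significant)
  expect_gt(cb$threshold, 0.5)
})

make_grid_metrics <- function(f) {
  g <- expand.grid(item = paste0("I", 1:10), horizon = c(0, 1, 7),
                   algorithm = c("gbt", "rnn"), stringsAsFactors = FALSE)
  g$value <- f(g)
  g
}

test_that("algorithm comparison is a paired two-sided Wilcoxon", {
  g <- make_grid_metrics(function(g) seq_len(nrow(g)) / 10)
  same <- g; same$value <- rep(1, nrow(g))
  expect_equal(compare_algorithms(same)$p_value, 1)
  # one algorithm uniformly better by a constant
  set.seed(5)
  g$value <- rnorm(nrow(g))
  g$value[g$algorithm == "rnn"] <- g$value[g$algorithm == "gbt"] + 1
  res <- compare_algorithms(g)
  expect_equal(res$n_pairs, 30)
  expect_lt(res$p_value, 0.001)
  expect_error(compare_algorithms(g[-1, ]), "unpaired|missing")
})

test_that("Friedman effects match a brute-force rank oracle", {
  g <- make_grid_metrics(function(g) rep(1, nrow(g)))
  res <- friedman_effect(g, "horizon")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(6)
  g$value <- rnorm(nrow(g))
  res <- friedman_effect(g, "horizon")
  # oracle: Q = 12/(nk(k+1)) * sum Rj^2 - 3n(k+1), ranks within blocks
  wide <- matrix(NA_real_, 20, 3)
  blocks <- unique(paste(g$item, g$algorithm))
  for (i in seq_along(blocks)) {
    sub <- g[paste(g$item, g$algorithm) == blocks[i], ]
    wide[i, ] <- sub$value[order(sub$horizon)]
  }
  R <- t(apply(wide, 1, rank))
  n <- 20; k <- 3
  Q <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, Q, tolerance = 1e-8)
  expect_equal(res$p_value, pchisq(Q, k - 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(res$df, 2)

  # mental-state analysis uses algorithm x horizon blocks (6 x 10)
  res2 <- friedman_effect(g, "mental_state")
  expect_equal(res2$df, 9)
  expect_error(friedman_effect(g[-1, ], "horizon"), "incomplete")
})

test_that("Spearman correlations handle ties like the average-rank oracle", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  res <- data.frame(task = "ordinal", imbalance = x, mamae = y,
                    mae = -y, bacc = NA, acc = NA)
  res <- rbind(res, within(res, { task <- "binary"; bacc <- -y; acc <- y }))
  out <- imbalance_correlations(res)
  oracle_rho <- cor(rank(x), rank(y))
  expect_equal(out$rho[out$pair == "imbalance vs mamae"], oracle_rho,
               tolerance = 1e-12)
  expect_equal(out$rho[out$pair == "imbalance vs mae"], -oracle_rho,
               tolerance = 1e-12)
  # perfect monotone relations reach +-1
  expect_equal(out$rho[out$pair == "imbalance vs acc"], oracle_rho)
  res_const <- res; res_const$mamae <- 1
  expect_error(imbalance_correlations(res_const), "constant")
})

test_that("task-equivalence residuals measure departure from the identity line", {
  g <- expand.grid(item = paste0("I", 1:5), horizon = c(0, 1),
                   algorithm = "gbt", stringsAsFactors = FALSE)
  ord <- cbind(g, task = "ordinal", nbe = seq(0.1, 1, length.out = 10))
  bin <- cbind(g, task = "binary", nbe = seq(0.1, 1, length.out = 10))
  expect_equal(task_equivalence_residuals(rbind(ord, bin))$mean_residual, 0)
  bin$nbe <- bin$nbe - 0.1
  res <- task_equivalence_residuals(rbind(ord, bin))
  expect_equal(res$mean_residual, 0.1, tolerance = 1e-12)
  expect_equal(res$n, 10)
  expect_error(task_equivalence_residuals(rbind(ord, bin[-1, ])), "unmatched")
})
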