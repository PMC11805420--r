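test_that("cutpoints invert the latent normal to the requested marginals", {
  expect_equal(cutpoints_from_marginals(rep(0.25, 4)),
               c(qnorm(0.25), 0, qnorm(0.75)), tolerance = 1e-12)
  expect_equal(cutpoints_from_marginals(rep(0.25, 4), latent_sd = 2),
               2 * c(qnorm(0.25), 0, qnorm(0.75)), tolerance = 1e-12)
  expect_error(cutpoints_from_marginals(c(0.5, 0.5, 0, 0)),
               "zero-probability")
  expect_error(cutpoints_from_marginals(c(0.5, 0.3, 0.3, 0.3)), "sum to 1")

  # simulated class frequencies from the latent construction reproduce the
  # marginals at Monte Carlo scale
  m <- c(0.78, 0.13, 0.06, 0.03)
  cp <- cutpoints_from_marginals(m, latent_sd = 1.3)
  set.seed(42)
  cls <- findInterval(rnorm(1e5, 0, 1.3), cp)
  expect_lt(max(abs(tabulate(cls + 1, 4) / 1e5 - m)), 0.005)
  expect_true(all(diff(cp) > 0))
})

test_that("generated cohorts are deterministic and structurally complete", {
  cfg <- cohort_config(n_participants = 3, days_per_participant = 30, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # exactly 4 periods per participant-day, no missing values, nonnegative
  per_day <- table(a$sensing$participant_id, a$sensing$date)
  expect_true(all(per_day == 4))
  expect_false(anyNA(a$sensing))
  num <- a$sensing[, sensing_feature_names()]
  expect_true(all(num >= 0))
  expect_true(all(unlist(a$surveys[, mental_state_items()$item]) %in% 0:3))
})

test_that("surveys follow the Mon/Wed/Fri cadence with rare shifts", {
  co <- generate_cohort(cohort_config(n_participants = 20,
                                      days_per_participant = 200, seed = 9))
  wd <- as.POSIXlt(co$surveys$date)$wday
  off <- mean(!wd %in% c(1, 3, 5))
  expect_gt(off, 0)       # some off-schedule reports exist
  expect_lt(off, 0.08)    # but they are a small minority (~3% target)
})

test_that("realized item marginals match targets within 2% at scale", {
  # a wide cohort: the participant random intercept makes participants the
  # effective sampling unit for marginal recovery, so many short series
  # give the tightest check
  co <- cached("cohort_marginals",
               function() generate_cohort(
                 cohort_config(n_participants = 600,
                               days_per_participant = 30, seed = 13)))
  targets <- default_item_marginals()
  n <- nrow(co$surveys)
  expect_gt(n * 10, 1e4)
  for (item in names(targets)) {
    realized <- tabulate(co$surveys[[item]] + 1, 4) / n
    expect_lt(max(abs(realized - targets[[item]])), 0.02)
  }
})

test_that("null generator yields labels independent of features", {
  # permutation test of feature-label association across replicate cohorts
  n_sig <- 0L
  n_tests <- 0L
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(n_participants = 8,
                                        days_per_participant = 60,
                                        signal_strength = 0, seed = 200 + s))
    day_feat <- aggregate(act_still ~ participant_id + date, co$sensing, sum)
    merged <- merge(co$surveys, day_feat, by = c("participant_id", "date"))
    obs <- abs(cor(merged$act_still, merged$Depressed))
    set.seed(s)
    perm <- replicate(399, abs(cor(merged$act_still, sample(merged$Depressed))))
    p <- (1 + sum(perm >= obs)) / 400
    n_tests <- n_tests + 1L
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("a fixed learner's validation error decreases with signal strength", {
  vals <- vapply(c(0, 0.5, 1, 2), function(s) {
    co <- generate_cohort(cohort_config(n_participants = 8,
                                        days_per_participant = 100,
                                        signal_strength = s, seed = 33))
    ts <- time_split(co$surveys)
    ex <- standardize_examples(
      build_examples(co$sensing, ts$surveys, 0, "Depressed"))
    train_gbt_ordinal(ex, n_trials = 3, seed = 33)$val_mamae
  }, numeric(1))
  # non-increasing across the signal ladder, allowing one inversion in noise
  expect_lte(sum(diff(vals) > 0), 1L)
  expect_lt(vals[4], vals[1])
})

test_that("cohorts round-trip through CSV", {
  co <- tiny_cohort(n = 2, days = 20)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$sensing$act_still, co$sensing$act_still)
  expect_equal(back$surveys$Depressed, co$surveys$Depressed)
  expect_s3_class(back$surveys$date, "Date")
  expect_true("Seeing things" %in% names(back$surveys))
})
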