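# Shared fixtures. Heavy benchmark runs are memoised so several tests can
# reuse a single computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

tiny_cohort <- function(seed = 7, signal = 2, n = 6, days = 80) {
  generate_cohort(cohort_config(n_participants = n,
                                days_per_participant = days,
                                signal_strength = signal, seed = seed))
}

tiny_examples <- function(item = "Depressed", horizon = 0, seed = 7,
                          signal = 2, n = 6, days = 80,
                          scope = "train") {
  co <- cached(sprintf("cohort_%d_%s_%d_%d", seed, signal, n, days),
               function() tiny_cohort(seed, signal, n, days))
  ts <- time_split(co$surveys)
  standardize_examples(build_examples(co$sensing, ts$surveys, horizon, item),
                       scope = scope)
}

# Reduced-scale strong-signal benchmark over the gbt half of the factorial
# grid (10 items x 3 horizons x 2 tasks = 60 model conditions). Shared by
# the imbalance-correlation, signal-recovery and task-equivalence checks.
# 20 participants give 140 test examples per condition, enough to resolve
# the Bonferroni-corrected baseline quantile with reasonable power (the
# emulated study evaluates on ~427).
strong_benchmark <- function() {
  cached("strong_benchmark", function() {
    cfg <- benchmark_config(
      cohort = cohort_config(n_participants = 20, days_per_participant = 150,
                             signal_strength = 2, seed = 11),
      algorithms = "gbt",
      gbt = list(n_trials = 10),
      n_draws = 12000, seed = 11)
    run_benchmark(cfg)
  })
}

# Moderate-signal benchmark at the generator's default signal strength:
# the regime of imperfect, partly majority-leaning models in which
# unbalanced metrics flatter imbalanced conditions. Used for the
# imbalance-correlation checks.
moderate_benchmark <- function() {
  cached("moderate_benchmark", function() {
    cfg <- benchmark_config(
      cohort = cohort_config(n_participants = 20, days_per_participant = 150,
                             signal_strength = 1, seed = 17),
      algorithms = "gbt",
      gbt = list(n_trials = 10, fixed_threshold = 0.5),
      n_draws = 12000, seed = 17)
    run_benchmark(cfg)
  })
}

# Null-signal runs: 5 replicate cohorts, reduced grid (one heavily skewed
# item, one flat item, 3 horizons, both tasks, gbt).
null_benchmarks <- function() {
  cached("null_benchmarks", function() {
    lapply(1:5, function(s) {
      cfg <- benchmark_config(
        cohort = cohort_config(n_participants = 10, days_per_participant = 100,
                               signal_strength = 0, seed = 100 + s),
        items = c("Harm", "Social"),
        algorithms = "gbt",
        gbt = list(n_trials = 5),
        n_draws = 12000, seed = 100 + s)
      run_benchmark(cfg)
    })
  })
}
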