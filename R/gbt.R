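#' @title Gradient-boosted forecasters
#' @description
#' Gradient-boosted decision trees (xgboost) for the ordinal-regression and
#' binary-classification tasks. The ordinal learner fits a continuous
#' regressor under squared loss on the raw ratings and discretizes its
#' output with three strictly increasing thresholds, initialized at the
#' midpoints (0.5, 1.5, 2.5) and tuned jointly with the hyperparameters to
#' minimize validation MAMAE. The binary learner is a logistic model whose
#' decision threshold is chosen on validation to maximize balanced accuracy.
#' Hyperparameters are drawn by uniform random search with a 10-trial
#' budget.
#' @name forecast_models_gbt
NULL

default_ordinal_thresholds <- function() c(0.5, 1.5, 2.5)

#' Discretize continuous predictions with ordinal thresholds
#'
#' A prediction falling exactly on a threshold is assigned to the upper
#' class.
#'
#' @param scores Continuous predictions.
#' @param thresholds Strictly increasing length-3 numeric vector.
#' @return Integer classes in `{0,1,2,3}`.
#' @export
#' @examples
#' apply_thresholds(c(0.2, 1.7, 2.9), c(0.5, 1.5, 2.5))  # 0 2 3
apply_thresholds <- function(scores, thresholds) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0))
  as.integer(rowSums(outer(scores, thresholds, ">=")))
}

# thresholds parameterized as (t1, log gap2, log gap3) so monotonicity is
# structural during optimization
par_to_thresholds <- function(par) cumsum(c(par[1], exp(par[2]), exp(par[3])))

tune_thresholds <- function(scores, y_val) {
  default <- default_ordinal_thresholds()
  obj <- function(par) {
    th <- par_to_thresholds(par)
    mamae(y_val, apply_thresholds(scores, th))
  }
  init <- c(0.5, 0, 0)
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 300))
  tuned <- par_to_thresholds(opt$par)
  # tuning searches a set containing the default; never return worse
  if (obj(opt$par) <= mamae(y_val, apply_thresholds(scores, default))) tuned
  else default
}

# search space sized for desk-scale cohorts: a few hundred training rows
# against 276 highly correlated columns favour shallow trees, aggressive
# column subsampling and moderate learning rates
sample_gbt_params <- function() {
  list(max_depth = sample(2:5, 1),
       eta = 10^stats::runif(1, log10(0.03), log10(0.3)),
       nrounds = sample(30:150, 1),
       subsample = stats::runif(1, 0.5, 1),
       colsample_bytree = stats::runif(1, 0.3, 0.8),
       min_child_weight = stats::runif(1, 1, 10))
}

fit_xgb <- function(X, y, params, objective, seed, nthread = 1) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(objective = objective, max_depth = params$max_depth,
                  eta = params$eta, subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  min_child_weight = params$min_child_weight,
                  tree_method = "hist", nthread = nthread, seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

split_tabular <- function(examples) {
  tab <- to_tabular(examples)
  s <- examples$meta$split
  list(tab = tab, train = which(s == "train"), val = which(s == "val"),
       test = which(s == "test"))
}

#' Train a gradient-boosted ordinal forecaster
#'
#' @param examples Standardized `forecast_examples` (ordinal labels).
#' @param n_trials Random-search budget (default 10 trials).
#' @param seed Integer seed for the search and the boosters.
#' @param tune_thresholds If `FALSE`, keep the default (0.5, 1.5, 2.5)
#'   discretization thresholds.
#' @param refit_final Refit the selected model on train+validation (default).
#' @param nthread xgboost threads (default 1, deterministic).
#' @return Object of class `gbt_ordinal` with the booster, `thresholds`,
#'   selected `params` and `val_mamae`.
#' @export
train_gbt_ordinal <- function(examples, n_trials = 10, seed = 1,
                              tune_thresholds = TRUE, refit_final = TRUE,
                              nthread = 1) {
  sp <- split_tabular(examples)
  y <- examples$y
  y_val <- y[sp$val]
  val_classes <- length(unique(y_val))
  allow_tuning <- tune_thresholds
  if (val_classes <= 1L) {
    warning("validation slice has <2 rating classes; using default thresholds")
    allow_tuning <- FALSE
  }
  set.seed(seed)
  best <- NULL
  for (trial in seq_len(n_trials)) {
    params <- sample_gbt_params()
    fit <- fit_xgb(sp$tab[sp$train, , drop = FALSE], y[sp$train], params,
                   "reg:squarederror", seed + trial, nthread)
    scores <- stats::predict(fit, sp$tab[sp$val, , drop = FALSE])
    th <- if (allow_tuning) tune_thresholds(scores, y_val)
          else default_ordinal_thresholds()
    score <- mamae(y_val, apply_thresholds(scores, th))
    if (is.null(best) || score < best$score)
      best <- list(params = params, thresholds = th, score = score)
  }
  fit_idx <- if (refit_final) c(sp$train, sp$val) else sp$train
  model <- fit_xgb(sp$tab[fit_idx, , drop = FALSE], y[fit_idx], best$params,
                   "reg:squarederror", seed, nthread)
  structure(list(model = model, thresholds = best$thresholds,
                 params = best$params, val_mamae = best$score,
                 item = examples$item, horizon = examples$horizon,
                 task = "ordinal", algorithm = "gbt"),
            class = c("gbt_ordinal", "phenocast_model"))
}

best_bacc_threshold <- function(prob, y) {
  if (length(unique(y)) < 2L) return(0.5)
  cand <- sort(unique(prob))
  cand <- unique(c(0.5, (c(0, cand) + c(cand, 1)) / 2))
  scores <- vapply(cand, function(t) bacc(y, as.integer(prob >= t)), numeric(1))
  cand[which.max(scores)]
}

#' Train a gradient-boosted binary forecaster
#'
#' Labels are binarized with the item's recoding rule before training under
#' binary cross-entropy.
#'
#' @inheritParams train_gbt_ordinal
#' @param fixed_threshold If not `NULL`, use this probability cutoff instead
#'   of maximizing validation balanced accuracy (e.g., 0.5).
#' @return Object of class `gbt_binary` with the booster, `prob_threshold`,
#'   selected `params` and `val_bacc`.
#' @export
train_gbt_binary <- function(examples, n_trials = 10, seed = 1,
                             fixed_threshold = NULL, refit_final = TRUE,
                             nthread = 1) {
  sp <- split_tabular(examples)
  y <- binarize(examples$y, examples$item)
  if (length(unique(y[sp$train])) < 2L)
    stop("single-class training labels: binary task is degenerate")
  y_val <- y[sp$val]
  set.seed(seed)
  best <- NULL
  for (trial in seq_len(n_trials)) {
    params <- sample_gbt_params()
    fit <- fit_xgb(sp$tab[sp$train, , drop = FALSE], y[sp$train], params,
                   "binary:logistic", seed + trial, nthread)
    prob <- stats::predict(fit, sp$tab[sp$val, , drop = FALSE])
    th <- if (is.null(fixed_threshold)) best_bacc_threshold(prob, y_val)
          else fixed_threshold
    score <- if (length(unique(y_val)) < 2L) accuracy(y_val, as.integer(prob >= th))
             else bacc(y_val, as.integer(prob >= th))
    if (is.null(best) || score > best$score)
      best <- list(params = params, threshold = th, score = score)
  }
  fit_idx <- if (refit_final) c(sp$train, sp$val) else sp$train
  model <- fit_xgb(sp$tab[fit_idx, , drop = FALSE], y[fit_idx], best$params,
                   "binary:logistic", seed, nthread)
  structure(list(model = model, prob_threshold = best$threshold,
                 params = best$params, val_bacc = best$score,
                 item = examples$item, horizon = examples$horizon,
                 task = "binary", algorithm = "gbt"),
            class = c("gbt_binary", "phenocast_model"))
}
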