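#' @title Time-based splitting, sequence pairing and standardization
#' @description
#' Participant-wise time-based splitting (latest surveys to test, previous
#' ones to validation), pairing of every survey with 3 days (12 six-hour
#' periods) of sensing input per forecast horizon, Yeo-Johnson
#' standardization fitted on training data only, and the flat tabular
#' reshape used by tree models.
#' @name splitting_features
NULL

#' Split specification
#'
#' @param n_test_surveys Surveys per participant in the test set (default 7).
#' @param n_val_surveys Surveys per participant in the validation set
#'   (default 7).
#' @param min_total_surveys Participants with fewer total surveys are
#'   excluded entirely (default 21, i.e., at least 7 training surveys).
#' @return List of class `split_spec`.
#' @export
split_spec <- function(n_test_surveys = 7, n_val_surveys = 7,
                       min_total_surveys = 21) {
  stopifnot(min_total_surveys >= n_test_surveys + n_val_surveys + 1)
  structure(list(n_test_surveys = n_test_surveys,
                 n_val_surveys = n_val_surveys,
                 min_total_surveys = min_total_surveys),
            class = "split_spec")
}

#' Assign surveys to time-based train/validation/test sets
#'
#' Within each participant, the latest `n_test_surveys` surveys form the test
#' set, the previous `n_val_surveys` the validation set, and all earlier
#' surveys the training set. Participants with fewer than
#' `min_total_surveys` surveys are excluded entirely, so every included
#' participant contributes equally to evaluation.
#'
#' @param surveys Survey data frame (`participant_id`, `date`, item columns).
#' @param spec A [split_spec()].
#' @return List with `surveys` (included rows plus a `split` column) and
#'   `excluded` (character vector of excluded participant ids).
#' @export
time_split <- function(surveys, spec = split_spec()) {
  key <- paste(surveys$participant_id, surveys$date)
  if (anyDuplicated(key))
    stop("duplicate (participant, date) surveys")
  counts <- table(surveys$participant_id)
  excluded <- names(counts)[counts < spec$min_total_surveys]
  kept <- surveys[!surveys$participant_id %in% excluded, , drop = FALSE]
  kept <- kept[order(kept$participant_id, kept$date), , drop = FALSE]
  split <- unlist(lapply(split(seq_len(nrow(kept)), kept$participant_id),
                         function(idx) {
    n <- length(idx)
    lab <- rep("train", n)
    lab[(n - spec$n_test_surveys - spec$n_val_surveys + 1):(n - spec$n_test_surveys)] <- "val"
    lab[(n - spec$n_test_surveys + 1):n] <- "test"
    lab
  }), use.names = FALSE)
  kept$split <- split
  list(surveys = kept, excluded = excluded)
}

#' Pair surveys with 12-period sensing input blocks
#'
#' For a survey on day `d` and horizon `h` (0 = same day, 1 = next day,
#' 7 = next week), the input block covers days `d - h - 2` through `d - h`,
#' expanded into 12 six-hour periods in chronological order (night first
#' within each day). Surveys lacking a complete 12-period window are dropped
#' and counted, not raised.
#'
#' @param sensing Sensing data frame from [generate_cohort()]/[read_cohort()].
#' @param surveys Assigned surveys (output of [time_split()], with `split`).
#' @param horizon Forecast horizon in days: 0, 1 or 7.
#' @param item Mental-state item whose rating is the label.
#' @return A `forecast_examples` object: list with `X` (n x 12 x F array),
#'   `y` (integer ordinal labels), `meta` (participant, survey date, split),
#'   `feature_names`, `item`, `horizon`, `n_dropped`.
#' @export
build_examples <- function(sensing, surveys, horizon, item) {
  stopifnot(horizon %in% c(0, 1, 7), item %in% mental_state_items()$item,
            "split" %in% names(surveys))
  feats <- sensing_feature_names()
  fmat <- as.matrix(sensing[, feats, drop = FALSE])
  skey <- paste(sensing$participant_id, sensing$date, sensing$period)

  n <- nrow(surveys)
  per <- periods()
  X <- array(NA_real_, c(n, 12L, length(feats)),
             dimnames = list(NULL, NULL, feats))
  ok <- logical(n)
  for (i in seq_len(n)) {
    days <- surveys$date[i] - horizon - (2:0)
    keys <- paste(surveys$participant_id[i], rep(days, each = 4L), per)
    idx <- match(keys, skey)
    if (anyNA(idx)) next
    X[i, , ] <- fmat[idx, , drop = FALSE]
    ok[i] <- TRUE
  }
  structure(list(X = X[ok, , , drop = FALSE],
                 y = as.integer(surveys[[item]][ok]),
                 meta = data.frame(participant_id = surveys$participant_id[ok],
                                   date = surveys$date[ok],
                                   split = surveys$split[ok],
                                   stringsAsFactors = FALSE),
                 feature_names = feats, item = item, horizon = horizon,
                 n_dropped = sum(!ok)),
            class = "forecast_examples")
}

yj_transform <- function(x, lambda) car::yjPower(x, lambda)

fit_yj_lambda <- function(x) {
  if (stats::sd(x) < 1e-12) return(1)
  if (length(unique(x)) <= 2L) return(1)  # indicator-like feature
  xs <- if (length(x) > 5000) x[seq(1, length(x), length.out = 5000)] else x
  tryCatch(as.numeric(stats::coef(car::powerTransform(xs, family = "yjPower"))),
           error = function(e) 1)
}

#' Fit and apply Yeo-Johnson standardization
#'
#' Per feature, a Yeo-Johnson power parameter is estimated by maximum
#' likelihood on the period-rows of the fitting scope (training examples by
#' default, pooled across participants), followed by zero-mean/unit-variance
#' scaling with moments from the same scope. The fitted transform is applied
#' to train, validation and test alike; no parameter depends on validation
#' or test data unless `scope = "train_val"` is requested (used when final
#' models are refit on train+validation). Constant or indicator features
#' degenerate to identity plus centering.
#'
#' @param examples A `forecast_examples` object.
#' @param scope `"train"` (default) or `"train_val"`.
#' @return The examples with transformed `X` and a `transform` element
#'   (data frame of per-feature `lambda`, `mean`, `sd`).
#' @export
standardize_examples <- function(examples, scope = c("train", "train_val")) {
  scope <- match.arg(scope)
  fit_rows <- examples$meta$split %in%
    (if (scope == "train") "train" else c("train", "val"))
  X <- examples$X
  d <- dim(X)
  flat <- matrix(aperm(X, c(2, 1, 3)), d[1] * d[2], d[3])  # period rows x F
  fit_idx <- rep(fit_rows, each = d[2])
  params <- data.frame(feature = examples$feature_names,
                       lambda = NA_real_, mean = NA_real_, sd = NA_real_)
  for (j in seq_len(d[3])) {
    lam <- fit_yj_lambda(flat[fit_idx, j])
    tr <- yj_transform(flat[, j], lam)
    mu <- mean(tr[fit_idx])
    sg <- stats::sd(tr[fit_idx])
    if (!is.finite(sg) || sg < 1e-12) sg <- 1
    flat[, j] <- (tr - mu) / sg
    params[j, 2:4] <- c(lam, mu, sg)
  }
  examples$X <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  dimnames(examples$X) <- list(NULL, NULL, examples$feature_names)
  examples$transform <- params
  examples
}

#' Flatten examples to the tabular format used by tree models
#'
#' Row-major flattening of each 12 x F block: the 12 period rows are laid
#' out consecutively, giving deterministic column names
#' `<feature>_p00` ... `<feature>_p11`.
#'
#' @param examples A `forecast_examples` object.
#' @return Numeric matrix, one row per example, `12 * F` named columns.
#' @export
to_tabular <- function(examples) {
  d <- dim(examples$X)
  out <- matrix(aperm(examples$X, c(1, 3, 2)), d[1], d[2] * d[3])
  colnames(out) <- as.vector(outer(examples$feature_names, 0:(d[2] - 1L),
                                   function(f, p) sprintf("%s_p%02d", f, p)))
  out
}
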