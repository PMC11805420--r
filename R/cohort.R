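#' @title Synthetic digital-phenotyping cohorts
#' @description
#' Generator for cohorts with the statistical structure the benchmark
#' assumes: passive-sensing features per participant x day x 6-hour period,
#' tri-weekly skewed ordinal self-reports, and a controllable feature-label
#' signal. An ordered-probit latent model with a participant random intercept
#' and an AR(1) daily state drives both a subset of the sensing features
#' (scaled by `signal_strength`) and, through item-specific cutpoints, the
#' ordinal ratings. At `signal_strength = 0` labels are independent of
#' features by construction.
#' @name synthetic_cohort
NULL

#' Default per-item target class proportions
#'
#' Target marginals over the rating classes `{0,1,2,3}` per item, chosen to
#' emulate the published label skew: the negative items Harm, Seeing things
#' and Voices put 76-81% of mass on "Not at all" and only 3-4% on
#' "Extremely"; positive items have a 33-48% majority class and a 7-11%
#' minority class; Social is flatter so its binary split is 2-vs-2.
#'
#' @return Named list of length-4 probability vectors.
#' @export
default_item_marginals <- function() {
  list(
    "Calm"          = c(0.09, 0.21, 0.30, 0.40),
    "Hopeful"       = c(0.10, 0.18, 0.28, 0.44),
    "Sleep"         = c(0.11, 0.21, 0.33, 0.35),
    "Social"        = c(0.20, 0.28, 0.30, 0.22),
    "Think"         = c(0.08, 0.16, 0.28, 0.48),
    "Depressed"     = c(0.52, 0.24, 0.15, 0.09),
    "Harm"          = c(0.78, 0.13, 0.06, 0.03),
    "Seeing things" = c(0.81, 0.11, 0.05, 0.03),
    "Stressed"      = c(0.47, 0.27, 0.17, 0.09),
    "Voices"        = c(0.76, 0.13, 0.07, 0.04)
  )
}

#' Cohort generation configuration
#'
#' @param n_participants Number of participants (>= 1).
#' @param days_per_participant Days of sensing per participant; scalar or a
#'   vector of length `n_participants`.
#' @param survey_weekdays Weekday indices (0 = Sunday) on which surveys are
#'   prompted; default Monday/Wednesday/Friday.
#' @param shift_prob Probability that a prompted survey is answered on an
#'   adjacent day instead (the real cadence has ~3% off-schedule reports).
#' @param signal_strength Nonnegative scaling of the latent-state loading on
#'   the sensing features; 0 yields labels independent of features.
#' @param item_marginals Named list of per-item target class proportions over
#'   `{0,1,2,3}`; each must be strictly positive and sum to 1.
#' @param ar_coefficient AR(1) coefficient of the daily latent state, in
#'   `[0, 1)`.
#' @param trait_sd,state_sd,item_noise_sd Standard deviations of the
#'   participant random intercept, the (stationary) daily state, and the
#'   item-specific rating noise.
#' @param start_date First calendar day of observation.
#' @param seed Integer master seed; per-participant substreams are derived
#'   deterministically from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 60,
                          days_per_participant = 350,
                          survey_weekdays = c(1, 3, 5),
                          shift_prob = 0.03,
                          signal_strength = 1,
                          item_marginals = default_item_marginals(),
                          ar_coefficient = 0.8,
                          trait_sd = 0.8,
                          state_sd = 0.6,
                          item_noise_sd = 0.8,
                          start_date = as.Date("2015-01-05"),
                          seed = 1) {
  stopifnot(n_participants >= 1, signal_strength >= 0,
            ar_coefficient >= 0, ar_coefficient < 1)
  for (m in item_marginals) {
    if (abs(sum(m) - 1) > 1e-9) stop("item marginals must sum to 1")
  }
  if (length(days_per_participant) == 1L)
    days_per_participant <- rep(days_per_participant, n_participants)
  stopifnot(length(days_per_participant) == n_participants,
            all(days_per_participant >= 1))
  structure(list(n_participants = n_participants,
                 days_per_participant = days_per_participant,
                 survey_weekdays = survey_weekdays,
                 shift_prob = shift_prob,
                 signal_strength = signal_strength,
                 item_marginals = item_marginals,
                 ar_coefficient = ar_coefficient,
                 trait_sd = trait_sd, state_sd = state_sd,
                 item_noise_sd = item_noise_sd,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Latent-normal cutpoints matching target class marginals
#'
#' Inverse-CDF construction: thresholds on a zero-mean Gaussian latent of
#' standard deviation `latent_sd` such that the threshold-crossing
#' probabilities equal the requested class proportions.
#'
#' @param marginals Length-4 vector of strictly positive proportions summing
#'   to 1.
#' @param latent_sd Positive standard deviation of the latent variable.
#' @return Strictly increasing numeric vector of 3 cutpoints.
#' @export
#' @examples
#' cutpoints_from_marginals(rep(0.25, 4))  # ~ (-0.674, 0, 0.674)
cutpoints_from_marginals <- function(marginals, latent_sd = 1) {
  if (length(marginals) != 4L) stop("marginals must have length 4")
  if (any(marginals <= 0))
    stop("zero-probability class: marginals must be strictly positive")
  if (abs(sum(marginals) - 1) > 1e-9) stop("marginals must sum to 1")
  stopifnot(latent_sd > 0)
  stats::qnorm(cumsum(marginals)[1:3], sd = latent_sd)
}

# Sensing feature specification: distribution family, per-period base means
# (night, morning, afternoon, evening), gamma shape, latent loading and a
# weekend multiplier. Durations are gamma (minutes/hours/km), counts Poisson.
sensing_feature_spec <- function() {
  f <- function(name, kind, night, morning, afternoon, evening,
                shape = 1, loading = 0, weekend = 1) {
    data.frame(name = name, kind = kind, night = night, morning = morning,
               afternoon = afternoon, evening = evening, shape = shape,
               loading = loading, weekend = weekend, stringsAsFactors = FALSE)
  }
  rbind(
    f("act_in_vehicle", "gamma",  2, 15, 18, 10, 1.2, -0.10, 1.15),
    f("act_on_bike",    "gamma",  0.5, 3,  4,  2, 0.8,  0.00, 1.1),
    f("act_on_foot",    "gamma",  3, 25, 30, 20, 1.5, -0.15, 1.1),
    f("act_walking",    "gamma",  2, 20, 25, 15, 1.5, -0.15, 1.1),
    f("act_running",    "gamma",  0.2, 2,  3,  1, 0.7, -0.10, 1.0),
    f("act_still",      "gamma", 320, 220, 210, 240, 8, 0.08, 1.05),
    f("act_tilting",    "gamma",  2,  8,  9,  7, 1.0,  0.00, 1.0),
    f("act_unknown",    "gamma",  4, 10, 10,  8, 1.0,  0.00, 1.0),
    f("distance_travelled", "gamma", 0.5, 3, 4, 2.5, 1.2, -0.20, 0.9),
    f("distinct_locations", "pois",  1, 2, 3, 2, 1, -0.20, 1.0),
    f("unlock_count",       "pois",  4, 15, 18, 20, 1, 0.10, 1.0),
    f("unlock_duration",    "gamma", 10, 40, 45, 50, 2, 0.10, 1.0),
    f("call_count",         "pois",  0.2, 1, 2, 2, 1, -0.10, 1.0),
    f("call_duration",      "gamma", 0.5, 4, 5, 6, 0.8, -0.10, 1.0),
    f("missed_calls",       "pois",  0.1, 0.3, 0.4, 0.5, 1, 0.15, 1.0),
    f("sms_count",          "pois",  1, 3, 4, 5, 1, -0.10, 1.0),
    f("conversation_count", "pois",  1, 6, 7, 8, 1, -0.15, 1.2),
    f("conversation_duration", "gamma", 5, 30, 35, 40, 1.5, -0.15, 1.2)
  )
}

#' Names of sensing columns used as model input features
#' @return Character vector (per-period sensing measures plus sleep and
#'   calendar features).
#' @export
sensing_feature_names <- function() {
  c(sensing_feature_spec()$name,
    "sleep_start", "sleep_end", "sleep_duration",
    "day_of_week", "day_of_month", "is_weekend")
}

periods <- function() c("night", "morning", "afternoon", "evening")

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic cohort
#'
#' For each participant: a participant trait `u ~ N(0, trait_sd^2)` and a
#' stationary AR(1) daily state `z_d` drive (i) the log-means of a subset of
#' right-skewed sensing features via `signal_strength * loading * (u + z_d)`
#' and (ii) every item's rating through an ordered-probit latent
#' `s_i (u + z_d) + noise` cut at item-specific thresholds derived from the
#' target marginals (`s_i` = -1 for positive items, +1 for negative ones, so
#' distressed days raise negative ratings and depress positive ones).
#' Realized item marginals therefore match `item_marginals` exactly in
#' expectation, and the generator is byte-reproducible given `seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `sensing` (one row per participant x day x period) and
#'   `surveys` (one row per survey, item ratings in named columns).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  spec <- sensing_feature_spec()
  item_tab <- mental_state_items()
  items <- item_tab$item
  if (!setequal(names(config$item_marginals), items))
    stop("item_marginals must be keyed by the 10 mental-state item names")
  latent_sd <- sqrt(config$trait_sd^2 + config$state_sd^2 + config$item_noise_sd^2)
  cutpts <- lapply(config$item_marginals, cutpoints_from_marginals,
                   latent_sd = latent_sd)
  sgn <- ifelse(item_tab$valence == "negative", 1, -1)
  names(sgn) <- items

  pseeds <- derive_seeds(config$seed, config$n_participants)
  sens_list <- vector("list", config$n_participants)
  surv_list <- vector("list", config$n_participants)

  for (p in seq_len(config$n_participants)) {
    set.seed(pseeds[p])
    nd <- config$days_per_participant[p]
    pid <- sprintf("P%03d", p)
    dates <- config$start_date + 0:(nd - 1L)
    wday <- as.POSIXlt(dates)$wday

    u <- stats::rnorm(1, 0, config$trait_sd)
    phi <- config$ar_coefficient
    innov_sd <- config$state_sd * sqrt(1 - phi^2)
    z <- numeric(nd)
    z[1] <- stats::rnorm(1, 0, config$state_sd)
    if (nd > 1) for (d in 2:nd) z[d] <- phi * z[d - 1] + stats::rnorm(1, 0, innov_sd)
    eta <- config$signal_strength * (u + z)   # daily latent driver of features

    # sensing: rows ordered day-major, period night->morning->afternoon->evening
    n_rows <- nd * 4L
    day_idx <- rep(seq_len(nd), each = 4L)
    per_idx <- rep(1:4, nd)
    is_we <- wday[day_idx] %in% c(0, 6)
    feat <- matrix(0, n_rows, nrow(spec), dimnames = list(NULL, spec$name))
    base <- as.matrix(spec[, c("night", "morning", "afternoon", "evening")])
    for (j in seq_len(nrow(spec))) {
      mu <- base[j, per_idx] * ifelse(is_we, spec$weekend[j], 1) *
        exp(spec$loading[j] * eta[day_idx])
      feat[, j] <- if (spec$kind[j] == "gamma") {
        stats::rgamma(n_rows, shape = spec$shape[j], rate = spec$shape[j] / mu)
      } else {
        stats::rpois(n_rows, mu)
      }
    }
    # daily sleep, replicated over the day's 4 periods
    sl_dur <- pmin(pmax(stats::rnorm(nd, 7 - 0.3 * eta, 1.1), 0), 14)
    sl_start <- (stats::rnorm(nd, 23, 1)) %% 24
    sl_end <- (sl_start + sl_dur) %% 24
    sens_list[[p]] <- data.frame(
      participant_id = pid, date = dates[day_idx],
      period = periods()[per_idx], feat,
      sleep_start = sl_start[day_idx], sleep_end = sl_end[day_idx],
      sleep_duration = sl_dur[day_idx],
      day_of_week = wday[day_idx],
      day_of_month = as.POSIXlt(dates[day_idx])$mday,
      is_weekend = as.integer(is_we),
      stringsAsFactors = FALSE, check.names = FALSE)

    # surveys: Mon/Wed/Fri cadence with a small chance of +-1 day shift
    sdays <- which(wday %in% config$survey_weekdays)
    if (length(sdays)) {
      shift <- ifelse(stats::runif(length(sdays)) < config$shift_prob,
                      sample(c(-1L, 1L), length(sdays), replace = TRUE), 0L)
      sdays <- pmin(pmax(sdays + shift, 1L), nd)
      sdays <- sort(unique(sdays))
      ratings <- matrix(0L, length(sdays), length(items),
                        dimnames = list(NULL, items))
      for (it in items) {
        lat <- sgn[it] * (u + z[sdays]) +
          stats::rnorm(length(sdays), 0, config$item_noise_sd)
        ratings[, it] <- findInterval(lat, cutpts[[it]])
      }
      surv_list[[p]] <- data.frame(participant_id = pid, date = dates[sdays],
                                   ratings, stringsAsFactors = FALSE,
                                   check.names = FALSE)
    }
  }
  list(sensing = do.call(rbind, sens_list),
       surveys = do.call(rbind, surv_list))
}

#' Write a cohort to CSV files
#'
#' Writes `sensing.csv` and `surveys.csv` with ISO-8601 dates into `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$sensing, file.path(dir, "sensing.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$surveys, file.path(dir, "surveys.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from CSV files written by [write_cohort()]
#' @param dir Directory containing `sensing.csv` and `surveys.csv`.
#' @return List with `sensing` and `surveys` data frames.
#' @export
read_cohort <- function(dir) {
  sensing <- utils::read.csv(file.path(dir, "sensing.csv"),
                             check.names = FALSE, stringsAsFactors = FALSE)
  surveys <- utils::read.csv(file.path(dir, "surveys.csv"),
                             check.names = FALSE, stringsAsFactors = FALSE)
  sensing$date <- as.Date(sensing$date)
  surveys$date <- as.Date(surveys$date)
  list(sensing = sensing, surveys = surveys)
}
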