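make_surveys <- function(n_by_pid, start = as.Date("2015-03-02")) {
  do.call(rbind, lapply(names(n_by_pid), function(pid) {
    data.frame(participant_id = pid,
               date = start + seq_len(n_by_pid[[pid]]) * 2,
               Depressed = 0L, stringsAsFactors = FALSE)
  }))
}

test_that("time_split assigns latest surveys to test and excludes short series", {
  sv <- make_surveys(list(A = 21, B = 20, C = 100))
  ts <- time_split(sv)
  expect_equal(ts$excluded, "B")
  a <- ts$surveys[ts$surveys$participant_id == "A", ]
  expect_equal(as.vector(table(a$split)[c("train", "val", "test")]),
               c(7L, 7L, 7L))
  c_ <- ts$surveys[ts$surveys$participant_id == "C", ]
  expect_equal(sum(c_$split == "train"), 86L)
  # chronology within each participant
  for (pid in c("A", "C")) {
    s <- ts$surveys[ts$surveys$participant_id == pid, ]
    expect_lt(max(s$date[s$split == "train"]), min(s$date[s$split == "val"]))
    expect_lt(max(s$date[s$split == "val"]), min(s$date[s$split == "test"]))
  }
  dup <- rbind(sv, sv[1, ])
  expect_error(time_split(dup), "duplicate")
})

test_that("input windows follow the horizon geometry", {
  co <- tiny_cohort(n = 3, days = 60)
  ts <- time_split(co$surveys, split_spec(2, 2, 6))
  sensing <- co$sensing
  for (h in c(0, 1, 7)) {
    ex <- build_examples(sensing, ts$surveys, h, "Calm")
    expect_equal(dim(ex$X)[2:3], c(12L, length(sensing_feature_names())))
    # reconstruct one example's window by hand: last input day = date - h
    i <- dim(ex$X)[1]
    pid <- ex$meta$participant_id[i]; d <- ex$meta$date[i]
    want <- sensing[sensing$participant_id == pid &
                    sensing$date %in% (d - h - 2:0), ]
    ord <- order(want$date, match(want$period,
                                  c("night", "morning", "afternoon", "evening")))
    want <- want[ord, ]
    expect_equal(unname(ex$X[i, , "act_still"]), want$act_still)
    expect_equal(max(want$date), d - h)
  }
})

test_that("incomplete windows are dropped and counted, not raised", {
  co <- tiny_cohort(n = 3, days = 40)
  ts <- time_split(co$surveys, split_spec(2, 2, 6))
  full <- build_examples(co$sensing, ts$surveys, 0, "Calm")
  # remove one mid-range day entirely for one participant
  pid <- co$sensing$participant_id[1]
  kill <- sort(unique(co$sensing$date))[20]
  sens2 <- co$sensing[!(co$sensing$participant_id == pid &
                        co$sensing$date == kill), ]
  broken <- build_examples(sens2, ts$surveys, 0, "Calm")
  expect_gt(broken$n_dropped, full$n_dropped)
  # conservation: examples + dropped = surveys of included participants
  expect_equal(dim(broken$X)[1] + broken$n_dropped, nrow(ts$surveys))
  expect_equal(dim(full$X)[1] + full$n_dropped, nrow(ts$surveys))
})

test_that("adjacent same-day windows of surveys 2 days apart share one day", {
  co <- tiny_cohort(n = 2, days = 40)
  ts <- time_split(co$surveys, split_spec(2, 2, 6))
  ex <- build_examples(co$sensing, ts$surveys, 0, "Calm")
  m <- ex$meta[ex$meta$participant_id == ex$meta$participant_id[1], ]
  gaps <- diff(m$date)
  i <- which(gaps == 2)[1]
  expect_false(is.na(i))
  w1 <- m$date[i] - 2:0
  w2 <- m$date[i + 1] - 2:0
  expect_length(intersect(w1, w2), 1L)
})

test_that("Yeo-Johnson standardization is fit on the training scope only", {
  ex <- tiny_examples("Calm", 0)
  tr <- ex$meta$split == "train"
  d <- dim(ex$X)
  flat <- matrix(aperm(ex$X, c(2, 1, 3)), d[1] * d[2], d[3])
  fit_idx <- rep(tr, each = 12)
  mu_tr <- colMeans(flat[fit_idx, ])
  sd_tr <- apply(flat[fit_idx, ], 2, sd)
  expect_true(all(abs(mu_tr) < 1e-8))
  nondeg <- sd_tr > 1e-6  # constant features degenerate to centering
  expect_true(all(abs(sd_tr[nondeg] - 1) < 1e-6))
  # test-set moments come from training parameters, so they differ from 0/1
  mu_te <- colMeans(flat[!fit_idx, , drop = FALSE])
  expect_gt(max(abs(mu_te)), 1e-4)
  # a feature that is already standard normal keeps lambda near 1
  raw <- build_examples(
    tiny_cohort(n = 6, days = 80)$sensing,
    time_split(tiny_cohort(n = 6, days = 80)$surveys)$surveys, 0, "Calm")
  set.seed(1)
  raw$X[, , "act_still"] <- rnorm(length(raw$X[, , "act_still"]))
  st <- standardize_examples(raw)
  lam <- st$transform$lambda[st$transform$feature == "act_still"]
  expect_lt(abs(lam - 1), 0.25)
})

test_that("tabular reshape is a deterministic row-major flattening", {
  ex <- tiny_examples("Calm", 0)
  tab <- to_tabular(ex)
  d <- dim(ex$X)
  expect_equal(ncol(tab), 12 * d[3])
  expect_equal(colnames(tab)[1:2],
               c("act_in_vehicle_p00", "act_on_bike_p00"))
  # inverse mapping: column <feature>_pKK holds X[, KK+1, feature]
  expect_equal(unname(tab[, "act_still_p05"]), unname(ex$X[, 6, "act_still"]))
  expect_equal(unname(tab[, "sleep_duration_p11"]),
               unname(ex$X[, 12, "sleep_duration"]))
  expect_identical(colnames(to_tabular(ex)), colnames(tab))
  expect_identical(to_tabular(ex), tab)
})
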