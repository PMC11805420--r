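# Naive per-example loop oracles for the evaluation metrics, kept
# independent of the package's vectorized implementations.

oracle_mae <- function(t, p) {
  s <- 0
  for (i in seq_along(t)) s <- s + abs(p[i] - t[i])
  s / length(t)
}

oracle_acc <- function(t, p) {
  s <- 0
  for (i in seq_along(t)) if (t[i] == p[i]) s <- s + 1
  s / length(t)
}

oracle_mamae <- function(t, p) {
  tot <- 0; k <- 0
  for (c0 in sort(unique(t))) {
    s <- 0; n <- 0
    for (i in seq_along(t)) if (t[i] == c0) { s <- s + abs(p[i] - c0); n <- n + 1 }
    tot <- tot + s / n; k <- k + 1
  }
  tot / k
}

oracle_bacc <- function(t, p) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(t)) {
    if (t[i] == 1 && p[i] == 1) tp <- tp + 1
    if (t[i] == 1 && p[i] == 0) fn <- fn + 1
    if (t[i] == 0 && p[i] == 0) tn <- tn + 1
    if (t[i] == 0 && p[i] == 1) fp <- fp + 1
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

oracle_nbe_ordinal <- function(t, p) {
  tot <- 0; k <- 0
  for (c0 in sort(unique(t))) {
    s <- 0; n <- 0
    for (i in seq_along(t)) if (t[i] == c0) { s <- s + abs(p[i] - c0); n <- n + 1 }
    tot <- tot + (s / n) / max(c0, 3 - c0); k <- k + 1
  }
  tot / k
}
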