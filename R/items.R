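#' Mental-state item table
#'
#' The ten self-reported mental states rated on the 4-point ordinal scale
#' ("Not at all" = 0, "A little" = 1, "Moderately" = 2, "Extremely" = 3),
#' their valence, and the ordinal-to-binary recoding cutoffs. The binary
#' recoding contrasts the cutoff chosen to yield the two best-balanced
#' classes: for the positive items Calm, Hopeful, Sleep and Think the
#' "Higher" class is rating 3 alone; the flatter Social item splits 0,1
#' against 2,3; for all negative items "Lower" is rating 0 alone.
#'
#' @return A data frame with one row per item and columns `item`, `valence`
#'   ("positive"/"negative"), `lower` and `higher` (list columns of integer
#'   rating classes), and `cutoff` (the smallest rating mapped to the binary
#'   "Higher" class).
#' @export
#' @examples
#' mental_state_items()
mental_state_items <- function() {
  items <- c("Calm", "Hopeful", "Sleep", "Social", "Think",
             "Depressed", "Harm", "Seeing things", "Stressed", "Voices")
  valence <- c(rep("positive", 5), rep("negative", 5))
  # smallest rating recoded as binary "Higher"
  cutoff <- c(3L, 3L, 3L, 2L, 3L, 1L, 1L, 1L, 1L, 1L)
  out <- data.frame(item = items, valence = valence, cutoff = cutoff,
                    stringsAsFactors = FALSE)
  out$lower <- lapply(cutoff, function(k) 0:(k - 1L))
  out$higher <- lapply(cutoff, function(k) k:3L)
  out
}

item_cutoff <- function(item) {
  tab <- mental_state_items()
  i <- match(item, tab$item)
  if (is.na(i)) stop("unknown mental-state item: ", item)
  tab$cutoff[i]
}

#' Recode ordinal ratings to binary classes
#'
#' Maps 4-point ordinal ratings onto the binary "Lower"/"Higher" classes of
#' the item's recoding rule. The positive class (1) is always "Higher",
#' irrespective of valence, which fixes the orientation of sensitivity and
#' specificity in balanced accuracy.
#'
#' @param ratings Integer vector of ordinal ratings in `{0,1,2,3}`.
#' @param item Item name (one of `mental_state_items()$item`).
#' @return Integer vector in `{0,1}` of the same length.
#' @export
#' @examples
#' binarize(c(3, 2, 0, 3), "Calm")   # 1 0 0 1
#' binarize(c(2, 1), "Social")       # 1 0
binarize <- function(ratings, item) {
  if (length(ratings) == 0L) return(integer(0))
  if (anyNA(ratings) || !all(ratings %in% 0:3))
    stop("ratings must all be in {0,1,2,3}")
  as.integer(ratings >= item_cutoff(item))
}

#' Class-imbalance statistic
#'
#' The difference between the counts of the majority and the minority class,
#' normalized by the total number of examples. Only classes actually present
#' in the labels enter the majority/minority determination, so a test slice
#' missing a rare class does not register imbalance 1. The same definition
#' applies to ordinal and binary label vectors; the value lies in `[0, 1)`.
#'
#' @param labels Non-empty vector of class labels.
#' @return Numeric scalar in `[0, 1)`.
#' @export
#' @examples
#' class_imbalance(rep(c(0, 1), c(76, 24)))          # 0.52
#' class_imbalance(rep(0:3, c(78, 13, 6, 3)))        # 0.75
class_imbalance <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  n <- table(labels)
  (max(n) - min(n)) / sum(n)
}
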