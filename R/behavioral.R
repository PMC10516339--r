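#' Score the cooperative communication game
#'
#' Communicative success in the guessing game is the mean absolute distance
#' between the participant's guess and the hidden 0-100 bullseye, over the
#' trials where the participant was the guesser; clue-giver trials are
#' ignored. For display and modelling conventions where higher = better, the
#' success score is the negated distance (any strictly order-reversing
#' transform would do; negation is range-agnostic).
#'
#' @param trials data frame with columns `role` ("guesser"/"clue_giver"),
#'   `bullseye` and `guess`, both integers in 0-100.
#' @return list with `communicative_distance` and `communicative_success`
#'   (`NA` with a warning when no guesser trials exist).
#' @export
score_game <- function(trials) {
  stopifnot(all(c("role", "bullseye", "guess") %in% names(trials)))
  g <- trials[trials$role == "guesser", , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no guesser trials; communicative success is missing")
    return(list(communicative_distance = NA_real_,
                communicative_success = NA_real_))
  }
  if (any(g$bullseye < 0 | g$bullseye > 100 | g$guess < 0 | g$guess > 100))
    stop("bullseye and guess must lie in [0, 100]")
  d <- mean(abs(g$guess - g$bullseye))
  list(communicative_distance = d, communicative_success = -d)
}

#' Perceived interaction quality composite
#'
#' Sum of the three post-interaction Likert items (overall quality,
#' enjoyment, desire to continue the friendship), each on a 1-5 scale,
#' giving a 3-15 composite.
#'
#' @param items numeric vector of exactly three responses in 1..5.
#' @return integer in `[3, 15]`.
#' @export
composite_quality <- function(items) {
  if (length(items) != 3L)
    stop("composite quality needs exactly three items; got ", length(items))
  bad <- which(items < 1 | items > 5 | items != round(items))
  if (length(bad))
    stop("item ", bad[1], " (value ", items[bad[1]],
         ") is outside the 1-5 Likert range")
  as.integer(sum(items))
}

#' Item-level similarity between partners' questionnaire responses
#'
#' Pearson correlation across matched items of the two partners' responses
#' (e.g. personality mini-markers or avocation interests), yielding one
#' similarity scalar per dyad.
#'
#' @param responses_a,responses_b numeric item vectors, same length and item
#'   order, at least 3 items.
#' @return correlation in `[-1, 1]`; `NA` with a warning when either vector
#'   is constant.
#' @export
item_similarity <- function(responses_a, responses_b) {
  if (length(responses_a) != length(responses_b))
    stop("item count mismatch: ", length(responses_a), " vs ",
         length(responses_b))
  if (length(responses_a) < 3L)
    stop("at least 3 items are required")
  if (stats::sd(responses_a) == 0 || stats::sd(responses_b) == 0) {
    warning("constant response vector; item similarity undefined")
    return(NA_real_)
  }
  stats::cor(as.numeric(responses_a), as.numeric(responses_b))
}

#' Sum-score a trait questionnaire with reverse-keyed items
#'
#' Reverse-keyed items are mapped `x -> scale_max + scale_min - x` before
#' summing; subscale scores are obtained by passing the subscale's index set
#' as `subset`.
#'
#' @param items numeric item responses.
#' @param reverse_keys integer indices of reverse-keyed items (default none).
#' @param scale_max,scale_min scale bounds (defaults 5 and 1).
#' @param subset optional index set to sum over (default: all items).
#' @return numeric total.
#' @export
trait_score <- function(items, reverse_keys = integer(0), scale_max = 5,
                        scale_min = 1, subset = NULL) {
  if (length(reverse_keys) &&
      (any(reverse_keys < 1) || any(reverse_keys > length(items))))
    stop("reverse_keys contains invalid indices")
  if (any(items < scale_min | items > scale_max))
    stop("item(s) outside the [", scale_min, ", ", scale_max, "] scale: ",
         paste(which(items < scale_min | items > scale_max), collapse = ", "))
  x <- as.numeric(items)
  x[reverse_keys] <- scale_max + scale_min - x[reverse_keys]
  if (is.null(subset)) subset <- seq_along(x)
  sum(x[subset])
}

#' Pairwise-complete correlations among outcome-table measures
#'
#' Correlation matrix over the requested columns with pairwise-complete
#' observations; cells with fewer than `min_pairs` complete pairs are set to
#' `NA`. The per-cell pair counts are attached as the `n` attribute.
#'
#' @param table data frame (e.g. an outcome table).
#' @param columns character vector of numeric columns to correlate.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return symmetric correlation matrix with unit diagonal and attribute `n`.
#' @export
measure_correlations <- function(table, columns, min_pairs = 3L) {
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(table[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(x))
  r[n < min_pairs] <- NA_real_
  diag(r) <- 1
  attr(r, "n") <- n
  r
}
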