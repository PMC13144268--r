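## Ordinal score tables (reader, case, hemisphere, method, session -> score)
## and the simulated-reader confusion model.

#' Construct and validate a score table
#'
#' A tidy table of four-point visual pattern scores, one row per
#' (reader, case, hemisphere, method, session).
#'
#' @param reader_id,case_id,hemisphere,method_id,session,score vectors of
#'   equal length; `hemisphere` in {"L","R"}, `session` in {1,2}, `score`
#'   integer in 1..4.
#' @return a `data.frame` of class `score_table`.
#' @export
score_table <- function(reader_id, case_id, hemisphere, method_id,
                        session = 1L, score) {
  df <- data.frame(reader_id = as.character(reader_id),
                   case_id = as.character(case_id),
                   hemisphere = as.character(hemisphere),
                   method_id = as.character(method_id),
                   session = as.integer(session),
                   score = as.integer(score),
                   stringsAsFactors = FALSE)
  validate_score_table(df)
}

#' @rdname score_table
#' @param df a data frame with the six score-table columns.
#' @export
validate_score_table <- function(df) {
  need <- c("reader_id", "case_id", "hemisphere", "method_id", "session",
            "score")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df)) {
    if (!all(df$hemisphere %in% c("L", "R")))
      stop("hemisphere must be 'L' or 'R'")
    if (!all(df$session %in% c(1L, 2L)))
      stop("session must be 1 or 2")
    if (anyNA(df$score) || !all(df$score %in% 1:4))
      stop("scores must be integers in 1..4")
    key <- do.call(paste, c(df[c("reader_id", "case_id", "hemisphere",
                                 "method_id", "session")], sep = "\r"))
    if (anyDuplicated(key))
      stop("at most one record per (reader, case, hemisphere, method, session)")
  }
  class(df) <- c("score_table", "data.frame")
  df
}

#' Gold-standard score table of a phantom cohort
#'
#' The phantom ground-truth pattern labels stand in for the consensus reading
#' of the long-acquisition images.
#'
#' @param cohort a `dat_cohort`.
#' @param method_id method label to record (default `"truth"`).
#' @return a `score_table` with reader `"gold"`.
#' @export
cohort_truth <- function(cohort, method_id = "truth") {
  stopifnot(inherits(cohort, "dat_cohort"))
  with(cohort$truth,
       score_table(reader_id = "gold", case_id = case_id,
                   hemisphere = hemisphere, method_id = method_id,
                   session = 1L, score = score))
}

#' Adjacent-category confusion matrix
#'
#' Row-stochastic 4 x 4 matrix: a rater reports the true category with
#' probability `accuracy` and spills the remainder onto the adjacent
#' categories (split evenly; edge categories give it all to their single
#' neighbour). `accuracy = 1` is the identity (noiseless reader).
#'
#' @param accuracy probability of reporting the true score.
#' @return a 4 x 4 row-stochastic matrix.
#' @export
adjacent_confusion <- function(accuracy) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  k <- 4L
  M <- matrix(0, k, k)
  for (i in seq_len(k)) {
    nb <- intersect(c(i - 1L, i + 1L), seq_len(k))
    M[i, i] <- accuracy
    M[i, nb] <- (1 - accuracy) / length(nb)
  }
  M
}

#' Simulate a reader from a confusion model
#'
#' Each truth score s is replaced by an independent draw from row s of the
#' confusion matrix; deterministic given the seed.
#'
#' @param truth a `score_table` of true scores.
#' @param confusion 4 x 4 row-stochastic matrix.
#' @param seed integer seed.
#' @param reader_id,method_id,session labels for the output rows (defaults
#'   keep the truth table's `method_id`).
#' @return a `score_table` of simulated scores.
#' @export
simulate_reader <- function(truth, confusion, seed, reader_id = "sim_reader",
                            method_id = NULL, session = 1L) {
  truth <- validate_score_table(truth)
  if (!is.matrix(confusion) || any(dim(confusion) != 4L))
    stop("confusion must be a 4 x 4 matrix")
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion matrix rows must be non-negative and sum to 1")
  new_scores <- with_seed(seed, vapply(truth$score, function(s) {
    sample.int(4L, 1L, prob = confusion[s, ])
  }, integer(1)))
  score_table(reader_id = reader_id, case_id = truth$case_id,
              hemisphere = truth$hemisphere,
              method_id = method_id %||% truth$method_id,
              session = session, score = new_scores)
}
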