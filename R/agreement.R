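## Reader-study statistics: quadratic weighted Cohen's kappa against a gold
## standard, and intraclass correlation (two-way random effects, absolute
## agreement, single measure; ICC(2,1)) for intra- and inter-rater
## reliability.

#' Quadratic weighted Cohen's kappa for ordinal scores
#'
#' Weights `w_ij = 1 - (i-j)^2/(k-1)^2` on the fixed category set 1..k (all
#' categories retained even if unobserved); chance agreement from the
#' marginal products. If both raters are constant and equal (weighted chance
#' agreement 1), kappa is defined as 1 and flagged via the `"degenerate"`
#' attribute.
#'
#' @param scores_a,scores_b equal-length integer vectors with values in 1..k.
#' @param k number of ordinal categories (default 4).
#' @return kappa in \[-1, 1\].
#' @export
weighted_kappa <- function(scores_a, scores_b, k = 4L) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length")
  n <- length(scores_a)
  if (n < 1L) stop("empty input")
  if (!all(scores_a %in% seq_len(k)) || !all(scores_b %in% seq_len(k)))
    stop("scores must be integers in 1..", k)
  O <- base::table(factor(scores_a, levels = seq_len(k)),
                   factor(scores_b, levels = seq_len(k))) / n
  W <- 1 - outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2) / (k - 1)^2
  E <- outer(rowSums(O), colSums(O))
  po <- sum(W * O)
  pe <- sum(W * E)
  if (abs(1 - pe) < 1e-12)
    return(structure(1, degenerate = TRUE))
  (po - pe) / (1 - pe)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the two-way
#' mean-squares decomposition (rows = items, columns = raters or sessions).
#'
#' @param ratings numeric matrix, items x raters, no missing cells.
#' @return ICC value.
#' @export
icc_single <- function(ratings) {
  if (!is.matrix(ratings)) stop("ratings must be a matrix (items x raters)")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 items and 2 raters")
  gm <- mean(ratings)
  if (sum((ratings - gm)^2) == 0)
    stop("zero total variance: ICC undefined for constant ratings")
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  MSR <- k * sum((row_m - gm)^2) / (n - 1)
  MSC <- n * sum((col_m - gm)^2) / (k - 1)
  SSE <- sum((ratings - gm)^2) - k * sum((row_m - gm)^2) -
    n * sum((col_m - gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# items x columns score matrix from a long score table
.score_matrix <- function(df, row_key_cols, col_key_col) {
  df$item <- do.call(paste, c(df[row_key_cols], sep = "\r"))
  cols <- sort(unique(df[[col_key_col]]))
  items <- sort(unique(df$item))
  m <- matrix(NA_real_, length(items), length(cols),
              dimnames = list(items, as.character(cols)))
  m[cbind(match(df$item, items), match(df[[col_key_col]], cols))] <- df$score
  m
}

#' Intra-rater reliability per reader
#'
#' ICC(2,1) between session 1 and session 2 scores of one method, over
#' (case x hemisphere) items, separately for each reader.
#'
#' @param scores a `score_table` containing both sessions for `method`.
#' @param method method id whose reading was duplicated.
#' @return data frame (reader_id, icc, n_items).
#' @export
intra_rater_report <- function(scores, method) {
  scores <- validate_score_table(scores)
  sub <- scores[scores$method_id == method, ]
  if (!all(c(1L, 2L) %in% sub$session))
    stop("both sessions must be present for method '", method, "'")
  out <- lapply(sort(unique(sub$reader_id)), function(r) {
    m <- .score_matrix(sub[sub$reader_id == r, ],
                       c("case_id", "hemisphere"), "session")
    if (ncol(m) != 2L || anyNA(m))
      stop("reader ", r, ": incomplete session pairs for method '", method, "'")
    data.frame(reader_id = r, icc = icc_single(m), n_items = nrow(m))
  })
  do.call(rbind, out)
}

#' Inter-rater reliability across readers
#'
#' ICC(2,1) for every reader pair over pooled items
#' (case x hemisphere x method, session 1), plus their average.
#'
#' @param scores a `score_table` with >= 2 readers scoring a common item set.
#' @return list with `pairs` (reader_a, reader_b, icc, n_items) and
#'   `average`.
#' @export
inter_rater_report <- function(scores) {
  scores <- validate_score_table(scores)
  sub <- scores[scores$session == 1L, ]
  m <- .score_matrix(sub, c("case_id", "hemisphere", "method_id"),
                     "reader_id")
  if (ncol(m) < 2L) stop("need at least 2 readers")
  keep <- stats::complete.cases(m)
  if (!any(keep)) stop("readers scored disjoint item sets")
  m <- m[keep, , drop = FALSE]
  readers <- colnames(m)
  combs <- utils::combn(readers, 2L)
  pairs <- apply(combs, 2L, function(pr) {
    data.frame(reader_a = pr[1], reader_b = pr[2],
               icc = icc_single(m[, pr, drop = FALSE]), n_items = nrow(m))
  })
  pairs <- do.call(rbind, pairs)
  list(pairs = pairs, average = mean(pairs$icc))
}

#' Weighted-kappa table versus the gold standard
#'
#' Quadratic weighted kappa per (reader, method) against the gold-standard
#' scores (matched on case x hemisphere), plus the per-method average across
#' readers.
#'
#' @param scores a `score_table` of reader scores (session 1 used).
#' @param gold a `score_table` of gold-standard scores covering all items.
#' @return list with `per_reader` (reader_id, method_id, kappa, n_items) and
#'   `per_method` (method_id, mean_kappa).
#' @export
kappa_report <- function(scores, gold) {
  scores <- validate_score_table(scores)
  gold <- validate_score_table(gold)
  sub <- scores[scores$session == 1L, ]
  gkey <- paste(gold$case_id, gold$hemisphere, sep = "\r")
  out <- list()
  for (r in sort(unique(sub$reader_id))) {
    for (m in sort(unique(sub$method_id))) {
      s <- sub[sub$reader_id == r & sub$method_id == m, ]
      if (!nrow(s)) next
      idx <- match(paste(s$case_id, s$hemisphere, sep = "\r"), gkey)
      if (anyNA(idx))
        stop("items missing from gold standard for reader ", r,
             ", method ", m)
      out[[length(out) + 1L]] <- data.frame(
        reader_id = r, method_id = m,
        kappa = as.numeric(weighted_kappa(s$score, gold$score[idx])),
        n_items = nrow(s))
    }
  }
  per_reader <- do.call(rbind, out)
  per_method <- stats::aggregate(kappa ~ method_id, per_reader, mean)
  names(per_method)[2] <- "mean_kappa"
  list(per_reader = per_reader, per_method = per_method)
}
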