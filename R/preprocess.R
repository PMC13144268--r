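## Preprocessing: max-count slice selection, central cropping, per-case
## normalisation, training-sample construction, and case-level splitting.
## Indexing is 1-based and inclusive throughout (native R convention).

#' Select analysis and reader slices from a long-acquisition stack
#'
#' The slice with the highest per-slice maximum of the case-normalised long
#' stack is taken as the centre (best striatal visualisation); the analysis
#' window is the centre plus the two slices on either side (5 slices), the
#' reader set is the centre plus one on either side (3 slices). Ties break to
#' the lowest index; windows are shifted to stay in bounds, preserving length.
#'
#' @param long_stack array (slices x rows x cols) with at least 5 slices.
#' @param case_id optional case identifier carried along for consistency
#'   checks downstream.
#' @return list with `case_id`, `center_index`, `window_indices` (length 5),
#'   `reader_indices` (length 3).
#' @export
select_slices <- function(long_stack, case_id = NULL) {
  d <- dim(long_stack)
  if (is.null(d) || length(d) != 3L)
    stop("long_stack must be a 3-D array (slices x rows x cols)")
  S <- d[1]
  if (S < 5L) stop("stack must have at least 5 slices, got ", S)
  slice_max <- apply(long_stack, 1, max)
  center <- which.max(slice_max)          # lowest index on ties
  clamp_window <- function(center, len, S) {
    half <- (len - 1L) %/% 2L
    lo <- center - half
    lo <- max(1L, min(lo, S - len + 1L))  # shift to stay in bounds
    seq.int(lo, lo + len - 1L)
  }
  list(case_id = case_id,
       center_index = as.integer(center),
       window_indices = clamp_window(center, 5L, S),
       reader_indices = clamp_window(center, 3L, S))
}

#' Crop the central 64 x 64 region of a 128 x 128 image
#'
#' Returns rows and columns 33..96 (the central half in each dimension).
#'
#' @param image a 128 x 128 matrix.
#' @return a 64 x 64 matrix.
#' @export
crop_center <- function(image) {
  if (!is.matrix(image) || any(dim(image) != c(128L, 128L)))
    stop("image must be exactly 128 x 128, got ",
         paste(dim(image), collapse = " x "))
  image[33:96, 33:96, drop = FALSE]
}

#' Normalise a stack to unit range by its global maximum
#'
#' Division is by the case-wide maximum (not per slice) so relative
#' inter-slice intensity is preserved; the output maximum is exactly 1.
#'
#' @param stack a numeric array with positive maximum.
#' @return the normalised stack.
#' @export
normalize_case <- function(stack) {
  m <- max(stack)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalise: stack maximum must be positive (all-zero stack?)")
  stack / m
}

#' Build the 5 training/evaluation samples of a case
#'
#' One sample per analysis-window slice: the input is the 5 short-time slices
#' centred on the target index (replicate-padded at the window boundary), the
#' target is the matching long-time slice; both are centre-cropped to 64 x 64
#' after case-level normalisation (short and long stacks each by their own
#' global maximum).
#'
#' @param pair an `acquisition_pair`.
#' @param selection a [select_slices()] result for the same case.
#' @param partition partition label stored with the samples.
#' @return list of 5 samples, each with `case_id`, `target_index`,
#'   `input_window` (64 x 64 x 5), `target` (64 x 64), `partition`.
#' @export
build_samples <- function(pair, selection, partition = "train") {
  stopifnot(inherits(pair, "acquisition_pair"))
  if (!is.null(selection$case_id) && selection$case_id != pair$case_id)
    stop("selection is for case '", selection$case_id,
         "' but pair is for case '", pair$case_id, "'")
  win <- selection$window_indices
  if (length(win) != 5L) stop("selection window must have 5 slices")
  short_n <- normalize_case(pair$short_stack)
  long_n <- normalize_case(pair$long_stack)
  lapply(seq_along(win), function(i) {
    tgt <- win[i]
    # 5-slice input window around the target, clamped to the analysis window
    in_idx <- pmin(pmax(tgt + (-2:2), min(win)), max(win))
    x <- array(0, dim = c(64L, 64L, 5L))
    for (k in 1:5) x[, , k] <- crop_center(short_n[in_idx[k], , ])
    list(case_id = pair$case_id, target_index = as.integer(tgt),
         input_window = x, target = crop_center(long_n[tgt, , ]),
         partition = partition)
  })
}

#' Split cases into train / validation / test partitions
#'
#' The split is by case, never by slice, so all 5 samples of a case share a
#' partition. Counts follow floor(fraction * n) for train and validation with
#' the remainder going to test (the emulated protocol's 120/37/50 split of
#' 207 cases arises from fractions 120/207, 37/207, 50/207).
#'
#' @param case_ids character vector of case identifiers.
#' @param fractions length-3 numeric (train, validation, test) summing to 1.
#' @param seed integer seed for the case permutation.
#' @return named character vector: partition (`"train"`, `"validation"`,
#'   `"test"`) per case id.
#' @export
split_dataset <- function(case_ids, fractions = c(120, 37, 50) / 207,
                          seed = 1L) {
  n <- length(case_ids)
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (n < 1L) stop("need at least one case")
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  perm <- with_seed(seed, sample.int(n))
  part <- rep("test", n)
  if (n_train > 0) part[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) part[perm[n_train + seq_len(n_val)]] <- "validation"
  stats::setNames(part, case_ids)
}

#' Preprocess a whole cohort into slice samples
#'
#' Runs slice selection on each case's long stack, builds the 5 samples per
#' case, and attaches the case-level partition assignment.
#'
#' @param cohort a `dat_cohort`.
#' @param fractions passed to [split_dataset()].
#' @param seed seed for the split.
#' @return list with `samples` (flat list, 5 per case), `selections`,
#'   `partition` (named vector per case).
#' @export
preprocess_cohort <- function(cohort, fractions = c(120, 37, 50) / 207,
                              seed = 1L) {
  stopifnot(inherits(cohort, "dat_cohort"))
  ids <- vapply(cohort$cases, `[[`, character(1), "case_id")
  partition <- split_dataset(ids, fractions, seed)
  selections <- lapply(cohort$pairs,
                       function(p) select_slices(p$long_stack, p$case_id))
  samples <- vector("list", 0L)
  for (i in seq_along(cohort$pairs)) {
    samples <- c(samples, build_samples(cohort$pairs[[i]], selections[[i]],
                                        partition = partition[[ids[i]]]))
  }
  list(samples = samples, selections = selections, partition = partition)
}

# Stack a list of samples into arrays: x (64,64,5,N), y (64,64,1,N).
samples_to_arrays <- function(samples) {
  n <- length(samples)
  x <- array(0, dim = c(64L, 64L, 5L, n))
  y <- array(0, dim = c(64L, 64L, 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$input_window
    y[, , 1L, i] <- samples[[i]]$target
  }
  list(x = x, y = y)
}
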