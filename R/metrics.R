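## Quantitative image-quality evaluation: per-slice PSNR/SSIM against the
## long-acquisition reference, mean +/- SD summaries, Friedman omnibus test,
## and Dunn post-hoc with Holm correction versus a reference method.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)`. Identical images give `Inf` (a sentinel
#' that [summarize_metrics()] excludes from means with a warning).
#'
#' @param reference,test numeric arrays of identical shape.
#' @param max_val peak signal value (1 for normalised floats, 255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, max_val = 1.0) {
  if (!identical(dim(reference) %||% length(reference),
                 dim(test) %||% length(test)))
    stop("reference and test must have identical shape")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Structural similarity index (mean over valid window positions)
#'
#' Local-statistics SSIM with the canonical 11 x 11 Gaussian window
#' (sigma = 1.5), stability constants `C1 = (K1*L)^2`, `C2 = (K2*L)^2`, and
#' weighted (not sample-corrected) local moments. The SSIM map is averaged
#' over positions whose window lies fully inside the image.
#'
#' @param reference,test numeric matrices of identical shape, at least
#'   11 x 11.
#' @param K1,K2 stability constants.
#' @param L dynamic range of the data.
#' @param sigma,win_size Gaussian window parameters.
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(reference, test, K1 = 0.01, K2 = 0.03, L = 1.0,
                 sigma = 1.5, win_size = 11L) {
  if (!is.matrix(reference) || !is.matrix(test) ||
      !identical(dim(reference), dim(test)))
    stop("reference and test must be matrices of identical shape")
  r <- (win_size - 1L) %/% 2L
  if (any(dim(reference) < win_size))
    stop("image smaller than the ", win_size, "x", win_size, " SSIM window")
  Br <- gaussian_band_matrix(nrow(reference), sigma, radius = r)
  Bc <- gaussian_band_matrix(ncol(reference), sigma, radius = r)
  f <- function(m) Br %*% m %*% t(Bc)
  mu_x <- f(reference); mu_y <- f(test)
  s_xx <- f(reference^2) - mu_x^2
  s_yy <- f(test^2) - mu_y^2
  s_xy <- f(reference * test) - mu_x * mu_y
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  map <- ((2 * mu_x * mu_y + C1) * (2 * s_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (s_xx + s_yy + C2))
  valid_r <- (r + 1L):(nrow(map) - r)
  valid_c <- (r + 1L):(ncol(map) - r)
  mean(map[valid_r, valid_c])
}

#' Construct a per-slice metric table
#'
#' Tidy paired design: every (slice, method) pair exactly once.
#'
#' @param slice_id,method_id,psnr,ssim equal-length vectors.
#' @param reference_method the method other methods are contrasted against.
#' @return a `data.frame` of class `metric_table`.
#' @export
metric_table <- function(slice_id, method_id, psnr, ssim,
                         reference_method = "unet_l4") {
  df <- data.frame(slice_id = as.character(slice_id),
                   method_id = as.character(method_id),
                   psnr = as.numeric(psnr), ssim = as.numeric(ssim),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$slice_id, df$method_id, sep = "\r")))
    stop("every (slice, method) pair must appear exactly once")
  tab <- table(df$slice_id, df$method_id)
  if (nrow(df) && any(tab != 1L))
    stop("paired design required: every slice must be scored by every method")
  if (any(df$ssim < -1 - 1e-12 | df$ssim > 1 + 1e-12, na.rm = TRUE))
    stop("ssim values must lie in [-1, 1]")
  attr(df, "reference_method") <- reference_method
  class(df) <- c("metric_table", "data.frame")
  df
}

# slices x methods value matrix for one metric, methods as columns
.metric_matrix <- function(table, metric = c("psnr", "ssim")) {
  metric <- match.arg(metric)
  wide <- stats::reshape(table[c("slice_id", "method_id", metric)],
                         idvar = "slice_id", timevar = "method_id",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub(paste0("^", metric, "\\."), "", colnames(m))
  rownames(m) <- wide$slice_id
  if (anyNA(m)) stop("paired design required: missing (slice, method) cells")
  m
}

#' Per-method mean and standard deviation of PSNR and SSIM
#'
#' Sample SD (n-1 denominator). Infinite PSNR rows are excluded with a
#' warning and their count reported; a single remaining value yields SD 0
#' with `degenerate = TRUE`.
#'
#' @param table a [metric_table()].
#' @return data frame (method_id, metric, mean, sd, n_used, n_excluded,
#'   degenerate).
#' @export
summarize_metrics <- function(table) {
  if (!nrow(table)) stop("empty metric table")
  out <- list()
  for (metric in c("psnr", "ssim")) {
    for (m in unique(table$method_id)) {
      v <- table[[metric]][table$method_id == m]
      inf <- !is.finite(v)
      if (any(inf))
        warning(sum(inf), " infinite ", metric, " value(s) excluded for ", m)
      v <- v[!inf]
      degen <- length(v) < 2L
      out[[length(out) + 1L]] <- data.frame(
        method_id = m, metric = metric,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (degen) 0 else stats::sd(v),
        n_used = length(v), n_excluded = sum(inf), degenerate = degen)
    }
  }
  do.call(rbind, out)
}

#' Friedman omnibus test across methods
#'
#' Within-slice ranks (average ranks for ties), tie-corrected chi-square
#' statistic with k-1 degrees of freedom.
#'
#' @param table a [metric_table()].
#' @param metric `"psnr"` or `"ssim"`.
#' @return list with `statistic`, `df`, `p_value`, `n_slices`, `k_methods`.
#' @export
friedman_test <- function(table, metric = c("psnr", "ssim")) {
  m <- .metric_matrix(table, metric)
  if (ncol(m) < 2L) stop("need at least 2 methods")
  if (nrow(m) < 2L) stop("need at least 2 slices")
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {
    # fully tied table: no evidence of any difference
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = as.integer(unname(ft$parameter)),
       p_value = p, n_slices = nrow(m), k_methods = ncol(m))
}

#' Dunn post-hoc contrasts against a reference method, Holm-adjusted
#'
#' Dunn z statistics from within-slice mean ranks with tie correction,
#' comparing the reference method against each other method only (m = k-1
#' contrasts); two-sided normal p-values with Holm step-down adjustment.
#'
#' @param table a [metric_table()].
#' @param metric `"psnr"` or `"ssim"`.
#' @param reference reference method id (default: the table's attribute).
#' @return data frame (method_id, z, raw_p, holm_p), one row per non-reference
#'   method.
#' @export
dunn_holm <- function(table, metric = c("psnr", "ssim"), reference = NULL) {
  reference <- reference %||% attr(table, "reference_method")
  m <- .metric_matrix(table, metric)
  if (!reference %in% colnames(m))
    stop("reference method '", reference, "' absent from table")
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1L, rank))          # average ranks for ties
  rbar <- colMeans(ranks)
  # tie correction: sum over slices of (t^3 - t) within tie groups
  tie_sum <- sum(apply(m, 1L, function(row) {
    tt <- base::table(row)
    sum(tt^3 - tt)
  }))
  var0 <- k * (k + 1) / (6 * n)
  corr <- 1 - tie_sum / (n * k * (k^2 - 1))
  se <- sqrt(var0 * corr)
  others <- setdiff(colnames(m), reference)
  z <- if (se > 0) (rbar[reference] - rbar[others]) / se
       else stats::setNames(rep(0, length(others)), others)
  raw_p <- 2 * stats::pnorm(-abs(z))
  holm_p <- stats::p.adjust(raw_p, method = "holm")
  data.frame(method_id = others, z = unname(z), raw_p = unname(raw_p),
             holm_p = unname(holm_p), row.names = NULL)
}

#' Evaluate enhancement methods on test samples
#'
#' Computes per-slice PSNR and SSIM of each method's output against the
#' long-acquisition target.
#'
#' @param outputs named list: `outputs[[method_id]]` is an array
#'   (64,64,1,N) aligned with `samples`.
#' @param samples the evaluation samples (targets are taken from these).
#' @param reference_method reference for post-hoc contrasts.
#' @return a [metric_table()].
#' @export
evaluate_methods <- function(outputs, samples,
                             reference_method = "unet_l4") {
  y <- samples_to_arrays(samples)$y
  slice_ids <- vapply(samples, function(s)
    paste0(s$case_id, "_s", s$target_index), character(1))
  rows <- list()
  for (m in names(outputs)) {
    out <- outputs[[m]]
    for (i in seq_along(samples)) {
      rows[[length(rows) + 1L]] <- data.frame(
        slice_id = slice_ids[i], method_id = m,
        psnr = psnr(y[, , 1L, i], out[, , 1L, i]),
        ssim = ssim(y[, , 1L, i], out[, , 1L, i]))
    }
  }
  df <- do.call(rbind, rows)
  metric_table(df$slice_id, df$method_id, df$psnr, df$ssim,
               reference_method = reference_method)
}
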