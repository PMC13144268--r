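# Independent brute-force oracles used to validate the package's statistics.
# These recompute each quantity from first principles (explicit loops over
# definitions), never calling the implementation under test.

# quadratic weighted Cohen's kappa from explicit confusion-matrix loops
kappa_oracle <- function(a, b, k = 4L) {
  n <- length(a)
  O <- matrix(0, k, k)
  for (t in seq_len(n)) O[a[t], b[t]] <- O[a[t], b[t]] + 1 / n
  po <- 0; pe <- 0
  pa <- vapply(seq_len(k), function(i) sum(a == i) / n, numeric(1))
  pb <- vapply(seq_len(k), function(j) sum(b == j) / n, numeric(1))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- 1 - (i - j)^2 / (k - 1)^2
    po <- po + w * O[i, j]
    pe <- pe + w * pa[i] * pb[j]
  }
  (po - pe) / (1 - pe)
}

# ICC(2,1) through the two-way ANOVA table fitted by stats::aov
icc_oracle <- function(m) {
  df <- data.frame(value = as.vector(m),
                   item = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(value ~ item + rater, data = df))[[1]]
  msr <- tab["item", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# mean SSIM by direct looping over every fully-interior window position
ssim_oracle <- function(x, y, K1 = 0.01, K2 = 0.03, L = 1, sigma = 1.5,
                        win = 11L) {
  r <- (win - 1L) %/% 2L
  k1d <- exp(-(-r:r)^2 / (2 * sigma^2))
  W <- outer(k1d, k1d)
  W <- W / sum(W)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (r + 1):(nrow(x) - r)) {
    for (j in (r + 1):(ncol(x) - r)) {
      px <- x[(i - r):(i + r), (j - r):(j + r)]
      py <- y[(i - r):(i + r), (j - r):(j + r)]
      mux <- sum(W * px); muy <- sum(W * py)
      sxx <- sum(W * px^2) - mux^2
      syy <- sum(W * py^2) - muy^2
      sxy <- sum(W * px * py) - mux * muy
      vals <- c(vals, ((2 * mux * muy + C1) * (2 * sxy + C2)) /
                        ((mux^2 + muy^2 + C1) * (sxx + syy + C2)))
    }
  }
  mean(vals)
}

# Friedman chi-square with tie correction, from the rank-sum formula
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  tie <- sum(apply(m, 1, function(row) {
    tt <- base::table(row); sum(tt^3 - tt)
  }))
  stat <- 12 * sum((colSums(R) - n * (k + 1) / 2)^2) /
    (n * k * (k + 1) - tie / (k - 1))
  list(statistic = stat, p_value = stats::pchisq(stat, k - 1,
                                                 lower.tail = FALSE))
}

# Dunn z / p / Holm for reference-vs-others contrasts, all steps explicit
dunn_oracle <- function(m, ref) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  rbar <- colMeans(R)
  tie <- sum(apply(m, 1, function(row) {
    tt <- base::table(row); sum(tt^3 - tt)
  }))
  se <- sqrt(k * (k + 1) / (6 * n) * (1 - tie / (n * k * (k^2 - 1))))
  others <- setdiff(colnames(m), ref)
  z <- if (se > 0) (rbar[ref] - rbar[others]) / se else rep(0, length(others))
  p <- 2 * stats::pnorm(-abs(z))
  # Holm step-down by hand
  ord <- order(p)
  mN <- length(p)
  adj <- numeric(mN)
  running <- 0
  for (i in seq_len(mN)) {
    running <- max(running, (mN - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  data.frame(method_id = others, z = unname(z), raw_p = unname(p),
             holm_p = adj)
}

# small phantom spec for fast simulation-heavy tests
tiny_spec <- function(...) {
  args <- utils::modifyList(list(grid_xy = 32L, n_slices = 7L,
                                 counts_per_cycle = 2000), list(...))
  do.call(phantom_spec, args)
}

# fabricate a complete paired metric table from a values matrix
mt_from_matrix <- function(m, reference = colnames(m)[1]) {
  metric_table(slice_id = rep(rownames(m) %||% paste0("s", seq_len(nrow(m))),
                              ncol(m)),
               method_id = rep(colnames(m), each = nrow(m)),
               psnr = as.vector(m), ssim = tanh(as.vector(m) / 50),
               reference_method = reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
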