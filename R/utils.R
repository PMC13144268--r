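#' @useDynLib datunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- seed discipline -------------------------------------------------------

# Deterministic child-seed derivation: one master seed fans out to independent
# streams (per case, per hemisphere, per cycle, ...) so that growing a cohort
# never reshuffles earlier cases. Arithmetic stays below 2^53 so the mixing is
# exact in doubles; results lie in [1, 2^31 - 2].
MIX_MOD <- 2147483647  # 2^31 - 1 (prime)
MIX_MUL <- 69069

#' Derive a child seed from a master seed and a stream path
#'
#' @param seed master seed (integer-valued scalar).
#' @param ... integer path components identifying the stream, e.g.
#'   `derive_seed(s, case_index, hemisphere_code)`.
#' @return an integer seed in `[1, 2^31 - 2]`, deterministic in its inputs.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- as.numeric(seed) %% MIX_MOD
  for (comp in c(...)) {
    x <- (x * MIX_MUL + as.numeric(comp) + 1) %% MIX_MOD
    x <- (x * MIX_MUL + 12345) %% MIX_MOD
  }
  as.integer(x %% (MIX_MOD - 1) + 1)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## ---- separable Gaussian filtering ------------------------------------------

# Band matrix realising 1-D Gaussian convolution with truncated, row-renormalised
# kernels at the boundary. Interior rows carry the exact kernel, so statistics
# computed away from the border match a 'valid' convolution.
gaussian_band_matrix <- function(n, sigma, radius = NULL) {
  stopifnot(n >= 1, sigma >= 0)
  if (sigma == 0) return(diag(n))
  if (is.null(radius)) radius <- ceiling(4 * sigma)
  offs <- -radius:radius
  k <- exp(-offs^2 / (2 * sigma^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    B[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  B
}

# 2-D separable Gaussian blur of a matrix (truncated renormalised boundary).
gaussian_blur2d <- function(x, sigma, radius = NULL) {
  if (sigma == 0) return(x)
  Br <- gaussian_band_matrix(nrow(x), sigma, radius)
  Bc <- gaussian_band_matrix(ncol(x), sigma, radius)
  Br %*% x %*% t(Bc)
}

# 3-D separable Gaussian blur of an array dim (slices, rows, cols); isotropic
# sigma in voxel units (in-plane and axial alike).
gaussian_blur3d <- function(a, sigma) {
  d <- dim(a)
  if (sigma == 0) return(a)
  out <- a
  for (s in seq_len(d[1])) out[s, , ] <- gaussian_blur2d(out[s, , ], sigma)
  Bz <- gaussian_band_matrix(d[1], sigma)
  m <- matrix(out, nrow = d[1])   # slices x (rows*cols), dim order preserved
  array(Bz %*% m, dim = d)
}

## ---- misc numeric helpers --------------------------------------------------

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
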