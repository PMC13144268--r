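## Classical image-filter baselines the network family is compared against.

# Band matrix realising 1-D Gaussian convolution with symmetric (reflect)
# boundary handling: out-of-range taps are folded back onto the edge pixels.
.reflect_band_matrix <- function(n, kernel, radius) {
  B <- matrix(0, n, n)
  offs <- -radius:radius
  for (i in seq_len(n)) {
    j <- i + offs
    j <- ifelse(j < 1L, 1L - j, j)          # reflect low edge
    j <- ifelse(j > n, 2L * n + 1L - j, j)  # reflect high edge
    for (t in seq_along(offs)) B[i, j[t]] <- B[i, j[t]] + kernel[t]
  }
  B
}

.gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  k <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian filtering baseline
#'
#' Isotropic Gaussian smoothing with reflect boundary handling. `sigma = 0`
#' is the identity.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return the filtered matrix.
#' @export
gaussian_baseline <- function(image, sigma = 1.0) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  r <- ceiling(4 * sigma)
  k <- .gaussian_kernel_1d(sigma, r)
  Br <- .reflect_band_matrix(nrow(image), k, r)
  Bc <- .reflect_band_matrix(ncol(image), k, r)
  Br %*% image %*% t(Bc)
}

#' Bilateral filtering baseline
#'
#' Standard bilateral filter: weights are the product of a spatial Gaussian
#' and a range (intensity) Gaussian, normalised per pixel. Edges are
#' preserved relative to plain Gaussian smoothing because taps across large
#' intensity steps receive small range weights.
#'
#' @param image numeric matrix.
#' @param sigma_spatial spatial standard deviation in pixels (> 0).
#' @param sigma_range range standard deviation in intensity units (> 0).
#' @return the filtered matrix.
#' @export
bilateral_baseline <- function(image, sigma_spatial = 2.0, sigma_range = 0.1) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop("sigma_spatial and sigma_range must be > 0")
  .bilateral_cpp(image, sigma_spatial, sigma_range,
                 as.integer(ceiling(4 * sigma_spatial)))
}

## ---- model registry --------------------------------------------------------

#' Method registry
#'
#' String-keyed registry of enhancement methods: the five U-Net depths, the
#' two classical filters, and the raw short image. Extensible: additional
#' entries (e.g. further network variants) can be supplied via `extra`.
#'
#' @param extra named list of additional method definitions, each a list with
#'   `kind` ("unet" or "filter") and either `depth` or `fn(image)`.
#' @return named list of method definitions.
#' @export
model_registry <- function(extra = NULL) {
  reg <- list(
    short     = list(kind = "identity"),
    gaussian  = list(kind = "filter",
                     fn = function(img) gaussian_baseline(img, sigma = 1.0)),
    bilateral = list(kind = "filter",
                     fn = function(img) bilateral_baseline(img, 2.0, 0.1))
  )
  for (d in 1:5) reg[[paste0("unet_l", d)]] <- list(kind = "unet", depth = d)
  c(reg, extra %||% list())
}

#' Apply an enhancement method to evaluation samples
#'
#' For `"unet"` methods `model` must be a trained network; `"filter"` methods
#' are applied to the centre channel of each input window (the target's own
#' short-time slice); `"identity"` returns that channel unchanged.
#'
#' @param method_id key into [model_registry()].
#' @param samples list of samples (see [build_samples()]).
#' @param model trained `unet` (for unet methods).
#' @param registry a [model_registry()].
#' @return array (64,64,1,N) of enhanced slices in \[0,1\].
#' @export
apply_method <- function(method_id, samples, model = NULL,
                         registry = model_registry()) {
  def <- registry[[method_id]]
  if (is.null(def)) stop("unknown method id: ", method_id)
  arr <- samples_to_arrays(samples)
  n <- dim(arr$x)[4]
  if (def$kind == "unet") {
    if (is.null(model)) stop("unet method requires a trained model")
    return(unet_predict(model, arr$x))
  }
  out <- array(0, dim = c(64L, 64L, 1L, n))
  for (i in seq_len(n)) {
    centre <- arr$x[, , 3L, i]
    out[, , 1L, i] <- switch(def$kind,
                             identity = centre,
                             filter = def$fn(centre),
                             stop("unknown method kind: ", def$kind))
  }
  pmin(pmax(out, 0), 1)
}
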