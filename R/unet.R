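## Compact U-Net family (depths 1-5) for translating 1-cycle slices into
## virtual 5-cycle slices. Forward/backward passes are built on the
## im2col+GEMM primitives in src/; training is plain MSE + Adam.

#' U-Net configuration for a given depth
#'
#' Filter schedule is 16 * 2^(level-1): (16), (16,32), ..., (16,...,256) for
#' depths 1-5. Input is a 5-channel 64 x 64 slice window, output a single
#' 64 x 64 slice. All convolutions are 3 x 3 with "same" padding; down/up
#' sampling is by factor 2 (2x2 max pool, nearest-neighbour upsampling).
#'
#' @param depth integer in 1..5 (number of resolution levels).
#' @return a list of class `unet_config`.
#' @export
unet_config <- function(depth) {
  if (length(depth) != 1L || !depth %in% 1:5)
    stop("depth must be an integer in 1..5, got ", paste(depth, collapse = ","))
  structure(list(depth = as.integer(depth),
                 filters_per_level = as.integer(16 * 2^(seq_len(depth) - 1)),
                 in_channels = 5L, out_channels = 1L,
                 conv_kernel = 3L, pool_factor = 2L),
            class = "unet_config")
}

.conv_param <- function(k, cin, cout) {
  # He initialisation for ReLU nets
  w <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

#' Build an initialised U-Net
#'
#' Encoder-decoder with `depth` resolution levels: two conv(3x3)+ReLU per
#' block, skip connections concatenating encoder features into the decoder at
#' each level, and a final 1x1 convolution to one channel. Initialisation is
#' deterministic given the seed.
#'
#' @param depth integer in 1..5.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `unet` (config + parameter arrays).
#' @export
build_unet <- function(depth, seed = 1L) {
  cfg <- unet_config(depth)
  f <- cfg$filters_per_level
  k <- cfg$conv_kernel
  params <- with_seed(seed, {
    enc <- vector("list", depth)
    for (l in seq_len(depth)) {
      cin <- if (l == 1L) cfg$in_channels else f[l - 1L]
      enc[[l]] <- list(.conv_param(k, cin, f[l]), .conv_param(k, f[l], f[l]))
    }
    dec <- if (depth > 1L) {
      d <- vector("list", depth - 1L)
      for (l in seq_len(depth - 1L)) {
        d[[l]] <- list(.conv_param(k, f[l + 1L] + f[l], f[l]),
                       .conv_param(k, f[l], f[l]))
      }
      d
    } else list()
    list(enc = enc, dec = dec,
         final = .conv_param(1L, f[1L], cfg$out_channels))
  })
  structure(list(config = cfg, params = params, seed = as.integer(seed),
                 history = NULL), class = "unet")
}

#' Number of trainable parameters of a U-Net
#' @param model a `unet`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity,
             numeric(1)))
}

## ---- forward / backward ----------------------------------------------------

.conv_relu_fwd <- function(x, p, relu = TRUE) {
  pre <- .nn_conv_fwd(x, p$w, p$b)
  list(out = if (relu) pmax(pre, 0) else pre, x = x,
       mask = if (relu) (pre > 0) else NULL)
}

.block_fwd <- function(x, block) {
  c1 <- .conv_relu_fwd(x, block[[1]])
  c2 <- .conv_relu_fwd(c1$out, block[[2]])
  list(out = c2$out, c1 = c1, c2 = c2)
}

.conv_relu_bwd <- function(cache, p, gy) {
  if (!is.null(cache$mask)) gy <- gy * cache$mask
  .nn_conv_bwd(cache$x, p$w, gy)   # list(gx, gw, gb)
}

.block_bwd <- function(cache, block, gy) {
  b2 <- .conv_relu_bwd(cache$c2, block[[2]], gy)
  b1 <- .conv_relu_bwd(cache$c1, block[[1]], b2$gx)
  list(gx = b1$gx, grads = list(list(gw = b1$gw, gb = b1$gb),
                                list(gw = b2$gw, gb = b2$gb)))
}

.concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(model, x, want_cache = TRUE) {
  p <- model$params
  depth <- model$config$depth
  enc_cache <- vector("list", depth)
  pool_cache <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    enc_cache[[l]] <- .block_fwd(cur, p$enc[[l]])
    if (l < depth) {
      pl <- .nn_maxpool_fwd(enc_cache[[l]]$out)
      pool_cache[[l]] <- pl
      cur <- pl$y
    }
  }
  cur <- enc_cache[[depth]]$out
  dec_cache <- vector("list", max(depth - 1L, 0L))
  if (depth > 1L) {
    for (l in rev(seq_len(depth - 1L))) {
      up <- .nn_upsample_fwd(cur)
      cat_in <- .concat_c(up, enc_cache[[l]]$out)
      dec_cache[[l]] <- .block_fwd(cat_in, p$dec[[l]])
      cur <- dec_cache[[l]]$out
    }
  }
  out <- .nn_conv_fwd(cur, p$final$w, p$final$b)
  if (!want_cache) return(list(out = out))
  list(out = out, enc = enc_cache, pool = pool_cache, dec = dec_cache,
       final_in = cur)
}

# Returns gradients with the same nesting as model$params.
unet_backward <- function(model, cache, g_out) {
  p <- model$params
  depth <- model$config$depth
  f <- model$config$filters_per_level
  grads <- list(enc = vector("list", depth),
                dec = vector("list", max(depth - 1L, 0L)), final = NULL)
  fin <- .nn_conv_bwd(cache$final_in, p$final$w, g_out)
  grads$final <- list(gw = fin$gw, gb = fin$gb)
  g_cur <- fin$gx                        # grad wrt decoder output at level 1
  g_enc <- vector("list", depth)         # grads wrt encoder block outputs
  if (depth > 1L) {
    for (l in seq_len(depth - 1L)) {
      bb <- .block_bwd(cache$dec[[l]], p$dec[[l]], g_cur)
      grads$dec[[l]] <- bb$grads
      g_cat <- bb$gx
      n_up <- f[l + 1L]
      g_up <- g_cat[, , seq_len(n_up), , drop = FALSE]
      g_skip <- g_cat[, , n_up + seq_len(f[l]), , drop = FALSE]
      g_enc[[l]] <- if (is.null(g_enc[[l]])) g_skip else g_enc[[l]] + g_skip
      g_cur <- .nn_upsample_bwd(g_up)    # grad wrt level-(l+1) output
    }
  }
  g_enc[[depth]] <- g_cur
  for (l in rev(seq_len(depth))) {
    bb <- .block_bwd(cache$enc[[l]], p$enc[[l]], g_enc[[l]])
    grads$enc[[l]] <- bb$grads
    if (l > 1L) {
      g_pool <- .nn_maxpool_bwd(cache$pool[[l - 1L]]$idx, bb$gx,
                                dim(cache$enc[[l - 1L]]$out))
      g_enc[[l - 1L]] <- if (is.null(g_enc[[l - 1L]])) g_pool
                         else g_enc[[l - 1L]] + g_pool
    }
  }
  grads
}

## ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults mirror the emulated protocol: 200 epochs, batch size 8, Adam,
#' MSE loss, learning rate 1e-3 dropping to 1e-5 after epoch 150.
#'
#' @param epochs number of epochs (0 allowed: returns the initialised model).
#' @param batch_size minibatch size.
#' @param lr_initial,lr_late learning rates before/after the switch.
#' @param lr_switch_epoch last epoch using `lr_initial`.
#' @param seed integer seed controlling shuffling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, lr_initial = 1e-3,
                         lr_late = 1e-5, lr_switch_epoch = 150L, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr_initial > 0, lr_late > 0,
            lr_switch_epoch >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", loss = "mse",
                 lr_initial = lr_initial, lr_late = lr_late,
                 lr_switch_epoch = as.integer(lr_switch_epoch),
                 seed = as.integer(seed)), class = "train_config")
}

#' Step learning-rate schedule
#'
#' `lr_initial` up to and including `lr_switch_epoch`, `lr_late` strictly
#' after it.
#'
#' @param epoch epoch number, 1-based, within `1..cfg$epochs`.
#' @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch < 1 || (cfg$epochs > 0 && epoch > cfg$epochs))
    stop("epoch out of range 1..", cfg$epochs)
  if (epoch <= cfg$lr_switch_epoch) cfg$lr_initial else cfg$lr_late
}

# Map over (params, grads) pairs with identical nesting.
.map_params <- function(p, g, fn) {
  if (is.list(p) && !is.null(p$w)) return(fn(p, g))
  out <- p
  for (i in seq_along(p)) if (length(p[[i]])) out[[i]] <- .map_params(p[[i]], g[[i]], fn)
  out
}

#' Train a U-Net by pixel-wise MSE
#'
#' Deterministic given `cfg$seed` (initialisation is fixed by the model's own
#' seed; shuffling by the training seed). No early stopping: the final-epoch
#' weights are returned, with a per-epoch loss history.
#'
#' @param model a `unet` from [build_unet()].
#' @param train_data samples (list from [build_samples()]) or a
#'   `list(x=, y=)` of arrays (64,64,5,N) / (64,64,1,N).
#' @param val_data optional validation samples in the same form.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the trained `unet` with a `history` data frame
#'   (epoch, lr, train_mse, val_mse).
#' @export
train_unet <- function(model, train_data, val_data = NULL,
                       cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "unet"))
  tr <- if (is.list(train_data) && !is.null(train_data$x)) train_data
        else samples_to_arrays(train_data)
  n <- dim(tr$x)[4]
  if (n < 1L) stop("training set must be non-empty")
  va <- if (is.null(val_data)) NULL
        else if (!is.null(val_data$x)) val_data else samples_to_arrays(val_data)
  if (!is.null(va) && dim(va$x)[4] == 0L) {
    warning("empty validation set; skipping validation curve")
    va <- NULL
  }
  adam_m <- .map_params(model$params, model$params,
                        function(p, g) list(w = array(0, dim(p$w)),
                                            b = numeric(length(p$b))))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- vector("list", cfg$epochs)
  with_seed(derive_seed(cfg$seed, 777L), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(epoch, cfg)
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      tot_loss <- 0
      for (bi in batches) {
        xb <- tr$x[, , , bi, drop = FALSE]
        yb <- tr$y[, , , bi, drop = FALSE]
        fw <- unet_forward(model, xb)
        resid <- fw$out - yb
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch,
               " (diverged; lower the learning rate)")
        tot_loss <- tot_loss + loss * length(bi)
        g_out <- (2 / length(resid)) * resid
        grads <- unet_backward(model, fw, g_out)
        step <- step + 1L
        c1 <- 1 - b1^step; c2 <- 1 - b2^step
        upd <- function(p, g, m, v) {
          m$w <- b1 * m$w + (1 - b1) * g$gw
          m$b <- b1 * m$b + (1 - b1) * g$gb
          v$w <- b2 * v$w + (1 - b2) * g$gw^2
          v$b <- b2 * v$b + (1 - b2) * g$gb^2
          p$w <- p$w - lr * (m$w / c1) / (sqrt(v$w / c2) + eps)
          p$b <- p$b - lr * (m$b / c1) / (sqrt(v$b / c2) + eps)
          list(p = p, m = m, v = v)
        }
        # walk the three nested structures in lockstep
        walk <- function(p, g, m, v) {
          if (is.list(p) && !is.null(p$w)) {
            r <- upd(p, g, m, v)
            return(r)
          }
          rp <- p; rm <- m; rv <- v
          for (i in seq_along(p)) {
            if (!length(p[[i]])) next
            r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
            rp[[i]] <- r$p; rm[[i]] <- r$m; rv[[i]] <- r$v
          }
          list(p = rp, m = rm, v = rv)
        }
        r <- walk(model$params, grads, adam_m, adam_v)
        model$params <- r$p; adam_m <- r$m; adam_v <- r$v
      }
      train_mse <- tot_loss / n
      val_mse <- NA_real_
      if (!is.null(va)) {
        pv <- unet_forward(model, va$x, want_cache = FALSE)$out
        val_mse <- mean((pv - va$y)^2)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_mse = train_mse, val_mse = val_mse)
      if (verbose)
        message(sprintf("epoch %3d  lr %.1e  train %.3e  val %.3e",
                        epoch, lr, train_mse, val_mse))
    }
  })
  model$history <- if (cfg$epochs) do.call(rbind, hist)
                   else data.frame(epoch = integer(0), lr = numeric(0),
                                   train_mse = numeric(0),
                                   val_mse = numeric(0))
  model$train_config <- cfg
  model
}

#' Predict enhanced slices
#'
#' Runs the forward pass in batches and clips outputs to \[0, 1\]. The result
#' does not depend on batch order.
#'
#' @param model a trained `unet`.
#' @param x array (64,64,5,N) or a list of samples.
#' @param batch_size inference batch size.
#' @return array (64,64,1,N) of enhanced slices in \[0, 1\].
#' @export
unet_predict <- function(model, x, batch_size = 16L) {
  if (is.list(x) && is.null(dim(x))) x <- samples_to_arrays(x)$x
  d <- dim(x)
  if (length(d) != 4L || d[3] != model$config$in_channels)
    stop("input must be (H, W, ", model$config$in_channels, ", N)")
  out <- array(0, dim = c(d[1], d[2], 1L, d[4]))
  for (lo in seq(1L, d[4], by = batch_size)) {
    hi <- min(lo + batch_size - 1L, d[4])
    out[, , , lo:hi] <- unet_forward(model, x[, , , lo:hi, drop = FALSE],
                                     want_cache = FALSE)$out
  }
  pmin(pmax(out, 0), 1)
}
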