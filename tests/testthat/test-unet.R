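# smooth random fields in [0,1] for optimisation sanity checks
smooth_field <- function(n, g = 16L, seed = 1L) {
  set.seed(seed)
  x <- array(0, c(g, g, 5L, n))
  for (i in seq_len(n)) for (c in 1:5) {
    m <- datunet:::gaussian_blur2d(matrix(runif(g * g), g, g), 2)
    x[, , c, i] <- (m - min(m)) / (max(m) - min(m))
  }
  x
}

test_that("configurations carry the documented filter schedules", {
  expect_identical(unet_config(4)$filters_per_level, c(16L, 32L, 64L, 128L))
  expect_identical(unet_config(1)$filters_per_level, 16L)
  expect_identical(unet_config(5)$filters_per_level,
                   c(16L, 32L, 64L, 128L, 256L))
  expect_error(unet_config(0), "1..5")
  expect_error(build_unet(6), "1..5")
})

test_that("parameter count is strictly increasing in depth", {
  counts <- vapply(1:5, function(d) count_parameters(build_unet(d, seed = 1)),
                   numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("the forward pass maps 5-channel input to a single channel", {
  x <- array(runif(64 * 64 * 5 * 2), c(64, 64, 5, 2))
  for (d in c(1L, 4L)) {
    out <- datunet:::unet_forward(build_unet(d, seed = 1), x,
                                  want_cache = FALSE)$out
    expect_identical(dim(out), c(64L, 64L, 1L, 2L))
  }
})

test_that("analytic gradients match numerical differentiation", {
  net <- build_unet(2, seed = 3)
  set.seed(4)
  x <- array(runif(8 * 8 * 5 * 2), c(8, 8, 5, 2))
  y <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fw <- datunet:::unet_forward(net, x)
  g <- datunet:::unet_backward(net, fw, (2 / length(fw$out)) * (fw$out - y))
  eps <- 1e-6
  probe <- function(setter, getter) {
    n1 <- setter(net, +eps)
    l1 <- mean((datunet:::unet_forward(n1, x, want_cache = FALSE)$out - y)^2)
    n2 <- setter(net, -eps)
    l2 <- mean((datunet:::unet_forward(n2, x, want_cache = FALSE)$out - y)^2)
    expect_equal((l1 - l2) / (2 * eps), getter(g), tolerance = 1e-5)
  }
  probe(function(m, d) { m$params$enc[[1]][[1]]$w[10] <-
                           m$params$enc[[1]][[1]]$w[10] + d; m },
        function(g) g$enc[[1]][[1]]$gw[10])
  probe(function(m, d) { m$params$dec[[1]][[2]]$w[4] <-
                           m$params$dec[[1]][[2]]$w[4] + d; m },
        function(g) g$dec[[1]][[2]]$gw[4])
  probe(function(m, d) { m$params$final$b[1] <- m$params$final$b[1] + d; m },
        function(g) g$final$gb[1])
})

test_that("the learning-rate schedule switches strictly after epoch 150", {
  cfg <- train_config()
  expect_equal(lr_schedule(1, cfg), 1e-3)
  expect_equal(lr_schedule(150, cfg), 1e-3)
  expect_equal(lr_schedule(151, cfg), 1e-5)
  expect_equal(lr_schedule(200, cfg), 1e-5)
  expect_error(lr_schedule(0, cfg), "out of range")
  expect_error(lr_schedule(201, cfg), "out of range")
})

test_that("zero-epoch training returns the initialisation with empty history", {
  net <- build_unet(1, seed = 9)
  x <- array(runif(16 * 16 * 5 * 4), c(16, 16, 5, 4))
  y <- array(runif(16 * 16 * 1 * 4), c(16, 16, 1, 4))
  tr <- train_unet(net, list(x = x, y = y), cfg = train_config(epochs = 0))
  expect_identical(tr$params, net$params)
  expect_identical(nrow(tr$history), 0L)
})

test_that("training reduces the loss and is deterministic under a fixed seed", {
  x <- smooth_field(20, seed = 11)
  y <- array(x[, , 3, ] * 0.8, c(16, 16, 1, 20))
  net <- build_unet(2, seed = 5)
  cfg <- train_config(epochs = 30, seed = 21)
  tr1 <- train_unet(net, list(x = x, y = y), cfg = cfg)
  expect_lt(tr1$history$train_mse[30], tr1$history$train_mse[1])
  tr2 <- train_unet(net, list(x = x, y = y), cfg = cfg)
  expect_equal(tr1$history$train_mse, tr2$history$train_mse,
               tolerance = 1e-6)
  expect_equal(tr1$params, tr2$params, tolerance = 1e-12)
})

test_that("a learnable identity task is solved to high accuracy", {
  x <- smooth_field(20, seed = 13)
  y <- array(x[, , 3, ], c(16, 16, 1, 20))   # target = centre channel
  net <- build_unet(1, seed = 2)
  # small net on a tiny task: a higher rate with decay converges quickly
  tr <- train_unet(net, list(x = x, y = y),
                   cfg = train_config(epochs = 200, lr_initial = 1e-2,
                                      lr_late = 3e-4, lr_switch_epoch = 150,
                                      seed = 3))
  pred <- datunet:::unet_forward(tr, x, want_cache = FALSE)$out
  expect_lt(mean((pred - y)^2), 1e-3)
})

test_that("prediction clips to [0,1] and is batch-order independent", {
  net <- build_unet(2, seed = 6)
  x <- array(runif(16 * 16 * 5 * 7), c(16, 16, 5, 7))
  out <- unet_predict(net, x, batch_size = 3L)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  out_perm <- unet_predict(net, x[, , , perm, drop = FALSE], batch_size = 2L)
  expect_equal(out_perm, out[, , , perm, drop = FALSE])
  expect_error(unet_predict(net, array(0, c(16, 16, 3, 2))), "\\(H, W, 5")
})

test_that("non-finite loss aborts with a diagnostic", {
  x <- smooth_field(8, seed = 15)
  y <- array(x[, , 3, ], c(16, 16, 1, 8))
  x[1, 1, 1, 1] <- NaN
  net <- build_unet(1, seed = 2)
  expect_error(train_unet(net, list(x = x, y = y),
                          cfg = train_config(epochs = 2, seed = 1)),
               "non-finite")
})

test_that("empty validation set warns and skips the validation curve", {
  x <- smooth_field(6, seed = 17)
  y <- array(x[, , 3, ], c(16, 16, 1, 6))
  net <- build_unet(1, seed = 2)
  expect_warning(
    tr <- train_unet(net, list(x = x, y = y),
                     val_data = list(x = x[, , , 0, drop = FALSE],
                                     y = y[, , , 0, drop = FALSE]),
                     cfg = train_config(epochs = 1, seed = 1)),
    "empty validation")
  expect_true(all(is.na(tr$history$val_mse)))
})
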