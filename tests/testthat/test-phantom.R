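test_that("pattern scores are validated", {
  expect_identical(striatal_pattern(3), 3L)
  expect_error(striatal_pattern(0), "1..4")
  expect_error(striatal_pattern(5), "1..4")
  expect_error(striatal_pattern(2.5), "1..4")
  expect_error(make_activity_volume(phantom_spec(), left = 6, right = 1),
               "1..4")
})

test_that("zero activity forces a zero volume and zero counts", {
  spec <- phantom_spec(background_activity = 0, striatal_activity = 0)
  case <- make_activity_volume(spec, 4, 4, seed = 1)
  expect_true(all(case$activity == 0))
  expect_true(all(simulate_cycle(case, seed = 9) == 0))
})

test_that("nominal geometry is mirror-symmetric about the mid-sagittal plane", {
  case <- make_activity_volume(phantom_spec(), 4, 4, seed = 1, jitter = FALSE)
  g <- dim(case$activity)[3]
  for (s in c(1, 8, 15))
    expect_equal(case$activity[s, , ], case$activity[s, , g:1])
})

test_that("striatal mask means realise the requested patterns exactly", {
  spec <- phantom_spec()
  case <- make_activity_volume(spec, left = 1, right = 4, seed = 1,
                               jitter = FALSE)
  left_mask <- unlist(case$masks$L)
  right_mask <- unlist(case$masks$R)
  expect_gt(length(left_mask), 0)
  expect_equal(mean(case$activity[left_mask]), spec$background_activity)
  expect_equal(mean(case$activity[right_mask]), spec$striatal_activity)
  # intermediate patterns order the within-mask means monotonically
  means <- vapply(1:4, function(p) {
    cs <- make_activity_volume(spec, p, p, seed = 1, jitter = FALSE)
    mean(cs$activity[unlist(cs$masks$L)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("sub-region masks are disjoint and within the brain", {
  case <- make_activity_volume(phantom_spec(), 4, 4, seed = 2)
  all_idx <- unlist(case$masks)
  expect_false(anyDuplicated(all_idx) > 0)
  expect_true(all(case$activity[all_idx] > 0))  # inside brain support
})

test_that("changing the left pattern never touches the right half-volume", {
  spec <- phantom_spec()
  g <- spec$grid_xy
  a <- make_activity_volume(spec, 4, 4, seed = 5)
  b <- make_activity_volume(spec, 1, 4, seed = 5)
  expect_equal(a$activity[, , (g / 2 + 1):g], b$activity[, , (g / 2 + 1):g])
  expect_false(isTRUE(all.equal(a$activity[, , 1:(g / 2)],
                                b$activity[, , 1:(g / 2)])))
})

test_that("cycle counts are Poisson with per-slice expected totals", {
  spec <- tiny_spec()
  case <- make_activity_volume(spec, 4, 3, seed = 1)
  # determinism
  expect_identical(simulate_cycle(case, seed = 42),
                   simulate_cycle(case, seed = 42))
  # Monte-Carlo: per-slice totals match counts_per_cycle within 3 SE
  ex <- expected_cycle(case)
  reps <- 500
  totals <- matrix(0, reps, spec$n_slices)
  for (r in seq_len(reps)) {
    cyc <- simulate_cycle(case, seed = r, expected = ex)
    totals[r, ] <- apply(cyc, 1, sum)
  }
  for (s in seq_len(spec$n_slices)) {
    se <- sqrt(spec$counts_per_cycle / reps)  # Poisson variance = mean
    expect_lt(abs(mean(totals[, s]) - spec$counts_per_cycle), 3 * se)
  }
})

test_that("acquisition pairs satisfy cycle additivity", {
  spec1 <- tiny_spec(n_cycles = 1L)
  case1 <- make_activity_volume(spec1, 4, 4, seed = 1)
  pair1 <- simulate_acquisition_pair(case1, seed = 3)
  expect_identical(pair1$short_stack, pair1$long_stack)

  spec <- tiny_spec()
  case <- make_activity_volume(spec, 4, 2, seed = 1)
  pair <- simulate_acquisition_pair(case, seed = 3)
  expect_identical(dim(pair$short_stack), dim(pair$noiseless_stack))
  expect_true(all(pair$short_stack >= 0) && all(pair$long_stack >= 0))
  expect_true(all(pair$long_stack >= pair$short_stack))
})

test_that("mean PSNR versus noiseless is non-decreasing in summed cycles", {
  spec <- tiny_spec()
  case <- make_activity_volume(spec, 4, 4, seed = 2)
  ex <- expected_cycle(case)
  reps <- 20
  mean_psnr <- numeric(spec$n_cycles)
  for (k in seq_len(spec$n_cycles)) {
    v <- numeric(reps)
    for (r in seq_len(reps)) {
      acc <- array(0, dim(ex))
      for (i in seq_len(k))
        acc <- acc + simulate_cycle(case, seed = derive_seed(r, i),
                                    expected = ex)
      v[r] <- psnr(ex * k / max(ex * k), acc / max(acc))
    }
    mean_psnr[k] <- mean(v)
  }
  expect_true(all(diff(mean_psnr) > 0))
})

test_that("cohorts are reproducible and prefix-stable", {
  spec <- tiny_spec()
  a <- generate_cohort(3, spec = spec, seed = 7)
  b <- generate_cohort(3, spec = spec, seed = 7)
  expect_identical(a$pairs[[2]]$long_stack, b$pairs[[2]]$long_stack)
  bigger <- generate_cohort(5, spec = spec, seed = 7)
  expect_identical(a$pairs[[3]]$short_stack, bigger$pairs[[3]]$short_stack)
  expect_identical(a$truth$score, bigger$truth$score[1:6])
})

test_that("cohort prevalence controls pattern frequencies", {
  spec <- phantom_spec(grid_xy = 16L, n_slices = 5L, counts_per_cycle = 100)
  expect_equal(length(generate_cohort(0, spec = spec, seed = 1)$cases), 0)
  all4 <- generate_cohort(10, pattern_prevalence = c(0, 0, 0, 1),
                          spec = spec, seed = 2)
  expect_true(all(all4$truth$score == 4L))
  expect_error(generate_cohort(2, pattern_prevalence = c(0.5, 0.5, 0.2, 0),
                               spec = spec, seed = 1), "sum to 1")
  prev <- c(0.17, 0.29, 0.28, 0.26)
  big <- generate_cohort(1000, pattern_prevalence = prev, spec = spec,
                         seed = 3)
  freq <- as.numeric(base::table(factor(big$truth$score, levels = 1:4))) / 2000
  se <- sqrt(prev * (1 - prev) / 2000)
  expect_true(all(abs(freq - prev) < 3 * se))
})

test_that("simulated readers follow their confusion model", {
  truth <- score_table("gold", rep(sprintf("c%04d", 1:1000), each = 2),
                       rep(c("L", "R"), 1000), "truth", 1L,
                       rep(1:4, 500))
  ident <- simulate_reader(truth, diag(4), seed = 1)
  expect_identical(ident$score, truth$score)
  expect_equal(as.numeric(weighted_kappa(ident$score, truth$score)), 1)
  # independent reader: kappa near zero
  flat <- matrix(0.25, 4, 4)
  rand <- simulate_reader(truth, flat, seed = 2)
  expect_lt(abs(weighted_kappa(rand$score, truth$score)), 0.1)
  # deterministic upward shift, clipped at 4
  shift <- matrix(0, 4, 4)
  for (i in 1:3) shift[i, i + 1] <- 1
  shift[4, 4] <- 1
  up <- simulate_reader(truth, shift, seed = 3)
  expect_identical(up$score, pmin(truth$score + 1L, 4L))
  expect_error(simulate_reader(truth, matrix(0.3, 4, 4), seed = 1),
               "sum to 1")
})
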