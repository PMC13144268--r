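test_that("weighted kappa handles the canonical special cases", {
  a <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expect_equal(as.numeric(weighted_kappa(a, a)), 1)
  expect_equal(as.numeric(weighted_kappa(1:4, 4:1)), -1, tolerance = 1e-12)
  expect_error(weighted_kappa(1:3, 1:4), "equal length")
  expect_error(weighted_kappa(integer(0), integer(0)), "empty")
  expect_error(weighted_kappa(c(1, 5), c(1, 2)), "1..4")
  # both raters constant and equal: defined as 1 with a flag
  kc <- weighted_kappa(rep(2, 5), rep(2, 5))
  expect_equal(as.numeric(kc), 1)
  expect_true(attr(kc, "degenerate"))
})

test_that("weighted kappa matches the brute-force formula", {
  a <- c(1, 1, 2, 2, 3, 3, 4, 4)
  b <- c(1, 2, 2, 3, 3, 4, 4, 4)
  expect_equal(as.numeric(weighted_kappa(a, b)), kappa_oracle(a, b),
               tolerance = 1e-12)
  set.seed(20)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 && identical(x, y)) next
    expect_equal(as.numeric(weighted_kappa(x, y)), kappa_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("kappa of independent raters is near zero", {
  set.seed(21)
  x <- sample(1:4, 1000, replace = TRUE)
  y <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(as.numeric(weighted_kappa(x, y))), 0.1)
})

test_that("ICC(2,1) special cases and ANOVA-table oracle", {
  m <- cbind(c(1, 2, 3, 4, 2, 3), c(1, 2, 3, 4, 2, 3))
  expect_equal(icc_single(m), 1)
  expect_error(icc_single(matrix(2, 4, 2)), "zero total variance")
  expect_error(icc_single(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(icc_single(matrix(1:2, 1, 2)), "at least 2")
  set.seed(22)
  noise <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(icc_single(noise)), 0.15)
  grid6 <- cbind(c(1, 2, 3, 3, 2, 4), c(2, 2, 3, 4, 2, 3))
  expect_equal(icc_single(grid6), icc_oracle(grid6), tolerance = 1e-10)
  for (i in 1:100) {
    n <- sample(4:20, 1); k <- sample(2:4, 1)
    g <- matrix(sample(1:4, n * k, replace = TRUE) + rnorm(n * k, sd = 0.01),
                n, k)
    expect_equal(icc_single(g), icc_oracle(g), tolerance = 1e-10)
  }
})

# build a truth table of n cases scored on both hemispheres
truth_of <- function(n, seed = 1) {
  set.seed(seed)
  score_table("gold", rep(sprintf("c%04d", 1:n), each = 2),
              rep(c("L", "R"), n), "truth", 1L,
              sample(1:4, 2 * n, replace = TRUE,
                     prob = c(0.17, 0.29, 0.28, 0.26)))
}

test_that("intra-rater ICC is 1 for duplicated sessions and stable under noise", {
  truth <- truth_of(50)
  s1 <- simulate_reader(truth, adjacent_confusion(0.9), seed = 1,
                        reader_id = "A", method_id = "unet_l4", session = 1)
  s2 <- s1; s2$session <- 2L
  sc <- validate_score_table(rbind(s1, s2))
  rep1 <- intra_rater_report(sc, "unet_l4")
  expect_equal(rep1$icc, 1)
  # identity confusion in both sessions
  i1 <- simulate_reader(truth, diag(4), seed = 2, reader_id = "A",
                        method_id = "unet_l4", session = 1)
  i2 <- simulate_reader(truth, diag(4), seed = 3, reader_id = "A",
                        method_id = "unet_l4", session = 2)
  expect_equal(intra_rater_report(validate_score_table(rbind(i1, i2)),
                                  "unet_l4")$icc, 1)
  # 20% symmetric adjacent noise: ICC strictly inside (0,1), seed-stable
  iccs <- vapply(1:3, function(sd) {
    a <- simulate_reader(truth, adjacent_confusion(0.8), seed = 10 + sd,
                         reader_id = "A", method_id = "unet_l4", session = 1)
    b <- simulate_reader(truth, adjacent_confusion(0.8), seed = 20 + sd,
                         reader_id = "A", method_id = "unet_l4", session = 2)
    intra_rater_report(validate_score_table(rbind(a, b)), "unet_l4")$icc
  }, numeric(1))
  expect_true(all(iccs > 0 & iccs < 1))
  expect_lt(max(iccs) - min(iccs), 0.2)
  expect_error(intra_rater_report(s1, "unet_l4"), "both sessions")
})

test_that("inter-rater ICC detects perfect and imperfect agreement", {
  truth <- truth_of(40, seed = 2)
  mk <- function(rid, seed, acc = 1) {
    simulate_reader(truth, adjacent_confusion(acc), seed = seed,
                    reader_id = rid, method_id = "unet_l4", session = 1)
  }
  same <- validate_score_table(rbind(mk("A", 1), mk("B", 1), mk("C", 1)))
  rep_same <- inter_rater_report(same)
  expect_equal(rep_same$pairs$icc, rep(1, 3))
  expect_equal(rep_same$average, 1)
  # shift one reader's scores on half the items
  b <- mk("B", 1)
  half <- seq(1, nrow(b), by = 2)
  b$score[half] <- pmin(b$score[half] + 1L, 4L)
  two <- validate_score_table(rbind(mk("A", 1), b))
  expect_lt(inter_rater_report(two)$pairs$icc, 1)
  # exchangeable simulated readers give similar pairwise ICCs
  truth_big <- truth_of(150, seed = 3)
  mk2 <- function(rid, seed) simulate_reader(truth_big,
                                             adjacent_confusion(0.8),
                                             seed = seed, reader_id = rid,
                                             method_id = "m", session = 1)
  three <- validate_score_table(rbind(mk2("A", 4), mk2("B", 5), mk2("C", 6)))
  rp <- inter_rater_report(three)
  expect_lt(max(rp$pairs$icc) - min(rp$pairs$icc), 0.2)
  expect_error(inter_rater_report(mk("A", 1)), "at least 2 readers")
})

test_that("kappa report mirrors the reader-study table structure", {
  truth <- truth_of(60, seed = 5)
  gold <- truth
  readers <- do.call(rbind, lapply(c(A = 1, B = 2, C = 3), function(s) {
    rbind(simulate_reader(truth, adjacent_confusion(0.55), seed = 100 + s,
                          reader_id = paste0("R", s), method_id = "short"),
          simulate_reader(truth, adjacent_confusion(0.9), seed = 200 + s,
                          reader_id = paste0("R", s), method_id = "unet_l4"))
  }))
  rep <- kappa_report(validate_score_table(readers), gold)
  expect_identical(nrow(rep$per_reader), 6L)
  # per-method average equals the arithmetic mean of reader kappas
  for (m in c("short", "unet_l4")) {
    expect_equal(rep$per_method$mean_kappa[rep$per_method$method_id == m],
                 mean(rep$per_reader$kappa[rep$per_reader$method_id == m]))
  }
  # reader identical to gold scores kappa 1
  perfect <- simulate_reader(truth, diag(4), seed = 1, reader_id = "P",
                             method_id = "unet_l4")
  repp <- kappa_report(perfect, gold)
  expect_equal(repp$per_reader$kappa, 1)
  # sharper confusion on enhanced images raises kappa
  expect_gt(rep$per_method$mean_kappa[rep$per_method$method_id == "unet_l4"],
            rep$per_method$mean_kappa[rep$per_method$method_id == "short"])
  # items missing from gold are rejected
  extra <- perfect
  extra$case_id[1] <- "not_in_gold"
  expect_error(kappa_report(extra, gold), "missing from gold")
})

test_that("kappa and ICC stay within [-1, 1] on fuzzed inputs", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    kv <- as.numeric(weighted_kappa(x, y))
    expect_gte(kv, -1 - 1e-12); expect_lte(kv, 1 + 1e-12)
    # note: the ICC(2,1) point estimate can dip slightly below -1 on
    # pathological two-rater tables (small n, MSR << MSE); the upper bound
    # and the near-[-1,1] range are what the estimator guarantees
    m <- matrix(sample(1:4, 2 * n, replace = TRUE), n, 2)
    if (stats::var(as.vector(m)) == 0) next
    iv <- icc_single(m)
    expect_gte(iv, -2); expect_lte(iv, 1 + 1e-12)
  }
})
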