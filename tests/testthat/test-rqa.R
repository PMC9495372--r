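test_that("time-delay embedding indexes correctly", {
  e <- embed_delay(1:10, dim = 3, delay = 2)
  expect_equal(nrow(e), 6)
  expect_equal(e[1, ], c(1, 3, 5))
  expect_equal(e[6, ], c(6, 8, 10))

  e1 <- embed_delay(1:7, dim = 1, delay = 5)
  expect_equal(as.numeric(e1), 1:7)

  expect_equal(nrow(embed_delay(rnorm(1000), dim = 10, delay = 5)), 955)
  expect_error(embed_delay(1:5, dim = 3, delay = 3),
               class = "emg_parameter_error")
})

test_that("the recurrence matrix is symmetric and respects the radius", {
  # two clusters far apart: recurrences only within clusters
  v <- matrix(c(0, 0.1, 0.05, 10, 10.1, 10.05), ncol = 1)
  rec <- recurrence_matrix(v, radius_fraction = 0.05)
  expect_true(isSymmetric(unname(rec)))
  expect_true(all(rec[1:3, 1:3]))
  expect_true(all(rec[4:6, 4:6]))
  expect_false(any(rec[1:3, 4:6]))

  # constant signal: degenerate, everything recurrent
  cst <- recurrence_matrix(matrix(1, 5, 2))
  expect_true(attr(cst, "degenerate"))
  expect_true(all(cst))
})

test_that("hand-computed 4-point example gives the expected measures", {
  # points 0, 1, 10, 11 in 1-D: max distance 11; radius 0.25 -> threshold 2.75
  # recurrent off-diagonal pairs: (1,2) and (3,4) and symmetric
  rec <- recurrence_matrix(matrix(c(0, 1, 10, 11), ncol = 1),
                           radius_fraction = 0.25)
  res <- rqa_measures(rec, l_min = 3)
  expect_equal(res$pct_rec, 100 * 4 / 12)
  expect_equal(res$pct_det, 0)  # isolated points only
})

test_that("constant signals give 100 % recurrence and determinism", {
  res <- rqa(rep(5, 100), dim = 3, delay = 2)
  expect_equal(res$pct_rec, 100)
  expect_equal(res$pct_det, 100)
  expect_true(res$degenerate)
})

test_that("isolated recurrent points yield zero determinism", {
  # sparse lattice of recurrent points: no two adjacent along any diagonal
  n <- 12
  rec <- outer(1:n, 1:n, function(i, j) i %% 3 == 0 & j %% 3 == 0 & i != j)
  res <- rqa_measures(rec, l_min = 3)
  expect_gt(res$pct_rec, 0)
  expect_equal(res$pct_det, 0)
})

test_that("RQA measures agree exactly with the brute-force oracle", {
  cases <- expand.grid(seed = 1:8, n = c(80, 160, 300))
  for (i in seq_len(nrow(cases))) {
    x <- gen_colored_noise(cases$n[i], beta = 0, seed = 6000 + cases$seed[i])
    mine <- rqa(x)
    oracle <- rqa_oracle(x)
    expect_equal(mine$pct_rec, oracle$pct_rec, info = sprintf("case %d", i))
    expect_equal(mine$pct_det, oracle$pct_det, info = sprintf("case %d", i))
  }
})

test_that("a sine is more deterministic than noise at equal length", {
  sine <- sin(2 * pi * (1:300) / 25)
  noise <- gen_colored_noise(300, beta = 0, seed = 61)
  expect_gt(rqa(sine)$pct_det, rqa(noise)$pct_det)
})

test_that("RQA measures are invariant under affine signal transforms", {
  x <- gen_colored_noise(300, beta = 0.5, seed = 62)
  a <- rqa(x)
  b <- rqa(2.5 * x - 7)
  expect_equal(a$pct_rec, b$pct_rec)
  expect_equal(a$pct_det, b$pct_det)
})

test_that("determinism is non-increasing in the minimum line length", {
  x <- gen_colored_noise(250, beta = 1, seed = 63)
  rec <- recurrence_matrix(embed_delay(x))
  dets <- sapply(2:6, function(l) rqa_measures(rec, l_min = l)$pct_det)
  expect_true(all(diff(dets) <= 1e-12))
})

test_that("AMI delay estimation finds the quarter period of a sine", {
  sine <- sin(2 * pi * (1:2000) / 20)
  est <- estimate_delay_ami(sine, max_lag = 15, n_bins = 10)
  expect_gte(est$delay, 3)
  expect_lte(est$delay, 7)
  expect_identical(est$delay,
                   estimate_delay_ami(sine, max_lag = 15, n_bins = 10)$delay)
})

test_that("AMI of white noise is flat from the first lag", {
  x <- gen_colored_noise(4000, beta = 0, seed = 64)
  est <- estimate_delay_ami(x, max_lag = 20)
  expect_lte(est$delay, 3)
  # the AMI curve is uniformly tiny compared to a structured signal
  expect_lt(max(est$ami$ami), 0.1)
})

test_that("false-nearest-neighbor dimension is 2 for a sine and grows for noise", {
  sine <- sin(2 * pi * (1:600) / 20)
  est <- estimate_dimension_fnn(sine, delay = 5, max_dim = 8)
  expect_equal(est$dim, 2)
  expect_gte(est$dim, 1)

  x <- gen_colored_noise(600, beta = 0, seed = 65)
  expect_warning(noisy <- estimate_dimension_fnn(x, delay = 1, max_dim = 4),
                 class = "emg_no_minimum")
  expect_equal(noisy$dim, 4)
})
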