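test_that("experimental values land in their bins with e-value multiplicities", {
  bs <- build_kde_bins(c(59.2, 60.7), c(30, 40), evalue = c(1e-6, 1e-2),
                       bin_width = 1)
  expect_setequal(names(bs$bins), c("59", "60"))
  # w = clamp(floor(-log10 e), 1, 10): 6 copies and 2 copies
  expect_equal(bs$bins[["59"]]$E, 6)
  expect_equal(bs$bins[["60"]]$E, 2)
  expect_equal(default_psm_weight(c(1e-6, 1e-2, 0.5, 1e-15)), c(6L, 2L, 1L, 10L))
})

test_that("per-bin KDEs integrate to one and degenerate bins get a floor bandwidth", {
  set.seed(61)
  bs <- build_kde_bins(rep(10.5, 200), rnorm(200, 50, 3), bin_width = 1)
  b <- bs$bins[["10"]]
  grid <- seq(20, 80, length.out = 4000)
  dens <- vapply(grid, function(g) msrescore:::kde_density(b, g), numeric(1))
  expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 1e-2)
  # single-observation bin: Gaussian centered at the value, floored bandwidth
  one <- build_kde_bins(5, 42, bin_width = 1)
  expect_equal(one$bins[["5"]]$bw, 0.1)
  expect_equal(msrescore:::kde_density(one$bins[["5"]], 42), dnorm(0, sd = 0.1))
})

test_that("the uniform-prior pseudo-count U uses the nearest-rank percentile", {
  # bin sizes 1,2,5,10,100 at the 10th percentile -> U = 1
  ex <- rep(c(1, 2, 3, 4, 5), times = c(1, 2, 5, 10, 100)) + 0.5
  bs <- build_kde_bins(ex, seq_along(ex), bin_width = 1, percentile = 0.10,
                       predicted_range = c(0, 100))
  expect_equal(bs$U, 1)
  expect_equal(bs$P_U, 0.01)
  # single bin: U equals its count
  one <- build_kde_bins(rep(1.5, 7), 1:7, bin_width = 1)
  expect_equal(one$U, 7)
})

test_that("Eq.-style blending hits its worked value and limits", {
  expect_equal(blend_uniform_prior(0.01, 10, 0.2, 30), 0.1525)
  # symmetric case: U=E and P_U=P_E=p -> p
  expect_equal(blend_uniform_prior(0.3, 5, 0.3, 5), 0.3)
  # E=0 -> exactly P_U
  expect_identical(blend_uniform_prior(0.07, 12, 0.9, 0), 0.07)
  # E -> infinity converges to P_E; output bounded by min/max of the two
  expect_lt(abs(blend_uniform_prior(0.01, 1, 0.2, 1e6) - 0.2), 1e-6 * 0.2)
  for (i in 1:20) {
    p <- runif(2); u <- runif(1, 0, 50); e <- runif(1, 0, 50)
    out <- blend_uniform_prior(p[1], u, p[2], e)
    expect_gte(out, min(p) - 1e-12)
    expect_lte(out, max(p) + 1e-12)
  }
})

test_that("empty-bin queries return the prior and output is monotone in P_E", {
  set.seed(62)
  bs <- build_kde_bins(runif(100, 10, 20), rnorm(100, 50, 5), bin_width = 1,
                       predicted_range = c(0, 100))
  expect_equal(probability_with_uniform_prior(bs, 99, 50), bs$P_U)
  pe <- seq(0, 1, length.out = 20)
  out <- vapply(pe, function(p) blend_uniform_prior(0.01, 4, p, 9), numeric(1))
  expect_true(all(diff(out) > 0))
})

test_that("the prior damps single-PSM bins against inflated probabilities", {
  one <- build_kde_bins(5, 42, bin_width = 1, predicted_range = c(0, 100))
  out <- probability_with_uniform_prior(one, 5, 42)
  P_E <- msrescore:::kde_density(one$bins[["5"]], 42)
  expect_lte(out, (one$P_U * one$U + P_E) / (one$U + 1))
  expect_lt(out, P_E)  # well below the raw (inflated) density
})

test_that("in-distribution predicted values score above uniform-random ones", {
  set.seed(63)
  n <- 600
  ex <- runif(n, 0, 60)
  pred <- 10 + 1.2 * ex + rnorm(n, 0, 2)  # concentrated per bin
  bs <- build_kde_bins(ex, pred, bin_width = 1, predicted_range = c(0, 100))
  good_q <- 10 + 1.2 * ex + rnorm(n, 0, 2)
  bad_q <- runif(n, 0, 100)
  good <- probability_with_uniform_prior(bs, ex, good_q)
  bad <- probability_with_uniform_prior(bs, ex, bad_q)
  expect_gt(median(good), median(bad))
})
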