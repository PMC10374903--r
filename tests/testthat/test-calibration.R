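psm_stub <- function(n, evalue, rank = 1L, label = 1L) {
  tibble::tibble(
    spec_id = sprintf("s%04d", seq_len(n)),
    label = rep_len(label, n), scan_nr = seq_len(n),
    rank = rep_len(rank, n), charge = 2L,
    evalue = evalue
  )
}

test_that("calibration PSM selection applies rank, label, threshold and caps", {
  # more qualifying PSMs than the cap -> lowest e-values kept, loess flag
  big <- psm_stub(6000, evalue = 10^-runif(6000, 4, 8))
  sel <- select_calibration_psms(big, max_n = 5000)
  expect_equal(nrow(sel$psms), 5000)
  expect_equal(sel$method, "loess")
  expect_lte(max(sel$psms$evalue), max(big$evalue))
  expect_equal(sel$psms$evalue, sort(sel$psms$evalue))

  # fewer than min_n -> linear fallback
  small <- psm_stub(30, evalue = rep(1e-5, 30))
  sel2 <- select_calibration_psms(small)
  expect_equal(nrow(sel2$psms), 30)
  expect_equal(sel2$method, "linear")

  # decoys and lower ranks never qualify
  mix <- dplyr::bind_rows(
    psm_stub(60, rep(1e-5, 60)),
    psm_stub(60, rep(1e-6, 60), label = -1L),
    psm_stub(60, rep(1e-6, 60), rank = 2L)
  )
  sel3 <- select_calibration_psms(mix)
  expect_equal(nrow(sel3$psms), 60)
  expect_true(all(sel3$psms$label == 1L & sel3$psms$rank == 1L))

  # everything above threshold -> error instructing to skip RT features
  expect_error(select_calibration_psms(psm_stub(100, rep(1e-2, 100))), "skip")
})

test_that("identity and linear relationships are recovered", {
  x <- seq(1, 100, length.out = 200)
  m <- fit_calibration(x, x, method = "loess", span = 0.05)
  expect_lt(max(abs(predict(m, x) - x)), 1e-6)

  m2 <- fit_calibration(x, 2 * x + 5, method = "linear")
  k <- tidy(m2)
  slope <- diff(k$calibrated) / diff(k$experimental)
  expect_equal(slope, 2, tolerance = 1e-9)
  expect_equal(k$calibrated[1] - 2 * k$experimental[1], 5, tolerance = 1e-9)
  expect_error(fit_calibration(rep(1, 10), 1:10), "distinct")
})

test_that("a noisy sigmoid warp is recovered monotone and accurate", {
  set.seed(51)
  x <- sort(runif(1000, -6, 6))
  truth <- function(v) 1 / (1 + exp(-v))
  y <- truth(x) + rnorm(1000, 0, 0.02)
  m <- fit_calibration(x, y, method = "loess", span = 0.05)
  grid <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = 2000)
  expect_lt(max(abs(predict(m, grid) - truth(grid))), 0.05)
  # non-decreasing on a dense grid spanning beyond the domain
  wide <- seq(-8, 8, length.out = 10000)
  expect_true(all(diff(predict(m, wide)) >= -1e-12))
  # out-of-domain queries clamp to boundary values
  expect_equal(predict(m, -100), predict(m, min(x)))
  expect_equal(predict(m, 100), predict(m, max(x)))
})

test_that("calibration error shrinks as training size grows", {
  truth <- function(v) 1 / (1 + exp(-v))
  rmse <- function(n, seed) {
    set.seed(seed)
    x <- sort(runif(n, -6, 6))
    y <- truth(x) + rnorm(n, 0, 0.05)
    m <- fit_calibration(x, y, span = 0.05)
    g <- seq(-5, 5, length.out = 500)
    sqrt(mean((predict(m, g) - truth(g))^2))
  }
  r100 <- vapply(1:10, function(s) rmse(100, s), numeric(1))
  r1000 <- vapply(1:10, function(s) rmse(1000, s + 100), numeric(1))
  expect_lt(median(r1000), median(r100))
})

test_that("per-charge IM models recover distinct linear maps with pooled fallback", {
  set.seed(52)
  n <- 500
  exp2 <- runif(n, 0.8, 1.2); exp3 <- runif(n, 0.9, 1.4)
  im_exp <- c(exp2, exp3, runif(10, 0.8, 1.4))
  charge <- c(rep(2L, n), rep(3L, n), rep(4L, 10))
  im_pred <- c(0.10 + 0.95 * exp2, -0.05 + 1.10 * exp3,
               0.10 + 0.95 * im_exp[(2 * n + 1):(2 * n + 10)]) +
    rnorm(2 * n + 10, 0, 0.005)
  models <- fit_im_models(im_exp, im_pred, charge, span = 0.1, min_n = 50)
  expect_setequal(names(models), c("2", "3", "4"))
  g2 <- seq(0.85, 1.15, length.out = 50)
  expect_lt(max(abs(predict(models[["2"]], g2) - (0.10 + 0.95 * g2))), 0.02)
  g3 <- seq(0.95, 1.35, length.out = 50)
  expect_lt(max(abs(predict(models[["3"]], g3) - (-0.05 + 1.10 * g3))), 0.02)
  # charge 4 had 10 PSMs -> pooled fallback
  expect_equal(models[["4"]]$charge, "all")
  # single-charge data yields exactly one model
  one <- fit_im_models(exp2, 0.1 + 0.95 * exp2, rep(2L, n))
  expect_equal(names(one), "2")
})

test_that("delta features behave as arithmetic says, with IQR normalisation", {
  x <- seq(0, 100, length.out = 200)
  m <- fit_calibration(x, x, span = 0.1)
  expect_equal(delta_calibrated(m, 50, 50), 0, tolerance = 1e-9)
  expect_equal(delta_calibrated(m, 50, 53.5), 3.5, tolerance = 1e-6)
  # residual_scale = IQR of training residuals; normalised = delta / IQR
  m$residual_iqr <- 2.0
  expect_equal(delta_calibrated_normalized(m, 50, 53.5), 1.75, tolerance = 1e-6)
  # doubling the residual scale halves every normalised delta
  m2 <- m; m2$residual_iqr <- 4.0
  expect_equal(delta_calibrated_normalized(m2, 50, 53.5),
               delta_calibrated_normalized(m, 50, 53.5) / 2, tolerance = 1e-9)
  # a perfect fit (zero IQR) falls back to the raw delta with a warning
  m$residual_iqr <- 0
  expect_warning(d <- delta_calibrated_normalized(m, 50, 53.5), "IQR")
  expect_equal(d, 3.5, tolerance = 1e-6)
})

test_that("true pairs have smaller deltas than permuted pairs under a sigmoid warp", {
  set.seed(53)
  x <- sort(runif(800, 0, 120))
  truth <- function(v) 100 / (1 + exp(-8 * (v / 120 - 0.5)))
  y <- truth(x) + rnorm(800, 0, 1)
  m <- fit_calibration(x, y, span = 0.05)
  d_true <- delta_calibrated(m, x, y)
  d_perm <- delta_calibrated(m, x, sample(y))
  expect_lt(median(d_true), median(d_perm))
})

test_that("models serialise to JSON and restore the same mapping", {
  set.seed(54)
  x <- sort(runif(300, 0, 50)); y <- sqrt(x) + rnorm(300, 0, 0.05)
  m <- fit_calibration(x, y, span = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(m, path)
  m2 <- calibration_from_json(path)
  g <- seq(0, 50, length.out = 200)
  expect_equal(predict(m2, g), predict(m, g), tolerance = 1e-9)
  expect_equal(m2$residual_iqr, m$residual_iqr, tolerance = 1e-12)
})
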