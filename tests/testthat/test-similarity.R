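frag_tbl <- function(mz, intensity = rep(1, length(mz))) {
  tibble::tibble(mz = mz, intensity = intensity,
                 ion_type = rep("b", length(mz)),
                 position = seq_along(mz), frag_charge = 1L)
}

peaks_tbl <- function(mz, intensity) {
  o <- order(mz)
  tibble::tibble(mz = mz[o], intensity = intensity[o])
}

test_that("matching selects the highest-intensity peak within tolerance", {
  # 20 ppm around 500 Th is +/- 0.01 Th; both candidates are inside
  pk <- peaks_tbl(c(499.995, 500.005), c(200, 100))
  m <- match_fragments(pk, frag_tbl(500.0), tol_ppm = 20)
  expect_equal(m$exp_intensity, 200)
  # nothing in tolerance -> all-zero experimental vector
  m2 <- match_fragments(peaks_tbl(600, 50), frag_tbl(c(500, 501)), tol_ppm = 20)
  expect_equal(m2$exp_intensity, c(0, 0))
  expect_false(any(m2$matched))
  # identical peak lists reproduce the predicted intensities
  pk3 <- peaks_tbl(c(300, 400, 500), c(5, 7, 9))
  m3 <- match_fragments(pk3, frag_tbl(c(300, 400, 500), c(5, 7, 9)), tol_ppm = 20)
  expect_true(all(m3$matched))
  expect_equal(m3$exp_intensity, m3$pred_intensity)
})

test_that("intensity ties break to the closest, then lower, m/z deterministically", {
  pk <- peaks_tbl(c(499.996, 500.003), c(100, 100))
  m <- match_fragments(pk, frag_tbl(500.0), tol_ppm = 20)
  expect_equal(pk$mz[m$peak_idx], 500.003)  # closer of the equal-intensity pair
  pk2 <- peaks_tbl(c(499.996, 500.004), c(100, 100))
  m2 <- match_fragments(pk2, frag_tbl(500.0), tol_ppm = 20)
  expect_equal(pk2$mz[m2$peak_idx], 499.996)  # equidistant -> lower m/z
})

test_that("matching is invariant to experimental peak order", {
  set.seed(41)
  frag <- frag_tbl(sort(runif(10, 200, 1200)), rexp(10))
  mz <- c(frag$mz * (1 + runif(10, -1e-5, 1e-5)), runif(30, 200, 1200))
  inten <- rexp(40)
  a <- match_fragments(peaks_tbl(mz, inten), frag, 20)
  perm <- sample(40)
  b <- match_fragments(peaks_tbl(mz[perm], inten[perm]), frag, 20)
  expect_equal(a$exp_intensity, b$exp_intensity)
})

test_that("entropy similarity equals the brute-force oracle and honors boundaries", {
  expect_equal(spectral_entropy_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(spectral_entropy_similarity(c(2, 6), c(1, 3)), 1)
  # worked case: P=[0.5,0.5], Q=[1,0]
  expect_equal(spectral_entropy_similarity(c(0.5, 0.5), c(1, 0)),
               oracle_entropy_similarity(c(0.5, 0.5), c(1, 0)))
  expect_equal(spectral_entropy_similarity(rep(1, 3), c(0, 0, 0)), 0)
  expect_error(spectral_entropy_similarity(c(-1, 2), c(1, 1)), "negative")
  set.seed(42)
  for (i in 1:300) {
    v <- random_vector_pair()
    s <- spectral_entropy_similarity(v$p, v$q)
    expect_equal(s, oracle_entropy_similarity(v$p, v$q), tolerance = 1e-12)
    expect_gte(s, 0); expect_lte(s, 1)
    # symmetry (skip the all-zero convention case)
    if (sum(v$q) > 0) {
      expect_equal(s, spectral_entropy_similarity(v$q, v$p), tolerance = 1e-12)
    }
  }
})

test_that("auxiliary similarities match independently coded formulas", {
  set.seed(43)
  for (i in 1:50) {
    f <- sample(3:12, 1)
    p <- rexp(f); q <- rexp(f); q[runif(f) < 0.3] <- 0
    m <- tibble::tibble(mz = seq_len(f), pred_intensity = p, exp_intensity = q,
                        matched = q > 0, peak_idx = ifelse(q > 0, seq_len(f), NA))
    a <- auxiliary_similarities(m)
    expect_equal(a$cosine_similarity, sum(p * q) / sqrt(sum(p^2) * sum(q^2)))
    expect_equal(a$dot_product, sum(p / sum(p) * q / sum(q)))
    expect_equal(a$pearson_corr, if (sd(q) == 0) 0 else cor(p, q))
    expect_equal(a$spearman_corr, if (sd(q) == 0) 0 else cor(p, q, method = "spearman"))
    expect_equal(a$bray_curtis, 1 - sum(abs(p - q)) / (sum(p) + sum(q)))
    expect_equal(a$n_matched, sum(q > 0))
    expect_equal(a$frac_matched, mean(q > 0))
  }
  ident <- tibble::tibble(mz = 1:3, pred_intensity = c(1, 2, 3),
                          exp_intensity = c(1, 2, 3), matched = TRUE, peak_idx = 1:3)
  a <- auxiliary_similarities(ident)
  expect_equal(a$cosine_similarity, 1)
  expect_equal(a$frac_matched, 1)
  orth <- tibble::tibble(mz = 1:2, pred_intensity = c(1, 0), exp_intensity = c(0, 1),
                         matched = c(FALSE, TRUE), peak_idx = c(NA, 2L))
  expect_equal(auxiliary_similarities(orth)$cosine_similarity, 0)
})

test_that("peak consumption removes one peak per distinct selection", {
  set.seed(44)
  pk <- peaks_tbl(seq(100, 1000, by = 100), rexp(10))
  frag <- frag_tbl(c(200, 400, 600, 800))
  out <- consume_matched_peaks(pk, frag, 20)
  expect_equal(nrow(out), 6)
  expect_false(any(out$mz %in% c(200, 400, 600, 800)))
  # two fragments claiming one peak -> exactly one deletion
  frag2 <- frag_tbl(c(500.000, 500.001))
  out2 <- consume_matched_peaks(pk, frag2, 20)
  expect_equal(nrow(out2), 9)
  # no match -> no-op
  expect_equal(consume_matched_peaks(pk, frag_tbl(123.456), 20), pk)
})

test_that("targets beat shuffled decoys on median entropy similarity", {
  set.seed(45)
  target <- decoy <- numeric(200)
  for (i in 1:200) {
    f <- 12
    pred <- rexp(f)
    tgt <- pred * exp(rnorm(f, 0, 0.3))
    target[i] <- spectral_entropy_similarity(pred, tgt)
    decoy[i] <- spectral_entropy_similarity(pred, sample(tgt))
  }
  expect_gt(median(target), median(decoy))
})
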