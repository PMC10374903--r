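test_that("b and y ion m/z match hand-computed monoisotopic values", {
  # b2 of PEPTIDE = P + E + proton
  expect_equal(fragment_mz("PEPTIDE", "b", 2, 1),
               97.05276 + 129.04259 + 1.0072765, tolerance = 1e-4)
  # y1 of a K-terminated peptide = K + water + proton
  expect_equal(fragment_mz("AAAK", "y", 1, 1),
               128.09496 + 18.010565 + 1.0072765, tolerance = 1e-4)
  # doubly charged ion: (neutral + 2 protons) / 2
  neutral_b3 <- fragment_mz("PEPTIDE", "b", 3, 1) - mass_proton
  expect_equal(fragment_mz("PEPTIDE", "b", 3, 2),
               (neutral_b3 + 2 * mass_proton) / 2)
  expect_error(fragment_mz("PEPTIDE", "b", 7, 1), "out of range")
})

test_that("b_i + y_(n-i) neutral masses conserve the precursor mass", {
  set.seed(21)
  for (rep in 1:25) {
    s <- random_test_peptide()
    mods <- tibble::tibble(position = c(0L, sample(nchar(s), 1)),
                           delta = c(42.0106, 79.96633))
    n <- nchar(s)
    total <- peptide_mass(s, mods)
    for (i in seq_len(n - 1)) {
      b <- fragment_mz(s, "b", i, 1, mods) - mass_proton
      y <- fragment_mz(s, "y", n - i, 1, mods) - mass_proton
      expect_equal(b + y, total, tolerance = 1e-6)
    }
  }
})

test_that("shifting predicted fragments equals regenerating them for the modified peptide", {
  set.seed(22)
  for (rep in 1:30) {
    s <- random_test_peptide()
    n <- nchar(s)
    extra <- tibble::tibble(position = sample(0:n, 1), delta = 79.96633)
    base <- theoretical_fragments(s, mods = NULL)
    base$intensity <- stats::rexp(nrow(base))
    shifted <- shift_predicted_fragments(base, n, extra)
    regen <- theoretical_fragments(s, mods = extra)
    expect_equal(shifted$mz, regen$mz, tolerance = 1e-9)
    expect_identical(shifted$intensity, base$intensity)
  }
})

test_that("a shift covers exactly the fragments spanning the modified residue", {
  # +79.96633 on residue 3 of a 7-mer
  s <- "ACDEFGH"
  frag <- theoretical_fragments(s)
  frag$intensity <- 1
  shifted <- shift_predicted_fragments(frag, 7, tibble::tibble(position = 3L, delta = 79.96633))
  z1 <- shifted$frag_charge == 1
  delta <- (shifted$mz - frag$mz)[z1]
  ion <- frag$ion_type[z1]; pos <- frag$position[z1]
  expect_equal(delta[ion == "b" & pos < 3], rep(0, 2))
  expect_equal(delta[ion == "b" & pos >= 3], rep(79.96633, 4))
  expect_equal(delta[ion == "y" & pos <= 4], rep(0, 4))
  expect_equal(delta[ion == "y" & pos >= 5], rep(79.96633, 2))
  # doubly charged fragments move by delta/2
  z2 <- shifted$frag_charge == 2 & frag$ion_type == "b" & frag$position >= 3
  expect_equal(unique(round(shifted$mz[z2] - frag$mz[z2], 6)), round(79.96633 / 2, 6))
  # empty mod set is the identity
  expect_identical(shift_predicted_fragments(frag, 7, tibble::tibble(position = integer(0), delta = numeric(0))),
                   frag)
})

test_that("unannotated fragments are dropped with a warning when shifting", {
  frag <- tibble::tibble(mz = c(200, 300), intensity = c(1, 2),
                         ion_type = c("b", NA), position = c(2L, NA), frag_charge = c(1L, 1L))
  expect_warning(out <- shift_predicted_fragments(frag, 7, tibble::tibble(position = 1L, delta = 10)),
                 "unannotated")
  expect_equal(nrow(out), 1)
})
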