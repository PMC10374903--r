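# Independent oracles and tiny fixture builders used across the suite.

# Brute-force entropy similarity, written directly from the definition and
# kept independent of the package implementation.
oracle_entropy_similarity <- function(p, q) {
  if (sum(q) == 0) return(0)
  p <- p / sum(p)
  q <- q / sum(q)
  ent <- function(v) {
    s <- 0
    for (x in v) if (x > 0) s <- s - x * log(x)
    s
  }
  m <- (p + q) / 2
  1 - (2 * ent(m) - ent(p) - ent(q)) / log(4)
}

# Random non-negative matched-vector pair of length <= 12, with some zeros.
random_vector_pair <- function() {
  f <- sample(2:12, 1)
  p <- stats::rexp(f)
  q <- stats::rexp(f)
  q[stats::runif(f) < 0.3] <- 0
  if (stats::runif(1) < 0.1) q[] <- 0
  list(p = p, q = q)
}

# Hand-rolled residue-mass table (typed in independently of the package).
oracle_residue <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00918, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

random_test_peptide <- function(min_len = 7, max_len = 15) {
  paste(sample(names(oracle_residue), sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

# A 3-row pin file fixture; returns its path.
write_toy_pin <- function(path, extra_rows = NULL) {
  lines <- c(
    "SpecId\tLabel\tScanNr\thyperscore\tlog10_evalue\tPeptide\tProteins",
    "run.00101.00101.2_1\t1\t101\t25.1\t4\tK.PEPTIDEK.R\tsp|P1|A",
    "run.00102.00102.2_1\t-1\t102\t11.0\t1.2\tK.LLQSVAK.R\trev_sp|P2|B",
    "run.00103.00103.3_2\t1\t103\t18.5\t2.5\tK.MC[57.02146]AVLK.R\tsp|P3|C\textra_tab_protein",
    extra_rows
  )
  writeLines(lines, path)
  path
}

# Minimal spectra tibble from raw vectors (peaks given unsorted on purpose
# by some tests).
toy_spectra <- function(scan_nr, mz_list, intensity_list, rt_min = NULL,
                        im = NULL, charge = NULL) {
  n <- length(scan_nr)
  tibble::tibble(
    scan_nr = as.integer(scan_nr),
    rt_min = if (is.null(rt_min)) rep(NA_real_, n) else rt_min,
    im = if (is.null(im)) rep(NA_real_, n) else im,
    precursor_charge = if (is.null(charge)) rep(NA_integer_, n) else as.integer(charge),
    peaks = purrr::map2(mz_list, intensity_list, function(mz, i) {
      o <- order(mz)
      tibble::tibble(mz = mz[o], intensity = i[o])
    })
  )
}
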