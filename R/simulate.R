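# Synthetic test data: a predicted-property library, matching experimental
# spectra, and a pin file with controllable target/decoy structure, RT/IM
# warping and spectral noise — everything the pipeline consumes, generated
# from one seeded pseudo-random stream so runs are byte-reproducible.
#
# Targets: the scan's spectrum is the peptide's predicted fragments under
# multiplicative log-normal intensity noise, per-fragment dropout, and
# uniform background peaks; the peptide's predicted RT is the monotone warp
# of the scan's experimental RT plus Gaussian noise (so the calibration has
# a known ground truth), and likewise per charge for ion mobility. Decoys
# pair a scan with an unrelated peptide's prediction: the spectrum is built
# from a shadow peptide that never enters the pin file, and the decoy
# peptide's predicted RT/IM follow the warp of a different, random
# experimental coordinate.

#' Monotone RT warp families used by the simulator
#'
#' Maps experimental minutes (0..run length) onto a bounded predicted scale
#' (0..100): `"identity"` rescales linearly, `"linear"` applies slope 2 and
#' intercept 5 on the rescaled axis, `"sigmoid"` is a logistic squash —
#' the kind of nonlinearity that defeats a global linear calibration.
#'
#' @param kind Warp family.
#' @param run_minutes Gradient length in minutes.
#' @return Function mapping minutes to the predicted scale.
#' @export
rt_warp_fun <- function(kind = c("sigmoid", "identity", "linear"), run_minutes = 120) {
  kind <- arg_match(kind)
  switch(kind,
    identity = function(x) 100 * x / run_minutes,
    linear = function(x) 5 + 2 * (100 * x / run_minutes) * 0.45,
    sigmoid = function(x) 100 / (1 + exp(-8 * (x / run_minutes - 0.5)))
  )
}

random_peptides <- function(n, min_len = 7, max_len = 15) {
  aas <- names(aa_monoisotopic)
  vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(min_len:max_len, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# predicted fragments of a peptide: up to n_frags most intense b/y ions at
# charges 1-2 with log-normal intensities
simulate_prediction <- function(sequence, mods, n_frags = 12) {
  frag <- theoretical_fragments(sequence, mods, frag_charges = 1:2)
  frag$intensity <- stats::rlnorm(nrow(frag), meanlog = 5, sdlog = 1)
  frag <- frag[order(-frag$intensity), , drop = FALSE]
  # drop fragments nearly coincident in m/z with a more intense one, so the
  # highest-intensity-in-tolerance matching rule is unambiguous
  sep <- rep(TRUE, nrow(frag))
  for (i in seq_len(nrow(frag))[-1]) {
    prev <- frag$mz[seq_len(i - 1)][sep[seq_len(i - 1)]]
    if (any(abs(prev - frag$mz[i]) / frag$mz[i] < 25e-6)) sep[i] <- FALSE
  }
  frag <- frag[sep, , drop = FALSE]
  frag <- frag[seq_len(min(n_frags, nrow(frag))), , drop = FALSE]
  frag[order(frag$mz), c("mz", "intensity", "ion_type", "position", "frag_charge")]
}

#' Generate a synthetic rescoring data set
#'
#' Writes a prediction library, an MGF (or mzML) spectra file, a pin file
#' and a truth table to `outdir`. One PSM per scan at rank 1; in DIA mode a
#' fraction of scans additionally carries a rank-2 decoy PSM.
#'
#' @param outdir Output directory (created).
#' @param n_psms Number of rank-1 PSMs (default 400).
#' @param decoy_fraction Fraction of rank-1 PSMs that are decoys
#'   (default 0.5, the usual 1:1 target/decoy search).
#' @param noise_sigma Multiplicative log-normal intensity noise sd on target
#'   fragments (default 0.3, a realistic spectrum-prediction mismatch).
#' @param dropout Per-fragment probability that a predicted fragment is
#'   absent from the spectrum (default 0.1).
#' @param background_peaks Uniform background peaks added per spectrum
#'   (default 10).
#' @param rt_warp Warp family of [rt_warp_fun()] (default `"sigmoid"`).
#' @param rt_noise Gaussian sd of predicted-RT error around the warp, in
#'   predicted-scale units (default 1).
#' @param im_noise Gaussian sd of predicted-IM error (default 0.01 1/K0).
#' @param with_im Simulate ion mobility (per-charge linear maps;
#'   default TRUE).
#' @param mod_fraction Fraction of peptides carrying a variable modification
#'   (default 0.2); a quarter of those get an extra "unsupported"
#'   phospho-like +79.96633 Da to exercise the m/z-shift path.
#' @param dia_rank2_fraction In DIA mode, fraction of scans with a rank-2
#'   decoy PSM (default 0 = DDA-style).
#' @param run_minutes Gradient length (default 120 min).
#' @param library_dialect `"msp"` or `"tsv"`.
#' @param spectra_format `"mgf"` or `"mzml"`.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @return List with paths `library`, `spectra`, `pin`, `truth` and the
#'   truth tibble (`spec_id`, `label`, `peptide`, `charge`, `scan_nr`,
#'   `rt_exp`, `rt_pred_true`, `im_exp`, `evalue`).
#' @export
simulate_rescoring_data <- function(outdir,
                                    n_psms = 400,
                                    decoy_fraction = 0.5,
                                    noise_sigma = 0.3,
                                    dropout = 0.1,
                                    background_peaks = 10,
                                    rt_warp = "sigmoid",
                                    rt_noise = 1,
                                    im_noise = 0.01,
                                    with_im = TRUE,
                                    mod_fraction = 0.2,
                                    dia_rank2_fraction = 0,
                                    run_minutes = 120,
                                    library_dialect = c("msp", "tsv"),
                                    spectra_format = c("mgf", "mzml"),
                                    seed = 1L) {
  library_dialect <- arg_match(library_dialect)
  spectra_format <- arg_match(spectra_format)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(seed)
  warp <- rt_warp_fun(rt_warp, run_minutes)

  n_decoy <- round(n_psms * decoy_fraction)
  n_rank2 <- round(n_psms * dia_rank2_fraction)
  # pin peptides + shadow peptides whose spectra the decoy scans show
  n_pep <- n_psms + n_rank2 + n_decoy
  seqs <- unique(random_peptides(n_pep * 2))[seq_len(n_pep)]
  mods <- purrr::map(seq_along(seqs), function(i) {
    m <- tibble(position = integer(0), delta = numeric(0))
    s <- seqs[i]
    cpos <- which(strsplit(s, "")[[1]] == "C")
    if (length(cpos) > 0) m <- bind_rows(m, tibble(position = cpos, delta = 57.02146))
    if (stats::runif(1) < mod_fraction) {
      mpos <- which(strsplit(s, "")[[1]] == "M")
      if (length(mpos) > 0) {
        m <- bind_rows(m, tibble(position = mpos[1], delta = 15.9949))
      } else {
        m <- bind_rows(m, tibble(position = 0L, delta = 42.0106))
      }
    }
    m[order(m$position), , drop = FALSE]
  })
  charges <- sample(2:3, n_pep, replace = TRUE, prob = c(0.7, 0.3))
  predictions <- purrr::map2(seqs, mods, simulate_prediction)

  label <- c(rep(1L, n_psms - n_decoy), rep(-1L, n_decoy))[sample(n_psms)]
  scan_nr <- seq_len(n_psms) * 2L + 100L
  rt_exp <- sort(stats::runif(n_psms, 0.02, 0.98) * run_minutes)
  # per-charge IM linear maps: im_pred = a_z + b_z * im_exp
  im_a <- c(`2` = 0.10, `3` = -0.05)
  im_b <- c(`2` = 0.95, `3` = 1.10)
  im_exp <- if (with_im) stats::runif(n_psms, 0.8, 1.4) else rep(NA_real_, n_psms)

  pep_idx <- seq_len(n_psms)              # rank-1 PSM i shows peptide i
  shadow_idx <- rep(NA_integer_, n_psms)  # spectrum source for decoy scans
  shadow_pool <- n_psms + n_rank2 + seq_len(n_decoy)
  shadow_idx[label == -1L] <- shadow_pool[seq_len(sum(label == -1L))]

  z <- charges[pep_idx]
  rt_pred_true <- warp(rt_exp)
  rt_pred <- rt_pred_true + stats::rnorm(n_psms, 0, rt_noise)
  im_pred <- if (with_im) {
    im_a[as.character(z)] + im_b[as.character(z)] * im_exp +
      stats::rnorm(n_psms, 0, im_noise)
  } else rep(NA_real_, n_psms)
  # decoy peptides elute somewhere unrelated: their predictions follow the
  # warp of a random coordinate, not this scan's
  dec <- which(label == -1L)
  if (length(dec) > 0) {
    other_rt <- stats::runif(length(dec), 0.02, 0.98) * run_minutes
    rt_pred[dec] <- warp(other_rt) + stats::rnorm(length(dec), 0, rt_noise)
    if (with_im) {
      other_im <- stats::runif(length(dec), 0.8, 1.4)
      im_pred[dec] <- im_a[as.character(z[dec])] + im_b[as.character(z[dec])] * other_im +
        stats::rnorm(length(dec), 0, im_noise)
    }
  }

  # rank-2 DIA PSMs: decoys against already-used scans
  r2_scan <- if (n_rank2 > 0) sample(seq_len(n_psms), n_rank2) else integer(0)
  r2_pep <- n_psms + seq_len(n_rank2)
  r2_rt_pred <- warp(stats::runif(n_rank2, 0.02, 0.98) * run_minutes) +
    stats::rnorm(n_rank2, 0, rt_noise)
  r2_im_pred <- if (with_im && n_rank2 > 0) {
    im_a[as.character(charges[r2_pep])] + im_b[as.character(charges[r2_pep])] *
      stats::runif(n_rank2, 0.8, 1.4)
  } else rep(NA_real_, n_rank2)

  # library: predictions for every pin peptidoform (not the shadows)
  lib_rows <- c(pep_idx, r2_pep)
  lib_rt <- c(rt_pred, r2_rt_pred)
  lib_im <- if (with_im) c(im_pred, r2_im_pred) else rep(NA_real_, length(lib_rows))
  library <- new_library_tbl(
    seqs[lib_rows], mods[lib_rows], purrr::map_chr(mods[lib_rows], format_mods),
    charges[lib_rows], lib_rt, lib_im, predictions[lib_rows]
  )

  # spectra: target scans show their own peptide, decoy scans a shadow
  spectra <- purrr::map(seq_len(n_psms), function(i) {
    src <- if (label[i] == 1L) pep_idx[i] else shadow_idx[i]
    frag <- predictions[[src]]
    keep <- stats::runif(nrow(frag)) >= dropout
    mz <- frag$mz[keep]
    inten <- frag$intensity[keep] * exp(stats::rnorm(sum(keep), 0, noise_sigma))
    if (background_peaks > 0) {
      mz <- c(mz, stats::runif(background_peaks, 150, 1500))
      inten <- c(inten, exp(stats::rnorm(background_peaks, 3, 0.5)))
    }
    sort_peaks(tibble(mz = mz, intensity = inten))
  })
  spectra_tbl <- new_spectra_tbl(scan_nr, rt_exp, im_exp, z, spectra)

  # e-values: overlapping confidence, targets better than decoys
  neg_log10_e <- ifelse(label == 1L, stats::runif(n_psms, 3, 9),
                        stats::runif(n_psms, 0.2, 3.2))
  r2_neg_log10_e <- stats::runif(n_rank2, 0.2, 2.5)

  pin_pep <- vapply(seq_len(n_psms), function(i) {
    modpep_string(seqs[pep_idx[i]], mods[[pep_idx[i]]])
  }, character(1))
  r2_pin_pep <- vapply(r2_pep, function(i) modpep_string(seqs[i], mods[[i]]), character(1))

  spec_id <- sprintf("sim.%05d.%05d.%d_1", scan_nr, scan_nr, z)
  r2_spec_id <- sprintf("sim.%05d.%05d.%d_2", scan_nr[r2_scan], scan_nr[r2_scan],
                        charges[r2_pep])
  hyperscore <- round(ifelse(label == 1L, stats::rnorm(n_psms, 22, 3),
                             stats::rnorm(n_psms, 14, 3)), 3)
  pin_lines <- c(
    paste(c("SpecId", "Label", "ScanNr", "hyperscore", "log10_evalue",
            "Peptide", "Proteins"), collapse = "\t"),
    sprintf("%s\t%d\t%d\t%.3f\t%.4f\t%s\t%s",
            spec_id, label, scan_nr, hyperscore, neg_log10_e,
            paste0("K.", pin_pep, ".R"),
            ifelse(label == 1L, sprintf("sp|P%05d|PROT", pep_idx),
                   sprintf("rev_sp|P%05d|PROT", pep_idx))),
    if (n_rank2 > 0) {
      sprintf("%s\t-1\t%d\t%.3f\t%.4f\t%s\t%s",
              r2_spec_id, scan_nr[r2_scan],
              round(stats::rnorm(n_rank2, 12, 3), 3), r2_neg_log10_e,
              paste0("K.", r2_pin_pep, ".R"),
              sprintf("rev_sp|P%05d|PROT", r2_pep))
    }
  )

  lib_path <- file.path(outdir, paste0("library.", library_dialect))
  spec_path <- file.path(outdir, paste0("spectra.",
                                        if (spectra_format == "mgf") "mgf" else "mzML"))
  pin_path <- file.path(outdir, "psms.pin")
  truth_path <- file.path(outdir, "truth.tsv")
  write_prediction_library(library, lib_path, library_dialect)
  if (spectra_format == "mgf") write_mgf(spectra_tbl, spec_path) else write_mzml(spectra_tbl, spec_path)
  writeLines(pin_lines, pin_path)

  truth <- tibble(
    spec_id = c(spec_id, r2_spec_id),
    label = c(label, rep(-1L, n_rank2)),
    rank = c(rep(1L, n_psms), rep(2L, n_rank2)),
    peptide = c(pin_pep, r2_pin_pep),
    charge = c(z, charges[r2_pep]),
    scan_nr = c(scan_nr, scan_nr[r2_scan]),
    rt_exp = c(rt_exp, rt_exp[r2_scan]),
    rt_pred_true = c(rt_pred_true, rep(NA_real_, n_rank2)),
    rt_pred = c(rt_pred, r2_rt_pred),
    im_exp = c(im_exp, im_exp[r2_scan]),
    evalue = 10^(-c(neg_log10_e, r2_neg_log10_e))
  )
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(library = lib_path, spectra = spec_path, pin = pin_path,
       truth_path = truth_path, truth = truth, warp = warp)
}
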