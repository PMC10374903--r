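# End-to-end orchestration: extract peptides for prediction, fit per-file
# calibration and KDE models from confident PSMs, compute features per PSM
# (consuming peaks between DIA ranks), and write extended pin files.

#' Extract prediction targets from pin files
#'
#' Iterates over pin tables and collects the deduplicated union of
#' (sequence, modifications, charge) over targets AND decoys — every
#' peptidoform matched to at least one PSM needs a prediction. Peptidoforms
#' carrying modifications the prediction model does not support are also
#' emitted as their supported-only counterpart (`request_key`), together
#' with the extra modifications to shift by at lookup time.
#'
#' @param pins A `pin_tbl` or list of them.
#' @param supported_mods Mass deltas the model supports (matched within
#'   0.001 Da).
#' @return Tibble with one row per unique peptidoform: `key`, `sequence`,
#'   `mods_str`, `charge`, `supported` (no unsupported modifications),
#'   `request_key` (key to request/look up in the library) and `extra_mods`
#'   (list-column of modifications to shift by; empty when supported).
#' @export
extract_prediction_targets <- function(pins, supported_mods = c(57.02146, 15.9949, 42.0106)) {
  if (inherits(pins, "pin_tbl")) pins <- list(pins)
  psms <- bind_rows(lapply(pins, parse_pin_psms))
  uni <- psms |> distinct(.data$key, .keep_all = TRUE)
  split_mods <- purrr::map(uni$mods, function(m) {
    if (nrow(m) == 0) return(list(sup = m, extra = m))
    is_sup <- vapply(m$delta, function(d) any(abs(d - supported_mods) < 1e-3), logical(1))
    list(sup = m[is_sup, , drop = FALSE], extra = m[!is_sup, , drop = FALSE])
  })
  extra <- purrr::map(split_mods, "extra")
  sup_str <- purrr::map_chr(purrr::map(split_mods, "sup"), format_mods)
  tibble(
    key = uni$key,
    sequence = uni$sequence,
    mods_str = uni$mods_str,
    charge = uni$charge,
    supported = purrr::map_int(extra, nrow) == 0L,
    request_key = peptide_key(uni$sequence, sup_str, uni$charge),
    extra_mods = extra
  )
}

# Look up a PSM's predicted entry, shifting fragments for unsupported mods.
# Returns NULL when neither the exact nor the supported-only key is present.
lookup_entry <- function(library, sequence, mods, charge, supported_mods) {
  key <- peptide_key(sequence, format_mods(mods), charge)
  i <- match(key, library$key)
  if (!is.na(i)) {
    return(list(fragments = library$fragments[[i]],
                rt_pred = library$rt_pred[i], im_pred = library$im_pred[i]))
  }
  if (nrow(mods) == 0) return(NULL)
  is_sup <- vapply(mods$delta, function(d) any(abs(d - supported_mods) < 1e-3), logical(1))
  if (all(is_sup)) return(NULL)
  base_key <- peptide_key(sequence, format_mods(mods[is_sup, , drop = FALSE]), charge)
  i <- match(base_key, library$key)
  if (is.na(i)) return(NULL)
  frag <- shift_predicted_fragments(library$fragments[[i]], nchar(sequence),
                                    mods[!is_sup, , drop = FALSE])
  # predicted RT/IM are reused unchanged from the unmodified counterpart
  list(fragments = frag, rt_pred = library$rt_pred[i], im_pred = library$im_pred[i])
}

#' Compute rescoring features for one pin / spectra file pair
#'
#' Calibration models and KDE bin sets are fitted from this file's confident
#' rank-1 target PSMs, then every PSM (all ranks up to `config$top_ranks`)
#' receives every configured feature. Within a scan PSMs are processed in
#' ascending rank; in DIA mode each PSM's matched experimental peaks are
#' consumed before the next rank is matched. PSMs whose scan is missing from
#' the spectra, or whose peptidoform has no library entry, carry the
#' missing-value sentinels.
#'
#' @param pin A `pin_tbl`.
#' @param spectra Spectra tibble from [read_spectra()].
#' @param library Library tibble from [read_prediction_library()].
#' @param config A [rescore_config()].
#' @return Tibble with `spec_id`, `label`, `scan_nr`, `rank`, plus one
#'   column per configured feature, in pin row order.
#' @export
compute_features <- function(pin, spectra, library, config = rescore_config()) {
  psms <- parse_pin_psms(pin)
  feats <- config$features
  n <- nrow(psms)

  spec_idx <- match(psms$scan_nr, spectra$scan_nr)
  entries <- purrr::pmap(list(psms$sequence, psms$mods, psms$charge),
                         lookup_entry, library = library,
                         supported_mods = config$supported_mods)
  rt_pred <- purrr::map_dbl(entries, ~ if (is.null(.x)) NA_real_ else .x$rt_pred)
  im_pred <- purrr::map_dbl(entries, ~ if (is.null(.x)) NA_real_ else .x$im_pred)
  rt_exp <- spectra$rt_min[spec_idx]
  im_exp <- spectra$im[spec_idx]

  need_rt <- any(c("delta_rt_loess", "delta_rt_loess_normalized",
                   "rt_probability_uniform_prior") %in% feats)
  need_im <- any(c("delta_im_loess", "im_probability_uniform_prior") %in% feats)

  # --- per-file models from confident rank-1 targets -----------------------
  rt_model <- NULL; rt_bins <- NULL; im_models <- NULL; im_binsets <- NULL
  sel <- NULL
  if (need_rt || need_im) {
    sel <- tryCatch(
      select_calibration_psms(psms, config$evalue_threshold,
                              config$calib_max_n, config$calib_min_n),
      error = function(e) {
        warn(paste0(conditionMessage(e), " — RT/IM features fall back to sentinels"))
        NULL
      }
    )
  }
  if (!is.null(sel)) {
    crows <- match(sel$psms$spec_id, psms$spec_id)
    c_rt_exp <- rt_exp[crows]; c_rt_pred <- rt_pred[crows]
    c_im_exp <- im_exp[crows]; c_im_pred <- im_pred[crows]
    c_charge <- psms$charge[crows]; c_ev <- psms$evalue[crows]
    ok_rt <- !is.na(c_rt_exp) & !is.na(c_rt_pred)
    if (need_rt && sum(ok_rt) >= 2) {
      method <- if (sum(ok_rt) >= config$calib_min_n) sel$method else "linear"
      rt_model <- fit_calibration(c_rt_exp[ok_rt], c_rt_pred[ok_rt],
                                  method = method, span = config$rt_span)
      rt_bins <- build_kde_bins(c_rt_exp[ok_rt], c_rt_pred[ok_rt], c_ev[ok_rt],
                                bin_width = config$rt_bin_width,
                                weight_rule = config$kde_weight_rule,
                                percentile = config$kde_percentile)
    }
    ok_im <- !is.na(c_im_exp) & !is.na(c_im_pred)
    if (need_im && sum(ok_im) >= 2) {
      im_models <- fit_im_models(c_im_exp[ok_im], c_im_pred[ok_im], c_charge[ok_im],
                                 span = config$im_span, min_n = config$calib_min_n)
      im_binsets <- lapply(split(which(ok_im), c_charge[ok_im]), function(rows) {
        build_kde_bins(c_im_exp[rows], c_im_pred[rows], c_ev[rows],
                       bin_width = config$im_bin_width,
                       weight_rule = config$kde_weight_rule,
                       percentile = config$kde_percentile)
      })
    } else if (need_im && sum(ok_im) < 2) {
      warn("no usable ion mobility values; IM features fall back to sentinels")
    }
  }

  # --- per-PSM spectral features, rank order within scan -------------------
  spectral_feats <- intersect(feats, c("unweighted_spectral_entropy",
                                       "cosine_similarity", "dot_product",
                                       "pearson_corr", "spearman_corr",
                                       "bray_curtis", "n_matched", "frac_matched"))
  out <- matrix(NA_real_, nrow = n, ncol = length(feats),
                dimnames = list(NULL, feats))
  if (length(spectral_feats) > 0) {
    peak_state <- new.env(parent = emptyenv())
    ord <- order(psms$scan_nr, psms$rank)
    for (i in ord) {
      if (psms$rank[i] > config$top_ranks && config$mode == "dia") next
      entry <- entries[[i]]
      si <- spec_idx[i]
      if (is.null(entry) || is.na(si) || nrow(entry$fragments) == 0) next
      skey <- as.character(psms$scan_nr[i])
      peaks <- if (config$mode == "dia" && !is.null(peak_state[[skey]])) {
        peak_state[[skey]]
      } else {
        spectra$peaks[[si]]
      }
      matched <- match_fragments(peaks, entry$fragments, config$tol_ppm, config$tol_da)
      if ("unweighted_spectral_entropy" %in% spectral_feats) {
        out[i, "unweighted_spectral_entropy"] <-
          spectral_entropy_similarity(matched$pred_intensity, matched$exp_intensity)
      }
      aux <- setdiff(spectral_feats, "unweighted_spectral_entropy")
      if (length(aux) > 0) {
        vals <- auxiliary_similarities(matched)
        for (a in aux) out[i, a] <- vals[[a]]
      }
      if (config$mode == "dia") {
        drop <- unique(matched$peak_idx[matched$matched])
        peak_state[[skey]] <- if (length(drop) > 0) peaks[-drop, , drop = FALSE] else peaks
      }
    }
  }

  # --- RT / IM features ----------------------------------------------------
  if ("delta_rt_loess" %in% feats && !is.null(rt_model)) {
    out[, "delta_rt_loess"] <- delta_calibrated(rt_model, rt_exp, rt_pred)
  }
  if ("delta_rt_loess_normalized" %in% feats && !is.null(rt_model)) {
    out[, "delta_rt_loess_normalized"] <- suppressWarnings(
      delta_calibrated_normalized(rt_model, rt_exp, rt_pred))
  }
  if ("rt_probability_uniform_prior" %in% feats && !is.null(rt_bins)) {
    out[, "rt_probability_uniform_prior"] <-
      probability_with_uniform_prior(rt_bins, rt_exp, rt_pred)
  }
  if (need_im && !is.null(im_models)) {
    for (z in names(im_models)) {
      rows <- which(as.character(psms$charge) == z)
      if (length(rows) == 0) next
      if ("delta_im_loess" %in% feats) {
        out[rows, "delta_im_loess"] <-
          delta_calibrated(im_models[[z]], im_exp[rows], im_pred[rows])
      }
      if ("im_probability_uniform_prior" %in% feats && !is.null(im_binsets[[z]])) {
        out[rows, "im_probability_uniform_prior"] <-
          probability_with_uniform_prior(im_binsets[[z]], im_exp[rows], im_pred[rows])
      }
    }
  }

  # --- sentinels: similarities 0, deltas large, probabilities P_U ----------
  n_missing <- sum(is.na(out))
  for (f in feats) {
    miss <- is.na(out[, f])
    if (!any(miss)) next
    out[miss, f] <- sentinel_value(f, config, rt_bins, im_binsets)
  }
  if (n_missing > 0) {
    inform(sprintf("%d feature value(s) filled with sentinels (missing scan, library entry, or model)",
                   n_missing))
  }
  bind_cols(
    psms[, c("spec_id", "label", "scan_nr", "rank")],
    as_tibble(out)
  )
}

sentinel_value <- function(feature, config, rt_bins, im_binsets) {
  if (feature %in% c("delta_rt_loess", "delta_rt_loess_normalized", "delta_im_loess")) {
    return(config$delta_sentinel)
  }
  if (feature == "rt_probability_uniform_prior") {
    return(if (!is.null(rt_bins)) rt_bins$P_U else 0)
  }
  if (feature == "im_probability_uniform_prior") {
    if (!is.null(im_binsets) && length(im_binsets) > 0) return(im_binsets[[1]]$P_U)
    return(0)
  }
  0  # similarities and counts
}

#' Annotate a pin table with computed features
#'
#' Runs [compute_features()] and returns the pin table with the new feature
#' columns inserted (written before the Peptide column on output). Original
#' columns, row order and values are untouched.
#'
#' @inheritParams compute_features
#' @param out Optional path; when given the extended pin file is written.
#' @return The feature tibble, invisibly when `out` is given; the written
#'   path is attached as attribute `path`.
#' @export
annotate_file_pair <- function(pin, spectra, library, config = rescore_config(),
                               out = NULL) {
  feats <- compute_features(pin, spectra, library, config)
  if (!is.null(out)) {
    new_features <- lapply(config$features, function(f) {
      stats::setNames(feats[[f]], feats$spec_id)
    })
    names(new_features) <- config$features
    write_pin(pin, out, new_features)
    attr(feats, "path") <- out
    return(invisible(feats))
  }
  feats
}

#' Run the full rescoring-feature pipeline
#'
#' Reads each pin / spectra pair, computes features against the prediction
#' library and writes `<pin stem>_rescored.pin` next to `out_dir`. Entirely
#' deterministic: identical inputs and config give byte-identical outputs.
#'
#' @param pin_paths,spectra_paths Parallel vectors of file paths.
#' @param library_path Prediction library (msp or TSV).
#' @param out_dir Output directory (created if needed).
#' @param config A [rescore_config()].
#' @return Tibble with one row per file pair: input paths, output path,
#'   PSM count, and per-file median of each feature (targets and decoys
#'   separately), invisibly.
#' @export
run_rescoring <- function(pin_paths, spectra_paths, library_path,
                          out_dir, config = rescore_config()) {
  stopifnot(length(pin_paths) == length(spectra_paths))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  library <- read_prediction_library(library_path)
  summaries <- purrr::map2(pin_paths, spectra_paths, function(pp, sp) {
    t0 <- Sys.time()
    pin <- read_pin(pp, config$evalue_column, config$evalue_transform)
    spectra <- read_spectra(sp)
    out <- file.path(out_dir, paste0(sub("\\.pin$", "", basename(pp)), "_rescored.pin"))
    feats <- annotate_file_pair(pin, spectra, library, config, out = out)
    med <- feats |>
      group_by(is_target = .data$label == 1L) |>
      summarise(dplyr::across(dplyr::all_of(config$features), median), .groups = "drop")
    inform(sprintf("%s: %d PSMs annotated with %d features in %.1f s -> %s",
                   basename(pp), nrow(feats), length(config$features),
                   as.numeric(difftime(Sys.time(), t0, units = "secs")), out))
    tibble(pin = pp, spectra = sp, out = out, n_psms = nrow(feats),
           medians = list(med))
  })
  invisible(bind_rows(summaries))
}
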