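# Run configuration.

rescore_feature_names <- c(
  "unweighted_spectral_entropy",
  "delta_rt_loess", "delta_rt_loess_normalized",
  "rt_probability_uniform_prior",
  "delta_im_loess", "im_probability_uniform_prior",
  # optional "multiple correlated features" set
  "cosine_similarity", "dot_product", "pearson_corr", "spearman_corr",
  "bray_curtis", "n_matched", "frac_matched"
)

#' Build a run configuration
#'
#' @param mode `"dda"` (single-rank; no peak consumption) or `"dia"`
#'   (multi-rank; after each PSM its matched experimental peaks are removed
#'   before the next rank of the same scan is processed).
#' @param top_ranks PSM ranks to process per scan; forced to 1 in DDA mode,
#'   defaults to 3 in DIA mode (use 5 for conventional wide-window DIA).
#' @param tol_ppm Fragment match tolerance in ppm (default 20, the usual
#'   search tolerance).
#' @param tol_da Optional absolute tolerance in Th, overriding `tol_ppm`.
#' @param features Feature columns to compute (see Details).
#' @param evalue_column,evalue_transform How to recover e-values from the
#'   pin file (see [read_pin()]).
#' @param evalue_threshold,calib_max_n,calib_min_n Calibration PSM selection
#'   (see [select_calibration_psms()]).
#' @param rt_span,im_span LOESS bandwidths (defaults 0.05 and 0.1).
#' @param rt_bin_width,im_bin_width KDE bin widths (defaults 1 min and
#'   0.01 1/K0).
#' @param kde_percentile Percentile defining the uniform-prior pseudo-count
#'   (default 0.10).
#' @param kde_weight_rule Function mapping e-values to integer bin
#'   multiplicities (default [default_psm_weight()]).
#' @param supported_mods Mass deltas the prediction model supports; peptides
#'   with other modifications are looked up without them and their predicted
#'   fragments are m/z-shifted.
#' @param delta_sentinel Missing-value sentinel for delta features (default
#'   100, a worst-case deviation); similarities use 0 and probabilities use
#'   `P_U`, so downstream rescoring always receives numerics, never NaN.
#' @details Available features: `unweighted_spectral_entropy`,
#'   `delta_rt_loess`, `delta_rt_loess_normalized`,
#'   `rt_probability_uniform_prior`, `delta_im_loess`,
#'   `im_probability_uniform_prior`, plus the optional correlated set
#'   `cosine_similarity`, `dot_product`, `pearson_corr`, `spearman_corr`,
#'   `bray_curtis`, `n_matched`, `frac_matched`.
#' @return A list of class `rescore_config`.
#' @export
rescore_config <- function(mode = c("dda", "dia"),
                           top_ranks = NULL,
                           tol_ppm = 20,
                           tol_da = NULL,
                           features = c("unweighted_spectral_entropy",
                                        "delta_rt_loess",
                                        "rt_probability_uniform_prior"),
                           evalue_column = "log10_evalue",
                           evalue_transform = "pow10_of_negated",
                           evalue_threshold = 10^-3.5,
                           calib_max_n = 5000,
                           calib_min_n = 50,
                           rt_span = 0.05,
                           im_span = 0.1,
                           rt_bin_width = 1,
                           im_bin_width = 0.01,
                           kde_percentile = 0.10,
                           kde_weight_rule = default_psm_weight,
                           supported_mods = c(57.02146, 15.9949, 42.0106),
                           delta_sentinel = 100) {
  mode <- arg_match(mode)
  unknown <- setdiff(features, rescore_feature_names)
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature name(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(top_ranks)) top_ranks <- if (mode == "dda") 1L else 3L
  if (mode == "dda") top_ranks <- 1L
  structure(
    list(mode = mode, top_ranks = as.integer(top_ranks), tol_ppm = tol_ppm,
         tol_da = tol_da, features = features,
         evalue_column = evalue_column, evalue_transform = evalue_transform,
         evalue_threshold = evalue_threshold,
         calib_max_n = calib_max_n, calib_min_n = calib_min_n,
         rt_span = rt_span, im_span = im_span,
         rt_bin_width = rt_bin_width, im_bin_width = im_bin_width,
         kde_percentile = kde_percentile, kde_weight_rule = kde_weight_rule,
         supported_mods = supported_mods, delta_sentinel = delta_sentinel),
    class = "rescore_config"
  )
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value` (`#` comments allowed). Values holding
#' commas become character vectors; numerics are converted. Recognised keys
#' are the arguments of [rescore_config()].
#'
#' @param path Path to the config file.
#' @return A `rescore_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  args <- list()
  for (l in lines) {
    key <- trimws(sub("=.*$", "", l))
    val <- trimws(sub("^[^=]*=", "", l))
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    args[[key]] <- val
  }
  do.call(rescore_config, args)
}
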