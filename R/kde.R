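# Per-experimental-bin kernel density estimates of predicted RT/IM, and the
# "probability with uniform prior" feature.
#
# The experimental axis is cut into equal bins (1 min for RT, 0.01 1/K0 for
# IM by default). Each confident PSM contributes its predicted value to the
# bin of its experimental value with an integer multiplicity derived from
# its e-value, so better-scoring PSMs weigh more. Each bin then gets a
# Gaussian KDE with Silverman's rule-of-thumb bandwidth. The feature blends
# the bin's KDE density P_E at the predicted value with a uniform prior
# density P_U over the whole predicted range:
#
#     (P_U * U) / (U + E)  +  (P_E * E) / (U + E)
#
# where E is the queried bin's weighted count and U the weighted count of
# the bin at a preset percentile (10th by default) of the bin-size
# distribution. The prior damps sparsely populated bins: a single-PSM bin
# cannot claim an artificially high probability.

#' Default e-value to multiplicity rule
#'
#' `clamp(floor(-log10(e)), 1, 10)`: an e-value of 1e-6 contributes 6
#' copies, 1e-2 contributes 2, anything weaker than 1e-1 contributes 1, and
#' the multiplicity saturates at 10.
#'
#' @param evalue Positive e-values.
#' @return Integer multiplicities in 1..10.
#' @export
default_psm_weight <- function(evalue) {
  as.integer(pmin(pmax(floor(-log10(evalue)), 1), 10))
}

#' Build per-bin weighted KDE distributions of predicted values
#'
#' @param experimental Experimental values (minutes for RT, 1/K0 for IM).
#' @param predicted Predicted values on the predicted scale.
#' @param evalue E-values driving the multiplicity (`NULL` for weight 1).
#' @param bin_width Experimental bin width (1 for RT minutes, 0.01 for IM).
#' @param weight_rule Function e-value -> integer multiplicity.
#' @param percentile Percentile of the ascending bin-size distribution that
#'   defines the pseudo-count `U` (default 0.10, nearest-rank).
#' @param predicted_range Range `(lo, hi)` over which the uniform prior is
#'   spread; defaults to the observed predicted range padded by 1% on each
#'   side.
#' @param charge Charge this bin set applies to (`"all"` when pooled; IM bin
#'   sets are built per charge).
#' @return An object of class `kde_binset`: per-bin weighted samples, total
#'   weighted counts `E`, Silverman bandwidths, and the uniform-prior
#'   parameters `P_U` and `U`.
#' @export
build_kde_bins <- function(experimental, predicted, evalue = NULL, bin_width = 1,
                           weight_rule = default_psm_weight, percentile = 0.10,
                           predicted_range = NULL, charge = "all") {
  keep <- !is.na(experimental) & !is.na(predicted)
  experimental <- experimental[keep]; predicted <- predicted[keep]
  if (length(experimental) == 0) abort("no PSMs to build KDE bins from")
  w <- if (is.null(evalue)) rep(1L, length(experimental)) else weight_rule(evalue[keep])
  if (is.null(predicted_range)) {
    pr <- range(predicted)
    pad <- 0.01 * diff(pr)
    if (pad == 0) pad <- max(abs(pr[1]), 1) * 0.01
    predicted_range <- c(pr[1] - pad, pr[2] + pad)
  }
  if (predicted_range[2] <= predicted_range[1]) abort("predicted range must have positive width")
  bin <- as.integer(floor(experimental / bin_width))
  bins <- lapply(split(rep(predicted, w), rep(bin, w)), function(sample) {
    m <- length(sample)
    s <- if (m > 1) sd(sample) else 0
    bw <- 1.06 * s * m^(-1 / 5)
    if (!is.finite(bw) || bw <= 0) bw <- 0.1 * bin_width  # degenerate bins get a floor
    list(sample = sample, E = m, bw = bw)
  })
  E_sorted <- sort(unname(vapply(bins, `[[`, numeric(1), "E")))
  idx <- max(1L, ceiling(percentile * length(E_sorted)))  # nearest-rank
  structure(
    list(
      bins = bins, bin_width = bin_width,
      P_U = 1 / diff(predicted_range), U = E_sorted[idx],
      predicted_range = predicted_range, percentile = percentile,
      charge = charge
    ),
    class = "kde_binset"
  )
}

#' @export
print.kde_binset <- function(x, ...) {
  cat(sprintf("<kde_binset> %d bins (width %g), charge %s, P_U = %.4g, U = %g\n",
              length(x$bins), x$bin_width, as.character(x$charge), x$P_U, x$U))
  invisible(x)
}

#' @describeIn build_kde_bins tidy() returns one row per bin with its index,
#'   weighted count and bandwidth.
#' @param x A `kde_binset`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kde_binset <- function(x, ...) {
  tibble(
    bin = as.integer(names(x$bins)),
    E = vapply(x$bins, `[[`, numeric(1), "E"),
    bandwidth = vapply(x$bins, `[[`, numeric(1), "bw")
  ) |> arrange(.data$bin)
}

#' @describeIn build_kde_bins glance() returns a one-row summary.
#' @exportS3Method generics::glance
glance.kde_binset <- function(x, ...) {
  E <- vapply(x$bins, `[[`, numeric(1), "E")
  tibble(n_bins = length(x$bins), bin_width = x$bin_width,
         charge = as.character(x$charge), P_U = x$P_U, U = x$U,
         total_weight = sum(E), median_E = median(E))
}

# Gaussian KDE density at x for one bin
kde_density <- function(bin, x) {
  mean(dnorm(x, mean = bin$sample, sd = bin$bw))
}

#' KDE probability with a uniform prior
#'
#' @param binset A `kde_binset`.
#' @param experimental Experimental value(s) selecting the bin.
#' @param predicted Predicted value(s) at which the bin's KDE is evaluated.
#' @return `(P_U*U)/(U+E) + (P_E*E)/(U+E)`, vectorised; an empty bin
#'   (`E = 0`) returns exactly `P_U`.
#' @export
#' @examples
#' # worked example: U=10, E=30, P_U=0.01, P_E=0.2 -> 0.1525
probability_with_uniform_prior <- function(binset, experimental, predicted) {
  stopifnot(inherits(binset, "kde_binset"))
  n <- max(length(experimental), length(predicted))
  experimental <- rep_len(experimental, n)
  predicted <- rep_len(predicted, n)
  vapply(seq_len(n), function(i) {
    if (is.na(experimental[i]) || is.na(predicted[i])) return(NA_real_)
    key <- as.character(as.integer(floor(experimental[i] / binset$bin_width)))
    bin <- binset$bins[[key]]
    if (is.null(bin)) return(binset$P_U)
    P_E <- kde_density(bin, predicted[i])
    blend_uniform_prior(binset$P_U, binset$U, P_E, bin$E)
  }, numeric(1))
}

#' @rdname probability_with_uniform_prior
#' @param P_U Uniform prior density.
#' @param U Prior pseudo-count.
#' @param P_E Empirical (KDE) density.
#' @param E Bin weighted count.
#' @export
blend_uniform_prior <- function(P_U, U, P_E, E) {
  if (U + E <= 0) return(P_U)
  (P_U * U) / (U + E) + (P_E * E) / (U + E)
}
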