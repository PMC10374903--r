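# Monotone calibration of experimental RT (minutes) or ion mobility (1/K0)
# onto the predicted scale.
#
# Confident rank-1 target PSMs train a local (LOESS, degree 1, tricube
# weights) regression of predicted on experimental values; the fitted values
# at the training abscissae are then passed through isotonic regression
# (pool-adjacent-violators) to enforce a non-decreasing mapping, and linear
# interpolation between the training abscissae gives the final piecewise
# mapping. Queries outside the training domain clamp to the boundary values.
# With too few confident PSMs an ordinary least-squares line is used instead.

#' Select PSMs for calibration
#'
#' Only rank-1 target PSMs are considered. Those with e-value below the
#' threshold qualify; if more than `max_n` qualify, the `max_n` with the
#' lowest e-values are kept. The returned `method` flag is `"loess"` when at
#' least `min_n` PSMs qualify and `"linear"` otherwise.
#'
#' @param psms Tibble from [parse_pin_psms()] (needs `rank`, `label`,
#'   `evalue`).
#' @param evalue_threshold Qualification threshold (default `10^-3.5`,
#'   below which decoy matches are essentially absent).
#' @param max_n Cap on the training-set size (default 5000).
#' @param min_n Below this count the linear fallback is used (default 50).
#' @return List with `psms` (the qualifying subset, ascending e-value) and
#'   `method` (`"loess"` or `"linear"`). Zero qualifying PSMs is an error;
#'   skip RT/IM features for the file in that case.
#' @export
select_calibration_psms <- function(psms, evalue_threshold = 10^-3.5,
                                    max_n = 5000, min_n = 50) {
  cand <- psms |>
    filter(.data$rank == 1L, .data$label == 1L, !is.na(.data$evalue),
           .data$evalue < evalue_threshold) |>
    arrange(.data$evalue)
  if (nrow(cand) == 0) {
    abort("no confident PSMs below the e-value threshold; skip RT/IM features for this file")
  }
  if (nrow(cand) > max_n) cand <- slice(cand, seq_len(max_n))
  list(psms = cand, method = if (nrow(cand) >= min_n) "loess" else "linear")
}

#' Fit a monotone calibration model
#'
#' @param experimental,predicted Paired training values (experimental scale
#'   -> predicted scale).
#' @param method `"loess"` (local linear fit, then isotonic regression, then
#'   piecewise-linear interpolation) or `"linear"` (ordinary least squares).
#' @param span LOESS bandwidth as the fraction of points in each local
#'   window; defaults used by the pipeline are 0.05 for RT and 0.1 for IM.
#'   The effective span is floored at `min(1, 30/n)` so each window holds
#'   enough points for a degree-1 local fit.
#' @param charge Charge this model applies to (`"all"` for pooled).
#' @return An object of class `rescore_calibration` with the mapping, its
#'   domain, knots, training size and the IQR of absolute training residuals
#'   (used by the normalised delta feature).
#' @export
fit_calibration <- function(experimental, predicted, method = c("loess", "linear"),
                            span = 0.05, charge = "all") {
  method <- arg_match(method)
  keep <- !is.na(experimental) & !is.na(predicted)
  x <- experimental[keep]
  y <- predicted[keep]
  if (length(unique(x)) < 2) abort("need at least 2 distinct experimental values")
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  if (method == "linear") {
    fit <- lm(y ~ x)
    cf <- coef(fit)
    knots <- tibble(x = range(x), y = unname(cf[1] + cf[2] * range(x)))
    # clamped like the loess mapping, so every model shares one domain rule
    mapping <- function(v) approx(knots$x, knots$y, xout = v, rule = 2, ties = "ordered")$y
    fitted_train <- mapping(x)
  } else {
    n <- length(x)
    span_eff <- max(span, min(1, 30 / n))
    lo <- loess(y ~ x, span = span_eff, degree = 1, family = "gaussian",
                control = loess.control(surface = "direct"))
    smoothed <- predict(lo, newdata = data.frame(x = x))
    iso <- isoreg(x, smoothed)
    yf <- if (is.null(iso$ord)) iso$yf else iso$yf[order(iso$ord)]
    # collapse duplicate abscissae to their mean fitted value
    knots <- tibble(x = x, y = yf) |>
      group_by(.data$x) |>
      summarise(y = mean(.data$y), .groups = "drop") |>
      arrange(.data$x)
    mapping <- function(v) {
      approx(knots$x, knots$y, xout = v, rule = 2, ties = "ordered")$y
    }
    fitted_train <- mapping(x)
  }
  structure(
    list(
      kind = if (method == "linear") "linear" else "loess_monotone",
      knots = knots,
      domain = range(x),
      n_train = length(x),
      span = if (method == "loess") span else NA_real_,
      charge = charge,
      residual_iqr = IQR(abs(fitted_train - y)),
      mapping = mapping
    ),
    class = "rescore_calibration"
  )
}

#' @export
predict.rescore_calibration <- function(object, newdata, ...) {
  object$mapping(newdata)
}

#' @export
print.rescore_calibration <- function(x, ...) {
  cat(sprintf("<rescore_calibration> %s, charge %s, n_train = %d, domain [%.3g, %.3g], residual IQR = %.4g\n",
              x$kind, as.character(x$charge), x$n_train, x$domain[1], x$domain[2],
              x$residual_iqr))
  invisible(x)
}

#' @describeIn fit_calibration tidy() returns the mapping knots.
#' @param x A `rescore_calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rescore_calibration <- function(x, ...) {
  rename(x$knots, experimental = "x", calibrated = "y")
}

#' @describeIn fit_calibration glance() returns a one-row fit summary.
#' @exportS3Method generics::glance
glance.rescore_calibration <- function(x, ...) {
  tibble(
    kind = x$kind, charge = as.character(x$charge), n_train = x$n_train,
    span = x$span, domain_min = x$domain[1], domain_max = x$domain[2],
    residual_iqr = x$residual_iqr
  )
}

#' Per-charge ion-mobility calibration
#'
#' One model is trained per precursor charge with at least `min_n` confident
#' PSMs; charges with fewer fall back to a model pooled over all charges.
#'
#' @param experimental,predicted,charge Paired training vectors.
#' @param span LOESS bandwidth (default 0.1 for IM).
#' @param min_n Minimum per-charge training size (default 50).
#' @return Named list of `rescore_calibration` models, one element per
#'   observed charge (names are the charge values); each is either that
#'   charge's own model or the pooled fallback (`charge = "all"`).
#' @export
fit_im_models <- function(experimental, predicted, charge, span = 0.1, min_n = 50) {
  keep <- !is.na(experimental) & !is.na(predicted) & !is.na(charge)
  if (!any(keep)) abort("no PSMs with both experimental and predicted ion mobility")
  experimental <- experimental[keep]; predicted <- predicted[keep]; charge <- charge[keep]
  charges <- sort(unique(charge))
  pooled <- NULL
  models <- list()
  for (z in charges) {
    sel <- charge == z
    if (sum(sel) >= min_n) {
      models[[as.character(z)]] <- fit_calibration(
        experimental[sel], predicted[sel],
        method = if (sum(sel) >= min_n) "loess" else "linear",
        span = span, charge = z
      )
    } else {
      if (is.null(pooled)) {
        pooled <- fit_calibration(
          experimental, predicted,
          method = if (length(experimental) >= min_n) "loess" else "linear",
          span = span, charge = "all"
        )
      }
      models[[as.character(z)]] <- pooled
    }
  }
  models
}

#' Delta features against a calibration model
#'
#' `delta_calibrated()` is the absolute difference between the calibrated
#' experimental value and the predicted value, on the predicted scale.
#' `delta_calibrated_normalized()` divides by the IQR of absolute training
#' residuals, a robust spread estimate that puts runs with different
#' calibration quality on a comparable scale; a zero IQR falls back to the
#' unnormalised delta with a warning.
#'
#' @param model A `rescore_calibration`.
#' @param experimental Experimental value(s) (minutes for RT, 1/K0 for IM).
#' @param predicted Predicted value(s) on the predicted scale.
#' @return Non-negative numeric vector (`NA` where inputs are `NA`; the
#'   pipeline replaces those with its missing-value sentinel).
#' @export
delta_calibrated <- function(model, experimental, predicted) {
  abs(predict(model, experimental) - predicted)
}

#' @rdname delta_calibrated
#' @export
delta_calibrated_normalized <- function(model, experimental, predicted) {
  d <- delta_calibrated(model, experimental, predicted)
  if (is.na(model$residual_iqr) || model$residual_iqr <= 0) {
    warn("zero residual IQR; returning unnormalised delta")
    return(d)
  }
  d / model$residual_iqr
}

#' Serialise / restore a calibration model
#'
#' The mapping is fully determined by its kind and knots, so a small JSON
#' text artifact suffices for reproducibility.
#'
#' @param model A `rescore_calibration`.
#' @param path Output (input) path.
#' @return `path` invisibly; `calibration_from_json()` returns the restored
#'   model.
#' @export
calibration_to_json <- function(model, path) {
  obj <- model[c("kind", "knots", "domain", "n_train", "span", "charge", "residual_iqr")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_to_json
#' @export
calibration_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  knots <- as_tibble(obj$knots)
  mapping <- function(v) approx(knots$x, knots$y, xout = v, rule = 2, ties = "ordered")$y
  structure(
    list(kind = obj$kind, knots = knots, domain = obj$domain,
         n_train = obj$n_train, span = obj$span, charge = obj$charge,
         residual_iqr = obj$residual_iqr, mapping = mapping),
    class = "rescore_calibration"
  )
}
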