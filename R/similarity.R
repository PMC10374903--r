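# Matched-vector construction and spectral similarity features.
#
# For every predicted fragment the highest-intensity experimental peak
# within the m/z tolerance is taken, so the predicted and experimental
# intensity vectors always have the same length (the number of predicted
# fragments); unmatched positions carry 0. One experimental peak may serve
# several predicted fragments of the same PSM — exclusivity is enforced only
# across PSM ranks, via peak consumption in DIA mode.

#' Match experimental peaks to predicted fragments
#'
#' @param peaks Tibble with `mz`, `intensity`, sorted ascending by m/z.
#' @param fragments Tibble of predicted fragments with `mz`, `intensity`.
#' @param tol_ppm Match tolerance in ppm (> 0). With `tol_da` set, an
#'   absolute tolerance in Th is used instead.
#' @param tol_da Optional absolute tolerance in Th (overrides `tol_ppm`).
#' @return Tibble with one row per predicted fragment: `mz`, `pred_intensity`,
#'   `exp_intensity` (0 when unmatched), `matched`, `peak_idx` (row index of
#'   the selected experimental peak, `NA` when unmatched). Selection is the
#'   highest-intensity in-tolerance peak; ties go to the peak closest in m/z,
#'   then to the lower m/z, so matching is deterministic and invariant to
#'   experimental peak order.
#' @export
match_fragments <- function(peaks, fragments, tol_ppm = 20, tol_da = NULL) {
  if (nrow(fragments) == 0) abort("no predicted fragments; similarity undefined")
  if (is.null(tol_da) && tol_ppm <= 0) abort("tol_ppm must be positive")
  mz <- peaks$mz
  inten <- peaks$intensity
  nfrag <- nrow(fragments)
  exp_intensity <- numeric(nfrag)
  peak_idx <- rep(NA_integer_, nfrag)
  for (i in seq_len(nfrag)) {
    m <- fragments$mz[i]
    tol <- if (!is.null(tol_da)) tol_da else m * tol_ppm * 1e-6
    lo <- findInterval(m - tol, mz) + 1L
    hi <- findInterval(m + tol, mz)
    if (hi >= lo) {
      idx <- lo:hi
      best <- idx[order(-inten[idx], abs(mz[idx] - m), mz[idx])][1]
      exp_intensity[i] <- inten[best]
      peak_idx[i] <- best
    }
  }
  tibble(
    mz = fragments$mz,
    pred_intensity = fragments$intensity,
    exp_intensity = exp_intensity,
    matched = !is.na(peak_idx),
    peak_idx = peak_idx
  )
}

#' Unweighted spectral entropy similarity
#'
#' Both spectra are normalised to unit sum (entropy needs probability
#' vectors); with Shannon entropy `S(x) = -sum(x * log(x))`, the similarity
#' is `1 - (2*S((P+Q)/2) - S(P) - S(Q)) / log(4)`. It lies in `[0, 1]`,
#' equals 1 iff the normalised spectra are identical and 0 for disjoint
#' spectra. An all-zero experimental vector returns 0 by convention so that
#' every PSM gets a numeric feature value.
#'
#' @param pred,exp Non-negative intensity vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' spectral_entropy_similarity(c(1, 0), c(0, 1)) # 0
#' spectral_entropy_similarity(c(2, 6), c(1, 3)) # 1
spectral_entropy_similarity <- function(pred, exp) {
  if (length(pred) != length(exp)) abort("vectors must have equal length")
  if (any(pred < 0) || any(exp < 0)) abort("negative intensities")
  sp <- sum(pred)
  if (sp <= 0) abort("predicted vector must have positive sum")
  if (sum(exp) <= 0) return(0)
  p <- pred / sp
  q <- exp / sum(exp)
  m <- (p + q) / 2
  1 - (2 * shannon(m) - shannon(p) - shannon(q)) / log(4)
}

shannon <- function(x) {
  x <- x[x > 0]
  -sum(x * log(x))
}

#' Auxiliary spectral similarity metrics
#'
#' The optional "multiple correlated features" set: cosine similarity
#' (L2-normalised), dot product on unit-sum vectors, Pearson and Spearman
#' correlation, the Bray-Curtis dissimilarity complement, and the count and
#' fraction of matched fragments. Correlations on constant vectors are 0 by
#' convention; every value is finite.
#'
#' @param matched Output of [match_fragments()].
#' @return Named list of numeric scalars.
#' @export
auxiliary_similarities <- function(matched) {
  p <- matched$pred_intensity
  q <- matched$exp_intensity
  cosine <- if (sum(q) > 0) sum(p * q) / (sqrt(sum(p^2)) * sqrt(sum(q^2))) else 0
  dot <- if (sum(q) > 0) sum((p / sum(p)) * (q / sum(q))) else 0
  safe_cor <- function(x, y, method) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y, method = method)
  }
  bray <- if (sum(p) + sum(q) > 0) 1 - sum(abs(p - q)) / (sum(p) + sum(q)) else 0
  list(
    cosine_similarity = cosine,
    dot_product = dot,
    pearson_corr = safe_cor(p, q, "pearson"),
    spearman_corr = safe_cor(p, q, "spearman"),
    bray_curtis = bray,
    n_matched = sum(matched$matched),
    frac_matched = mean(matched$matched)
  )
}

#' Remove matched experimental peaks (DIA rank consumption)
#'
#' After a PSM's features are computed in multi-rank (DIA) mode, the single
#' highest-intensity in-tolerance experimental peak of each predicted
#' fragment is deleted, so lower-ranking PSMs of the same scan cannot reuse
#' it — sharing MS/MS peaks across co-fragmented PSMs invites spurious hits.
#' Two fragments selecting the same peak cause exactly one deletion; nothing
#' matching is a no-op.
#'
#' @inheritParams match_fragments
#' @return The peaks tibble with the selected peaks removed.
#' @export
consume_matched_peaks <- function(peaks, fragments, tol_ppm = 20, tol_da = NULL) {
  matched <- match_fragments(peaks, fragments, tol_ppm, tol_da)
  drop <- unique(matched$peak_idx[matched$matched])
  if (length(drop) == 0) return(peaks)
  peaks[-drop, , drop = FALSE]
}
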