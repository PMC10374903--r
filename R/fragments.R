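# Theoretical b/y fragment m/z and m/z shifting for modifications that the
# prediction model does not support.

#' Theoretical fragment m/z
#'
#' Monoisotopic m/z of a b- or y-ion of a (modified) peptide. b-ions carry
#' the N-terminal residues (and any N-terminal modification); y-ions carry
#' the C-terminal residues plus water (and any C-terminal modification).
#'
#' @param sequence Stripped peptide sequence.
#' @param ion_type `"b"` or `"y"`.
#' @param position Fragment position, `1 <= position <= nchar(sequence) - 1`.
#'   Vectorised together with `ion_type` and `frag_charge`.
#' @param frag_charge Fragment charge, 1 or 2.
#' @param mods Optional tibble with `position` (0 = N-terminus,
#'   `nchar(sequence)` = C-terminal residue) and `delta` (Da).
#' @return Numeric vector of m/z values (Th).
#' @export
#' @examples
#' fragment_mz("PEPTIDE", "b", 2, 1) # 227.1026
fragment_mz <- function(sequence, ion_type, position, frag_charge = 1L, mods = NULL) {
  n <- nchar(sequence)
  len <- max(length(ion_type), length(position), length(frag_charge))
  ion_type <- rep_len(ion_type, len)
  position <- rep_len(as.integer(position), len)
  frag_charge <- rep_len(as.integer(frag_charge), len)
  if (any(position < 1L | position > n - 1L)) {
    abort(sprintf("fragment position out of range 1..%d for '%s'", n - 1L, sequence))
  }
  if (!all(ion_type %in% c("b", "y"))) abort("ion_type must be 'b' or 'y'")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res_mass <- unname(aa_monoisotopic[res])
  cum <- cumsum(res_mass)
  total <- cum[n]
  mod_pos <- integer(0); mod_delta <- numeric(0)
  if (!is.null(mods) && nrow(mods) > 0) {
    mod_pos <- as.integer(mods$position)
    mod_delta <- mods$delta
  }
  # modification mass carried by a fragment: b_i covers positions 0..i,
  # y_i covers positions (n-i+1)..n
  mod_sum_b <- vapply(position, function(p) sum(mod_delta[mod_pos <= p]), numeric(1))
  mod_sum_y <- vapply(position, function(p) sum(mod_delta[mod_pos >= n - p + 1L]), numeric(1))
  neutral <- ifelse(
    ion_type == "b",
    cum[position] + mod_sum_b,
    total - ifelse(position == n, 0, cum[n - position]) + mass_water + mod_sum_y
  )
  (neutral + frag_charge * mass_proton) / frag_charge
}

#' All theoretical b/y fragments of a peptide
#'
#' @inheritParams fragment_mz
#' @param frag_charges Fragment charges to enumerate (default 1:2).
#' @return Tibble with `ion_type`, `position`, `frag_charge`, `mz`.
#' @export
theoretical_fragments <- function(sequence, mods = NULL, frag_charges = 1:2) {
  n <- nchar(sequence)
  grid <- tidyr::expand_grid(
    ion_type = c("b", "y"),
    position = seq_len(n - 1L),
    frag_charge = as.integer(frag_charges)
  )
  grid$mz <- fragment_mz(sequence, grid$ion_type, grid$position, grid$frag_charge, mods)
  grid
}

#' Shift predicted fragments to accommodate extra modifications
#'
#' When a peptide carries a modification the prediction model does not
#' support, the library holds the prediction for the peptide without that
#' modification. Each fragment whose residue span covers a modified position
#' has its m/z shifted by the covered mass delta divided by the fragment
#' charge; intensities, predicted RT and predicted IM are left untouched.
#'
#' @param fragments Tibble with `mz`, `intensity`, `ion_type`, `position`,
#'   `frag_charge` (the prediction for the unmodified counterpart).
#' @param sequence_length Length of the peptide sequence.
#' @param extra_mods Tibble with `position` (0 = N-terminus) and `delta` (Da).
#' @return The fragments tibble with shifted `mz`. Fragments lacking an
#'   annotation (`NA` ion_type/position) are dropped with a warning, since
#'   their residue coverage cannot be determined.
#' @export
shift_predicted_fragments <- function(fragments, sequence_length, extra_mods) {
  if (is.null(extra_mods) || nrow(extra_mods) == 0) return(fragments)
  unannotated <- is.na(fragments$ion_type) | is.na(fragments$position)
  if (any(unannotated)) {
    warn(sprintf("dropping %d unannotated fragment(s); cannot place m/z shift", sum(unannotated)))
    fragments <- fragments[!unannotated, , drop = FALSE]
  }
  n <- sequence_length
  shift <- vapply(seq_len(nrow(fragments)), function(i) {
    p <- fragments$position[i]
    if (fragments$ion_type[i] == "b") {
      sum(extra_mods$delta[extra_mods$position <= p])
    } else {
      sum(extra_mods$delta[extra_mods$position >= n - p + 1L])
    }
  }, numeric(1))
  fragments$mz <- fragments$mz + shift / fragments$frag_charge
  fragments
}
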