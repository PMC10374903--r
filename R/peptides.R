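# Monoisotopic residue masses and modified-peptide string handling.

#' Physical constants and residue masses
#'
#' Monoisotopic masses of the 20 standard amino-acid residues (Da), the
#' proton mass and the mass of water, as used throughout fragment m/z
#' arithmetic.
#'
#' @format `aa_monoisotopic` is a named numeric vector of length 20.
#' @name masses
NULL

#' @rdname masses
#' @export
aa_monoisotopic <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276385,
  V = 99.06841391, T = 101.04767846, C = 103.00918447, L = 113.08406397,
  I = 113.08406397, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048508, H = 137.05891185,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931294
)

#' @rdname masses
#' @export
mass_proton <- 1.00727646688

#' @rdname masses
#' @export
mass_water <- 18.0105646863

#' Parse a modified-peptide string
#'
#' Accepts the bracketed mass-delta notation common in pin files, e.g.
#' `n[42.0106]PEPC[57.02146]K`: an optional `n[delta]` prefix marks an
#' N-terminal modification (position 0) and a bracket after a residue marks a
#' modification on that residue (1-based position). Multiple deltas reported
#' at the same position are summed.
#'
#' @param peptide Character vector of modified-peptide strings.
#' @return A tibble with one row per input: `peptide` (the input string),
#'   `sequence` (stripped upper-case residues), `mods` (list-column of
#'   tibbles with `position` and `delta`), and `mods_str` (canonical
#'   `"pos:delta"` encoding, semicolon-separated, sorted by position).
#' @export
#' @examples
#' parse_modified_peptide("n[42.0106]PEPC[57.02146]K")
parse_modified_peptide <- function(peptide) {
  out <- purrr::map(peptide, parse_one_peptide)
  tibble(
    peptide = peptide,
    sequence = purrr::map_chr(out, "sequence"),
    mods = purrr::map(out, "mods"),
    mods_str = purrr::map_chr(out, ~ format_mods(.x$mods))
  )
}

parse_one_peptide <- function(pep) {
  rest <- pep
  positions <- numeric(0)
  deltas <- numeric(0)
  seq_chars <- character(0)
  # optional N-terminal block
  m <- stringr::str_match(rest, "^n\\[([0-9eE.+-]+)\\]")
  if (!is.na(m[1, 1])) {
    positions <- c(positions, 0)
    deltas <- c(deltas, as.numeric(m[1, 2]))
    rest <- substr(rest, nchar(m[1, 1]) + 1L, nchar(rest))
  }
  i <- 1L
  n <- nchar(rest)
  while (i <= n) {
    ch <- substr(rest, i, i)
    if (grepl("^[A-Z]$", ch)) {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(rest, i, n), fixed = TRUE)
      if (j < 0) abort(sprintf("unclosed modification bracket in '%s'", pep))
      delta <- as.numeric(substr(rest, i + 1L, i + j - 2L))
      if (is.na(delta)) abort(sprintf("unparsable modification mass in '%s'", pep))
      if (length(seq_chars) == 0L) {
        abort(sprintf("modification bracket before any residue in '%s'", pep))
      }
      positions <- c(positions, length(seq_chars))
      deltas <- c(deltas, delta)
      i <- i + j
    } else if (ch == "c") {
      # C-terminal block c[delta]
      m2 <- stringr::str_match(substr(rest, i, n), "^c\\[([0-9eE.+-]+)\\]")
      if (is.na(m2[1, 1])) abort(sprintf("unparsable token at '%s' in '%s'", ch, pep))
      positions <- c(positions, length(seq_chars) + stringr::str_count(substr(rest, i + nchar(m2[1, 1]), n), "[A-Z]") )
      deltas <- c(deltas, as.numeric(m2[1, 2]))
      i <- i + nchar(m2[1, 1])
    } else {
      abort(sprintf("unexpected character '%s' in peptide '%s'", ch, pep))
    }
  }
  sequence <- paste(seq_chars, collapse = "")
  if (length(positions) > 0) {
    agg <- vapply(split(deltas, positions), sum, numeric(1))
    pos <- as.integer(names(agg))
    o <- order(pos)
    mods <- tibble(position = pos[o], delta = unname(agg)[o])
  } else {
    mods <- tibble(position = integer(0), delta = numeric(0))
  }
  list(sequence = sequence, mods = mods)
}

#' Canonical encoding of a modification set
#'
#' @param mods Tibble with `position` and `delta` columns.
#' @return A single string like `"0:42.01060;4:57.02146"`; `""` when
#'   unmodified. Deltas are formatted with five decimals so that keys built
#'   from pin files and from library files agree.
#' @export
format_mods <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0) return("")
  o <- order(mods$position)
  paste(sprintf("%d:%.5f", as.integer(mods$position[o]), mods$delta[o]), collapse = ";")
}

parse_mods_str <- function(s) {
  if (is.na(s) || !nzchar(s)) return(tibble(position = integer(0), delta = numeric(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble(
    position = as.integer(purrr::map_chr(kv, 1)),
    delta = as.numeric(purrr::map_chr(kv, 2))
  )
}

#' Library key for a peptidoform
#'
#' Peptides with the same sequence but different modifications and/or charges
#' are distinct entries, so the key concatenates all three.
#'
#' @param sequence Stripped sequence.
#' @param mods_str Canonical modification string from [format_mods()].
#' @param charge Precursor charge.
#' @return Character key.
#' @export
peptide_key <- function(sequence, mods_str, charge) {
  paste(sequence, mods_str, charge, sep = "/")
}

#' Monoisotopic neutral mass of a (modified) peptide
#'
#' @param sequence Stripped residue string.
#' @param mods Optional tibble with `position`, `delta`.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, mods = NULL) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(aa_monoisotopic))
  if (length(bad) > 0) abort(sprintf("unknown residue(s): %s", paste(bad, collapse = ", ")))
  m <- sum(aa_monoisotopic[res]) + mass_water
  if (!is.null(mods) && nrow(mods) > 0) m <- m + sum(mods$delta)
  m
}
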