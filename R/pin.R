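# Percolator pin reading/writing.
#
# A pin file is tab-separated with columns SpecId, Label, ScanNr, <features>,
# Peptide, Proteins. In some dialects the Proteins column itself contains raw
# tabs, so rows may carry more fields than the header; everything beyond the
# header width is folded back into Proteins. Original field strings are kept
# verbatim so a read/write round trip is byte-identical.

pin_required <- c("SpecId", "Label", "ScanNr", "Peptide", "Proteins")

#' Read a Percolator pin file
#'
#' @param path Path to the pin file.
#' @param evalue_column Name of the column holding the expectation value (or
#'   a transform of it). Pin files do not standardise this column, so it is
#'   configurable; set to `NULL` to skip e-value parsing.
#' @param evalue_transform How to recover the e-value from the column:
#'   `"identity"` (column is the e-value), `"pow10_of_negated"` (column is
#'   `-log10(e)`), or `"exp_of_negated"` (column is `-ln(e)`).
#' @return A tibble of class `pin_tbl` with every original column as
#'   character (verbatim), plus attributes `source_path`, `evalue_column`,
#'   `evalue_transform`. Use [parse_pin_psms()] for typed PSM records.
#' @export
read_pin <- function(path, evalue_column = "log10_evalue",
                     evalue_transform = c("pow10_of_negated", "identity", "exp_of_negated")) {
  evalue_transform <- arg_match(evalue_transform)
  if (!file.exists(path)) abort(sprintf("pin file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("empty pin file: %s", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(pin_required, header)
  if (length(missing_cols) > 0) {
    abort(sprintf("pin file %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(evalue_column) && !evalue_column %in% header) {
    abort(sprintf("pin file %s has no e-value column '%s'", path, evalue_column))
  }
  ncol <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) > ncol) {
      # fold the tab-containing Proteins tail back into one field
      f <- c(f[seq_len(ncol - 1L)], paste(f[ncol:length(f)], collapse = "\t"))
    }
    if (length(f) != ncol) {
      abort(sprintf("pin file %s line %d: %d fields, expected %d",
                    path, i + 1L, length(f), ncol))
    }
    f
  })
  mat <- if (length(rows) > 0) do.call(rbind, rows) else matrix(character(0), 0, ncol)
  colnames(mat) <- header
  tbl <- as_tibble(mat)
  # feature columns (between ScanNr and Peptide) must be numeric
  pep_idx <- match("Peptide", header)
  scan_idx <- match("ScanNr", header)
  feat_cols <- header[seq_len(pep_idx - 1L)][-seq_len(scan_idx)]
  for (col in feat_cols) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl[[col]]))))
    if (length(bad) > 0) {
      abort(sprintf("pin file %s: non-numeric value '%s' in feature column '%s' at line %d",
                    path, tbl[[col]][bad[1]], col, bad[1] + 1L))
    }
  }
  structure(
    tbl,
    class = c("pin_tbl", class(tbl)),
    source_path = path,
    pin_header = header,
    evalue_column = evalue_column,
    evalue_transform = evalue_transform
  )
}

apply_evalue_transform <- function(x, transform) {
  switch(transform,
    identity = x,
    pow10_of_negated = 10^(-x),
    exp_of_negated = exp(-x),
    abort(sprintf("unknown e-value transform '%s'", transform))
  )
}

#' Parse typed PSM records from a pin table
#'
#' Extracts one typed record per pin row: label, scan number, PSM rank and
#' precursor charge (both parsed from the SpecId, which follows the
#' `base.scan.scan.charge_rank` convention; a missing `_rank` suffix means
#' rank 1), the modified-peptide string with flanking residues stripped, and
#' the e-value recovered through the configured transform.
#'
#' @param pin A `pin_tbl` from [read_pin()].
#' @return Tibble with `spec_id`, `label`, `scan_nr`, `rank`, `charge`,
#'   `peptide`, `sequence`, `mods` (list-column), `mods_str`, `key`,
#'   `evalue`.
#' @export
parse_pin_psms <- function(pin) {
  stopifnot(inherits(pin, "pin_tbl"))
  ev_col <- attr(pin, "evalue_column")
  ev_tr <- attr(pin, "evalue_transform")
  spec_id <- pin$SpecId
  last <- stringr::str_extract(spec_id, "[^.]+$")
  charge <- suppressWarnings(as.integer(stringr::str_extract(last, "^\\d+")))
  rank <- suppressWarnings(as.integer(stringr::str_match(last, "_(\\d+)$")[, 2]))
  rank[is.na(rank)] <- 1L
  pep_raw <- pin$Peptide
  # strip flanking residues "K.PEPTIDE.R" if present
  pep <- stringr::str_replace(pep_raw, "^[A-Z-]\\.", "")
  pep <- stringr::str_replace(pep, "\\.[A-Z-]$", "")
  parsed <- parse_modified_peptide(pep)
  evalue <- rep(NA_real_, nrow(pin))
  if (!is.null(ev_col)) {
    evalue <- apply_evalue_transform(as.numeric(pin[[ev_col]]), ev_tr)
    if (any(!is.na(evalue) & evalue <= 0)) abort("recovered e-values must be positive")
  }
  tibble(
    spec_id = spec_id,
    label = as.integer(pin$Label),
    scan_nr = as.integer(pin$ScanNr),
    rank = rank,
    charge = charge,
    peptide = pep,
    sequence = parsed$sequence,
    mods = parsed$mods,
    mods_str = parsed$mods_str,
    key = peptide_key(parsed$sequence, parsed$mods_str, charge),
    evalue = evalue
  )
}

#' Write a (possibly extended) pin file
#'
#' New feature columns are inserted immediately before the Peptide column —
#' the Percolator convention is that every column between ScanNr and Peptide
#' is a rescoring feature. Original columns, row order and field strings are
#' preserved verbatim, so writing with no new features round-trips
#' byte-identically. Feature values are serialised with `%.6g`.
#'
#' @param pin A `pin_tbl`.
#' @param path Output path.
#' @param new_features Named list; each element is a numeric vector named by
#'   `SpecId` (one value per PSM). `NULL` or empty adds nothing.
#' @return `path`, invisibly.
#' @export
write_pin <- function(pin, path, new_features = NULL) {
  stopifnot(inherits(pin, "pin_tbl"))
  header <- attr(pin, "pin_header")
  pep_idx <- match("Peptide", header)
  mat <- as.matrix(as_tibble(pin)[header])
  new_cols <- character(0)
  if (!is.null(new_features) && length(new_features) > 0) {
    ids <- pin$SpecId
    for (feat in names(new_features)) {
      vals <- new_features[[feat]]
      missing_ids <- setdiff(ids, names(vals))
      if (length(missing_ids) > 0) {
        abort(sprintf("feature '%s' missing values for PSM(s): %s", feat,
                      paste(head(missing_ids, 5), collapse = ", ")))
      }
      col <- sprintf("%.6g", unname(vals[ids]))
      mat <- cbind(mat[, seq_len(pep_idx - 1L + length(new_cols)), drop = FALSE],
                   col,
                   mat[, (pep_idx + length(new_cols)):ncol(mat), drop = FALSE])
      new_cols <- c(new_cols, feat)
    }
  }
  out_header <- append(header, new_cols, after = pep_idx - 1L)
  body <- if (nrow(mat) > 0) apply(mat, 1, paste, collapse = "\t") else character(0)
  lines <- c(paste(out_header, collapse = "\t"), body)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
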