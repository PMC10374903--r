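# Predicted-property library: per peptidoform fragment intensities, one
# predicted RT (arbitrary predicted scale, e.g. iRT) and optionally one
# predicted inverse ion mobility (1/K0).
#
# Two on-disk dialects are supported and are interchangeable:
#
# msp (NIST-style):
#   Name: n[42.0106]PEPC[57.02146]K/2
#   Comment: RT=55.31 IM=0.952
#   Num peaks: 4
#   227.10263<TAB>1000<TAB>"b2"
#   ...
# Fragment annotations are "b3", "y5" or "y5^2" (fragment charge 2).
#
# TSV: one row per entry, columns
#   peptide  mods  charge  rt  im  fragments
# where peptide is the stripped sequence, mods is the canonical
# "pos:delta;pos:delta" string ("" if unmodified), im may be empty, and
# fragments is a semicolon-separated list of "mz,intensity,annotation"
# triples.

parse_fragment_annotation <- function(ann) {
  m <- stringr::str_match(ann, "^([by])(\\d+)(?:\\^(\\d))?$")
  tibble(
    ion_type = m[, 2],
    position = suppressWarnings(as.integer(m[, 3])),
    frag_charge = ifelse(is.na(m[, 4]), 1L, suppressWarnings(as.integer(m[, 4])))
  )
}

format_fragment_annotation <- function(ion_type, position, frag_charge) {
  paste0(ion_type, position, ifelse(frag_charge > 1, paste0("^", frag_charge), ""))
}

new_library_tbl <- function(sequence, mods, mods_str, charge, rt_pred, im_pred, fragments) {
  tbl <- tibble(
    key = peptide_key(sequence, mods_str, charge),
    sequence = sequence,
    mods = mods,
    mods_str = mods_str,
    charge = as.integer(charge),
    rt_pred = as.numeric(rt_pred),
    im_pred = as.numeric(im_pred),
    fragments = fragments
  )
  dup <- tbl$key[duplicated(tbl$key)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate library key(s): %s", paste(head(dup, 3), collapse = ", ")))
  }
  tbl
}

#' Read a predicted-property library
#'
#' @param path Path to the library file.
#' @param dialect `"msp"` or `"tsv"`; guessed from the extension by default.
#' @return Tibble with one row per (sequence, modifications, charge):
#'   `key`, `sequence`, `mods` (list-column), `mods_str`, `charge`,
#'   `rt_pred`, `im_pred` (`NA` when the model predicts no ion mobility —
#'   IM features are skipped for those entries), `fragments` (list-column of
#'   tibbles with `mz`, `intensity`, `ion_type`, `position`, `frag_charge`).
#'   Entries are keyed uniquely; duplicate keys are an error. Fragment
#'   annotations that cannot be parsed are dropped with a warning.
#' @export
read_prediction_library <- function(path, dialect = c("auto", "msp", "tsv")) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) abort(sprintf("library file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "msp") "msp" else "tsv"
  }
  if (dialect == "msp") read_library_msp(path) else read_library_tsv(path)
}

read_library_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name_idx <- which(stringr::str_starts(lines, "Name:"))
  if (length(name_idx) == 0) abort(sprintf("no entries in msp file %s", path))
  bounds <- c(name_idx, length(lines) + 1L)
  entries <- purrr::map(seq_along(name_idx), function(i) {
    block <- lines[bounds[i]:(bounds[i + 1] - 1L)]
    name <- trimws(sub("^Name:", "", block[1]))
    slash <- regexpr("/(?=[0-9]+$)", name, perl = TRUE)
    if (slash < 0) abort(sprintf("msp Name without charge: '%s'", name))
    pep <- substr(name, 1, slash - 1L)
    charge <- as.integer(substr(name, slash + 1L, nchar(name)))
    comment <- block[stringr::str_starts(block, "Comment:")]
    rt <- NA_real_; im <- NA_real_
    if (length(comment) > 0) {
      rt <- suppressWarnings(as.numeric(stringr::str_match(comment[1], "RT=([0-9eE.+-]+)")[, 2]))
      im <- suppressWarnings(as.numeric(stringr::str_match(comment[1], "IM=([0-9eE.+-]+)")[, 2]))
    }
    np_idx <- which(stringr::str_starts(block, "Num peaks:"))
    frag <- tibble(mz = numeric(0), intensity = numeric(0),
                   ion_type = character(0), position = integer(0), frag_charge = integer(0))
    if (length(np_idx) > 0) {
      pk_lines <- block[-seq_len(np_idx[1])]
      pk_lines <- pk_lines[nzchar(trimws(pk_lines))]
      if (length(pk_lines) > 0) {
        m <- do.call(rbind, strsplit(pk_lines, "\t", fixed = TRUE))
        ann <- gsub("\"", "", m[, 3])
        pa <- parse_fragment_annotation(ann)
        bad <- is.na(pa$ion_type)
        if (any(bad)) {
          warn(sprintf("entry '%s': dropping %d fragment(s) with unparsable annotation",
                       name, sum(bad)))
        }
        frag <- tibble(
          mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]),
          ion_type = pa$ion_type, position = pa$position, frag_charge = pa$frag_charge
        )[!bad, , drop = FALSE]
      }
    }
    if (any(frag$intensity < 0)) abort(sprintf("entry '%s': negative intensity", name))
    parsed <- parse_one_peptide(pep)
    list(sequence = parsed$sequence, mods = parsed$mods,
         mods_str = format_mods(parsed$mods), charge = charge,
         rt = rt, im = im, frag = frag)
  })
  new_library_tbl(
    purrr::map_chr(entries, "sequence"),
    purrr::map(entries, "mods"),
    purrr::map_chr(entries, "mods_str"),
    purrr::map_int(entries, "charge"),
    purrr::map_dbl(entries, "rt"),
    purrr::map_dbl(entries, "im"),
    purrr::map(entries, "frag")
  )
}

read_library_tsv <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("peptide", "mods", "charge", "rt", "im", "fragments")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("library TSV missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  frag <- purrr::map2(tbl$fragments, tbl$peptide, function(s, pep) {
    if (!nzchar(s)) {
      return(tibble(mz = numeric(0), intensity = numeric(0),
                    ion_type = character(0), position = integer(0), frag_charge = integer(0)))
    }
    triples <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
    m <- do.call(rbind, triples)
    pa <- parse_fragment_annotation(m[, 3])
    bad <- is.na(pa$ion_type)
    if (any(bad)) {
      warn(sprintf("entry '%s': dropping %d fragment(s) with unparsable annotation",
                   pep, sum(bad)))
    }
    tibble(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]),
           ion_type = pa$ion_type, position = pa$position,
           frag_charge = pa$frag_charge)[!bad, , drop = FALSE]
  })
  mods <- purrr::map(tbl$mods, parse_mods_str)
  new_library_tbl(
    tbl$peptide, mods, purrr::map_chr(mods, format_mods),
    as.integer(tbl$charge), as.numeric(tbl$rt),
    suppressWarnings(as.numeric(ifelse(nzchar(tbl$im), tbl$im, NA))), frag
  )
}

#' Write a predicted-property library
#'
#' Inverse of [read_prediction_library()]; used by the synthetic-data
#' generator and to cross-check dialect equivalence.
#'
#' @param library Library tibble.
#' @param path Output path.
#' @param dialect `"msp"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_prediction_library <- function(library, path, dialect = c("msp", "tsv")) {
  dialect <- arg_match(dialect)
  if (dialect == "msp") {
    blocks <- purrr::pmap(library, function(key, sequence, mods, mods_str, charge,
                                            rt_pred, im_pred, fragments) {
      name <- modpep_string(sequence, mods)
      comment <- sprintf("Comment: RT=%.5f%s", rt_pred,
                         if (!is.na(im_pred)) sprintf(" IM=%.6f", im_pred) else "")
      ann <- format_fragment_annotation(fragments$ion_type, fragments$position,
                                        fragments$frag_charge)
      pk <- sprintf("%.5f\t%.6g\t\"%s\"", fragments$mz, fragments$intensity, ann)
      c(sprintf("Name: %s/%d", name, charge), comment,
        sprintf("Num peaks: %d", nrow(fragments)), pk, "")
    })
    writeLines(unlist(blocks), path)
  } else {
    rows <- purrr::pmap_chr(library, function(key, sequence, mods, mods_str, charge,
                                              rt_pred, im_pred, fragments) {
      ann <- format_fragment_annotation(fragments$ion_type, fragments$position,
                                        fragments$frag_charge)
      fr <- paste(sprintf("%.5f,%.6g,%s", fragments$mz, fragments$intensity, ann),
                  collapse = ";")
      paste(sequence, mods_str, charge, sprintf("%.5f", rt_pred),
            if (!is.na(im_pred)) sprintf("%.6f", im_pred) else "",
            fr, sep = "\t")
    })
    writeLines(c(paste(c("peptide", "mods", "charge", "rt", "im", "fragments"),
                       collapse = "\t"), rows), path)
  }
  invisible(path)
}

# rebuild the bracketed modified-peptide string from sequence + mods
modpep_string <- function(sequence, mods) {
  if (is.null(mods) || nrow(mods) == 0) return(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(0)
  nterm <- mods$delta[mods$position == 0]
  if (length(nterm) > 0) out <- sprintf("n[%.5f]", sum(nterm))
  for (i in seq_along(res)) {
    out <- c(out, res[i])
    d <- mods$delta[mods$position == i]
    if (length(d) > 0) out <- c(out, sprintf("[%.5f]", sum(d)))
  }
  paste(out, collapse = "")
}
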