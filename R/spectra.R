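# Experimental spectrum reading: MGF (native) and mzML (via mzR).

new_spectra_tbl <- function(scan_nr, rt_min, im, precursor_charge, peaks) {
  tibble(
    scan_nr = as.integer(scan_nr),
    rt_min = as.numeric(rt_min),
    im = as.numeric(im),
    precursor_charge = as.integer(precursor_charge),
    peaks = peaks
  )
}

sort_peaks <- function(peaks) {
  if (any(peaks$intensity < 0)) abort("negative peak intensity")
  peaks[order(peaks$mz), , drop = FALSE]
}

#' Read experimental MS/MS spectra
#'
#' Dispatches on the file extension: `.mgf` is parsed natively, `.mzML` is
#' read through the mzR/proteowizard backend. Retention times are converted
#' to minutes regardless of the source unit; ion mobility (1/K0) is captured
#' when present. Peaks are returned sorted ascending by m/z.
#'
#' @param path Path to an MGF or mzML file.
#' @return Tibble with one row per MS2 scan: `scan_nr`, `rt_min` (minutes,
#'   `NA` if the scan carries no RT — such scans are kept but excluded from
#'   RT features downstream), `im` (1/K0 or `NA`), `precursor_charge`
#'   (or `NA`), and `peaks` (list-column of tibbles with `mz`, `intensity`).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(sprintf("spectra file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mgf") {
    read_mgf(path)
  } else if (ext == "mzml") {
    read_mzml(path)
  } else {
    abort(sprintf("unsupported spectra format '.%s' (use MGF or mzML)", ext))
  }
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) abort(sprintf("unbalanced BEGIN/END IONS in %s", path))
  recs <- purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    scan <- suppressWarnings(as.integer(getv("SCANS")))
    if (is.na(scan)) {
      title <- getv("TITLE")
      scan <- suppressWarnings(as.integer(stringr::str_match(title, "scan=(\\d+)")[, 2]))
    }
    rt_sec <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    rt_min <- rt_sec / 60
    if (is.na(rt_min)) {
      warn(sprintf("MGF scan %s has no RTINSECONDS; excluded from RT features", scan))
    }
    im <- suppressWarnings(as.numeric(getv("ION_MOBILITY")))
    charge <- suppressWarnings(as.integer(sub("\\+$", "", getv("CHARGE"))))
    pk_lines <- block[!is_kv]
    pk_lines <- pk_lines[nzchar(trimws(pk_lines))]
    if (length(pk_lines) > 0) {
      m <- do.call(rbind, strsplit(trimws(pk_lines), "[ \t]+"))
      peaks <- tibble(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    } else {
      peaks <- tibble(mz = numeric(0), intensity = numeric(0))
    }
    list(scan_nr = scan, rt_min = rt_min, im = im, charge = charge,
         peaks = sort_peaks(peaks))
  })
  new_spectra_tbl(
    purrr::map_int(recs, "scan_nr"),
    purrr::map_dbl(recs, "rt_min"),
    purrr::map_dbl(recs, "im"),
    purrr::map_int(recs, "charge"),
    purrr::map(recs, "peaks")
  )
}

#' @rdname read_spectra
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package")
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  ms2 <- which(hd$msLevel == 2)
  if (length(ms2) == 0) {
    return(new_spectra_tbl(integer(0), numeric(0), numeric(0), integer(0), list()))
  }
  pks <- mzR::peaks(h, ms2)
  if (is.matrix(pks)) pks <- list(pks)
  peaks <- purrr::map(pks, function(p) {
    sort_peaks(tibble(mz = p[, 1], intensity = p[, 2]))
  })
  im <- if ("ionMobilityDriftTime" %in% names(hd)) hd$ionMobilityDriftTime[ms2] else NA_real_
  rt_min <- hd$retentionTime[ms2] / 60  # mzR reports seconds
  missing_rt <- is.na(rt_min)
  if (any(missing_rt)) {
    warn(sprintf("%d mzML scan(s) without RT; excluded from RT features", sum(missing_rt)))
  }
  new_spectra_tbl(hd$acquisitionNum[ms2], rt_min, im, hd$precursorCharge[ms2], peaks)
}

#' Write spectra to MGF
#'
#' Inverse of [read_mgf()] for the keys this package uses; used by the
#' synthetic-data generator. Peak m/z are written with five decimals,
#' intensities with `%.6g`.
#'
#' @param spectra Spectra tibble as returned by [read_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap(spectra, function(scan_nr, rt_min, im, precursor_charge, peaks) {
    hdr <- c(
      "BEGIN IONS",
      sprintf("TITLE=scan=%d", scan_nr),
      sprintf("SCANS=%d", scan_nr),
      if (!is.na(rt_min)) sprintf("RTINSECONDS=%.4f", rt_min * 60),
      if (!is.na(precursor_charge)) sprintf("CHARGE=%d+", precursor_charge),
      if (!is.na(im)) sprintf("ION_MOBILITY=%.6f", im)
    )
    pk <- sprintf("%.5f %.6g", peaks$mz, peaks$intensity)
    c(hdr, pk, "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Write spectra to a minimal mzML document
#'
#' Emits an uncompressed mzML 1.1.0 file with 64-bit float peak arrays —
#' enough structure for standard readers (mzR/proteowizard) to recover scan
#' numbers, MS level, RT, precursor charge and peaks. Used by the
#' synthetic-data generator.
#'
#' @inheritParams write_mgf
#' @export
write_mzml <- function(spectra, path) {
  enc <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                                   endian = "little"))
  arr <- function(acc, name, unit, b) {
    paste0('<binaryDataArray encodedLength="', nchar(b), '">',
           '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
           '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
           '<cvParam cvRef="MS" accession="', acc, '" name="', name, '" value=""', unit, '/>',
           '<binary>', b, '</binary></binaryDataArray>')
  }
  blocks <- purrr::pmap_chr(
    mutate(spectra, idx = seq_len(nrow(spectra)) - 1L),
    function(scan_nr, rt_min, im, precursor_charge, peaks, idx) {
      paste0(
        sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
                idx, scan_nr, nrow(peaks)),
        '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
        '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
        '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/><scan>',
        if (!is.na(rt_min)) sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>', rt_min * 60) else "",
        if (!is.na(im)) sprintf('<cvParam cvRef="MS" accession="MS:1002815" name="inverse reduced ion mobility" value="%.6f" unitCvRef="MS" unitAccession="MS:1002814" unitName="volt-second per square centimeter"/>', im) else "",
        '</scan></scanList>',
        '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
        '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="500.0" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
        if (!is.na(precursor_charge)) sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>', precursor_charge) else "",
        '</selectedIon></selectedIonList></precursor></precursorList>',
        '<binaryDataArrayList count="2">',
        arr("MS:1000514", "m/z array",
            ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"', enc(peaks$mz)),
        arr("MS:1000515", "intensity array", "", enc(peaks$intensity)),
        '</binaryDataArrayList></spectrum>'
      )
    })
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UNIT-ONTOLOGY" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="sim"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1">\n<spectrumList count="%d" defaultDataProcessingRef="dp">\n', nrow(spectra)),
    paste(blocks, collapse = "\n"),
    '\n</spectrumList></run></mzML>'
  )
  writeLines(doc, path)
  invisible(path)
}
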