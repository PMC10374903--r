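toy_library <- function() {
  frag <- theoretical_fragments("PEPTIDEK")
  frag$intensity <- seq_len(nrow(frag))
  frag <- frag[c(1, 3, 16, 20), c("mz", "intensity", "ion_type", "position", "frag_charge")]
  mods2 <- tibble::tibble(position = 3L, delta = 15.9949)
  frag2 <- theoretical_fragments("PEMSK", mods2)
  frag2$intensity <- rev(seq_len(nrow(frag2)))
  frag2 <- frag2[1:6, c("mz", "intensity", "ion_type", "position", "frag_charge")]
  msrescore:::new_library_tbl(
    c("PEPTIDEK", "PEMSK"),
    list(tibble::tibble(position = integer(0), delta = numeric(0)), mods2),
    c("", format_mods(mods2)),
    c(2L, 3L), c(55.31, 20.5), c(0.952, NA), list(frag, frag2)
  )
}

test_that("msp entries round-trip with annotations, RT and optional IM", {
  lib <- toy_library()
  path <- withr::local_tempfile(fileext = ".msp")
  write_prediction_library(lib, path, "msp")
  back <- read_prediction_library(path)
  expect_equal(back$key, lib$key)
  expect_equal(back$charge, lib$charge)
  expect_equal(back$rt_pred, lib$rt_pred, tolerance = 1e-5)
  expect_equal(back$im_pred, lib$im_pred, tolerance = 1e-6)
  expect_equal(nrow(back$fragments[[1]]), 4)
  expect_equal(back$fragments[[1]]$ion_type, lib$fragments[[1]]$ion_type)
  expect_equal(back$fragments[[1]]$position, lib$fragments[[1]]$position)
  expect_equal(back$fragments[[1]]$frag_charge, lib$fragments[[1]]$frag_charge)
  expect_equal(back$fragments[[1]]$mz, lib$fragments[[1]]$mz, tolerance = 1e-5)
  # entry without IM stays NA so IM features are later skipped for it
  expect_true(is.na(back$im_pred[2]))
})

test_that("msp and TSV dialects of the same content parse identically", {
  lib <- toy_library()
  p1 <- withr::local_tempfile(fileext = ".msp")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_library(lib, p1, "msp")
  write_prediction_library(lib, p2, "tsv")
  a <- read_prediction_library(p1)
  b <- read_prediction_library(p2)
  expect_equal(a$key, b$key)
  expect_equal(a$rt_pred, b$rt_pred)
  expect_equal(a$im_pred, b$im_pred)
  for (i in seq_len(nrow(a))) expect_equal(a$fragments[[i]], b$fragments[[i]])
})

test_that("duplicate keys error and bad annotations drop with a warning", {
  lib <- toy_library()
  dup <- lib
  dup$charge <- c(2L, 2L)
  dup$sequence <- c("PEPTIDEK", "PEPTIDEK")
  dup$mods_str <- c("", "")
  expect_error(
    msrescore:::new_library_tbl(dup$sequence, dup$mods, dup$mods_str, dup$charge,
                                dup$rt_pred, dup$im_pred, dup$fragments),
    "duplicate"
  )
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c(
    "Name: PEPTIDEK/2", "Comment: RT=10.0", "Num peaks: 2",
    "227.10263\t100\t\"b2\"", "350.0\t50\t\"w9\"", ""
  ), path)
  expect_warning(lib2 <- read_prediction_library(path), "unparsable")
  expect_equal(nrow(lib2$fragments[[1]]), 1)
})

test_that("library m/z annotations agree with fragment_mz within 1e-3 Th", {
  lib <- toy_library()
  for (i in seq_len(nrow(lib))) {
    f <- lib$fragments[[i]]
    regen <- fragment_mz(lib$sequence[i], f$ion_type, f$position, f$frag_charge,
                         lib$mods[[i]])
    expect_equal(f$mz, regen, tolerance = 1e-3)
  }
})
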