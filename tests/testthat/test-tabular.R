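# Table loading, missing values, identifier detection, generalization.

test_that("a blank cell loads as missing and write/load round-trips the table", {
  p <- write_tsv_lines(c("ID\tSEX\tHEIGHT",
                         "S01\tM\t172",
                         "S02\tF\t",
                         "S03\tF\t181"))
  tbl <- load_table(p)
  expect_identical(nrow(find_missing(tbl)), 1L)
  expect_identical(find_missing(tbl)$column, "HEIGHT")
  expect_identical(find_missing(tbl)$row, 2L)
  expect_true(is.numeric(tbl$HEIGHT))
  out <- tempfile(fileext = ".tsv")
  write_table(tbl, out)
  expect_identical(load_table(out), tbl)
  # missing cell serialized as the literal missing code
  expect_match(readLines(out)[3], "\tNA$")
})

test_that("all recognized missing tokens parse as missing", {
  p <- write_tsv_lines(c("ID\tA\tB\tC\tD",
                         "S01\tNA\tNaN\tN/A\t.",
                         "S02\t1\t2\t3\t4"))
  tbl <- load_table(p)
  expect_identical(nrow(find_missing(tbl)), 4L)
  expect_true(all(find_missing(tbl)$row == 1L))
})

test_that("duplicate IDs and ragged rows are load errors", {
  p <- write_tsv_lines(c("ID\tX", "S01\t1", "S01\t2"))
  expect_error(load_table(p), class = "neuroscrub_duplicate_id")
  p2 <- write_tsv_lines(c("ID\tX\tY", "S01\t1", "S02\t1\t2"))
  expect_error(load_table(p2), class = "neuroscrub_ragged_table")
})

test_that("single-letter categorical columns stay character, never logical", {
  # an all-"F" sex column must not be read as logical FALSE
  p <- write_tsv_lines(c("ID\tSEX\tAGE", "S01\tF\t20", "S02\tF\t58"))
  tbl <- load_table(p)
  expect_identical(tbl$SEX, c("F", "F"))
  expect_identical(tbl$AGE, c(20, 58))
  out <- tempfile(fileext = ".tsv")
  write_table(tbl, out)
  expect_identical(readLines(out)[2], "S01\tF\t20")
})

test_that("comma-delimited files are sniffed automatically", {
  p <- write_tsv_lines(c("ID,AGE", "S01,40", "S02,52"))
  tbl <- load_table(p)
  expect_identical(names(tbl), c("ID", "AGE"))
  expect_identical(tbl$AGE, c(40, 52))
})

test_that("identifier columns are flagged by name pattern and by date content", {
  tbl <- tibble::tibble(ID = c("S01", "S02"), NAME = c("A B", "C D"),
                        DOB = c("1970-01-01", "1980-05-02"),
                        SEX = c("M", "F"), HEIGHT = c(172, 168))
  f <- detect_identifier_columns(tbl)
  expect_setequal(f$column, c("ID", "NAME", "DOB"))
  expect_identical(f$reason[f$column == "ID"], "ID_LABEL")

  # a date-valued column whose name matches no pattern
  tbl2 <- tibble::tibble(ID = c("S01", "S02", "S03"),
                         VISIT = c("2011-03-04", "2011-05-09", "03/07/2012"),
                         SCORE = c(1, 2, 3))
  f2 <- detect_identifier_columns(tbl2)
  expect_identical(f2$reason[f2$column == "VISIT"], "DATE_VALUES")

  # purely numeric columns: only the mandatory ID finding
  tbl3 <- tibble::tibble(SUBJ = c("a", "b"), SEX = c("M", "F"), SCORE = c(1, 2))
  f3 <- detect_identifier_columns(tbl3)
  expect_identical(f3$column, "SUBJ")

  # deterministic / pure
  expect_identical(detect_identifier_columns(tbl), f)
})

test_that("dropping columns preserves the remaining cells and the original table", {
  tbl <- tibble::tibble(ID = c("S01", "S02"), NAME = c("A", "B"),
                        DOB = c("1970-01-01", "1980-05-02"),
                        SEX = c("M", "F"), HEIGHT = c(172, 168))
  out <- drop_columns(tbl, c("NAME", "DOB"))
  expect_identical(names(out), c("ID", "SEX", "HEIGHT"))
  expect_identical(nrow(out), 2L)
  expect_identical(out, tbl[, c("ID", "SEX", "HEIGHT")])
  expect_identical(ncol(tbl), 5L)  # source untouched
  expect_identical(drop_columns(tbl, character()), tbl)
  expect_error(drop_columns(tbl, "ID"), class = "neuroscrub_id_column_needed")
  expect_error(drop_columns(tbl, "NOPE"), class = "neuroscrub_unknown_column")
})

test_that("bin rounding maps heights to the nearest multiple of the width", {
  tbl <- tibble::tibble(ID = c("a", "b", "c"), HEIGHT = c(172, 168, 181))
  out <- generalize_column(tbl, "HEIGHT", "bin_round", 5)
  expect_identical(out$HEIGHT, c(170, 170, 180))
  # width 1 on integers is the identity
  ints <- tibble::tibble(ID = "a", X = 37)
  expect_identical(generalize_column(ints, "X", "bin_round", 1)$X, 37)
  # halves round away from zero
  tb2 <- tibble::tibble(ID = c("a", "b"), X = c(2.5, -2.5))
  expect_identical(generalize_column(tb2, "X", "bin_round", 5)$X, c(5, -5))
})

test_that("range banding hides an extreme age inside its decade band", {
  tbl <- tibble::tibble(ID = "a", AGE = 96)
  expect_identical(generalize_column(tbl, "AGE", "range_band", 10)$AGE,
                   "[90, 100)")
})

test_that("generalization properties: bounded error, idempotence, shape-preserving", {
  set.seed(20)
  tbl <- tibble::tibble(ID = sprintf("S%02d", 1:40),
                        X = round(runif(40, -200, 200), 2))
  tbl$X[c(4, 17)] <- NA
  for (w in c(2, 5, 10)) {
    g1 <- generalize_column(tbl, "X", "bin_round", w)
    expect_identical(dim(g1), dim(tbl))
    expect_identical(names(g1), names(tbl))
    expect_true(all(abs(g1$X - tbl$X) <= w / 2 + 1e-9, na.rm = TRUE))
    expect_identical(is.na(g1$X), is.na(tbl$X))
    expect_identical(generalize_column(g1, "X", "bin_round", w)$X, g1$X)
  }
  sf <- generalize_column(tbl, "X", "sig_figs", 2)
  expect_identical(sf$X, signif(tbl$X, 2))
  expect_error(generalize_column(tbl, "ID", "bin_round", 5),
               class = "neuroscrub_type_error")
})
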