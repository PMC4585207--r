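# Demographic/behavioral table handling. Tables are plain tibbles whose
# FIRST column is the subject-ID column (the linkage key for associative
# matching); missing values are NA in memory and a configurable token on
# disk.

MISSING_TOKENS <- c("", "NA", "NaN", "N/A", ".")

#' Load a delimited demographic/behavioral table
#'
#' Reads a TSV/CSV with a header row; the delimiter is sniffed from the
#' header line unless forced. Numeric-looking columns are typed as
#' numbers; the tokens `""`, `"NA"`, `"NaN"`, `"N/A"` and `"."` are read
#' as missing. The first column is the subject-ID column: it is always
#' typed as character and must be unique and non-missing.
#'
#' @param path Delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma
#'   from the header line.
#' @return A tibble.
#' @export
load_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such table file: ", path),
                 class = "neuroscrub_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    rlang::abort("empty table file", class = "neuroscrub_table_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\t", lines[1])) "\t" else ","
  }
  # count separators (not split fields) so trailing empty cells still count
  arity <- vapply(lines, function(l) {
    m <- gregexpr(delim, l, fixed = TRUE)[[1]]
    sum(m > 0) + 1L
  }, integer(1), USE.NAMES = FALSE)
  if (length(unique(arity)) > 1L) {
    rlang::abort(
      sprintf("ragged table: header has %d fields but row %d has %d",
              arity[1], which(arity != arity[1])[1] - 1L,
              arity[arity != arity[1]][1]),
      class = "neuroscrub_ragged_table"
    )
  }
  tbl <- readr::read_delim(path, delim = delim, na = MISSING_TOKENS,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  # type numeric-looking columns ourselves: readr's guesser would read a
  # single-letter sex column ("F") as logical and corrupt the cells
  for (j in seq_along(tbl)[-1]) {
    x <- tbl[[j]]
    num <- suppressWarnings(as.numeric(x))
    if (!any(is.na(num) & !is.na(x))) tbl[[j]] <- num
  }
  validate_table(tbl)
  tbl
}

validate_table <- function(table) {
  ids <- table[[1]]
  if (anyNA(ids)) {
    rlang::abort("missing value in the subject-ID column",
                 class = "neuroscrub_table_error")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    rlang::abort(paste0("duplicate subject ID(s): ", paste(dup, collapse = ", ")),
                 class = "neuroscrub_duplicate_id")
  }
  invisible(table)
}

#' Write a table as delimited text
#'
#' Header row first; missing cells are written as `missing_code`.
#'
#' @param table A tibble/data frame.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @param missing_code Token written for missing cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, delim = "\t", missing_code = "NA") {
  readr::write_delim(table, path, delim = delim, na = missing_code)
  invisible(path)
}

#' Locate missing cells
#'
#' @param table A tibble.
#' @return A tibble with one row per missing cell, columns `row`,
#'   `column` (name) and `col` (index), in row-major order.
#' @export
find_missing <- function(table) {
  hits <- which(is.na(as.matrix(table)), arr.ind = TRUE)
  out <- tibble::tibble(row = as.integer(hits[, 1]),
                        col = as.integer(hits[, 2]))
  out <- dplyr::arrange(out, .data$row, .data$col)
  dplyr::mutate(out, column = names(table)[.data$col], .before = "col")
}

default_identifier_patterns <- function() {
  # "id" is matched as a token (bounded by non-letters or string edges) so
  # that e.g. a RESIDUAL column is not flagged; the rest match as substrings
  # (TESTDATE must trip "date").
  c(id = "(^|[^a-z])id([^a-z]|$)",
    name = "name", dob = "dob", birth = "birth", date = "date",
    address = "address", phone = "phone", ssn = "ssn", mrn = "mrn",
    email = "email", zip = "zip")
}

DATE_FORMATS <- c("%Y-%m-%d", "%m/%d/%Y", "%d/%m/%Y")

date_parse_fraction <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(0)
  x <- as.character(x)
  # each value may use any accepted pattern (mixed exports are common)
  ok <- Reduce(`|`, lapply(DATE_FORMATS, function(f) !is.na(as.Date(x, format = f))))
  mean(ok)
}

#' Auto-detect identifier columns
#'
#' Flags (a) the first column, always, as the ID column; (b) columns
#' whose name matches a configured identifier pattern (default roster:
#' id, name, dob, birth, date, address, phone, ssn, mrn, email, zip;
#' case-insensitive); (c) character columns in which at least
#' `date_threshold` of the non-missing values parse as calendar dates
#' (ISO `yyyy-mm-dd`, US `mm/dd/yyyy` or European `dd/mm/yyyy`).
#' Detection is pure and deterministic.
#'
#' @param table A tibble.
#' @param patterns Named character vector of case-insensitive regexes
#'   matched against column names.
#' @param date_threshold Fraction of non-missing values that must parse
#'   as dates for a `DATE_VALUES` finding (default 0.8).
#' @return A tibble of findings: `column`, `reason`
#'   (`ID_LABEL`/`NAME_PATTERN`/`DATE_VALUES`), `note`.
#' @export
detect_identifier_columns <- function(table,
                                      patterns = default_identifier_patterns(),
                                      date_threshold = 0.8) {
  findings <- purrr::imap(names(table), function(nm, i) {
    if (i == 1L) {
      return(tibble::tibble(column = nm, reason = "ID_LABEL",
                            note = "first column is the subject-ID column"))
    }
    hit <- which(vapply(patterns, function(p) grepl(p, nm, ignore.case = TRUE),
                        logical(1)))
    if (length(hit)) {
      return(tibble::tibble(column = nm, reason = "NAME_PATTERN",
                            note = paste0("column name matches pattern '",
                                          names(patterns)[hit[1]], "'")))
    }
    if (is.character(table[[i]])) {
      frac <- date_parse_fraction(table[[i]])
      if (frac >= date_threshold) {
        return(tibble::tibble(column = nm, reason = "DATE_VALUES",
                              note = sprintf("%.0f%% of values parse as dates",
                                             100 * frac)))
      }
    }
    NULL
  })
  dplyr::bind_rows(findings)
}

#' Drop columns from a table
#'
#' Returns a new table without the named columns; the input is not
#' modified, so the operation can be reverted by keeping the original.
#' The subject-ID column (column 1) may not be dropped while it is still
#' needed for image matching; set `allow_id = TRUE` only after the IDs
#' have been re-labelled.
#'
#' @param table A tibble.
#' @param columns Column names to drop.
#' @param allow_id Permit dropping the first column.
#' @return The reduced tibble.
#' @export
drop_columns <- function(table, columns, allow_id = FALSE) {
  unknown <- setdiff(columns, names(table))
  if (length(unknown)) {
    rlang::abort(paste0("no such column(s): ", paste(unknown, collapse = ", ")),
                 class = "neuroscrub_unknown_column")
  }
  if (!allow_id && names(table)[1] %in% columns) {
    rlang::abort("refusing to drop the subject-ID column before re-labelling",
                 class = "neuroscrub_id_column_needed")
  }
  dplyr::select(table, -dplyr::all_of(columns))
}

round_half_away <- function(x, w) {
  sign(x) * floor(abs(x) / w + 0.5) * w
}

#' Generalize a quasi-identifier column
#'
#' Coarsens a numeric column to reduce re-identification risk while
#' preserving analytic structure:
#' \describe{
#'   \item{`bin_round`}{round to the nearest multiple of `parameter`
#'     (halves away from zero), e.g. heights 172, 168, 181 with width 5
#'     become 170, 170, 180.}
#'   \item{`sig_figs`}{keep `parameter` significant figures.}
#'   \item{`range_band`}{replace x by the label `"[kw, (k+1)w)"` with
#'     `k = floor(x/w)`; an age of 96 with width 10 becomes
#'     `"[90, 100)"`, hiding extreme values inside a band.}
#' }
#' Missing cells pass through unchanged.
#'
#' @param table A tibble.
#' @param column Name of a numeric column.
#' @param kind `"bin_round"`, `"sig_figs"` or `"range_band"`.
#' @param parameter Bin width, significant figures, or band width
#'   (must be > 0).
#' @return The tibble with the column generalized (`range_band` converts
#'   it to character).
#' @export
generalize_column <- function(table, column,
                              kind = c("bin_round", "sig_figs", "range_band"),
                              parameter) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(parameter), parameter > 0)
  if (!column %in% names(table)) {
    rlang::abort(paste0("no such column: ", column),
                 class = "neuroscrub_unknown_column")
  }
  x <- table[[column]]
  if (!is.numeric(x)) {
    bad <- which(!is.na(x))[1]
    rlang::abort(
      sprintf("cannot generalize non-numeric column '%s' (e.g. cell row %d: '%s')",
              column, bad, x[bad]),
      class = "neuroscrub_type_error"
    )
  }
  table[[column]] <- switch(kind,
    bin_round = round_half_away(x, parameter),
    sig_figs = signif(x, digits = as.integer(parameter)),
    range_band = {
      k <- floor(x / parameter)
      ifelse(is.na(x), NA_character_,
             sprintf("[%g, %g)", k * parameter, (k + 1) * parameter))
    }
  )
  table
}
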