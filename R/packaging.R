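# Audited packaging: share manifest, identifier leak scan, tar.gz build.

SHARING_LEVELS <- c("OPEN", "ENCLAVE", "RECIPIENT_ONLY")
KEY_FILE_PATTERN <- "_?key\\.tsv$"

#' Build a share manifest
#'
#' Records who prepared the dataset, where, when, at which sharing level
#' — open access, data-enclave access, or recipient-only — and the
#' required attestation that the data have been inspected and carry no
#' personal health identifiers. Packaging refuses to proceed without the
#' attestation.
#'
#' @param user Contributor name (non-empty).
#' @param institution Contributor institution (non-empty).
#' @param sharing_level One of `"OPEN"`, `"ENCLAVE"`, `"RECIPIENT_ONLY"`.
#' @param attestation Must be `TRUE`: the contributor has inspected the
#'   de-identified data.
#' @return An object of class `ns_manifest`.
#' @export
build_manifest <- function(user, institution,
                           sharing_level = SHARING_LEVELS,
                           attestation = FALSE) {
  sharing_level <- match.arg(sharing_level)
  if (!is.character(user) || !nzchar(trimws(user))) {
    rlang::abort("contributor name must be non-empty",
                 class = "neuroscrub_bad_input")
  }
  if (!is.character(institution) || !nzchar(trimws(institution))) {
    rlang::abort("institution must be non-empty",
                 class = "neuroscrub_bad_input")
  }
  if (!isTRUE(attestation)) {
    rlang::abort(
      "attestation required: confirm the data have been inspected for identifiers",
      class = "neuroscrub_attestation_required"
    )
  }
  structure(
    list(user = user, institution = institution,
         sharing_level = sharing_level, attestation = TRUE,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         tool_version = as.character(utils::packageVersion("neuroscrub"))),
    class = "ns_manifest"
  )
}

format_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "ns_manifest"))
  paste0(c("contributor", "institution", "sharing_level", "attestation",
           "timestamp", "tool_version"), ": ",
         c(manifest$user, manifest$institution, manifest$sharing_level,
           tolower(manifest$attestation), manifest$timestamp,
           manifest$tool_version))
}

#' @export
print.ns_manifest <- function(x, ...) {
  cat(format_manifest(x), sep = "\n")
  invisible(x)
}

write_manifest <- function(manifest, path) {
  writeLines(format_manifest(manifest), path)
  invisible(path)
}

#' Scan a de-identified dataset for identifier leaks
#'
#' Case-sensitive substring search for every original subject ID and
#' every distinct value from dropped identifier columns across (a) every
#' filename under `dataset_dir`, (b) every cell of the shared table,
#' (c) every editable free-text header field of every image under
#' `dataset_dir`, and (d) the manifest/log text if present. An empty
#' findings table means the set is clean; packaging is gated on it.
#'
#' @param dataset_dir Directory holding the shareable output.
#' @param table The shared (re-labelled) tibble, or `NULL`.
#' @param original_ids Character vector of the original subject IDs.
#' @param dropped_values Distinct values from dropped identifier columns
#'   (names, dates of birth, ...).
#' @return An object of class `ns_leak_report`: a tibble of findings with
#'   columns `kind` (`FILENAME`/`TABLE_CELL`/`HEADER_FIELD`/`MANIFEST`),
#'   `location`, `matched`.
#' @export
scan_for_leaks <- function(dataset_dir, table = NULL, original_ids,
                           dropped_values = character()) {
  needles <- unique(c(as.character(original_ids), as.character(dropped_values)))
  needles <- needles[!is.na(needles) & nzchar(needles)]
  findings <- list()
  add <- function(kind, location, matched) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(kind = kind, location = location, matched = matched)
  }
  scan_text <- function(kind, location, text) {
    for (ndl in needles) {
      if (any(grepl(ndl, text, fixed = TRUE))) add(kind, location, ndl)
    }
  }
  files <- sort(list.files(dataset_dir, recursive = TRUE, full.names = FALSE))
  for (fl in files) scan_text("FILENAME", fl, fl)
  if (!is.null(table)) {
    cells <- as.matrix(dplyr::mutate(table, dplyr::across(dplyr::everything(),
                                                          as.character)))
    for (ndl in needles) {
      hit <- which(!is.na(cells) & grepl(ndl, cells, fixed = TRUE),
                   arr.ind = TRUE)
      if (nrow(hit)) {
        add("TABLE_CELL",
            sprintf("row %d, column %s", hit[, 1], colnames(cells)[hit[, 2]]),
            rep(ndl, nrow(hit)))
      }
    }
  }
  hdr_files <- files[grepl(IMAGE_EXTS, files, ignore.case = TRUE)]
  for (fl in hdr_files) {
    h <- read_header(file.path(dataset_dir, fl))
    for (fname in editable_fields(h)) {
      scan_text("HEADER_FIELD", paste0(fl, ":", fname), h$values[[fname]])
    }
  }
  for (fl in files[grepl("\\.(log|txt)$", files)]) {
    scan_text("MANIFEST", fl, readLines(file.path(dataset_dir, fl), warn = FALSE))
  }
  out <- if (length(findings)) dplyr::bind_rows(findings) else
    tibble::tibble(kind = character(), location = character(),
                   matched = character())
  class(out) <- c("ns_leak_report", class(out))
  out
}

#' Package a de-identified dataset as tar.gz
#'
#' Writes the manifest log into `dataset_dir` and archives the directory
#' (images, shared table, log) as a gzip-compressed POSIX tar with
#' members sorted by path, so packaging is deterministic for fixed
#' inputs. Refuses to run if the manifest is not attested, if the leak
#' report has findings (unless `force = TRUE`, which logs an override),
#' or if an ID key file is present inside `dataset_dir` — the key must
#' never be shared.
#'
#' @param dataset_dir Directory with the shareable files.
#' @param manifest An attested `ns_manifest`.
#' @param out_path Output `.tar.gz` path.
#' @param leak_report An `ns_leak_report` for the dataset (from
#'   [scan_for_leaks()]); `NULL` skips the gate only with `force`.
#' @param force Package despite leak findings; the override is recorded
#'   in the log.
#' @return `out_path`, invisibly.
#' @export
package_dataset <- function(dataset_dir, manifest, out_path,
                            leak_report = NULL, force = FALSE) {
  stopifnot(inherits(manifest, "ns_manifest"))
  if (!isTRUE(manifest$attestation)) {
    rlang::abort("manifest is not attested",
                 class = "neuroscrub_attestation_required")
  }
  key_hits <- list.files(dataset_dir, pattern = KEY_FILE_PATTERN,
                         recursive = TRUE)
  if (length(key_hits)) {
    rlang::abort(paste0("ID key file inside dataset directory: ",
                        paste(key_hits, collapse = ", ")),
                 class = "neuroscrub_key_in_output")
  }
  has_findings <- !is.null(leak_report) && nrow(leak_report) > 0
  if ((is.null(leak_report) || has_findings) && !force) {
    msg <- if (is.null(leak_report)) {
      "no leak report supplied; run scan_for_leaks() or pass force = TRUE"
    } else {
      sprintf("leak scan reported %d finding(s); refusing to package", nrow(leak_report))
    }
    rlang::abort(msg, class = "neuroscrub_leak_detected")
  }
  log_lines <- format_manifest(manifest)
  if (force && (is.null(leak_report) || has_findings)) {
    log_lines <- c(log_lines, "leak_gate_override: true")
  }
  writeLines(log_lines, file.path(dataset_dir, "share.log"))
  members <- sort(list.files(dataset_dir, recursive = TRUE))
  old <- setwd(dataset_dir)
  on.exit(setwd(old), add = TRUE)
  out_abs <- if (grepl("^/", out_path)) out_path else file.path(old, out_path)
  utils::tar(out_abs, files = members, compression = "gzip", tar = "internal")
  invisible(out_abs)
}
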