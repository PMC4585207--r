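# Container conversion between single-file NIfTI-1, NIfTI-1 hdr/img pairs
# and Analyze 7.5. Some Windows brain-extraction builds only accept the
# hdr/img bundle, so the pipeline converts .nii inputs before stripping
# and converts results back.

expected_data_bytes <- function(header) {
  dims <- header$values$dim[2:4]
  prod(dims) * header$values$bitpix / 8
}

#' Convert a single-file NIfTI to a hdr/img pair
#'
#' Splits a `.nii` into a 348-byte `.hdr` (magic rewritten to `"ni1\0"`,
#' `vox_offset` reset to 0) and a raw `.img` holding exactly the voxel
#' bytes that started at the source's `vox_offset`. Header extensions, if
#' present, are dropped with a warning: extension blocks are opaque and
#' can carry identifiers.
#'
#' @param path A `.nii` file (`detect_format` must say `NIFTI_SINGLE`).
#' @param out_dir Output directory (created if missing).
#' @return Named character vector `c(hdr = ..., img = ...)`.
#' @export
convert_nii_to_pair <- function(path, out_dir) {
  all_bytes <- readBin(path, "raw", n = file.size(path))
  fmt <- detect_format(all_bytes)
  if (fmt != "NIFTI_SINGLE") {
    rlang::abort(sprintf("%s is %s, not a single-file NIfTI", path, fmt),
                 class = "neuroscrub_format_error")
  }
  h <- read_header(utils::head(all_bytes, HEADER_SIZE))
  vox_offset <- as.integer(round(h$values$vox_offset))
  if (vox_offset < 352L) {
    rlang::abort(sprintf("malformed .nii: vox_offset %d < 352", vox_offset),
                 class = "neuroscrub_malformed_file")
  }
  if (vox_offset > 352L) {
    warning("dropping NIfTI header extensions during conversion", call. = FALSE)
  }
  nbytes <- expected_data_bytes(h)
  if (length(all_bytes) < vox_offset + nbytes) {
    rlang::abort("malformed .nii: file shorter than vox_offset + voxel data",
                 class = "neuroscrub_malformed_file")
  }
  data <- all_bytes[(vox_offset + 1L):(vox_offset + nbytes)]
  h <- hdr_poke(h, "magic", "ni1")
  h <- hdr_poke(h, "vox_offset", 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- tools::file_path_sans_ext(basename(path))
  hdr <- file.path(out_dir, paste0(stem, ".hdr"))
  img <- file.path(out_dir, paste0(stem, ".img"))
  writeBin(h$bytes, hdr)
  writeBin(data, img)
  c(hdr = hdr, img = img)
}

# Analyze 7.5 bytes 0..251 are layout-compatible with NIfTI-1 for the
# geometry fields; the data_history struct (252..347) is not, so a
# promoted header keeps only geometry + free text and leaves the NIfTI
# intent/slice/transform fields at identity-compatible defaults
# (qform_code = sform_code = 0, scl_slope = 0).
promote_analyze_header <- function(h) {
  nh <- build_header_bytes("NIFTI_SINGLE", h$values$dim[2:4], h$values$datatype,
                           pixdim = h$values$pixdim[2:4], endian = h$endianness)
  for (name in c("data_type", "db_name", "extents", "session_error", "regular",
                 "dim", "datatype", "bitpix", "pixdim", "cal_max", "cal_min",
                 "glmax", "glmin", "descrip", "aux_file")) {
    nh <- hdr_poke(nh, name, h$values[[name]])
  }
  nh <- hdr_poke(nh, "dim", h$values$dim)  # keep full 8-slot dim array
  nh
}

#' Convert a hdr/img pair (NIfTI or Analyze) to a single-file NIfTI
#'
#' Writes one `.nii` with magic `"n+1\0"` and `vox_offset = 352`, voxel
#' bytes appended after the header. Analyze 7.5 inputs are promoted to
#' NIfTI-1 with identity-compatible defaults for the NIfTI-only fields;
#' their free-text history fields do not survive promotion (they have no
#' NIfTI slot), which is de-identification-safe by construction.
#'
#' @param hdr_path The `.hdr` file.
#' @param img_path The `.img` file; inferred from `hdr_path` when `NULL`.
#' @param out_dir Output directory (created if missing).
#' @return Path of the written `.nii`.
#' @export
convert_pair_to_nii <- function(hdr_path, img_path = NULL, out_dir) {
  if (is.null(img_path)) img_path <- sub("\\.hdr$", ".img", hdr_path,
                                         ignore.case = TRUE)
  h <- read_header(hdr_path)
  if (h$format == "NIFTI_SINGLE") {
    rlang::abort("input is a single-file NIfTI already",
                 class = "neuroscrub_format_error")
  }
  nbytes <- expected_data_bytes(h)
  actual <- file.size(img_path) - as.integer(round(h$values$vox_offset))
  if (is.na(actual) || actual != nbytes) {
    rlang::abort(
      sprintf(".img size mismatch: header implies %d data bytes, file has %s",
              nbytes, actual),
      class = "neuroscrub_size_mismatch"
    )
  }
  data <- readBin(img_path, "raw", n = file.size(img_path))
  if (h$values$vox_offset > 0) {
    data <- data[-seq_len(as.integer(round(h$values$vox_offset)))]
  }
  if (h$format == "ANALYZE75") {
    h <- promote_analyze_header(h)
  } else {
    h <- hdr_poke(h, "magic", "n+1")
    h <- hdr_poke(h, "vox_offset", 352)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- tools::file_path_sans_ext(basename(hdr_path))
  nii <- file.path(out_dir, paste0(stem, ".nii"))
  writeBin(c(h$bytes, raw(4L), data), nii)
  nii
}
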