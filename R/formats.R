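#' Detect the on-disk image format from a 348-byte header
#'
#' Classifies a candidate header as single-file NIfTI-1 (`"NIFTI_SINGLE"`),
#' NIfTI-1 hdr/img pair (`"NIFTI_PAIR"`) or Analyze 7.5 (`"ANALYZE75"`) by
#' inspecting the four magic bytes at offset 344: `"n+1\0"` marks a
#' single-file NIfTI, `"ni1\0"` a NIfTI pair, and anything else an
#' Analyze 7.5 header. An Analyze header whose `smin` field happens to spell
#' one of the magic strings is (by this rule) treated as NIfTI; the
#' probability of a legitimate `smin` doing so is negligible.
#'
#' @param x Path to a `.hdr`/`.nii` file, or a raw vector holding at least
#'   the first 348 bytes of one.
#' @return A length-1 character: `"NIFTI_SINGLE"`, `"NIFTI_PAIR"` or
#'   `"ANALYZE75"`.
#' @examples
#' p <- make_head_volume(fixture_spec(seed = 1), format = "nii",
#'                       dir = tempdir(), stem = "ex")
#' detect_format(p$paths[1])
#' @export
detect_format <- function(x) {
  bytes <- header_bytes_from(x, n = HEADER_SIZE)
  if (length(bytes) < HEADER_SIZE) {
    rlang::abort(
      sprintf("malformed header: need %d bytes, got %d", HEADER_SIZE, length(bytes)),
      class = "neuroscrub_malformed_header"
    )
  }
  if (is.na(detect_endianness(bytes))) {
    rlang::abort(
      "unrecognized format: sizeof_hdr is not 348 under either byte order",
      class = "neuroscrub_unrecognized_format"
    )
  }
  magic <- bytes[345:348]
  if (identical(magic, c(charToRaw("ni1"), as.raw(0L)))) return("NIFTI_PAIR")
  if (identical(magic, c(charToRaw("n+1"), as.raw(0L)))) return("NIFTI_SINGLE")
  "ANALYZE75"
}

header_bytes_from <- function(x, n = HEADER_SIZE) {
  if (is.raw(x)) return(utils::head(x, n))
  if (!is.character(x) || length(x) != 1L) {
    stop("expected a file path or raw vector")
  }
  if (!file.exists(x)) {
    rlang::abort(paste0("cannot read header: no such file: ", x),
                 class = "neuroscrub_io_error")
  }
  readBin(x, what = "raw", n = n)
}

detect_endianness <- function(bytes) {
  for (e in c("little", "big")) {
    sz <- readBin(bytes[1:4], "integer", n = 1L, size = 4L, endian = e)
    if (identical(sz, HEADER_SIZE)) return(e)
  }
  NA_character_
}

decode_field <- function(bytes, offset, storage, n, endian) {
  span <- bytes[(offset + 1L):(offset + storage_size(storage) * n)]
  switch(storage,
    int8    = readBin(span, "integer", n = n, size = 1L, signed = TRUE, endian = endian),
    int16   = readBin(span, "integer", n = n, size = 2L, signed = TRUE, endian = endian),
    int32   = readBin(span, "integer", n = n, size = 4L, endian = endian),
    float32 = readBin(span, "numeric", n = n, size = 4L, endian = endian),
    char    = decode_cstring(span)
  )
}

decode_cstring <- function(span) {
  nul <- which(span == as.raw(0L))
  if (length(nul)) span <- span[seq_len(nul[1L] - 1L)]
  if (!length(span)) return("")
  rawToChar(span)
}

encode_field <- function(value, storage, n, endian) {
  out <- switch(storage,
    int8    = writeBin(as.integer(value), raw(), size = 1L, endian = endian),
    int16   = writeBin(as.integer(value), raw(), size = 2L, endian = endian),
    int32   = writeBin(as.integer(value), raw(), size = 4L, endian = endian),
    float32 = writeBin(as.double(value),  raw(), size = 4L, endian = endian),
    char    = encode_cstring(value, n)
  )
  width <- storage_size(storage) * n
  if (length(out) != width) {
    stop(sprintf("encoded %d bytes for a %d-byte field", length(out), width))
  }
  out
}

encode_cstring <- function(value, width) {
  value <- as.character(value)
  b <- charToRaw(value)
  if (length(b) > width) {
    rlang::abort(
      sprintf("value '%s' is %d bytes; field holds at most %d (oversize values are rejected, not truncated)",
              value, length(b), width),
      class = "neuroscrub_oversize_value"
    )
  }
  c(b, raw(width - length(b)))
}

#' Read and decode an image header
#'
#' Reads the 348-byte Analyze 7.5 / NIfTI-1 header of a `.hdr` or `.nii`
#' file, auto-detecting format and byte order (via `sizeof_hdr == 348`
#' after a trial byte swap), and decodes every field at its published
#' offset. The original bytes are retained so that unedited headers
#' re-encode byte-for-byte.
#'
#' @param x Path to a `.hdr` or `.nii` file, or a raw vector with the
#'   header bytes.
#' @return An object of class `ns_header`: a list with elements `format`,
#'   `endianness`, `layout` (field table), `values` (named list of decoded
#'   values), `bytes` (current 348 header bytes) and `raw` (bytes as read).
#' @seealso [header_fields()] for a tibble view, [edit_header_field()],
#'   [scrub_header()]
#' @export
read_header <- function(x) {
  if (is.character(x) && grepl("\\.img$", x, ignore.case = TRUE)) {
    rlang::abort("pass the .hdr file of a pair, not the .img",
                 class = "neuroscrub_io_error")
  }
  bytes <- header_bytes_from(x, n = HEADER_SIZE)
  format <- detect_format(bytes)
  endian <- detect_endianness(bytes)
  layout <- layout_for_format(format)
  values <- purrr::map(seq_len(nrow(layout)), function(i) {
    decode_field(bytes, layout$offset[i], layout$storage[i], layout$n[i], endian)
  })
  names(values) <- layout$name
  structure(
    list(format = format, endianness = endian, layout = layout,
         values = values, bytes = bytes, raw = bytes,
         path = if (is.character(x)) x else NA_character_),
    class = "ns_header"
  )
}

#' Re-encode a decoded header to its 348 bytes
#'
#' Encodes every decoded field back into its byte span. For a header with
#' no edits this reproduces the bytes read from disk exactly; the identity
#' `encode_header(read_header(x))$bytes == bytes(x)` is part of the format
#' contract and is fuzz-tested.
#'
#' @param header An `ns_header`.
#' @return A raw vector of length 348.
#' @export
encode_header <- function(header) {
  stopifnot(inherits(header, "ns_header"))
  out <- raw(HEADER_SIZE)
  lay <- header$layout
  for (i in seq_len(nrow(lay))) {
    enc <- encode_field(header$values[[lay$name[i]]], lay$storage[i], lay$n[i],
                        header$endianness)
    out[(lay$offset[i] + 1L):(lay$offset[i] + length(enc))] <- enc
  }
  out
}

#' Tabular view of a decoded header
#'
#' @param header An `ns_header`.
#' @return A tibble with one row per field: `name`, `offset`, `storage`,
#'   `size` (bytes), `editable`, and `value` (formatted as a string; array
#'   fields are space-separated).
#' @export
header_fields <- function(header) {
  stopifnot(inherits(header, "ns_header"))
  dplyr::mutate(
    header$layout,
    size = storage_size_vec(.data$storage) * .data$n,
    value = purrr::map_chr(header$values[.data$name], format_field_value)
  )[, c("name", "offset", "storage", "size", "editable", "value")]
}

storage_size_vec <- function(storage) {
  vapply(storage, storage_size, integer(1), USE.NAMES = FALSE)
}

format_field_value <- function(v) {
  if (is.character(v)) return(v)
  paste(format(v, trim = TRUE, digits = 7), collapse = " ")
}

#' @export
print.ns_header <- function(x, ...) {
  cat(sprintf("<%s header, %s-endian>\n", x$format, x$endianness))
  f <- header_fields(x)
  tag <- ifelse(f$editable, "editable ", "protected")
  cat(sprintf("  %-14s @%3d %-9s [%s] %s\n",
              f$name, f$offset, f$storage, tag, f$value), sep = "")
  invisible(x)
}

field_row <- function(header, name) {
  i <- match(name, header$layout$name)
  if (is.na(i)) {
    rlang::abort(sprintf("unknown header field '%s'", name),
                 class = "neuroscrub_unknown_field")
  }
  header$layout[i, ]
}

# Write a value into a field's byte span without the editable check;
# used internally by format conversion, which must rewrite protected
# fields (magic, vox_offset) as part of the container change.
hdr_poke <- function(header, name, value) {
  f <- field_row(header, name)
  enc <- encode_field(value, f$storage, f$n, header$endianness)
  header$bytes[(f$offset + 1L):(f$offset + length(enc))] <- enc
  header$values[[name]] <- decode_field(header$bytes, f$offset, f$storage, f$n,
                                        header$endianness)
  header
}

#' Edit one editable header field
#'
#' Returns a new header whose re-encoded bytes differ from the original
#' only within the named field's byte span. Geometry and codec fields
#' (`dim`, `datatype`, `bitpix`, `pixdim`, `vox_offset`, transform fields,
#' ...) are protected and cannot be edited, preserving the image format.
#' Strings longer than the field are rejected rather than truncated.
#'
#' @param header An `ns_header`.
#' @param name Field name (see [header_fields()]).
#' @param value New value; character for the free-text fields.
#' @return The edited `ns_header`.
#' @export
edit_header_field <- function(header, name, value) {
  stopifnot(inherits(header, "ns_header"))
  f <- field_row(header, name)
  if (!f$editable) {
    rlang::abort(sprintf("field '%s' is protected and cannot be edited", name),
                 class = "neuroscrub_protected_field")
  }
  hdr_poke(header, name, value)
}

#' Editable field names of a header
#'
#' @param header An `ns_header`.
#' @return Character vector of the free-text field names that may be
#'   edited or scrubbed for this header's format.
#' @export
editable_fields <- function(header) {
  stopifnot(inherits(header, "ns_header"))
  header$layout$name[header$layout$editable]
}

#' Scrub free-text header fields
#'
#' Zero-fills the named fields (default: every editable free-text field),
#' removing embedded identifiers such as a patient ID or experiment date
#' while leaving all protected geometry bytes untouched. Scrubbing is
#' idempotent.
#'
#' @param header An `ns_header`.
#' @param fields Field names to scrub; must all be editable. Defaults to
#'   the full editable roster.
#' @return The scrubbed `ns_header`; scrubbed fields decode to `""`.
#' @export
scrub_header <- function(header, fields = NULL) {
  stopifnot(inherits(header, "ns_header"))
  if (is.null(fields)) fields <- editable_fields(header)
  for (name in fields) {
    f <- field_row(header, name)
    if (!f$editable) {
      rlang::abort(sprintf("refusing to scrub protected field '%s'", name),
                   class = "neuroscrub_protected_field")
    }
    width <- storage_size(f$storage) * f$n
    header$bytes[(f$offset + 1L):(f$offset + width)] <- raw(width)
    header$values[[name]] <- ""
  }
  header
}

#' Scrub the header of an image file on disk
#'
#' Applies [scrub_header()] to a `.hdr` or `.nii` file in place (or to a
#' copy at `out_path`). For single-file NIfTI images any header extensions
#' are dropped with a warning — extension blocks are opaque and a common
#' hiding place for identifiers — and the voxel data is preserved.
#'
#' @param path `.hdr` or `.nii` file.
#' @param fields Passed to [scrub_header()].
#' @param out_path Output file; defaults to rewriting `path`.
#' @return `out_path`, invisibly.
#' @export
scrub_image_header <- function(path, fields = NULL, out_path = path) {
  all_bytes <- readBin(path, "raw", n = file.size(path))
  h <- read_header(utils::head(all_bytes, HEADER_SIZE))
  h <- scrub_header(h, fields)
  if (h$format == "NIFTI_SINGLE") {
    vox_offset <- h$values$vox_offset
    ext_flag <- if (length(all_bytes) >= HEADER_SIZE + 4L) {
      all_bytes[HEADER_SIZE + 1L]
    } else raw(1)
    if (ext_flag != as.raw(0L) || vox_offset > 352) {
      warning("dropping NIfTI header extensions during scrub", call. = FALSE)
      h <- hdr_poke(h, "vox_offset", 352)
    }
    data <- all_bytes[(vox_offset + 1L):length(all_bytes)]
    out <- c(h$bytes, raw(4L), data)
  } else {
    out <- c(h$bytes, all_bytes[-seq_len(min(length(all_bytes), HEADER_SIZE))])
  }
  writeBin(out, out_path)
  invisible(out_path)
}
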