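# Voxel codec table: NIfTI/Analyze datatype code -> storage parameters.
DATATYPES <- list(
  `2`  = list(name = "uint8",   size = 1L, signed = FALSE, what = "integer", bitpix = 8L),
  `4`  = list(name = "int16",   size = 2L, signed = TRUE,  what = "integer", bitpix = 16L),
  `8`  = list(name = "int32",   size = 4L, signed = TRUE,  what = "integer", bitpix = 32L),
  `16` = list(name = "float32", size = 4L, signed = TRUE,  what = "numeric", bitpix = 32L)
)

datatype_info <- function(code) {
  info <- DATATYPES[[as.character(code)]]
  if (is.null(info)) {
    rlang::abort(sprintf("unsupported datatype code %s", code),
                 class = "neuroscrub_unsupported_datatype")
  }
  info
}

# Volumes are environments so voxel data can be materialized on first
# access and released again; a package-level registry tracks how many
# volumes hold data at once, which keeps whole-directory operations
# (montage, batch defacing) honest about their memory footprint.
.vol_registry <- new.env(parent = emptyenv())
.vol_registry$current <- 0L
.vol_registry$peak <- 0L
.vol_registry$loads <- 0L

#' Reset / read the volume load counters
#'
#' The registry counts volumes whose voxel data is currently materialized
#' in memory (`current`), the historical maximum (`peak`) and the total
#' number of loads (`loads`). Batch operations such as [render_montage()]
#' are written to keep `peak` at 2 (one original/stripped pair)
#' regardless of how many volumes they traverse.
#'
#' @return `volume_load_stats()` returns a tibble with columns `current`,
#'   `peak`, `loads`.
#' @export
volume_load_stats <- function() {
  tibble::tibble(current = .vol_registry$current,
                 peak = .vol_registry$peak,
                 loads = .vol_registry$loads)
}

#' @rdname volume_load_stats
#' @export
reset_volume_load_stats <- function() {
  .vol_registry$current <- 0L
  .vol_registry$peak <- 0L
  .vol_registry$loads <- 0L
  invisible(NULL)
}

new_volume <- function(header, data_path, data_offset, data = NULL) {
  v <- new.env(parent = emptyenv())
  v$header <- header
  v$data_path <- data_path
  v$data_offset <- data_offset
  v$data <- data
  v$dims <- header$values$dim[2:4]
  v$datatype <- header$values$datatype
  if (!is.null(data)) register_load()
  class(v) <- "ns_volume"
  v
}

register_load <- function() {
  .vol_registry$current <- .vol_registry$current + 1L
  .vol_registry$loads <- .vol_registry$loads + 1L
  .vol_registry$peak <- max(.vol_registry$peak, .vol_registry$current)
}

#' Open an image volume (lazily)
#'
#' Opens a `.nii` single file or a `.hdr`/`.img` pair (NIfTI or Analyze).
#' Only the 348-byte header is read at open time; voxel data is read from
#' disk on the first call to [voxels()] and cached until [release_voxels()]
#' — the lazy-loading contract that lets directory-scale operations bound
#' their memory use.
#'
#' @param path Path to a `.nii` or `.hdr` file (an `.img` path is
#'   redirected to its `.hdr`).
#' @return An `ns_volume` object.
#' @export
read_volume <- function(path) {
  if (grepl("\\.img$", path, ignore.case = TRUE)) {
    path <- sub("\\.img$", ".hdr", path, ignore.case = TRUE)
  }
  header <- read_header(path)
  datatype_info(header$values$datatype)  # fail fast on unsupported codes
  if (header$format == "NIFTI_SINGLE") {
    data_path <- path
    data_offset <- as.integer(round(header$values$vox_offset))
  } else {
    data_path <- sub("\\.hdr$", ".img", path, ignore.case = TRUE)
    if (!file.exists(data_path)) {
      rlang::abort(paste0("missing .img companion for ", path),
                   class = "neuroscrub_io_error")
    }
    data_offset <- as.integer(round(header$values$vox_offset))
  }
  new_volume(header, data_path, data_offset)
}

#' Access the voxel array of a volume
#'
#' Materializes the 3-D voxel array on first access (registering the load
#' with the volume registry) and caches it in the volume object.
#'
#' @param volume An `ns_volume`.
#' @return A 3-D numeric/integer array with `prod(dim)` voxels.
#' @export
voxels <- function(volume) {
  stopifnot(inherits(volume, "ns_volume"))
  if (is.null(volume$data)) {
    volume$data <- read_voxel_array(volume$data_path, volume$data_offset,
                                    volume$dims, volume$datatype,
                                    volume$header$endianness)
    register_load()
  }
  volume$data
}

#' @rdname voxels
#' @export
release_voxels <- function(volume) {
  stopifnot(inherits(volume, "ns_volume"))
  if (!is.null(volume$data)) {
    volume$data <- NULL
    .vol_registry$current <- max(0L, .vol_registry$current - 1L)
  }
  invisible(volume)
}

read_voxel_array <- function(path, offset, dims, datatype, endian) {
  info <- datatype_info(datatype)
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  vals <- readBin(con, info$what, n = n, size = info$size,
                  signed = info$signed, endian = endian)
  if (length(vals) != n) {
    rlang::abort(sprintf("voxel data truncated: expected %d values, read %d",
                         n, length(vals)),
                 class = "neuroscrub_io_error")
  }
  array(vals, dim = dims)
}

#' @export
print.ns_volume <- function(x, ...) {
  cat(sprintf("<ns_volume %s %s %s, %s>\n",
              paste(x$dims, collapse = "x"),
              datatype_info(x$datatype)$name,
              x$header$format,
              if (is.null(x$data)) "not loaded" else "loaded"))
  invisible(x)
}

#' @export
dim.ns_volume <- function(x) x$dims

guess_datatype <- function(arr) {
  if (is.integer(arr) || (is.numeric(arr) && all(arr == round(arr)))) {
    rng <- range(arr)
    if (rng[1] >= 0 && rng[2] <= 255) return(2L)
    if (rng[1] >= -32768 && rng[2] <= 32767) return(4L)
    return(8L)
  }
  16L
}

build_header_bytes <- function(format, dims, datatype, pixdim = c(1, 1, 1),
                               endian = "little") {
  info <- datatype_info(datatype)
  layout <- layout_for_format(format)
  values <- purrr::map(seq_len(nrow(layout)), function(i) {
    f <- layout[i, ]
    if (f$storage == "char") "" else rep(0, f$n)
  })
  names(values) <- layout$name
  values$sizeof_hdr <- HEADER_SIZE
  values$regular <- "r"
  values$dim <- c(3L, dims, rep(1L, 7 - length(dims)))
  values$datatype <- datatype
  values$bitpix <- info$bitpix
  values$pixdim <- c(1, pixdim, rep(0, 7 - length(pixdim)))
  if (format == "NIFTI_SINGLE") {
    values$magic <- "n+1"
    values$vox_offset <- 352
  } else if (format == "NIFTI_PAIR") {
    values$magic <- "ni1"
    values$vox_offset <- 0
  }
  h <- structure(list(format = format, endianness = endian, layout = layout,
                      values = values, bytes = raw(HEADER_SIZE),
                      raw = raw(HEADER_SIZE), path = NA_character_),
                 class = "ns_header")
  h$bytes <- encode_header(h)
  # re-decode so every value carries its storage type (int fields integer)
  read_header(h$bytes)
}

encode_voxel_bytes <- function(arr, datatype, endian) {
  info <- datatype_info(datatype)
  vals <- as.vector(arr)
  if (info$what == "integer") {
    writeBin(as.integer(vals), raw(), size = info$size, endian = endian)
  } else {
    writeBin(as.double(vals), raw(), size = info$size, endian = endian)
  }
}

#' Write a voxel array or volume to disk
#'
#' Writes a 3-D array (or an `ns_volume`) as single-file NIfTI-1
#' (`"nii"`), NIfTI-1 hdr/img pair (`"pair"`) or Analyze 7.5
#' (`"analyze"`). Integer voxel data round-trips bit-exactly; float data
#' round-trips to float32 representation.
#'
#' @param x 3-D array or `ns_volume`.
#' @param path Output path; extension `.nii` or `.hdr` is enforced to
#'   match `format`.
#' @param format One of `"nii"`, `"pair"`, `"analyze"`.
#' @param datatype NIfTI datatype code (2, 4, 8 or 16); guessed from the
#'   array's storage and range when `NULL`.
#' @param pixdim Voxel sizes along the three axes.
#' @return Character vector of the file(s) written (`.nii`, or
#'   `.hdr` + `.img`), invisibly.
#' @export
write_volume <- function(x, path, format = c("nii", "pair", "analyze"),
                         datatype = NULL, pixdim = c(1, 1, 1)) {
  format <- match.arg(format)
  if (inherits(x, "ns_volume")) {
    arr <- voxels(x)
    if (is.null(datatype)) datatype <- x$datatype
  } else {
    arr <- x
  }
  stopifnot(length(dim(arr)) == 3L)
  if (is.null(datatype)) datatype <- guess_datatype(arr)
  fk <- switch(format, nii = "NIFTI_SINGLE", pair = "NIFTI_PAIR",
               analyze = "ANALYZE75")
  h <- build_header_bytes(fk, dim(arr), datatype, pixdim)
  data <- encode_voxel_bytes(arr, datatype, h$endianness)
  if (format == "nii") {
    path <- ensure_ext(path, ".nii")
    writeBin(c(h$bytes, raw(4L), data), path)
    return(invisible(path))
  }
  hdr <- ensure_ext(path, ".hdr")
  img <- sub("\\.hdr$", ".img", hdr)
  writeBin(h$bytes, hdr)
  writeBin(data, img)
  invisible(c(hdr, img))
}

# Rewrite a volume's voxel data in place, keeping its existing header
# bytes (so audited fields, pixdim and transforms survive defacing).
write_volume_like <- function(arr, volume, path) {
  h <- volume$header
  stopifnot(identical(dim(arr), volume$dims))
  data <- encode_voxel_bytes(arr, volume$datatype, h$endianness)
  if (h$format == "NIFTI_SINGLE") {
    h <- hdr_poke(h, "vox_offset", 352)
    writeBin(c(h$bytes, raw(4L), data), path)
    return(invisible(path))
  }
  hdr <- sub("\\.nii$", ".hdr", path, ignore.case = TRUE)
  img <- sub("\\.hdr$", ".img", hdr, ignore.case = TRUE)
  h <- hdr_poke(h, "vox_offset", 0)
  writeBin(h$bytes, hdr)
  writeBin(data, img)
  invisible(c(hdr, img))
}

ensure_ext <- function(path, ext) {
  if (!grepl(paste0("\\", ext, "$"), path, ignore.case = TRUE)) {
    path <- paste0(sub("\\.(nii|hdr|img)$", "", path, ignore.case = TRUE), ext)
  }
  path
}
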