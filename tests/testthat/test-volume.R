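# Voxel I/O: datatype round trips, lazy loading, conversion round trips.

test_that("voxel arrays round-trip bit-exactly for every supported datatype", {
  td <- withr::local_tempdir()
  cases <- list(
    list(code = 2L,  make = function(n) array(sample.int(256L, n, TRUE) - 1L, c(7, 6, 5))),
    list(code = 4L,  make = function(n) array(sample.int(65536L, n, TRUE) - 32768L, c(7, 6, 5))),
    list(code = 8L,  make = function(n) array(sample.int(10^6, n, TRUE), c(7, 6, 5))),
    list(code = 16L, make = function(n) array(runif(n, -10, 10), c(7, 6, 5)))
  )
  set.seed(99)
  for (cs in cases) {
    arr <- cs$make(210)
    if (cs$code != 16L) storage.mode(arr) <- "integer"
    for (fmt in c("nii", "pair", "analyze")) {
      p <- write_volume(arr, file.path(td, paste0("dt", cs$code, fmt)),
                        format = fmt, datatype = cs$code)
      back <- voxels(read_volume(p[1]))
      if (cs$code == 16L) {
        # float32 representation, not double
        expect_equal(back, arr, tolerance = 1e-7)
      } else {
        expect_identical(back, arr)
      }
    }
  }
})

test_that("a 16-bit 64x64x40 volume holds 163840 voxels", {
  td <- withr::local_tempdir()
  arr <- array(0L, c(64L, 64L, 40L))
  p <- write_volume(arr, file.path(td, "big"), format = "nii", datatype = 4L)
  v <- read_volume(p)
  expect_identical(prod(dim(v)), 163840)
})

test_that("voxel data is read lazily, on first access only", {
  td <- withr::local_tempdir()
  p <- tiny_volume_file(td, "lazy")
  reset_volume_load_stats()
  v <- read_volume(p)
  expect_identical(volume_load_stats()$loads, 0L)
  invisible(voxels(v))
  expect_identical(volume_load_stats()$loads, 1L)
  invisible(voxels(v))  # cached; no second load
  expect_identical(volume_load_stats()$loads, 1L)
  release_voxels(v)
  expect_identical(volume_load_stats()$current, 0L)
})

test_that("unsupported datatype codes are refused", {
  h <- neuroscrub:::build_header_bytes("NIFTI_PAIR", c(4L, 4L, 4L), 4L)
  h <- neuroscrub:::hdr_poke(h, "datatype", 128L)  # RGB24: unsupported
  td <- withr::local_tempdir()
  writeBin(h$bytes, file.path(td, "bad.hdr"))
  writeBin(raw(192), file.path(td, "bad.img"))
  expect_error(read_volume(file.path(td, "bad.hdr")),
               class = "neuroscrub_unsupported_datatype")
})

test_that("voxel decode agrees with an independent NIfTI reader", {
  skip_if_not_installed("RNifti")
  td <- withr::local_tempdir()
  p <- tiny_volume_file(td, "vox_oracle", format = "nii", seed = 5)
  ref <- RNifti::readNifti(p)
  expect_identical(as.vector(voxels(read_volume(p))), as.vector(ref[, , ]))
})

protected_fields_except_container <- function(h) {
  setdiff(h$layout$name[!h$layout$editable], c("magic", "vox_offset"))
}

test_that("nii -> pair -> nii round-trips voxels and protected fields exactly", {
  td <- withr::local_tempdir()
  src <- tiny_volume_file(td, "conv", format = "nii", dims = c(10L, 9L, 8L), seed = 3)
  pair <- convert_nii_to_pair(src, file.path(td, "pair"))
  expect_identical(detect_format(pair["hdr"]), "NIFTI_PAIR")
  expect_identical(read_header(pair["hdr"])$values$magic, "ni1")
  expect_identical(read_header(pair["hdr"])$values$vox_offset, 0)
  expect_identical(voxels(read_volume(pair["hdr"])), voxels(read_volume(src)))
  back <- convert_pair_to_nii(pair["hdr"], out_dir = file.path(td, "back"))
  expect_identical(detect_format(back), "NIFTI_SINGLE")
  expect_identical(voxels(read_volume(back)), voxels(read_volume(src)))
  h0 <- read_header(src); h1 <- read_header(back)
  for (f in protected_fields_except_container(h0)) {
    expect_identical(h1$values[[f]], h0$values[[f]], label = paste("field", f))
  }
  # editable (audited) fields survive the round trip too
  for (f in editable_fields(h0)) {
    expect_identical(h1$values[[f]], h0$values[[f]])
  }
})

test_that("conversion rejects undersized vox_offset and img size mismatch", {
  td <- withr::local_tempdir()
  src <- tiny_volume_file(td, "bado", format = "nii")
  bytes <- readBin(src, "raw", file.size(src))
  h <- read_header(utils::head(bytes, 348L))
  h <- neuroscrub:::hdr_poke(h, "vox_offset", 100)
  writeBin(c(h$bytes, bytes[-(1:348)]), file.path(td, "small_off.nii"))
  expect_error(convert_nii_to_pair(file.path(td, "small_off.nii"), td),
               class = "neuroscrub_malformed_file")

  pair <- tiny_volume_file(td, "trunc", format = "pair")
  img <- pair[2]
  writeBin(readBin(img, "raw", file.size(img))[1:100], img)
  expect_error(convert_pair_to_nii(pair[1], out_dir = td),
               class = "neuroscrub_size_mismatch")
})

test_that("Analyze inputs are promoted to NIfTI with matching geometry", {
  td <- withr::local_tempdir()
  pa <- tiny_volume_file(td, "ana", format = "analyze", dims = c(6L, 5L, 4L), seed = 8)
  expect_identical(detect_format(pa[1]), "ANALYZE75")
  nii <- convert_pair_to_nii(pa[1], out_dir = file.path(td, "up"))
  h0 <- read_header(pa[1]); h1 <- read_header(nii)
  expect_identical(h1$values$dim, h0$values$dim)
  expect_identical(h1$values$datatype, h0$values$datatype)
  expect_identical(h1$values$bitpix, h0$values$bitpix)
  expect_identical(voxels(read_volume(nii)), voxels(read_volume(pa[1])))
})
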