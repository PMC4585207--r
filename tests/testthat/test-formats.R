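# Byte-level header engine: detection, decode/encode, editing, scrubbing.

craft_header <- function(magic = NULL, endian = "little", sizeof = 348L) {
  b <- raw(348)
  b[1:4] <- writeBin(as.integer(sizeof), raw(), size = 4L, endian = endian)
  if (!is.null(magic)) b[345:348] <- c(charToRaw(magic), raw(4 - nchar(magic)))
  b
}

test_that("magic bytes at offset 344 classify the three formats, both endiannesses", {
  for (endian in c("little", "big")) {
    expect_identical(detect_format(craft_header("ni1", endian)), "NIFTI_PAIR")
    expect_identical(detect_format(craft_header("n+1", endian)), "NIFTI_SINGLE")
    expect_identical(detect_format(craft_header(NULL, endian)), "ANALYZE75")
  }
})

test_that("short or unrecognized headers are rejected", {
  expect_error(detect_format(raw(100)), class = "neuroscrub_malformed_header")
  bad <- craft_header("n+1"); bad[1:4] <- as.raw(c(1, 2, 3, 4))
  expect_error(detect_format(bad), class = "neuroscrub_unrecognized_format")
})

test_that("planted Analyze history fields decode with the editable flag set", {
  h <- neuroscrub:::build_header_bytes("ANALYZE75", c(8L, 8L, 6L), 4L)
  h <- neuroscrub:::hdr_poke(h, "patient_id", "PT007")
  h2 <- read_header(h$bytes)
  expect_identical(h2$values$patient_id, "PT007")
  f <- header_fields(h2)
  expect_true(f$editable[f$name == "patient_id"])
  expect_identical(f$offset[f$name == "patient_id"], 283L)
  expect_false(f$editable[f$name == "dim"])
})

test_that("NIfTI dim decodes as eight int16 values at offset 40", {
  h <- neuroscrub:::build_header_bytes("NIFTI_SINGLE", c(64L, 64L, 40L), 4L)
  h2 <- read_header(h$bytes)
  expect_identical(h2$values$dim, c(3L, 64L, 64L, 40L, 1L, 1L, 1L, 1L))
})

test_that("byte-swapped headers decode to the same values (oracle: span-wise swap)", {
  h <- random_header(seed = 42)
  # independent construction of the big-endian twin: reverse the bytes of
  # every element of every non-char field
  swapped <- h$bytes
  lay <- h$layout
  for (i in seq_len(nrow(lay))) {
    if (lay$storage[i] == "char") next
    esz <- c(int8 = 1L, int16 = 2L, int32 = 4L, float32 = 4L)[[lay$storage[i]]]
    for (k in seq_len(lay$n[i])) {
      span <- lay$offset[i] + (k - 1L) * esz + seq_len(esz)
      swapped[span] <- rev(swapped[span])
    }
  }
  hb <- read_header(swapped)
  expect_identical(hb$endianness, "big")
  expect_identical(hb$values, h$values)
  expect_identical(encode_header(hb), swapped)
})

test_that("decode/encode identity holds over fuzzed canonical headers", {
  for (seed in 1:25) {
    for (fmt in c("NIFTI_SINGLE", "ANALYZE75")) {
      h <- random_header(fmt, seed = seed)
      expect_identical(encode_header(read_header(h$bytes)), h$bytes)
    }
  }
})

test_that("editing an editable field changes only that field's byte span", {
  for (fmt in c("NIFTI_SINGLE", "ANALYZE75")) {
    h <- random_header(fmt, seed = 7)
    for (fname in editable_fields(h)) {
      lay <- h$layout[h$layout$name == fname, ]
      h2 <- edit_header_field(h, fname, "X")
      changed <- which(h2$bytes != h$bytes)
      expect_true(all(changed > lay$offset & changed <= lay$offset + lay$n),
                  label = paste("edit locality for", fmt, fname))
      expect_identical(h2$values[[fname]], "X")
    }
  }
})

test_that("protected fields, unknown fields and oversize values are refused", {
  h <- read_header(neuroscrub:::build_header_bytes("NIFTI_SINGLE", c(8L, 8L, 6L), 4L)$bytes)
  expect_error(edit_header_field(h, "dim", c(3, 8, 8, 6, 1, 1, 1, 1)),
               class = "neuroscrub_protected_field")
  expect_error(edit_header_field(h, "pixdim", rep(1, 8)),
               class = "neuroscrub_protected_field")
  expect_error(edit_header_field(h, "no_such_field", "x"),
               class = "neuroscrub_unknown_field")
  expect_error(edit_header_field(h, "aux_file", strrep("a", 25)),
               class = "neuroscrub_oversize_value")
})

test_that("re-editing a field to its current value reproduces the bytes exactly", {
  h <- random_header(seed = 3)
  h2 <- edit_header_field(h, "descrip", h$values$descrip)
  expect_identical(h2$bytes, h$bytes)
})

test_that("scrubbing zero-fills the policy fields, is idempotent, and spares geometry", {
  h <- neuroscrub:::build_header_bytes("ANALYZE75", c(8L, 8L, 6L), 4L)
  h <- neuroscrub:::hdr_poke(h, "patient_id", "PT007")
  h <- neuroscrub:::hdr_poke(h, "exp_date", "2012-01-05")
  s1 <- scrub_header(h)
  expect_identical(s1$values$patient_id, "")
  expect_identical(s1$values$exp_date, "")
  # all bytes in scrubbed spans are NUL
  lay <- s1$layout[s1$layout$name == "patient_id", ]
  expect_identical(s1$bytes[lay$offset + seq_len(lay$n)], raw(lay$n))
  # geometry untouched
  expect_identical(s1$values$dim, h$values$dim)
  expect_identical(scrub_header(s1)$bytes, s1$bytes)
  # scrub then re-decode -> empty strings
  expect_identical(read_header(s1$bytes)$values$exp_date, "")
  # scrubbing an already blank header is the identity
  blank <- neuroscrub:::build_header_bytes("ANALYZE75", c(8L, 8L, 6L), 4L)
  expect_identical(scrub_header(blank)$bytes, blank$bytes)
  expect_error(scrub_header(h, fields = "dim"),
               class = "neuroscrub_protected_field")
})

test_that("scrub_image_header removes identifiers from files in place", {
  td <- withr::local_tempdir()
  p <- tiny_volume_file(td, "scrubme", format = "analyze")
  h <- read_header(p[1])
  h <- neuroscrub:::hdr_poke(h, "patient_id", "S01")
  writeBin(h$bytes, p[1])
  scrub_image_header(p[1])
  expect_identical(read_header(p[1])$values$patient_id, "")
  # voxels unchanged
  expect_identical(voxels(read_volume(p[1])), tiny_array())
})

test_that("header decode agrees with an independent NIfTI reader", {
  skip_if_not_installed("RNifti")
  td <- withr::local_tempdir()
  p <- tiny_volume_file(td, "oracle", format = "nii", dims = c(9L, 7L, 5L))
  ref <- RNifti::niftiHeader(p)
  h <- read_header(p)
  expect_identical(h$values$dim, as.integer(ref$dim))
  expect_identical(h$values$datatype, as.integer(ref$datatype))
  expect_identical(h$values$bitpix, as.integer(ref$bitpix))
})
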