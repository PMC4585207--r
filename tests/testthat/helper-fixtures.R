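# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# A small deterministic voxel array (integer, int16-safe).
tiny_array <- function(dims = c(8L, 8L, 6L), seed = 1L) {
  set.seed(seed)
  arr <- array(sample.int(2000L, prod(dims), replace = TRUE), dim = dims)
  storage.mode(arr) <- "integer"
  arr
}

# Write a tiny volume and return its path(s).
tiny_volume_file <- function(dir, stem = "vol", format = "nii",
                             dims = c(8L, 8L, 6L), seed = 1L, datatype = 4L) {
  arr <- tiny_array(dims, seed)
  write_volume(arr, file.path(dir, stem), format = format, datatype = datatype)
}

# A canonical random header: valid geometry, random printable strings in
# the char fields (NUL-padded on encode), random values elsewhere.
random_header <- function(format = "NIFTI_SINGLE", seed = 1L) {
  set.seed(seed)
  arr_dims <- c(sample(4:16, 1), sample(4:16, 1), sample(4:12, 1))
  h <- neuroscrub:::build_header_bytes(format, arr_dims, 4L)
  rand_string <- function(width) {
    n <- sample(0:(width - 1L), 1)
    paste(sample(c(LETTERS, letters, 0:9, " ", "-", "_"), n, replace = TRUE),
          collapse = "")
  }
  for (f in editable_fields(h)) {
    lay <- h$layout[h$layout$name == f, ]
    h <- edit_header_field(h, f, rand_string(lay$n))
  }
  # randomize a few protected numeric fields through the internal poke
  h <- neuroscrub:::hdr_poke(h, "cal_max", stats::runif(1, 0, 4000))
  h <- neuroscrub:::hdr_poke(h, "glmax", sample.int(10000L, 1))
  h
}

# Minimal demographic tibble for matching tests.
id_table <- function(ids) {
  tibble::tibble(ID = ids, SCORE = seq_along(ids))
}

write_tsv_lines <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}
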