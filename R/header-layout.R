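# Field layouts for the 348-byte Analyze 7.5 and NIfTI-1 headers.
# Offsets are 0-based byte offsets into the header; `size` is bytes per
# element, `n` the element count (for char fields, n is the byte width).
# Every byte in [0, 348) is covered by exactly one field, so re-encoding
# all fields reconstructs the header byte-for-byte.

layout_row <- function(name, offset, storage, n, editable) {
  tibble::tibble(name = name, offset = offset, storage = storage,
                 n = n, editable = editable)
}

storage_size <- function(storage) {
  c(int8 = 1L, int16 = 2L, int32 = 4L, float32 = 4L, char = 1L)[[storage]]
}

# NIfTI-1: free-text fields descrip, aux_file and db_name are editable;
# geometry, codec and transform fields are protected.
nifti1_layout <- function() {
  dplyr::bind_rows(
    layout_row("sizeof_hdr",     0L, "int32",   1L, FALSE),
    layout_row("data_type",      4L, "char",   10L, FALSE),
    layout_row("db_name",       14L, "char",   18L, TRUE),
    layout_row("extents",       32L, "int32",   1L, FALSE),
    layout_row("session_error", 36L, "int16",   1L, FALSE),
    layout_row("regular",       38L, "char",    1L, FALSE),
    layout_row("dim_info",      39L, "int8",    1L, FALSE),
    layout_row("dim",           40L, "int16",   8L, FALSE),
    layout_row("intent_p1",     56L, "float32", 1L, FALSE),
    layout_row("intent_p2",     60L, "float32", 1L, FALSE),
    layout_row("intent_p3",     64L, "float32", 1L, FALSE),
    layout_row("intent_code",   68L, "int16",   1L, FALSE),
    layout_row("datatype",      70L, "int16",   1L, FALSE),
    layout_row("bitpix",        72L, "int16",   1L, FALSE),
    layout_row("slice_start",   74L, "int16",   1L, FALSE),
    layout_row("pixdim",        76L, "float32", 8L, FALSE),
    layout_row("vox_offset",   108L, "float32", 1L, FALSE),
    layout_row("scl_slope",    112L, "float32", 1L, FALSE),
    layout_row("scl_inter",    116L, "float32", 1L, FALSE),
    layout_row("slice_end",    120L, "int16",   1L, FALSE),
    layout_row("slice_code",   122L, "int8",    1L, FALSE),
    layout_row("xyzt_units",   123L, "int8",    1L, FALSE),
    layout_row("cal_max",      124L, "float32", 1L, FALSE),
    layout_row("cal_min",      128L, "float32", 1L, FALSE),
    layout_row("slice_duration", 132L, "float32", 1L, FALSE),
    layout_row("toffset",      136L, "float32", 1L, FALSE),
    layout_row("glmax",        140L, "int32",   1L, FALSE),
    layout_row("glmin",        144L, "int32",   1L, FALSE),
    layout_row("descrip",      148L, "char",   80L, TRUE),
    layout_row("aux_file",     228L, "char",   24L, TRUE),
    layout_row("qform_code",   252L, "int16",   1L, FALSE),
    layout_row("sform_code",   254L, "int16",   1L, FALSE),
    layout_row("quatern_b",    256L, "float32", 1L, FALSE),
    layout_row("quatern_c",    260L, "float32", 1L, FALSE),
    layout_row("quatern_d",    264L, "float32", 1L, FALSE),
    layout_row("qoffset_x",    268L, "float32", 1L, FALSE),
    layout_row("qoffset_y",    272L, "float32", 1L, FALSE),
    layout_row("qoffset_z",    276L, "float32", 1L, FALSE),
    layout_row("srow_x",       280L, "float32", 4L, FALSE),
    layout_row("srow_y",       296L, "float32", 4L, FALSE),
    layout_row("srow_z",       312L, "float32", 4L, FALSE),
    layout_row("intent_name",  328L, "char",   16L, FALSE),
    layout_row("magic",        344L, "char",    4L, FALSE)
  )
}

# Analyze 7.5: the data_history struct carries the free-text provenance
# fields (originator .. exp_time) that hold subject-linkable information.
analyze75_layout <- function() {
  dplyr::bind_rows(
    layout_row("sizeof_hdr",     0L, "int32",   1L, FALSE),
    layout_row("data_type",      4L, "char",   10L, FALSE),
    layout_row("db_name",       14L, "char",   18L, TRUE),
    layout_row("extents",       32L, "int32",   1L, FALSE),
    layout_row("session_error", 36L, "int16",   1L, FALSE),
    layout_row("regular",       38L, "char",    1L, FALSE),
    layout_row("hkey_un0",      39L, "char",    1L, FALSE),
    layout_row("dim",           40L, "int16",   8L, FALSE),
    layout_row("unused8",       56L, "int16",   7L, FALSE),
    layout_row("datatype",      70L, "int16",   1L, FALSE),
    layout_row("bitpix",        72L, "int16",   1L, FALSE),
    layout_row("dim_un0",       74L, "int16",   1L, FALSE),
    layout_row("pixdim",        76L, "float32", 8L, FALSE),
    layout_row("vox_offset",   108L, "float32", 1L, FALSE),
    layout_row("funused1",     112L, "float32", 1L, FALSE),
    layout_row("funused2",     116L, "float32", 1L, FALSE),
    layout_row("funused3",     120L, "float32", 1L, FALSE),
    layout_row("cal_max",      124L, "float32", 1L, FALSE),
    layout_row("cal_min",      128L, "float32", 1L, FALSE),
    layout_row("compressed",   132L, "float32", 1L, FALSE),
    layout_row("verified",     136L, "float32", 1L, FALSE),
    layout_row("glmax",        140L, "int32",   1L, FALSE),
    layout_row("glmin",        144L, "int32",   1L, FALSE),
    layout_row("descrip",      148L, "char",   80L, TRUE),
    layout_row("aux_file",     228L, "char",   24L, TRUE),
    layout_row("orient",       252L, "int8",    1L, FALSE),
    layout_row("originator",   253L, "char",   10L, TRUE),
    layout_row("generated",    263L, "char",   10L, TRUE),
    layout_row("scannum",      273L, "char",   10L, TRUE),
    layout_row("patient_id",   283L, "char",   10L, TRUE),
    layout_row("exp_date",     293L, "char",   10L, TRUE),
    layout_row("exp_time",     303L, "char",   10L, TRUE),
    layout_row("hist_un0",     313L, "char",    3L, FALSE),
    layout_row("views",        316L, "int32",   1L, FALSE),
    layout_row("vols_added",   320L, "int32",   1L, FALSE),
    layout_row("start_field",  324L, "int32",   1L, FALSE),
    layout_row("field_skip",   328L, "int32",   1L, FALSE),
    layout_row("omax",         332L, "int32",   1L, FALSE),
    layout_row("omin",         336L, "int32",   1L, FALSE),
    layout_row("smax",         340L, "int32",   1L, FALSE),
    layout_row("smin",         344L, "int32",   1L, FALSE)
  )
}

.layout_cache <- new.env(parent = emptyenv())

layout_for_format <- function(format) {
  key <- switch(format,
    NIFTI_SINGLE = ,
    NIFTI_PAIR   = "nifti1",
    ANALYZE75    = "analyze75",
    stop("unknown format: ", format)
  )
  if (is.null(.layout_cache[[key]])) {
    .layout_cache[[key]] <- if (key == "nifti1") nifti1_layout() else analyze75_layout()
  }
  .layout_cache[[key]]
}

HEADER_SIZE <- 348L
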