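# QC montage: one row per subject, the three mid-slices (axial, coronal,
# sagittal) of the original beside those of the stripped image. Volumes
# are loaded one pair at a time and released immediately, so the peak
# number of resident voxel arrays is 2 no matter how many subjects are
# rendered.

mid_slices <- function(arr) {
  d <- dim(arr)
  list(
    axial    = arr[, , ceiling(d[3] / 2)],
    coronal  = arr[, ceiling(d[2] / 2), ],
    sagittal = arr[ceiling(d[1] / 2), , ]
  )
}

normalize01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

pad_to <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' Render an original-vs-stripped QC montage
#'
#' Writes a grayscale PNG grid with one row per subject and six panels
#' per row: the axial, coronal and sagittal mid-slices of the original
#' image followed by the same slices of the stripped image. Each pair of
#' volumes is loaded, sliced and released before the next is touched
#' (see [volume_load_stats()]), so arbitrarily many subjects can be
#' rendered under a fixed memory bound.
#'
#' @param pairs A data frame with columns `original` and `stripped`
#'   holding image file paths (one row per subject).
#' @param out_path Output PNG path.
#' @param slices_per_volume Number of orthogonal mid-slices per volume
#'   (fixed at 3: axial, coronal, sagittal).
#' @return `out_path`, invisibly.
#' @export
render_montage <- function(pairs, out_path, slices_per_volume = 3L) {
  if (!is.data.frame(pairs) || !all(c("original", "stripped") %in% names(pairs))) {
    rlang::abort("pairs must be a data frame with columns original, stripped",
                 class = "neuroscrub_bad_input")
  }
  if (!nrow(pairs)) {
    rlang::abort("at least one original/stripped pair is required",
                 class = "neuroscrub_bad_input")
  }
  stopifnot(slices_per_volume == 3L)
  rows <- vector("list", nrow(pairs))
  tile <- c(0L, 0L)
  for (i in seq_len(nrow(pairs))) {
    vo <- read_volume(pairs$original[i])
    vs <- read_volume(pairs$stripped[i])
    panels <- c(lapply(mid_slices(voxels(vo)), normalize01),
                lapply(mid_slices(voxels(vs)), normalize01))
    release_voxels(vo)
    release_voxels(vs)
    tile <- pmax(tile, c(max(vapply(panels, nrow, integer(1))),
                         max(vapply(panels, ncol, integer(1)))))
    rows[[i]] <- panels
  }
  canvas <- matrix(0, nrow = nrow(pairs) * tile[1], ncol = 6L * tile[2])
  for (i in seq_along(rows)) {
    for (j in seq_along(rows[[i]])) {
      p <- pad_to(rows[[i]][[j]], tile[1], tile[2])
      canvas[(i - 1L) * tile[1] + seq_len(tile[1]),
             (j - 1L) * tile[2] + seq_len(tile[2])] <- p
    }
  }
  png::writePNG(canvas, out_path)
  invisible(out_path)
}
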