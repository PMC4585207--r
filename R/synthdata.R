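# Synthetic fixtures: head phantoms with ground-truth brain/face masks
# and demographic tables with planted identifiers and missing cells.
# These define the package's test conditions; no external data needed.

#' Specification of a synthetic head phantom
#'
#' The phantom is geometric, not anatomical: a bright brain ellipsoid, a
#' medium-intensity skull shell around it, and a protruding
#' low-intensity anterior wedge standing in for the face, over a
#' zero-background with additive truncated-Gaussian noise. The three
#' regions are disjoint; the face wedge sits outside the skull shell the
#' way a nose/face surface protrudes from the cranium. The default
#' intensities (brain 1000, skull 600, face 300, noise sd 10) place the
#' face below and the brain above the default f = 0.5 threshold of the
#' builtin stripper.
#'
#' @param dims Voxel counts per axis.
#' @param brain_center,brain_semiaxes,brain_intensity Brain ellipsoid.
#' @param skull_scales,skull_intensity Inner/outer scale factors of the
#'   skull shell relative to the brain ellipsoid, and its intensity.
#' @param face_box Integer ranges (`xlim`, `ylim`, `zlim`) of the
#'   anterior face wedge.
#' @param face_intensity Face wedge intensity.
#' @param noise_sd Additive Gaussian noise sd (negatives clamped to 0).
#' @param seed RNG seed; the phantom is deterministic per seed.
#' @return A list of class `ns_fixture_spec`.
#' @export
fixture_spec <- function(dims = c(64L, 64L, 40L),
                         brain_center = c(32, 30, 20),
                         brain_semiaxes = c(18, 16, 11),
                         brain_intensity = 1000,
                         skull_scales = c(1.25, 1.35),
                         skull_intensity = 600,
                         face_box = list(xlim = c(24L, 40L),
                                         ylim = c(54L, 60L),
                                         zlim = c(8L, 20L)),
                         face_intensity = 300,
                         noise_sd = 10,
                         seed = 1L) {
  structure(
    list(dims = dims, brain_center = brain_center,
         brain_semiaxes = brain_semiaxes, brain_intensity = brain_intensity,
         skull_scales = skull_scales, skull_intensity = skull_intensity,
         face_box = face_box, face_intensity = face_intensity,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ns_fixture_spec"
  )
}

ellipsoid_r2 <- function(dims, center, semiaxes) {
  x <- (seq_len(dims[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(dims[2]) - center[2]) / semiaxes[2]
  z <- (seq_len(dims[3]) - center[3]) / semiaxes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

box_mask <- function(dims, box) {
  m <- array(FALSE, dim = dims)
  m[box$xlim[1]:box$xlim[2], box$ylim[1]:box$ylim[2], box$zlim[1]:box$zlim[2]] <- TRUE
  m
}

#' Generate a synthetic head volume with ground-truth masks
#'
#' Builds the phantom described by `spec`, writes it in the requested
#' format, and returns the written path(s) together with the ground-truth
#' brain and face masks the QC and defacing tests check against.
#'
#' @param spec An [fixture_spec()].
#' @param format `"nii"`, `"pair"` or `"analyze"`.
#' @param dir Output directory.
#' @param stem Output file stem.
#' @return List with `paths` (written files), `array` (the voxel array),
#'   `brain_mask`, `face_mask` (logical arrays), and `spec`.
#' @export
make_head_volume <- function(spec = fixture_spec(), format = c("nii", "pair", "analyze"),
                             dir = tempdir(), stem = "head") {
  format <- match.arg(format)
  stopifnot(inherits(spec, "ns_fixture_spec"))
  d <- spec$dims
  r2 <- ellipsoid_r2(d, spec$brain_center, spec$brain_semiaxes)
  brain <- r2 <= 1
  skull <- r2 > spec$skull_scales[1]^2 & r2 <= spec$skull_scales[2]^2
  face <- box_mask(d, spec$face_box)
  if (any(face & (brain | skull))) {
    rlang::abort("fixture regions overlap: face wedge intersects brain/skull",
                 class = "neuroscrub_bad_spec")
  }
  arr <- array(0, dim = d)
  arr[brain] <- spec$brain_intensity
  arr[skull] <- spec$skull_intensity
  arr[face] <- spec$face_intensity
  arr <- with_local_seed(spec$seed, {
    noise <- array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
    pmax(round(arr + noise), 0)
  })
  storage.mode(arr) <- "integer"
  paths <- write_volume(arr, file.path(dir, stem), format = format,
                        datatype = 4L)
  list(paths = paths, array = arr, brain_mask = brain, face_mask = face,
       spec = spec)
}

FIRST_NAMES <- c("Alice", "Brian", "Carla", "David", "Elena", "Frank",
                 "Grace", "Hassan", "Irene", "Jorge", "Kara", "Liam",
                 "Mona", "Nikhil", "Olga", "Peter", "Quinn", "Rosa",
                 "Sven", "Tara")
LAST_NAMES <- c("Abbott", "Baker", "Chen", "Diaz", "Evans", "Fischer",
                "Gupta", "Hansen", "Ibrahim", "Jones", "Kim", "Lopez",
                "Mueller", "Novak", "Okafor", "Park", "Quirke", "Rossi",
                "Silva", "Tanaka")

random_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  format(from + sample.int(as.integer(to - from), n, replace = TRUE), "%Y-%m-%d")
}

#' Generate a synthetic demographic/behavioral table
#'
#' Columns `ID, NAME, DOB, TESTDATE, SEX, AGE, HEIGHT, WEIGHT, SCORE1,
#' SCORE2`, with planted direct identifiers (names, dates) for the
#' identifier-detection tests, one planted extreme value (`AGE = 96`,
#' when `n >= 10`) motivating range-band generalization, and missing
#' cells planted at `missing_rate` in the non-ID columns, their positions
#' recorded in the `planted_missing` attribute. Deterministic per seed.
#'
#' @param n Number of subjects (rows).
#' @param seed RNG seed.
#' @param missing_rate Fraction of non-ID cells set missing.
#' @return A tibble with attribute `planted_missing` (tibble `row`,
#'   `column`).
#' @export
make_demographics <- function(n, seed = 1L, missing_rate = 0.02) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    width <- max(3L, nchar(as.character(n)))
    tbl <- tibble::tibble(
      ID = sprintf("S%0*d", width, seq_len(n)),
      NAME = paste(sample(FIRST_NAMES, n, replace = TRUE),
                   sample(LAST_NAMES, n, replace = TRUE)),
      DOB = random_dates(n, "1940-01-01", "2005-12-31"),
      TESTDATE = random_dates(n, "2011-01-01", "2013-12-31"),
      SEX = sample(c("M", "F"), n, replace = TRUE),
      AGE = sample(18:85, n, replace = TRUE),
      HEIGHT = round(stats::rnorm(n, 170, 10), 1),
      WEIGHT = round(stats::rnorm(n, 75, 12), 1),
      SCORE1 = round(stats::rnorm(n, 100, 15), 2),
      SCORE2 = round(stats::runif(n, 0, 50), 2)
    )
    if (n >= 10) tbl$AGE[10] <- 96L
    planted <- tibble::tibble(row = integer(), column = character())
    if (missing_rate > 0) {
      cells <- expand.grid(row = seq_len(n), col = 2:ncol(tbl))
      k <- round(missing_rate * nrow(cells))
      if (k > 0) {
        pick <- cells[sample.int(nrow(cells), k), ]
        for (i in seq_len(nrow(pick))) {
          tbl[pick$row[i], pick$col[i]] <- NA
        }
        planted <- tibble::tibble(row = as.integer(pick$row),
                                  column = names(tbl)[pick$col])
        planted <- dplyr::arrange(planted, .data$row, .data$column)
      }
    }
    attr(tbl, "planted_missing") <- planted
    tbl
  })
}

#' Generate a complete synthetic dataset (table + one image per subject)
#'
#' Convenience wrapper for end-to-end runs: writes a demographic table
#' and one head phantom per subject (named by subject ID) into `dir`.
#' Each subject's phantom uses a subject-specific noise seed derived from
#' `seed`.
#'
#' @param n Number of subjects.
#' @param dir Output directory.
#' @param format Image format passed to [make_head_volume()].
#' @param seed Base RNG seed.
#' @param missing_rate Passed to [make_demographics()].
#' @return List with `table_path`, `table`, `image_paths`, `dir`.
#' @export
make_synthetic_dataset <- function(n, dir, format = "nii", seed = 1L,
                                   missing_rate = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- make_demographics(n, seed = seed, missing_rate = missing_rate)
  table_path <- file.path(dir, "demographics.tsv")
  write_table(tbl, table_path)
  image_paths <- unlist(lapply(seq_len(n), function(i) {
    make_head_volume(fixture_spec(seed = seed + i), format = format,
                     dir = dir, stem = tbl$ID[i])$paths
  }))
  list(table_path = table_path, table = tbl, image_paths = unname(image_paths),
       dir = dir)
}
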