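# Associative matching: link each image file to the subject ID it belongs
# to, using the ID embedded in the filename or path. A hdr/img pair is one
# logical image keyed by its shared stem; matching is deterministic
# (inputs are sorted internally) and resolves prefix collisions (S1 vs
# S10) by giving longer IDs precedence.

IMAGE_EXTS <- "\\.(nii|hdr)$"

# Collapse raw paths to logical images: every .nii, plus every .hdr (its
# .img companion rides along). Bare .img files resolve to their .hdr.
logical_images <- function(paths) {
  paths <- sort(unique(paths))
  paths[grepl("\\.img$", paths, ignore.case = TRUE)] <-
    sub("\\.img$", ".hdr", paths[grepl("\\.img$", paths, ignore.case = TRUE)],
        ignore.case = TRUE)
  sort(unique(paths[grepl(IMAGE_EXTS, paths, ignore.case = TRUE)]))
}

image_stem <- function(path) tools::file_path_sans_ext(basename(path))

# Tier at which `id` matches `path` (Inf = no match). Lower is stronger:
#  1 basename-without-extension equals the ID
#  2 the user pattern, with {id} substituted, globs the basename
#  3 the basename contains the ID bounded by non-alphanumerics or edges
#  4 (if search_full_path) some directory component equals the ID
match_tier <- function(id, path, pattern, search_full_path, ignore_case) {
  stem <- image_stem(path)
  base <- basename(path)
  cmp <- if (ignore_case) tolower else identity
  if (cmp(stem) == cmp(id)) return(1)
  if (!is.null(pattern)) {
    rx <- utils::glob2rx(sub("{id}", id, pattern, fixed = TRUE))
    if (grepl(rx, base, ignore.case = ignore_case)) return(2)
  }
  bounded <- paste0("(^|[^A-Za-z0-9])", escape_regex(id), "($|[^A-Za-z0-9])")
  if (grepl(bounded, base, ignore.case = ignore_case)) return(3)
  if (search_full_path) {
    comps <- strsplit(dirname(path), "/", fixed = TRUE)[[1]]
    if (any(cmp(comps) == cmp(id))) return(4)
  }
  Inf
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Match image files to subject IDs
#'
#' Associates each logical image (a `.nii`, or a `.hdr`/`.img` pair keyed
#' by its stem) with a subject ID from the table's first column. Per
#' file, the claiming subject is the one matching at the strongest tier
#' (exact stem, wildcard pattern, bounded substring, then path
#' component); ties at the same tier are broken in favour of the longer
#' ID, so `S10.nii` can never be claimed by `S1`. A tie between two IDs
#' of equal length is an ambiguity error rather than a silent pick.
#'
#' @param table Demographic tibble; column 1 holds the subject IDs.
#' @param image_paths Character vector of image file paths.
#' @param pattern Optional wildcard template containing `{id}` exactly
#'   once, matched against basenames with glob semantics
#'   (e.g. `"{id}_*"`).
#' @param allow_multiple Accept more than one image per subject
#'   (runs/repeats); without it a second image for a subject is an error.
#' @param search_full_path Also accept a directory component equal to the
#'   ID (images stored in subject-specific directories).
#' @param ignore_case Case-insensitive ID comparison (default FALSE:
#'   explicit is safer for an audit trail).
#' @return An object of class `ns_match`: a list with `entries` (tibble
#'   `subject_id`, `paths` list-column, `n_images`, `status`
#'   MATCHED/MISMATCH) and `unmatched_files` (images claimed by no
#'   subject). Every input image appears either in exactly one entry or
#'   in `unmatched_files`.
#' @export
match_images <- function(table, image_paths, pattern = NULL,
                         allow_multiple = FALSE, search_full_path = FALSE,
                         ignore_case = FALSE) {
  validate_table(table)
  if (!is.null(pattern)) {
    n_ph <- lengths(regmatches(pattern, gregexpr("{id}", pattern, fixed = TRUE)))
    if (n_ph != 1L) {
      rlang::abort("pattern must contain the placeholder {id} exactly once",
                   class = "neuroscrub_bad_pattern")
    }
  }
  ids <- table[[1]]
  files <- logical_images(image_paths)
  claims <- vector("list", length(files))
  for (fi in seq_along(files)) {
    tiers <- vapply(ids, match_tier, numeric(1), path = files[fi],
                    pattern = pattern, search_full_path = search_full_path,
                    ignore_case = ignore_case)
    if (all(is.infinite(tiers))) next
    best <- which(tiers == min(tiers))
    if (length(best) > 1L) {
      lens <- nchar(ids[best])
      best <- best[lens == max(lens)]
    }
    if (length(best) > 1L) {
      rlang::abort(
        sprintf("ambiguous match: %s is claimable by subjects %s",
                basename(files[fi]), paste(ids[best], collapse = " and ")),
        class = "neuroscrub_ambiguous_match"
      )
    }
    claims[[fi]] <- ids[best]
  }
  claimed_by <- vapply(claims, function(x) if (is.null(x)) NA_character_ else x,
                       character(1))
  entries <- tibble::tibble(
    subject_id = ids,
    paths = purrr::map(ids, ~ files[!is.na(claimed_by) & claimed_by == .x])
  )
  entries$n_images <- lengths(entries$paths)
  if (!allow_multiple && any(entries$n_images > 1L)) {
    bad <- entries$subject_id[entries$n_images > 1L][1]
    rlang::abort(
      sprintf("subject %s has %d images; pass allow_multiple = TRUE to accept",
              bad, entries$n_images[entries$subject_id == bad]),
      class = "neuroscrub_multiple_images"
    )
  }
  entries$status <- ifelse(entries$n_images >= 1L, "MATCHED", "MISMATCH")
  structure(
    list(entries = entries, unmatched_files = files[is.na(claimed_by)]),
    class = "ns_match"
  )
}

#' @export
print.ns_match <- function(x, ...) {
  n_mis <- sum(x$entries$status == "MISMATCH")
  cat(sprintf("<ns_match: %d subjects, %d MISMATCH, %d unmatched file(s)>\n",
              nrow(x$entries), n_mis, length(x$unmatched_files)))
  print(x$entries[, c("subject_id", "n_images", "status")])
  invisible(x)
}

#' Tidy a match result
#'
#' @param x An `ns_match`.
#' @param ... Unused.
#' @return The `entries` tibble (one row per subject).
#' @method tidy ns_match
#' @export
tidy.ns_match <- function(x, ...) x$entries

#' Add rows for images that have no table entry
#'
#' For every unmatched image whose stem (the inferred subject ID) is
#' absent from the table, appends a row carrying that ID and missing
#' values in every other column — the "image present, data missing" case.
#'
#' @param table Demographic tibble.
#' @param match An `ns_match` from [match_images()].
#' @return The table with one appended row per new inferred ID.
#' @export
fill_missing_rows <- function(table, match) {
  stopifnot(inherits(match, "ns_match"))
  new_ids <- sort(unique(vapply(match$unmatched_files, image_stem, character(1),
                                USE.NAMES = FALSE)))
  clash <- intersect(new_ids, table[[1]])
  if (length(clash)) {
    rlang::abort(paste0("inferred ID already present in table: ",
                        paste(clash, collapse = ", ")),
                 class = "neuroscrub_duplicate_id")
  }
  if (!length(new_ids)) return(table)
  filler <- table[rep(NA_integer_, length(new_ids)), ]
  filler[[1]] <- new_ids
  dplyr::bind_rows(table, filler)
}
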