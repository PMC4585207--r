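# Pseudonymization: collision-free random ID maps, their application to
# table + image files, and the automated anonymize-and-compare
# validation loop.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a collision-free random ID map
#'
#' Draws one new pseudonym per original ID from a seeded RNG:
#' `prefix` + zero-padded random integer of `digits` digits, sampled
#' without replacement. Any candidate equal to an original ID is rejected
#' and redrawn, so the new-ID set is always disjoint from the original
#' set; if the label space cannot supply enough distinct safe labels, the
#' digit width widens automatically. Deterministic for a fixed seed.
#'
#' @param original_ids Character vector of unique original IDs.
#' @param prefix New-ID prefix (default `"SUB"`).
#' @param digits Zero-padded digit width (default 4; widened if needed).
#' @param seed Integer RNG seed.
#' @return An object of class `ns_id_map`: a tibble with columns
#'   `original` and `new`, plus attributes `prefix`, `digits`, `seed`.
#' @export
generate_id_map <- function(original_ids, prefix = "SUB", digits = 4L,
                            seed = 1L) {
  original_ids <- as.character(original_ids)
  if (!length(original_ids)) {
    rlang::abort("original_ids must be non-empty",
                 class = "neuroscrub_bad_input")
  }
  if (anyDuplicated(original_ids)) {
    rlang::abort("original_ids must be unique",
                 class = "neuroscrub_duplicate_id")
  }
  n <- length(original_ids)
  new_ids <- with_local_seed(seed, {
    width <- as.integer(digits)
    acc <- character(0)
    repeat {
      space <- 10^width
      want <- n - length(acc)
      draw <- sample.int(space, size = min(space, want * 2L + 16L)) - 1L
      cand <- sprintf("%s%0*d", prefix, width, draw)
      cand <- setdiff(cand, c(original_ids, acc))
      acc <- c(acc, utils::head(cand, want))
      if (length(acc) == n) break
      # count how many safe labels remain at this width; widen if the
      # space is (nearly) exhausted
      remaining <- space - length(acc) -
        sum(grepl(sprintf("^%s[0-9]{%d}$", escape_regex(prefix), width),
                  original_ids))
      if (remaining < (n - length(acc))) width <- width + 1L
    }
    acc
  })
  structure(
    tibble::tibble(original = original_ids, new = new_ids),
    class = c("ns_id_map", class(tibble::tibble())),
    prefix = prefix, digits = as.integer(digits), seed = as.integer(seed)
  )
}

id_map_lookup <- function(id_map, ids) {
  i <- match(ids, id_map$original)
  if (anyNA(i)) {
    rlang::abort(paste0("unmapped ID(s): ",
                        paste(unique(ids[is.na(i)]), collapse = ", ")),
                 class = "neuroscrub_unmapped_id")
  }
  id_map$new[i]
}

#' Apply an ID map to a matched dataset
#'
#' Copies every matched image into `out_dir` renamed to the subject's new
#' ID (a subject with several images gets `newid_1`, `newid_2`, ... in
#' sorted source order; hdr/img pairs are copied as pairs), rewrites the
#' table's ID column, and writes the original-to-new key file to
#' `key_path` — which must lie *outside* `out_dir`, because the key is
#' the one artifact that re-links subjects and must never enter the
#' shared set. Source files are left untouched.
#'
#' @param match An `ns_match` from [match_images()].
#' @param table The demographic tibble used for the match.
#' @param id_map An `ns_id_map` covering every table ID.
#' @param out_dir Output directory for the renamed images.
#' @param key_path Where to write the ID key (TSV); default
#'   `<out_dir>_key.tsv` next to, not inside, `out_dir`.
#' @return A list: `table` (re-labelled tibble), `files` (tibble
#'   `original`, `new` of copied image files), `key_path`.
#' @export
apply_id_map <- function(match, table, id_map, out_dir,
                         key_path = paste0(sub("/+$", "", out_dir), "_key.tsv")) {
  stopifnot(inherits(match, "ns_match"), inherits(id_map, "ns_id_map"))
  if (normalizePath(dirname(key_path), mustWork = FALSE) ==
      normalizePath(out_dir, mustWork = FALSE)) {
    rlang::abort("key_path must not be inside the shared output directory",
                 class = "neuroscrub_key_in_output")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  copies <- purrr::pmap(match$entries, function(subject_id, paths, n_images, status) {
    if (!n_images) return(NULL)
    new_id <- id_map_lookup(id_map, subject_id)
    stems <- if (n_images == 1L) new_id else
      sprintf("%s_%d", new_id, seq_len(n_images))
    purrr::map2(paths, stems, function(src, stem) {
      ext <- tolower(tools::file_ext(src))
      targets <- character(0)
      for (e in if (ext == "hdr") c("hdr", "img") else ext) {
        from <- sub("\\.(nii|hdr)$", paste0(".", e), src, ignore.case = TRUE)
        to <- file.path(out_dir, paste0(stem, ".", e))
        if (file.exists(to)) {
          rlang::abort(paste0("output collision: ", to),
                       class = "neuroscrub_output_collision")
        }
        file.copy(from, to, overwrite = FALSE)
        targets <- c(targets, to)
      }
      tibble::tibble(original = src, new = targets[1])
    })
  })
  files <- dplyr::bind_rows(purrr::flatten(purrr::compact(copies)))
  new_table <- table
  new_table[[1]] <- id_map_lookup(id_map, table[[1]])
  write_table(tibble::tibble(original = id_map$original, new = id_map$new),
              key_path)
  list(table = new_table, files = files, key_path = key_path)
}

#' Round-trip validation of the anonymization step
#'
#' Automated self-test of the pseudonymization pipeline: each repetition
#' draws a uniformly-sized random subset of rows (without replacement),
#' generates a fresh ID map (seed `seed + rep`), re-labels the subset,
#' and compares every non-ID cell of the re-labelled table against the
#' original under the map. Any cell inequality counts as a failure and
#' the first one is recorded; new-ID collisions with original IDs are
#' counted separately. A correct pipeline reports 0 failures and 0
#' collisions at any number of repetitions.
#'
#' @param table Validated demographic tibble.
#' @param repetitions Number of random-sampling repetitions.
#' @param seed Base RNG seed; repetition r uses `seed + r`.
#' @param fault Optional function `(tibble) -> tibble` applied to the
#'   anonymized subset before comparison; used to verify that an injected
#'   corruption is caught. `NULL` (default) tests the real pipeline.
#' @return An object of class `ns_validation`: list with `repetitions`,
#'   `failures`, `duplicate_id_violations`, `first_failure` (NULL, or
#'   list(rep, row, column)).
#' @export
validate_round_trip <- function(table, repetitions = 1000L, seed = 1L,
                                fault = NULL) {
  validate_table(table)
  failures <- 0L
  dup_violations <- 0L
  first_failure <- NULL
  n <- nrow(table)
  other_cols <- names(table)[-1]
  orig_chr <- as.matrix(dplyr::mutate(table[, -1, drop = FALSE],
                                      dplyr::across(dplyr::everything(),
                                                    as.character)))
  for (r in seq_len(repetitions)) {
    rows <- with_local_seed(seed + r, sample.int(n, size = sample.int(n, 1L)))
    sub <- table[rows, , drop = FALSE]
    map <- generate_id_map(sub[[1]], seed = seed + r)
    dup_violations <- dup_violations + length(intersect(map$new, table[[1]]))
    anon <- sub
    anon[[1]] <- id_map_lookup(map, sub[[1]])
    if (!is.null(fault)) anon <- fault(anon)
    # compare under the map: re-key the anonymized rows by original ID
    back <- map$original[match(anon[[1]], map$new)]
    anon_chr <- as.matrix(dplyr::mutate(anon[, -1, drop = FALSE],
                                        dplyr::across(dplyr::everything(),
                                                      as.character)))
    exp_chr <- orig_chr[match(back, table[[1]]), , drop = FALSE]
    neq_mat <- (is.na(anon_chr) != is.na(exp_chr)) |
      (!is.na(anon_chr) & !is.na(exp_chr) & anon_chr != exp_chr)
    neq <- which(neq_mat, arr.ind = TRUE)
    if (anyNA(back) || nrow(neq)) {
      failures <- failures + 1L
      if (is.null(first_failure)) {
        first_failure <- if (nrow(neq)) {
          list(rep = r, row = rows[neq[1, 1]], column = other_cols[neq[1, 2]])
        } else list(rep = r, row = NA_integer_, column = NA_character_)
      }
    }
  }
  structure(
    list(repetitions = as.integer(repetitions), failures = failures,
         duplicate_id_violations = dup_violations,
         first_failure = first_failure),
    class = "ns_validation"
  )
}

#' @export
print.ns_validation <- function(x, ...) {
  cat(sprintf("<ns_validation: %d repetitions, %d failures, %d duplicate-ID violations>\n",
              x$repetitions, x$failures, x$duplicate_id_violations))
  if (!is.null(x$first_failure)) {
    cat(sprintf("  first failure: rep %d, row %s, column %s\n",
                x$first_failure$rep, x$first_failure$row, x$first_failure$column))
  }
  invisible(x)
}

#' @method glance ns_validation
#' @export
glance.ns_validation <- function(x, ...) {
  tibble::tibble(repetitions = x$repetitions, failures = x$failures,
                 duplicate_id_violations = x$duplicate_id_violations,
                 passed = x$failures == 0L && x$duplicate_id_violations == 0L)
}

#' @method tidy ns_validation
#' @export
tidy.ns_validation <- function(x, ...) glance.ns_validation(x)
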