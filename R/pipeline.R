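# End-to-end orchestration: match -> identifier audit/drop -> generalize
# -> anonymize -> deface -> header scrub -> leak scan -> package, with a
# structured audit log and hard stops at every safety gate.

default_config <- function() {
  list(
    table = NULL, images = NULL, out_dir = NULL, package_path = NULL,
    seed = 1L, prefix = "SUB", digits = 4L,
    match = list(pattern = NULL, allow_multiple = FALSE,
                 search_full_path = FALSE, fill_missing = FALSE,
                 ignore_case = FALSE),
    drop_auto = TRUE, drop_columns = character(),
    generalize = list(),
    deface = list(enabled = TRUE, f = 0.5, backend = "builtin"),
    scrub_headers = TRUE,
    manifest = list(user = NULL, institution = NULL,
                    sharing_level = "OPEN", attest = FALSE)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) && k != "generalize") {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full de-identification pipeline
#'
#' Executes, in order: associative match, identifier-column audit and
#' drop, quasi-identifier generalization, collision-free re-labelling
#' (table + image files), defacing, header scrubbing, leak scan, and
#' packaging. Every stage is appended to an audit log (stage, detail,
#' timestamp); the first gate failure stops the run with a non-zero
#' status and the stage name. Reruns with the same seed produce the same
#' shared table and the same new-ID set.
#'
#' @param config A named list (or path to a YAML file) overriding the
#'   defaults: `table` (TSV/CSV path), `images` (directory or file
#'   paths), `out_dir`, `package_path`, `seed`, `prefix`, `digits`,
#'   `match` (pattern/allow_multiple/search_full_path/fill_missing),
#'   `drop_auto`, `drop_columns`, `generalize` (list of
#'   `list(column, kind, parameter)`), `deface` (enabled/f/backend),
#'   `scrub_headers`, `manifest` (user/institution/sharing_level/attest).
#' @return An object of class `ns_pipeline`: list with `status` (0 on
#'   success), `log` (tibble), `failed_stage`, `error`, plus on success
#'   `shared_table`, `out_dir`, `package_path`, `key_path`,
#'   `leak_report`, `id_map`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, detail = detail,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  }
  stage <- "setup"
  result <- tryCatch({
    stopifnot(!is.null(cfg$table), !is.null(cfg$images), !is.null(cfg$out_dir))
    image_paths <- if (length(cfg$images) == 1L && dir.exists(cfg$images)) {
      list.files(cfg$images, pattern = "\\.(nii|hdr|img)$", full.names = TRUE,
                 recursive = TRUE, ignore.case = TRUE)
    } else cfg$images

    stage <- "load_table"
    table <- load_table(cfg$table)
    note(stage, sprintf("%d rows, %d columns", nrow(table), ncol(table)))

    stage <- "match"
    match <- match_images(table, image_paths, pattern = cfg$match$pattern,
                          allow_multiple = isTRUE(cfg$match$allow_multiple),
                          search_full_path = isTRUE(cfg$match$search_full_path),
                          ignore_case = isTRUE(cfg$match$ignore_case))
    if (isTRUE(cfg$match$fill_missing) && length(match$unmatched_files)) {
      table <- fill_missing_rows(table, match)
      match <- match_images(table, image_paths, pattern = cfg$match$pattern,
                            allow_multiple = isTRUE(cfg$match$allow_multiple),
                            search_full_path = isTRUE(cfg$match$search_full_path),
                            ignore_case = isTRUE(cfg$match$ignore_case))
    }
    note(stage, sprintf("%d MATCHED, %d MISMATCH, %d unmatched file(s)",
                        sum(match$entries$status == "MATCHED"),
                        sum(match$entries$status == "MISMATCH"),
                        length(match$unmatched_files)))

    stage <- "identifier_audit"
    dropped_values <- character()
    drop <- unique(as.character(cfg$drop_columns))
    if (isTRUE(cfg$drop_auto)) {
      findings <- detect_identifier_columns(table)
      drop <- unique(c(drop, setdiff(findings$column, names(table)[1])))
    }
    drop <- intersect(drop, names(table))
    if (length(drop)) {
      vals <- unlist(lapply(table[drop], as.character), use.names = FALSE)
      dropped_values <- unique(vals[!is.na(vals)])
      table <- drop_columns(table, drop)
    }
    note(stage, sprintf("dropped %d identifier column(s): %s",
                        length(drop), paste(drop, collapse = ", ")))

    stage <- "generalize"
    for (rule in cfg$generalize) {
      table <- generalize_column(table, rule$column, rule$kind, rule$parameter)
      note(stage, sprintf("%s: %s(%s)", rule$column, rule$kind, rule$parameter))
    }

    stage <- "anonymize"
    id_map <- generate_id_map(table[[1]], prefix = cfg$prefix,
                              digits = cfg$digits, seed = cfg$seed)
    anon <- apply_id_map(match, table, id_map, cfg$out_dir)
    shared_table <- anon$table
    note(stage, sprintf("%d subjects re-labelled, %d image file(s) copied",
                        nrow(id_map), nrow(anon$files)))

    stage <- "deface"
    if (isTRUE(cfg$deface$enabled)) {
      hdrs <- sort(list.files(cfg$out_dir, pattern = IMAGE_EXTS,
                              full.names = TRUE, ignore.case = TRUE))
      for (p in hdrs) {
        v <- read_volume(p)
        res <- skull_strip(v, f = cfg$deface$f, backend = cfg$deface$backend)
        write_volume_like(res$stripped, v, p)
        release_voxels(v)
      }
      note(stage, sprintf("defaced %d image(s), backend %s, f = %g",
                          length(hdrs), cfg$deface$backend, cfg$deface$f))
    } else {
      note(stage, "skipped (--no-strip)")
    }

    stage <- "scrub_headers"
    if (isTRUE(cfg$scrub_headers)) {
      hdrs <- sort(list.files(cfg$out_dir, pattern = IMAGE_EXTS,
                              full.names = TRUE, ignore.case = TRUE))
      for (p in hdrs) scrub_image_header(p)
      note(stage, sprintf("scrubbed %d header(s)", length(hdrs)))
    }

    stage <- "write_shared_table"
    write_table(shared_table, file.path(cfg$out_dir, "demographics.tsv"))

    stage <- "leak_scan"
    leaks <- scan_for_leaks(cfg$out_dir, shared_table,
                            original_ids = id_map$original,
                            dropped_values = dropped_values)
    note(stage, sprintf("%d finding(s)", nrow(leaks)))
    if (nrow(leaks)) {
      rlang::abort(sprintf("leak scan reported %d finding(s)", nrow(leaks)),
                   class = "neuroscrub_leak_detected")
    }

    stage <- "package"
    manifest <- build_manifest(cfg$manifest$user, cfg$manifest$institution,
                               cfg$manifest$sharing_level,
                               attestation = isTRUE(cfg$manifest$attest))
    pkg_path <- cfg$package_path %||%
      paste0(sub("/+$", "", cfg$out_dir), ".tar.gz")
    package_dataset(cfg$out_dir, manifest, pkg_path, leak_report = leaks)
    note(stage, pkg_path)

    list(status = 0L, failed_stage = NULL, error = NULL,
         shared_table = shared_table, out_dir = cfg$out_dir,
         package_path = pkg_path, key_path = anon$key_path,
         leak_report = leaks, id_map = id_map)
  }, error = function(e) {
    note(stage, paste0("FAILED: ", conditionMessage(e)))
    list(status = 1L, failed_stage = stage, error = e)
  })
  result$log <- dplyr::bind_rows(log)
  class(result) <- "ns_pipeline"
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ns_pipeline <- function(x, ...) {
  cat(sprintf("<ns_pipeline: %s>\n",
              if (x$status == 0L) "completed" else
                paste0("FAILED at stage ", x$failed_stage)))
  print(x$log)
  invisible(x)
}
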