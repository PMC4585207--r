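# Associative matching and missing-row filling.

touch_images <- function(dir, names) {
  paths <- file.path(dir, names)
  for (p in paths) writeLines("", p)
  paths
}

test_that("exact stem matches give 1:1 MATCHED with nothing left over", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, c("S01.nii", "S02.nii"))
  m <- match_images(id_table(c("S01", "S02")), paths)
  expect_identical(m$entries$status, c("MATCHED", "MATCHED"))
  expect_identical(m$entries$n_images, c(1L, 1L))
  expect_length(m$unmatched_files, 0)
})

test_that("a subject without an image is reported MISMATCH", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, "S01.nii")
  m <- match_images(id_table(c("S01", "S02")), paths)
  expect_identical(m$entries$status[m$entries$subject_id == "S01"], "MATCHED")
  expect_identical(m$entries$status[m$entries$subject_id == "S02"], "MISMATCH")
})

test_that("longer IDs win prefix collisions (S1 never claims S10.nii)", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, c("S1.nii", "S10.nii"))
  m <- match_images(id_table(c("S1", "S10")), paths)
  got <- setNames(vapply(m$entries$paths, basename, ""), m$entries$subject_id)
  # brute-force oracle: over both assignment orders, exactly one complete
  # assignment is consistent with exact-stem matching
  consistent <- list()
  for (ord in list(c("S1", "S10"), c("S10", "S1"))) {
    taken <- character(0); asg <- c()
    for (id in ord) {
      cand <- setdiff(basename(paths), taken)
      hit <- cand[tools::file_path_sans_ext(cand) == id]
      if (length(hit) == 1) { taken <- c(taken, hit); asg[id] <- hit }
    }
    if (length(asg) == 2) consistent[[length(consistent) + 1]] <- asg[c("S1", "S10")]
  }
  expect_true(all(vapply(consistent, identical, TRUE, y = got[c("S1", "S10")])))
  expect_identical(unname(got["S1"]), "S1.nii")
  expect_identical(unname(got["S10"]), "S10.nii")
})

test_that("multiple runs per subject are accepted only with allow_multiple", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, c("S01_run1.nii", "S01_run2.nii"))
  expect_error(match_images(id_table("S01"), paths),
               class = "neuroscrub_multiple_images")
  m <- match_images(id_table("S01"), paths, allow_multiple = TRUE)
  expect_identical(m$entries$status, "MATCHED")
  expect_identical(m$entries$n_images, 2L)
  expect_identical(basename(m$entries$paths[[1]]),
                   c("S01_run1.nii", "S01_run2.nii"))
})

test_that("wildcard patterns and path search extend the match", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, c("scan_S01_T1.nii"))
  m <- match_images(id_table("S01"), paths, pattern = "scan_{id}_*")
  expect_identical(m$entries$status, "MATCHED")
  expect_error(match_images(id_table("S01"), paths, pattern = "scan_*"),
               class = "neuroscrub_bad_pattern")

  sd <- file.path(td, "S02"); dir.create(sd)
  p2 <- touch_images(sd, "anat.nii")
  expect_identical(match_images(id_table("S02"), p2)$entries$status, "MISMATCH")
  m2 <- match_images(id_table("S02"), p2, search_full_path = TRUE)
  expect_identical(m2$entries$status, "MATCHED")
})

test_that("a file claimable by two same-length IDs is an ambiguity error", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, "S01_S02.nii")
  expect_error(match_images(id_table(c("S01", "S02")), paths),
               class = "neuroscrub_ambiguous_match")
})

test_that("hdr/img pairs are one logical image and files partition cleanly", {
  td <- withr::local_tempdir()
  for (f in c("S01.hdr", "S01.img", "S02.hdr", "S02.img", "XX9.nii")) {
    writeLines("", file.path(td, f))
  }
  all_paths <- list.files(td, full.names = TRUE)
  m <- match_images(id_table(c("S01", "S02")), all_paths)
  matched <- unlist(m$entries$paths)
  expect_identical(sort(c(matched, m$unmatched_files)),
                   sort(file.path(td, c("S01.hdr", "S02.hdr", "XX9.nii"))))
  expect_length(intersect(matched, m$unmatched_files), 0)
  expect_identical(basename(m$unmatched_files), "XX9.nii")
})

test_that("matching is independent of input file ordering", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, c("S1.nii", "S10.nii", "S2_run1.nii", "S2_run2.nii"))
  tbl <- id_table(c("S1", "S10", "S2"))
  m1 <- match_images(tbl, paths, allow_multiple = TRUE)
  m2 <- match_images(tbl, rev(paths), allow_multiple = TRUE)
  set.seed(4); m3 <- match_images(tbl, sample(paths), allow_multiple = TRUE)
  expect_identical(m1$entries, m2$entries)
  expect_identical(m1$entries, m3$entries)
})

test_that("fill_missing_rows appends all-missing rows for orphan images", {
  td <- withr::local_tempdir()
  paths <- touch_images(td, c("S01.nii", "S02.nii"))
  tbl <- tibble::tibble(ID = "S01", SEX = "M", SCORE = 3)
  m <- match_images(tbl, paths)
  filled <- fill_missing_rows(tbl, m)
  expect_identical(filled$ID, c("S01", "S02"))
  expect_true(all(is.na(filled[2, -1])))
  # no unmatched files -> identity
  m2 <- match_images(filled, paths)
  expect_identical(fill_missing_rows(filled, m2), filled)
  # two orphan copies of one new subject -> a single new row
  d1 <- file.path(td, "a"); d2 <- file.path(td, "b")
  dir.create(d1); dir.create(d2)
  p1 <- touch_images(d1, "S03.nii"); p2 <- touch_images(d2, "S03.nii")
  m3 <- match_images(tbl, c(paths[1], p1, p2), allow_multiple = TRUE)
  expect_length(m3$unmatched_files, 2)
  filled3 <- fill_missing_rows(tbl, m3)
  expect_identical(filled3$ID, c("S01", "S03"))
})
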