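# neuroscrub

De-identification and audited packaging of linked neuroimaging datasets:
structural brain volumes (Analyze 7.5 `.hdr`/`.img`, NIfTI-1 `.nii` or
`.hdr`/`.img`) together with the delimited demographic/behavioral table
whose first column holds the subject IDs.

Sharing human-subject imaging data requires producing a limited dataset:
no direct identifiers (names, dates, patient IDs buried in image headers),
no renderable face voxels, no unusual quasi-identifier values, and new
subject labels that cannot be traced back to the originals — while the
images and the table stay correctly linked under the new labels.
neuroscrub is a headless library + CLI for that workflow, aimed at
researchers preparing structural MRI studies for open or controlled
sharing.

## What it does

* **Byte-level header engine.** The 348-byte Analyze/NIfTI header is
  decoded against an explicit field-layout table (published offsets,
  storage types, both byte orders). Free-text fields (`descrip`,
  `patient_id`, `exp_date`, ...) are editable/scrubbable; geometry fields
  (`dim`, `datatype`, `pixdim`, ...) are protected and cannot be touched.
  Re-encoding an unedited header reproduces the input byte-for-byte, and
  an edit changes only that field's byte span. Format auto-detection
  follows the magic bytes at offset 344 (`ni1`/`n+1`/neither), and
  `.nii` ↔ `.hdr`/`.img` conversion round-trips voxels bit-exactly.
* **Associative matching.** Image files are linked to table rows by the
  subject ID in the filename or path (exact stem, `{id}` wildcard
  pattern, bounded substring, path component), longest-ID-first so `S1`
  never claims `S10.nii`; unmatched subjects are reported `MISMATCH`.
* **Tabular auditing.** Missing-cell report, automatic identifier-column
  detection (name patterns + date-valued columns), column dropping, and
  quasi-identifier generalization: rounding to a bin width, significant
  figures, or range bands (an age of 96 becomes `"[90, 100)"`).
* **Pseudonymization with validation.** Collision-free random ID maps
  (`SUB` + zero-padded digits, seeded, disjoint from the original IDs by
  rejection sampling); table and image files are re-labelled together and
  the key file is kept out of the shared set. `validate_round_trip()`
  re-runs anonymize-and-compare on random row subsets — 1000 repetitions
  on a 581-row table in the acceptance run — and must see 0 cell
  mismatches and 0 duplicate-ID violations.
* **Defacing + QC.** Skull-stripping through an external brain-extraction
  tool when installed, or a built-in fractional-intensity fallback
  (threshold t = p2 + f·(p98 − p2) over the robust intensity range,
  largest 6-connected component, radius-1 closing; monotone in f, default
  f = 0.5). QC metrics against ground-truth masks and an
  original-vs-stripped montage PNG rendered two volumes at a time.
* **Leak scan + audited packaging.** Substring scan for every original ID
  and dropped identifier value across filenames, table cells, editable
  header fields and the log; packaging into a deterministic tar.gz is
  gated on a clean scan, an explicit attestation, and the absence of the
  ID key file.
* **Synthetic data.** Head phantoms (brain ellipsoid, skull shell, face
  wedge, recorded ground-truth masks) and demographic tables with planted
  identifiers/missing cells make every stage testable with no external
  data.

## Worked example

```r
library(neuroscrub)

td <- tempdir()
ds <- make_synthetic_dataset(3, file.path(td, "study"), seed = 42)

res <- run_pipeline(list(
  table = ds$table_path, images = file.path(td, "study"),
  out_dir = file.path(td, "shared"), seed = 2026,
  generalize = list(list(column = "HEIGHT", kind = "bin_round", parameter = 5),
                    list(column = "AGE", kind = "range_band", parameter = 10)),
  manifest = list(user = "J. Contributor", institution = "Example University",
                  sharing_level = "OPEN", attest = TRUE)))

res$log[, c("stage", "detail")]
#> # A tibble: 10 × 2
#>    stage            detail
#>  1 load_table       3 rows, 10 columns
#>  2 match            3 MATCHED, 0 MISMATCH, 0 unmatched file(s)
#>  3 identifier_audit dropped 3 identifier column(s): NAME, DOB, TESTDATE
#>  4 generalize       HEIGHT: bin_round(5)
#>  5 generalize       AGE: range_band(10)
#>  6 anonymize        3 subjects re-labelled, 3 image file(s) copied
#>  7 deface           defaced 3 image(s), backend builtin, f = 0.5
#>  8 scrub_headers    scrubbed 3 header(s)
#>  9 leak_scan        0 finding(s)
#> 10 package          /tmp/.../shared.tar.gz

res$shared_table
#> # A tibble: 3 × 7
#>   ID      SEX   AGE      HEIGHT WEIGHT SCORE1 SCORE2
#> 1 SUB3704 F     [20, 30)    170   85.6   87.8   48.7
#> 2 SUB9184 F     [50, 60)    185   80.8  104.    21.6
#> 3 SUB2341 F     [40, 50)    180   86.6   97.6   47.9
```

The direct identifiers (NAME, DOB, TESTDATE) are gone, heights are rounded
to 5 cm, ages are decade bands, the subjects carry fresh random `SUB` labels
(disjoint from `S001`–`S003`), the shared images are defaced and their
headers scrubbed, the leak scan found nothing, and
`shared.tar.gz` holds images + table + audit log — while `shared_key.tsv`
(the only way back to the original IDs) stays outside the archive.

The same operations are available from the shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "neuroscrub", package = "neuroscrub"))')
Rscript $CLI synth --subjects 5 --out study/ --seed 1
Rscript $CLI detect study/S001.nii          # NIFTI_SINGLE
Rscript $CLI table audit study/demographics.tsv
Rscript $CLI run --config pipeline.yaml --seed 2026
```

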