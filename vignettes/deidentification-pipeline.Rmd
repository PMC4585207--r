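---
title: "De-identifying linked neuroimaging datasets with neuroscrub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying linked neuroimaging datasets with neuroscrub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroscrub)
```

## The problem

Sharing human-subject imaging studies requires removing every direct and
indirect identifier from two linked artifacts at once: the structural brain
volumes (whose headers carry free-text fields such as a patient ID or scan
date, and whose voxels can render a recognizable face) and the
demographic/behavioral spreadsheet keyed by subject ID. The two must stay
linked after de-identification, so the subject labels have to be replaced
consistently — and the replacement must not be invertible by a recipient.

neuroscrub implements that workflow headlessly: format detection and
byte-level header auditing for Analyze 7.5 and NIfTI-1, associative matching
of image files to table rows, identifier-column removal and quasi-identifier
generalization, collision-free random re-labelling with automated round-trip
validation, defacing with QC, an identifier leak scan, and audited tar.gz
packaging.

## Header model

Both supported formats share a 348-byte binary header. The package decodes
it against an explicit field-layout table (name, byte offset, storage type,
element count) and keeps the original bytes alongside the decoded values,
which gives two guarantees the auditing workflow depends on:

* **Re-encoding identity.** `encode_header(read_header(x))` reproduces the
  input byte-for-byte for any canonical header, in either byte order
  (detected by decoding `sizeof_hdr == 348` after a trial byte swap, and
  written back in the source's byte order).
* **Edit locality.** Editing a field rewrites only that field's byte span.
  Geometry and codec fields (`dim`, `datatype`, `bitpix`, `pixdim`,
  `vox_offset`, the transform block) are *protected*: editing them would
  corrupt the image, so the API refuses. The editable roster is the
  free-text fields only — `descrip`, `aux_file`, `db_name`, plus the
  Analyze history fields (`originator`, `generated`, `scannum`,
  `patient_id`, `exp_date`, `exp_time`). A user scrub policy may narrow
  this roster but never widen it into protected fields.

Oversize string edits are rejected rather than truncated: silent truncation
could corrupt an audit trail. Scrubbing zero-fills the policy fields and is
idempotent. NIfTI header extensions are dropped (with a warning) on scrub
and on conversion — extension blocks are opaque byte ranges and a natural
hiding place for identifiers. One documented corner case: format detection
follows the magic bytes at offset 344, so an Analyze file whose `smin`
field happened to spell `"ni1\0"` would be mis-typed as NIfTI; a legitimate
`smin` value doing so is vanishingly unlikely.

```{r}
fx <- make_head_volume(fixture_spec(seed = 7), format = "analyze",
                       dir = tempdir(), stem = "demo")
h <- read_header(fx$paths[1])
h <- edit_header_field(h, "patient_id", "PT007")
header_fields(h)[c(1, 7, 10, 24, 30), ]
scrub_header(h)$values$patient_id
```

## Associative matching

Each logical image (a `.nii`, or a `.hdr`/`.img` pair keyed by the shared
stem) is linked to the subject ID in the table's first column. Matching is
resolved per file at the strongest applicable tier — exact stem, user
wildcard pattern (`"{id}_*"`, glob semantics), ID bounded by
non-alphanumerics in the basename, then (optionally) a path component equal
to the ID. Ties at the same tier go to the longer ID, so `S1` can never
claim `S10.nii`; a tie between equal-length IDs is an error, never a silent
pick. Subjects without an image are reported `MISMATCH`; orphan images can
be appended to the table as all-missing rows. Inputs are sorted internally,
so the result does not depend on file ordering. ID comparison is
case-sensitive by default (`ignore_case = TRUE` to relax): on mixed
filesystems explicitness is safer for an audit trail.

## Re-labelling and its validation

`generate_id_map()` draws `prefix` + zero-padded random integers from a
seeded RNG without replacement, rejecting any candidate equal to an
original ID, and widening the digit width if the label space runs short, so
the new-ID set is always internally unique and disjoint from the originals.
The original-to-new key is written *outside* the shared directory and the
packager refuses to archive a directory containing a key file: the shared
set itself carries no link back, while the contributor retains a local key
(useful if an incidental finding in shared data must be traced back).

`validate_round_trip()` is the automated self-test of this step: each
repetition samples a random non-empty row subset (without replacement;
subset size uniform), generates a fresh map with a per-repetition seed
(`seed + rep`, reproducible failure reports), re-labels, and compares every
non-ID cell against the original under the map. The package's acceptance
run performs 1000 repetitions on a 581-row synthetic table and requires 0
failures and 0 duplicate-ID violations — and, with a deliberately injected
cell corruption, requires the comparison to catch it.

```{r}
tbl <- make_demographics(50, seed = 2)
glance(validate_round_trip(tbl, repetitions = 100, seed = 7))
```

## Tabular auditing and generalization

`detect_identifier_columns()` flags the ID column, any column whose name
matches the identifier roster (id as a token; name, dob, birth, date,
address, phone, ssn, mrn, email, zip as substrings, case-insensitively),
and character columns where at least 80% of non-missing values parse as
dates (ISO, US `mm/dd/yyyy`, or European `dd/mm/yyyy`). The 80% threshold
and the pattern roster are configurable; they are a pragmatic heuristic for
"this column is a date/identifier", not a disclosure-risk model — formal
k-anonymity optimization is out of scope.

Generalization coarsens numeric quasi-identifiers: `bin_round` rounds to
the nearest multiple of a width w (halves away from zero — the convention
is stated because plain "rounding" is ambiguous), `sig_figs` keeps s
significant figures, and `range_band` replaces x with the label
`[kw, (k+1)w)` — an extreme value such as a 96-year-old participant becomes
an unremarkable `"[90, 100)"`. Missing cells pass through; `bin_round`
never moves a value by more than w/2 and is idempotent.

## Defacing

The defacing stage removes voxels representing the face by skull-stripping.
When an external brain-extraction executable (`bet`) is on `PATH` it is
invoked with `-f <f>` and its output defines the mask. Because that
toolchain is frequently absent, a built-in fallback is always available; it
mimics the fractional-intensity-threshold semantics of the external tool
but is a deliberately simple stand-in, not a reimplementation of the
published surface-evolution algorithm:

1. robust intensity range: 2nd and 98th percentiles (p2, p98) over nonzero
   voxels;
2. threshold t = p2 + f (p98 − p2), f in [0, 1], default 0.5 — larger f
   removes more;
3. keep the largest 6-connected component above t (drops the disconnected
   skull shell and face surface);
4. radius-1 morphological closing (6-neighborhood) to fill pinholes.

The builtin mask is deterministic and monotone in f (larger f gives a
subset mask), and the stripped volume equals the input inside the mask and
zero outside. An all-zero volume yields an empty mask with
`removed_fraction` defined as 0. Re-stripping with a different f after QC
is just another call. Already-stripped data can bypass the stage
(`deface$enabled = FALSE` in the pipeline config).

QC is quantitative and visual: `qc_compare()` reports removed fraction and
per-region retention against ground-truth masks, and `render_montage()`
writes an original-vs-stripped mid-slice grid (axial/coronal/sagittal),
loading one pair of volumes at a time — voxel data is lazily materialized
on first access and released per pair, so the peak number of resident
volumes is 2 regardless of cohort size (`volume_load_stats()` instruments
this contract).

## Leak scan and packaging

Before packaging, `scan_for_leaks()` does a case-sensitive substring
search for every original ID and every value from dropped identifier
columns across output filenames, every table cell, every editable header
field of every shared image, and the manifest text. Packaging is gated on
an empty report (stronger than a manual attestation alone: the gate
verifies the scrub), on the contributor's explicit attestation, and on the
absence of a key file in the shared directory; `force = TRUE` overrides the
leak gate and records the override in the log. The archive is a
POSIX tar + gzip with members sorted by path, so packaging is deterministic
and extraction is byte-identical. Remote transfer is out of scope — the
archive is transport-agnostic.

## Synthetic data: what it does and does not show

All tests run on generated fixtures. The head phantom is geometric: a
brain ellipsoid (intensity 1000), a skull shell (600), an anterior face
wedge (300) over a zero background with additive truncated-Gaussian noise
(sd 10), at 64 x 64 x 40 voxels (int16). Those intensities place the face
wedge below and the brain above the default f = 0.5 threshold, and the
wedge is spatially disconnected from the brain, so the builtin stripper's
contract (face fully removed, at least 95% of brain retained) is decidable
against recorded ground-truth masks. The demographic generator plants real
identifier shapes (names, DOBs, test dates), one extreme age (96), and
missing cells at a configurable rate with recorded positions, at up to the
581-row scale used in the validation runs.

What passing these tests shows: the byte-level format engine, the matching
and re-labelling algebra, the gates, and the mask-removal contracts are
correct. What they do not show: performance of the *builtin* defacer on
real anatomy — it has no bias-field handling, no neck, no connected
skull-brain bridges. On real data the external brain-extraction backend
should be preferred and its output reviewed with the montage; that caveat
is inherent to any intensity-threshold stand-in.

## Numerical and design choices

* Problem sizes in the test suite: 1000 fuzzed header cases, 1000
  validation repetitions on 581 synthetic subjects, 200 random ID-map
  draws up to 10^4 IDs, a five-point f grid for mask monotonicity, and
  5-subject end-to-end runs; the whole suite runs in well under a minute.
* Per-repetition and per-subject seeds are derived additively
  (`seed + k`) so every random artifact is reproducible from one CLI
  `--seed`.
* Analyze-to-NIfTI promotion keeps geometry and free-text description
  fields and sets the NIfTI-only fields to identity-compatible defaults
  (`qform_code = sform_code = 0`, `scl_slope = 0`); the Analyze history
  fields have no NIfTI slot and do not survive promotion, which is the
  safe direction for de-identification.
* Conversion necessarily rewrites the two container fields (`magic`,
  `vox_offset`); every other protected field is preserved exactly, and
  round trips preserve voxel bytes bit-for-bit.
* The comparison in `validate_round_trip()` operates on the table (the
  artifact the evaluation compares); image copying is validated separately
  by the packaging round-trip tests.

## Limitations

DICOM, NIfTI-2 and compressed `.nii.gz` inputs are unsupported; binary
`.xls` spreadsheets are not parsed (delimited text covers the data model);
there is no fuzzy ID matching; and the leak scan is substring-based — it
catches verbatim identifier reuse, not semantic leaks (e.g. a free-text
note describing a subject). Disclosure-risk scoring is deliberately out of
scope.
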