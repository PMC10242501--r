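---
title: "A radiology operations warehouse: data model, query semantics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A radiology operations warehouse: data model, query semantics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radwarehouse)
```

`radwarehouse` turns flat radiology-information-system (RIS) exports into an
entity-attribute-value (EAV) warehouse and answers cross-tabulation cohort
queries on it. This vignette explains the model and the choices behind it:
what is computed, under which conventions, and what the synthetic test data
do and do not establish about real exports.

## The data model

A RIS export is one examination per row, one attribute per column, attribute
names in the first row. The import configuration maps each column to a
catalog entry and flags the metadata roles. Three roles are mandatory —
appointment/case identifier, examination start time (the *measure time* of
all values in that row), and modality; patient and examination identifiers
are optional because real exports often lack them — many hospitals cannot
(or only with effort) ship a patient pseudonym, and some ship no
per-examination identifier at all.

The warehouse is two tables. The **catalog** holds attribute types,
identified by the combination of external ID and project (terminology name);
the numeric attribute ID is installation-local and never part of a query, so
the same query file runs against any installation that shares the
terminology. Catalog entries may have parents; the links form a forest, and a
query on a parent matches values of any descendant (the usual ICD-style
convention; a strict flag disables it). The **info** table holds one record
per non-empty cell: attribute, patient/appointment/examination identifiers,
measure time, and the value as text in a canonical rendering — numbers in
locale-independent decimal text, booleans as `true`/`false`, timestamps as
ISO-8601. When no examination identifier is configured, one is synthesized
as `<appointment>#<ordinal>`; the per-appointment ordinals continue across
appended files so identifiers never collide.

Empty cells are skipped silently (counted); type-invalid cells (a non-number
in a Number column, an unknown boolean token) are skipped with a warning and
counted separately. An import never aborts for cell-level problems — a
malformed export should yield a report of what was dropped, not a dead
pipeline. Misconfiguration, by contrast, fails loudly: if `ColumnName` and
`ColumnNumber` disagree about which export column is meant, that is an error,
never a silent preference.

Timestamps are parsed from ISO-8601 and from the German RIS convention
`dd.mm.yyyy HH:MM[:SS]`, and stored normalized. All times are naive local
times: single-site exports have no timezone information, and inventing one
would only create daylight-saving artefacts in shift assignment.

## Derived metrics

Calculators are the second half of the model: each owns one catalog attribute
(project `"derived"` by default) and a delete-and-replace contract, so
re-running a calculator — or re-running it for just the patients an appended
file touched — is idempotent. The built-ins:

* **Shift**: early `[06:00, 14:00)`, late `[14:00, 22:00)`, night otherwise.
  The paper-trail for shift boundaries in German hospitals is thin; the
  standard three-shift split at 6/14/22 is used and configurable. Half-open
  left-closed intervals make the partition exact: every timestamp gets
  exactly one label.
* **Turnaround** (request → start, hours) and **duration** (start → end,
  minutes): signed differences. Negative values — timestamps out of order in
  the source — are stored and *flagged* in the run statistics rather than
  dropped, because they are a data-quality signal the operations team should
  see.
* **Report availability bucket**: the smallest number of 24-hour windows
  (1–4) after the examination start within which the report was available;
  upper bounds closed (exactly 24 h later is bucket 1), values beyond four
  days clamp into bucket 4, so the buckets partition all reported
  examinations and percentage rows sum to 100. Calendar-day bucketing would
  be an alternative reading ("available the next day"); the 24-hour-window
  reading is used because "available within *n* days" is most naturally a
  duration, and the choice is confined to one function
  (`availability_bucket()`).
* **Device vacancy**: idle minutes between consecutive examinations on the
  same device within one calendar day, attached to the earlier examination;
  the last examination of a device-day has no gap. Overlaps give negative
  gaps, kept and flagged. The day boundary prevents overnight "idle" time
  from dominating the statistic.
* **Modality sequences**: per patient and grouping key (medical-question
  code by default; body region is the other field-typical choice, and the
  key is a parameter), the start-time-ordered modalities rendered `Rö→CT`,
  with the span in hours. The derived records attach to the *first*
  examination of each sequence — some single examination has to carry them,
  and the first is the one whose timestamp dates the sequence.
* **First-contact flags**: per examination, whether it is the patient's
  earliest examination of its calendar year, and the earliest with its
  modality; ties break on (start time, examination ID) so each patient-year
  carries exactly one first-contact flag.

Calculators whose source attributes a given export lacks are skipped with a
warning (an export with only start times simply gets no turnaround metrics);
calculators that need patient identifiers are skipped on exports without
them, and error with an explicit capability condition when called directly.

## The index and MXQL

The query index follows a nested-document picture: one document per patient,
appointment and examination, each knowing the set of attribute IDs occurring
anywhere in its scope (*ContainingFields*) and the typed value postings. The
physical structure is an in-process postings table — an external search
server would add operational weight without changing any observable
behaviour, which is fixed instead by two tested contracts: query results
equal a brute-force scan of the flat export, and ContainingFields pruning is
lossless (disabling it never changes a result).

MXQL queries are XML: a root `Query`, a required `IDFilter` with
`filterIDType` ∈ {`PID`, `AID`, `EID`}, and `DistributionRow` /
`DistributionColumn` / `DistributionFilter` elements each wrapping one
constraint tree of `Attribute` elements, nestable under `And`/`Or`, with
`not="true"` available on any attribute. Operators: `equals` (exact for
codes — case-sensitive, by value for numbers and instants), `not_equals`,
`contains` (case-insensitive substring, forgiving for free text), `regex`
(full match), `lt/le/gt/ge` and a closed `between` for numbers and
timestamps; an attribute without desired content matches by presence.
`desiredContentMax` carries the upper bound of `between`. Serialization is
round-trip stable, which the suite checks on randomized ASTs.

A cell of the result counts distinct IDs at the query's level matching the
row, the column and all filters. Negation is a *document-level complement*:
"not modality=CT" at patient level means patients with **no** CT anywhere,
not patients with some non-CT examination. Two consequences worth noting:

* Co-occurrence is at the ID level. A patient can satisfy
  `modality=Rö and region=Abdomen` through two different examinations.
  Users who mean "the same examination" must count at `EID` level.
* Per constraint, match counts are monotone across levels (every matching
  appointment contains a matching examination, for negated constraints all
  of them). For intersections of several constraints this monotonicity can
  legitimately invert — an appointment can match `CT and Rö` while none of
  its single examinations does — which is exactly the ID-level co-occurrence
  semantics at work, not a bug; the test suite asserts the per-constraint
  form.

Cells are defined independently (one conceptual query per cell); the engine
shares work across cells but is tested cell-by-cell against the brute-force
definition.

## Incremental updates

Two pathways avoid full re-imports. `update_attributes()` takes a list of
attribute names (or a single-column CSV of them): named import columns are
deleted and re-imported from the export, named calculators re-run, and the
index patched with `atomic_update()`, which replaces all postings of the
affected attributes. `append_examinations()` imports a file of new rows
(rows with already-known examination IDs are rejected and counted), runs
per-examination calculators on the new examinations only, and re-runs cohort
calculators for the touched patients only; device vacancy is recomputed
whole because a new examination changes its neighbours' gaps. The governing
property — any interleaving of updates and appends ends query-equivalent to
one full build on the concatenated export — is enforced by the acceptance
suite over randomized queries, with the flat-table oracle as a third
independent route.

One caveat is inherent to synthesized examination IDs: reprocessing a column
recomputes `<appointment>#<ordinal>` from the file itself, which matches the
original import for the originally imported file. Reprocessing columns after
appends therefore requires the concatenated export (or, better, a configured
`ExamID` column, which removes the issue entirely).

## The synthetic generator

The generator emulates a mid-size German single-site export: defaults are
500 patients over one calendar year, one to three appointments per patient
and one to three examinations per appointment (≈1,900 examinations in
expectation, about four per patient), modality mix 40% X-ray / 25% CT / 15%
MRI / 20% ultrasound written as RIS codes (`XR`, `CT`, `MR`, `US`) so the
import's value-mapping path is exercised, eight body regions, five
requesting departments, six devices tied to modalities, ten medical-question
codes, 55% inpatients, 85% statutory insurance. Appointment anchors are
uniform weekdays with 15% late and 5% night starts, so shift reports are
non-degenerate; request-to-start and end-to-report delays are lognormal
(medians ≈12 h and ≈20 h) so the four availability buckets are all
populated. 2% of optional cells are blanked to exercise the skip path. With
probability 0.1 (a rate parameter) a patient additionally receives an
injected X-ray-then-CT pair on a dedicated question code, recorded in the
ground-truth sidecar; dedicating the key keeps "was the injected sequence
recovered exactly" a well-posed question, at the price of not testing
recovery of sequences interleaved with background examinations on the same
key (those are covered separately by randomized group-by oracle tests).

The sidecar also stores true counts per modality, department, shift and
availability bucket computed directly from the flat table, giving the
end-to-end conservation check its independent reference. The same seed
yields byte-identical files.

What passing on this data does *not* show: robustness to genuinely malformed
real-world exports (mixed encodings, shifted headers, free-text where codes
are expected beyond what `ValueMappings` handles), multi-year DST edge
cases, or clinically realistic free-text medical questions — the generator
writes codes, not prose.

## Numerical and scale notes

All counting is exact integer set arithmetic; the only floating-point
quantities are elapsed times and report percentages (rounded to one decimal
for display, raw counts always retained). Timestamp comparisons happen on
parsed instants, not strings. The test suite runs the full pipeline at
roughly 50,000 examinations (about 440,000 imported values) in a few
minutes on one CPU; the acceptance checks use 500 patients/≈1,900
examinations with 100 randomized queries, and 1,000 patients for sequence
recovery, sizes at which the brute-force oracle remains fast enough to check
every query exactly.

## Known limitations

* Excel *writing* shells out to the system Python's `openpyxl`; reading uses
  `readxl`. Systems without Python keep full CSV/JSON functionality.
* Negation is per-attribute, not per-group (`not(And(...))` must be
  rewritten by De Morgan by the user).
* No deletion/correction pathway for historical examinations; the store is
  append-and-recompute.
* MeasureTime is taken from one configured column per row and applied to all
  attributes of that row; per-attribute measure times would need a wider
  export format.
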