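# radwarehouse

A small, dependency-light clinical data warehouse for **radiology operations
metrics**, written for hospital data scientists and controlling teams who
receive radiology-information-system (RIS) exports as flat tables and need
reproducible cohort counts and cross-tab reports from them.

Radiology departments steer their capacity with a handful of recurring
numbers: patients / appointments / examinations per modality, turnaround
times from request to examination and to report availability, idle time
("vacancy") between examinations on each device, and repeated examinations of
the same body region or medical question for one patient. `radwarehouse`
computes all of these from any RIS export that can be written as one
examination per row.

## What it does

* **Configuration-driven import.** A RIS export (CSV, Excel or JSON, one
  examination per row, attribute names in the first row) is mapped to the
  warehouse by a small 7-column configuration table (`DisplayTitle, ExtID,
  DataType, ColumnName, ColumnNumber, ValueMappings, MetaDataType`). Only
  three roles are required: the appointment/case identifier, the examination
  start time, and the modality. `ValueMappings` rewrites RIS codes (e.g.
  `XR=Rö;US=Sono`) during import.
* **Entity-attribute-value store.** Two tables: a *catalog* of attribute
  types, identified by `(ExternalID, Project)` and optionally arranged in a
  hierarchy, and an *info* table of `(patient, appointment, examination,
  measure time, value)` records. Everything — imported or derived — is an
  ordinary attribute, so everything is queryable the same way.
* **Derived metrics as pluggable calculators**: working shift
  (early/late/night), request-to-start turnaround, examination duration,
  report-availability bucket (1–4 days), device vacancy, per-patient modality
  sequences (`Rö→CT`) per medical question or body region, and
  first-contact flags. Calculators own their records, so re-running them
  replaces rather than duplicates.
* **A three-level query index** over patients, appointments and examinations,
  with per-document attribute sets for candidate pruning and atomic
  per-attribute updates.
* **MXQL**, an XML cross-tabulation query language: `DistributionRow`s ×
  `DistributionColumn`s × `DistributionFilter`s over attribute constraints
  (`equals`, `contains`, `regex`, numeric/time comparisons, `between`,
  negation, nested `And`/`Or`), counted at a chosen ID level (`PID`, `AID`,
  `EID`). A cell counts the distinct IDs at that level matching the row, the
  column and every filter; constraints co-occur *at the ID level* (a patient
  matches `modality=Rö and region=Abdomen` if both occur anywhere in their
  records — run an `EID`-level query for same-examination co-occurrence).
* **Incremental updates**: reprocess a named subset of attributes, or append
  a file of new examinations; both are query-equivalent to a full rebuild,
  which the test suite verifies against a brute-force oracle.
* **A deterministic synthetic RIS generator** with a ground-truth sidecar, so
  the whole pipeline is testable without any protected data.

## Worked example

```r
library(radwarehouse)

# a synthetic single-site export: 500 patients, one calendar year
g  <- generate_ris_export(generator_params(seed = 1), out_dir = "demo")
pl <- import_pipeline(g$paths$csv, g$paths$config)   # import + derive + index
glance(pl$wh)
#> # A tibble: 1 × 6
#>   catalog_entries patients appointments examinations values_imported
#>             <int>    <int>        <int>        <int>           <int>
#> 1              22      500         1073         1919           24801
#> # i 1 more variable: values_generated <int>

# patients per modality x body region, restricted to one requesting department
q <- mx_query(
  rows    = list(mx_attribute("MOD", "ris", "equals", "Rö", display_name = "X-ray"),
                 mx_attribute("MOD", "ris", "equals", "CT", display_name = "CT")),
  cols    = list(mx_attribute("LOC", "ris", "equals", "Abdomen", display_name = "Abdomen"),
                 mx_attribute("LOC", "ris", "equals", "BWS", display_name = "BWS")),
  filters = list(mx_attribute("DEPT", "ris", "equals", "Chirurgie")),
  id_level = "PID")
evaluate(pl$ix, pl$wh, q)
#> <result_table> counted at level PID
#>       Abdomen BWS
#> X-ray      98  91
#> CT         87  77
```

98 is the number of distinct patients with at least one X-ray, at least one
abdominal examination and at least one examination requested by surgery
anywhere in their records. The same query serializes to an MXQL XML file with
`serialize_mxql()` and can be re-run later with `run_saved_query()`.

Report-availability percentages (share of reports ready within 1–4 days, per
modality):

```r
predefined_reports(pl$ix, pl$wh, "availability_buckets")$percentages
#>         1    2    3    4
#> CT   63.5 19.3  7.0 10.2
#> MRI  56.7 24.3 12.3  6.7
#> Rö   60.6 22.4  8.2  8.8
#> Sono 55.3 20.5 11.5 12.6
```

A thin command-line wrapper (`inst/cli/radwh.R`) exposes the same pipeline as
`generate` / `import` / `update` / `append` / `query` / `report` / `inspect`
subcommands over a file-backed store.

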