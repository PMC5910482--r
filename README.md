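# mwtabr

Parse, validate and convert **mwTab** files — the flat-file format of the
Metabolomics Workbench Data Repository.

## The problem

Metabolomics studies deposited in the Metabolomics Workbench are stored as
mwTab text files: sequentially ordered `#`-prefixed blocks (PROJECT, STUDY,
SUBJECT, ANALYSIS, ...) holding key–value metadata, a
SUBJECT_SAMPLE_FACTORS block mapping each sample to its subject and
experimental factors, and feature-by-sample matrices of measured values
(`MS_METABOLITE_DATA` or `NMR_BINNED_DATA`) with a mandatory units field.
Each file carries a study identifier (`ST######`, shared across analyses)
and a unique analysis identifier (`AN######`).

Deposited files drift from the format specification in practice — blank
lines before the `#METABOLOMICS WORKBENCH` header, missing `#END` markers,
empty mandatory units fields, case variants of the same unit name
("Peak height" vs "peak height"). Anyone auditing, cleaning or reusing
repository metadata needs a parser that survives those defects, reports
them precisely, and loses no information on the way in or out.

`mwtabr` provides the full round trip for R users:

* **Lexing + parsing** (`tokenize()`, `parse_mwtab()`) into an ordered
  document model with uniform key access: `get_value(doc, "PROJECT",
  "PROJECT_SUMMARY")` or `doc[["PROJECT"]][["PROJECT_SUMMARY"]]`.
* **Lossless bidirectional JSON conversion** (`write_json()`,
  `parse_json()`, `write_mwtab()`): both serializations carry the same
  (section, key, value) triples and table cells, and
  `parse_*(write_*(doc))` reproduces the document exactly.
* **Schema validation** (`validate_document()`): per-block required /
  optional field sets (the PROJECT block requires PROJECT_TITLE,
  PROJECT_SUMMARY, INSTITUTE, LAST_NAME, FIRST_NAME, ADDRESS, EMAIL and
  PHONE, the last two with format regexes), plus file-level and
  cross-block consistency checks (missing `#END`, empty units, sample
  columns vs factor records, ragged table rows), all collected as data
  with stable machine codes — never thrown.
* **Streaming multi-source input** (`read_files()`): one file, a
  directory, a zip / tar.gz / tar.bz2 archive, a URL or a bare analysis
  id, read lazily one document at a time; per-file failures become error
  records instead of stream aborts.
* **Batch conversion and a CLI** (`convert()`, `cli_main()`, plus the
  `inst/exec/mwtab` Rscript wrapper) for `convert` / `validate` from the
  shell, with exit codes 0 (clean), 1 (validation errors), 2 (usage),
  3 (I/O).
* **A deterministic fixture generator** (`generate_document()`,
  `inject_corruption()`) producing schema-valid synthetic analyses with
  known ground truth and seven seeded corruption classes — the package's
  test bed, and a convenient corpus source for anyone testing mwTab
  tooling offline.

## Worked example

```r
library(mwtabr)

fx  <- generate_document(fixture_spec(seed = 42, n_samples = 4, n_metabolites = 10))
doc <- fx$document
doc
#> <mwtab_document>
#>   study ST000043, analysis AN000043
#>   #METABOLOMICS WORKBENCH: 4 items
#>   #PROJECT: 8 items
#>   ...
#>   #SUBJECT_SAMPLE_FACTORS: 0 items + 4 sample records
#>   #MS_METABOLITE_DATA: 0 items + MS_METABOLITE_DATA table [10 x 4]

get_value(doc, "PROJECT", "EMAIL")
#> [1] "jane.doe@example.org"
list_sample_columns(doc)
#> [1] "S001" "S002" "S003" "S004"

# knock out the end marker and validate
broken <- inject_corruption(write_mwtab(doc), "MISSING_END")
validate_document(parse_mwtab(broken$text))
#> 1 validation finding(s):
#>   [error] MISSING_END (file): file is missing the '#END' marker that
#>   signals the end of the file

# the measured-value matrix as a data.frame (values stay verbatim text)
head(as.data.frame(doc$sections$MS_METABOLITE_DATA$data_table), 3)
#>   feature_id       S001       S002       S003       S004
#> 1    alanine  7234.5886  5322.4171 53192.1249 73764.4226
#> 2   arginine 74321.3401 73134.2346 88512.9175 35509.0655
#> 3 asparagine 85194.5792 44285.1989 15796.4312 50918.7400
```

From the shell:

```sh
mwtab convert AN000001.txt AN000001.json --from_format=mwtab --to_format=json
mwtab validate AN000001.txt --report=json
```

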