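---
title: "The mwTab format toolkit: model, dialect and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mwTab format toolkit: model, dialect and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwtabr)
```

This vignette is the package's own account of how it models the mwTab
flat-file format, which dialect decisions it fixes where the format
leaves room, and what its validation and synthetic test bed do and do
not establish about real repository files.

## The document model

An mwTab file is a sequence of `#`-prefixed text blocks. The model
mirrors that directly: an `mwtab_document` is an ordered collection of
sections, each holding an ordered key–value item map and, depending on
the block, either subject–sample–factor records
(`SUBJECT_SAMPLE_FACTORS`) or a feature-by-sample data table (the MS /
NMR results blocks and the `METABOLITES` metadata table) — never both.
Three modelling commitments drive everything else:

* **Order is data.** Sections and keys serialize exactly in stored
  order, so a parse→write cycle is a fixed point and diffs against the
  original file stay meaningful.
* **All values are text.** Matrix cells, dates, numeric-looking
  metadata — everything is kept verbatim as character data; numeric
  interpretation belongs to the consumer. This is what makes the
  mwTab↔JSON mapping lossless in both directions.
* **The header is a pseudo-section.** The fields of the
  `#METABOLOMICS WORKBENCH` header line (STUDY_ID, ANALYSIS_ID) and the
  adjacent top-of-file items (VERSION, CREATED_ON) are exposed as an
  ordinary section named `METABOLOMICS WORKBENCH`, so one access idiom
  (`get_value`, `[[`) covers the whole file; a derived `header` record
  offers the same four fields as typed slots.

Two-letter key prefixes (`PR:`, `ST:`, `SU:`, `CO:`, `TR:`, `SP:`,
`CH:`, `AN:`, `MS:`, `NM:`) are stripped at parse time and regenerated
from a fixed section→prefix table at write time: keys become clean
identifiers in memory while the emitted file stays faithful.

## Lexing dialect

Deposited files vary between tab-separated and visually aligned
key columns, and between LF and CRLF line endings. The lexer therefore
fixes a tolerant reading rule and the writer a canonical emitting rule:

* **Item split rule.** The key is the first whitespace-delimited field
  of the line; the value is the remainder after that whitespace run,
  with trailing whitespace stripped. Values keep internal whitespace
  (including tabs, which is how `SUBJECT_SAMPLE_FACTORS` rows carry
  their tab-separated fields through the item channel).
* **Writer layout.** By default the key field is left-padded to 33
  characters followed by a tab (`layout_policy("fixed")`), matching the
  aligned look of deposited files; `layout_policy("tab")` emits plain
  `key<TAB>value`. A key wider than the column falls back to single-tab
  separation with a warning. Output always uses LF.
* **Continuation values.** A long value is written as repeated-key
  lines wrapped greedily at spaces to at most 80 value characters, and
  repeated keys merge back into one value at parse time. The format
  itself does not state the merge separator; this package uses a single
  space (configurable via `layout_policy(merge_sep = )`), under which
  wrap→merge is exactly inverse for space-separated prose. Values with
  runs of consecutive spaces longer than the wrap width are the one
  known exception; none of the metadata fields the format carries in
  practice look like that.
* **Totality.** The lexer never fails on decodable text. Blank lines
  (legal anywhere, including before the header) lex as BLANK tokens,
  and non-blank content before the header becomes a diagnostic-carrying
  token; deciding severity is the validator's job, not the lexer's. Any
  `NAME_START` / `NAME_END` pair fences a table, so unknown table
  blocks lex as tables (`EXTENDED` kind) rather than breaking the
  stream.

Recoverable structural defects found during parsing — content before
the header, a table left open at a section boundary, items belonging to
no section, content after `#END` — are recorded as findings on the
document and re-reported by `validate_document()`. Only a file with no
`#METABOLOMICS WORKBENCH` line at all is a fatal parse error: without
it there is no evidence the input is an mwTab file.

## The JSON mapping

The JSON representation is a one-to-one image of the model: a single
top-level object keyed by section name in document order. Ordinary
sections become objects of key→string; `SUBJECT_SAMPLE_FACTORS` becomes
an array of `{"Subject type", "Sample ID", "Factors", "Additional
sample data"}` records (arrays preserve duplicate sample ids, which an
object could silently collapse); data sections become `{"Units",
"Samples", "Factors" (optional), "Data"}` with one object per feature,
keyed `"Metabolite"` (or `"Bin range"` for NMR binned data) plus one
member per sample in column order. No JSON numbers are ever emitted —
quoting every scalar keeps e.g. `007.500` intact.

Structurally foreign JSON fails with a `MAPPING_ERROR` naming the
offending key; syntactically broken JSON fails with the underlying
parser's position message. Both are classed conditions, so callers can
branch without matching message text.

## Validation design

Findings are data, never exceptions: every check appends a row
(severity, stable code, section, key, line, message) to an ordered
frame, and validating the same document twice yields identical frames.
Severity policy: structural breaches and missing required metadata are
**errors** (MISSING_END, MISSING_REQUIRED_FIELD, CONSTRAINT_VIOLATION,
EMPTY_UNITS, SSF_MALFORMED, ROW_ARITY, ORPHAN_ITEM, TABLE_WITHOUT_END,
MULTIPLE_RESULTS); tolerable drift is a **warning** (LEADING_CONTENT,
UNKNOWN_KEY, COLUMN_MISMATCH, ID_MISMATCH, POST_END_CONTENT). The split
reflects how the repository actually behaves: files with leading blank
lines or extra keys remain perfectly usable, files without required
metadata do not.

The PROJECT block schema — eight required fields (PROJECT_TITLE,
PROJECT_SUMMARY, INSTITUTE, LAST_NAME, FIRST_NAME, ADDRESS, EMAIL,
PHONE) and eight optional ones (PROJECT_TYPE, DEPARTMENT, LABORATORY,
FUNDING_SOURCE, PROJECT_COMMENTS, PUBLICATIONS, CONTRIBUTIONS, DOI) —
is built into the package. Schemas for the remaining blocks are loaded
from a bundled JSON file (`inst/extdata/mwtab_schema.json`) modelled on
the official block structure, and a user file merged on top may
override any of them, including PROJECT. The EMAIL rule (one `@`,
non-empty local and dotted domain part) and PHONE rule (at least seven
characters from digits, space, `+-().`) are deliberately permissive
schema *data*, not code: deposited contact fields are free text, and
the constraints aim to catch category errors (a name in the phone
field), not to enforce RFC syntax.

Cross-block consistency covers what is checkable within one file: the
results table's sample-column count against the factor-record count,
per-row cell arity against the table header, and the header ANALYSIS_ID
against an `AN<digits>` id embedded in the source address. Between
files, batch validation checks one thing — STUDY_ID agreement across
the batch, reported as a single coherence warning; deeper cross-file
semantics (shared subjects, comparable factor levels) are out of scope.

`survey_units()` supports the corpus-level audit that per-file
validation cannot express: it tallies the mandatory units value of
every results table across a collection, counts empty ones, and
optionally case-folds so that variants like "Peak height" and
"peak height" merge into one entry.

## The synthetic test bed

`generate_document()` builds a complete, schema-valid analysis file
from a seed: synthetic ST/AN identifiers, every required key of every
schema-covered block populated with plausible laboratory metadata, a
multi-line project summary long enough to exercise continuation
wrapping, `n_samples` factor records, and an `n_metabolites ×
n_samples` matrix of uniform decimals rendered to four places
(metabolite names drawn from a fixed pool of real compound names; NMR
fixtures use chemical-shift bin ranges instead). All randomness flows
from the spec's seed through an isolated RNG scope, so identical specs
render byte-identical files and generation never perturbs the caller's
random stream. Defaults (6 samples, 20 features, one two-level factor)
are desk-scale stand-ins for a small deposited analysis; bounds
(10^4 samples, 10^5 features) keep accidental monsters out of test
runs.

`inject_corruption()` introduces exactly one defect of a named class
and returns the issue codes the validator must — and must only —
report: leading blank lines → LEADING_CONTENT; removed `#END` →
MISSING_END; blanked units value → EMPTY_UNITS; a dropped required
PROJECT key (seeded choice) → MISSING_REQUIRED_FIELD; a blanked sample
id in one factor row → SSF_MALFORMED; a truncated table row →
ROW_ARITY. The seventh class, UNITS_CASE_VARIANT, is the deliberate
exception with an empty expected set: flipping the case of a units
value leaves the file individually valid and only becomes visible when
a collection is surveyed with case folding — mirroring how such
variants actually manifest in the repository.

What passing this test bed shows: the parser, writer, JSON codec,
archive readers and validator are exact inverses / exact detectors on
the format dialect defined above, including its defect classes. What it
does not show: robustness to layout quirks outside those classes
(exotic encodings, interleaved tables, hand-mangled factor syntax), or
anything statistical about real metabolite intensity distributions —
fixture values are uniform noise by design.

Problem sizes used by the shipped checks: the round-trip property runs
100 fixtures spanning both platforms, 1–50 samples and 1–500 features
(the corners included deliberately); fault detection runs all seven
classes × 20 seeds; source equivalence packs one six-file corpus as a
directory, zip, tar.gz and tar.bz2. These sizes exercise every code
path — larger corpora change nothing structurally and are left to the
`fixtures` CLI subcommand.

## Numerical and degenerate-input choices

* An empty units value is *written back* as an empty units line rather
  than dropped, so the writer never hides what the validator should
  report.
* An empty subject field in a factor record is stored as the
  conventional `-` placeholder; writing a truly empty first field would
  shift the tab layout of the row.
* Ragged table rows (cell count ≠ header count) are kept verbatim in
  the model — padding or truncating would destroy the evidence the
  ROW_ARITY finding points at. The JSON image of a *short* ragged row
  pads missing samples with empty strings on re-parse; round-trip
  identity is guaranteed only for structurally valid tables.
* At most one MS/NMR results table is expected per file; extra ones
  parse fine and are flagged MULTIPLE_RESULTS rather than rejected,
  since the official grammar's stance is unstated.
* Archive members stream in archive order (not name order), matching
  streaming decompression; directory scans sort lexicographically for
  reproducibility.
* Network access (URL and analysis-id sources) is off by default and
  must be enabled per call; the REST URL template is configuration, so
  nothing in the package hard-codes an endpoint or touches the network
  in tests.

## Known limitations

* The continuation-merge separator is a dialect choice (space); a file
  whose long values encode meaningful newlines would round-trip to
  space-joined prose.
* Leading/trailing whitespace inside value fields is normalized by the
  item split rule; byte-level fidelity is guaranteed for the canonical
  writer's output, not for arbitrary third-party layouts.
* Schemas for blocks other than PROJECT capture the official block
  structure at the level this package needs (required/optional key
  sets); they are intended to be user-replaceable data, not a frozen
  authority.
* `validate` exit status reflects per-file errors only; batch coherence
  issues are warnings by design.
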