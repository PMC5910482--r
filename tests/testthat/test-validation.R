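test_that("the built-in PROJECT schema encodes the block contract", {
  sch <- default_schemas()$PROJECT
  expect_length(sch$required, 8L)
  expect_true("DOI" %in% sch$optional)
  expect_length(intersect(sch$required, sch$optional), 0L)
  # EMAIL and PHONE carry format constraints
  expect_false(is.null(sch$value_rules$EMAIL$regex))
  expect_false(is.null(sch$value_rules$PHONE$regex))
})

test_that("a missing required field yields exactly one descriptive error", {
  fx <- fixture_text(seed = 12)
  doc <- parse_mwtab(fx$text)
  sec <- doc$sections$PROJECT
  sec$items <- sec$items[names(sec$items) != "PROJECT_TITLE"]
  issues <- validate_section(sec, default_schemas()$PROJECT)
  expect_equal(nrow(issues), 1L)
  expect_equal(issues$code, "MISSING_REQUIRED_FIELD")
  expect_equal(issues$severity, "error")
  expect_equal(issues$key, "PROJECT_TITLE")
  expect_match(issues$message, "PROJECT_TITLE")
})

test_that("a complete well-formed PROJECT block validates cleanly", {
  fx <- fixture_text(seed = 22, include_optional_keys = TRUE)
  issues <- validate_section(fx$document$sections$PROJECT, default_schemas()$PROJECT)
  expect_equal(nrow(issues), 0L)
})

test_that("value rules catch malformed EMAIL and PHONE entries", {
  fx <- fixture_text(seed = 25)
  doc <- set_value(fx$document, "PROJECT", "EMAIL", "not-an-email")
  issues <- validate_section(doc$sections$PROJECT, default_schemas()$PROJECT)
  expect_equal(issues$code, "CONSTRAINT_VIOLATION")
  expect_equal(issues$key, "EMAIL")

  doc2 <- set_value(fx$document, "PROJECT", "PHONE", "abc")
  issues2 <- validate_section(doc2$sections$PROJECT, default_schemas()$PROJECT)
  expect_equal(issues2$code, "CONSTRAINT_VIOLATION")
  expect_equal(issues2$key, "PHONE")
})

test_that("keys outside the schema are warnings, never errors", {
  fx <- fixture_text(seed = 26)
  doc <- set_value(fx$document, "PROJECT", "MYSTERY_KEY", "x")
  issues <- validate_section(doc$sections$PROJECT, default_schemas()$PROJECT)
  expect_equal(issues$code, "UNKNOWN_KEY")
  expect_equal(issues$severity, "warning")
})

test_that("a user schema file can tighten the defaults", {
  user <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(PROJECT = list(
    required = as.list(c(default_schemas()$PROJECT$required, "DOI")),
    optional = as.list(setdiff(default_schemas()$PROJECT$optional, "DOI"))
  )), auto_unbox = TRUE), user)
  schemas <- default_schemas(user)
  fx <- fixture_text(seed = 27)   # fixture has no DOI by default
  issues <- validate_document(parse_mwtab(fx$text), schemas)
  expect_true(any(issues$code == "MISSING_REQUIRED_FIELD" & issues$key == "DOI"))

  expect_error(default_schemas(file.path(tempdir(), "no-such-schema.json")),
               class = "mwtab_schema_load_error")
  broken <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", broken)
  expect_error(default_schemas(broken), class = "mwtab_schema_load_error")
})

test_that("document-level checks report missing #END exactly once", {
  fx <- fixture_text(seed = 30)
  broken <- inject_corruption(fx$text, "MISSING_END")$text
  issues <- validate_document(parse_mwtab(broken))
  expect_equal(sum(issues$code == "MISSING_END"), 1L)
  expect_equal(issues$severity[issues$code == "MISSING_END"], "error")
})

test_that("a pristine fixture yields zero findings of any severity", {
  for (platform in c("MS", "NMR")) {
    fx <- fixture_text(seed = 35, platform = platform)
    expect_equal(nrow(validate_document(parse_mwtab(fx$text))), 0L)
  }
})

test_that("an empty mandatory units field is reported exactly once", {
  fx <- fixture_text(seed = 36)
  broken <- inject_corruption(fx$text, "EMPTY_UNITS")$text
  issues <- validate_document(parse_mwtab(broken))
  expect_equal(issues$code, "EMPTY_UNITS")
})

test_that("consistency checking compares sample columns to factor records", {
  fx <- fixture_text(seed = 38, n_samples = 6, n_metabolites = 4)
  doc <- parse_mwtab(fx$text)
  expect_equal(nrow(check_consistency(doc)), 0L)

  # drop one factor record: 6 columns vs 5 records
  sec <- doc$sections$SUBJECT_SAMPLE_FACTORS
  sec$ssf_records <- sec$ssf_records[-1]
  doc2 <- doc
  doc2$sections$SUBJECT_SAMPLE_FACTORS <- sec
  issues <- check_consistency(doc2)
  expect_equal(issues$code, "COLUMN_MISMATCH")
  expect_equal(issues$severity, "warning")
  expect_match(issues$message, "6 sample columns")
  expect_match(issues$message, "5 samples")

  # a document without a data table has nothing to cross-check
  expect_equal(nrow(check_consistency(parse_mwtab(minimal_mwtab()))), 0L)
})

test_that("a header analysis id conflicting with the source address is flagged", {
  fx <- fixture_text(seed = 39)
  doc <- parse_mwtab(fx$text, source_id = "/data/AN999999.txt")
  issues <- check_consistency(doc)
  expect_true("ID_MISMATCH" %in% issues$code)
  ok <- parse_mwtab(fx$text, source_id = paste0(fx$ground_truth$analysis_id, ".txt"))
  expect_false("ID_MISMATCH" %in% check_consistency(ok)$code)
})

test_that("validation is deterministic and ordered", {
  fx <- fixture_text(seed = 44)
  broken <- inject_corruption(fx$text, "DROP_REQUIRED_KEY", seed = 2)$text
  doc <- parse_mwtab(broken)
  expect_identical(as.data.frame(validate_document(doc)),
                   as.data.frame(validate_document(doc)))
})

test_that("supplying a required key with a valid value never adds errors", {
  fx <- fixture_text(seed = 46)
  schemas <- default_schemas()
  for (drop_key in c("PROJECT_TITLE", "EMAIL", "PHONE")) {
    broken <- fx$document
    sec <- broken$sections$PROJECT
    sec$items <- sec$items[names(sec$items) != drop_key]
    broken$sections$PROJECT <- sec
    n_before <- sum(validate_document(broken, schemas)$severity == "error")
    fixed <- set_value(broken, "PROJECT", drop_key,
                       get_value(fx$document, "PROJECT", drop_key))
    n_after <- sum(validate_document(fixed, schemas)$severity == "error")
    expect_lte(n_after, n_before)
  }
})

test_that("the units survey tallies values and counts missing fields", {
  docs <- list()
  for (i in 1:10) {
    fx <- fixture_text(seed = 100 + i, n_samples = 2, n_metabolites = 2)
    text <- if (i <= 3) inject_corruption(fx$text, "EMPTY_UNITS")$text else fx$text
    docs[[i]] <- parse_mwtab(text)
  }
  sv <- survey_units(docs)
  expect_equal(sv$missing_count, 3L)
  expect_equal(sv$n_tables, 10L)
  expect_equal(sum(sv$tally) + sv$missing_count, sv$n_tables)
})

test_that("case folding merges unit-name variants into one tally entry", {
  mk <- function(units_line_case, seed) {
    fx <- fixture_text(seed = seed, n_samples = 2, n_metabolites = 2)
    text <- if (units_line_case) inject_corruption(fx$text, "UNITS_CASE_VARIANT")$text
            else fx$text
    parse_mwtab(text)
  }
  docs <- list(mk(TRUE, 1), mk(TRUE, 2), mk(FALSE, 3))   # "Peak area" x2, "peak area" x1
  verbatim <- survey_units(docs, "verbatim")
  expect_length(verbatim$tally, 2L)
  folded <- survey_units(docs, "case-folded")
  expect_length(folded$tally, 1L)
  expect_equal(unname(folded$tally[[1]]), 3L)
  expect_equal(names(folded$tally), "peak area")

  empty <- survey_units(list())
  expect_equal(empty$missing_count, 0L)
  expect_length(empty$tally, 0L)
})

test_that("schema definitions reject overlapping required/optional sets", {
  expect_error(schema_definition("X", required = "A", optional = c("A", "B")),
               class = "mwtab_schema_load_error")
})
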