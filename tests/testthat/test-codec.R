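test_that("repeated item keys merge into a single continuation value", {
  doc <- parse_mwtab(minimal_mwtab())
  expect_equal(get_value(doc, "PROJECT", "PROJECT_SUMMARY"), "part A part B")
})

test_that("a header-and-end-only stream builds a document with no ordinary sections", {
  doc <- parse_mwtab("#METABOLOMICS WORKBENCH\n#END")
  expect_equal(section_names(doc), "METABOLOMICS WORKBENCH")
  expect_true(doc$end_marker)
})

test_that("the parsed document has exactly the generated section count", {
  for (platform in c("MS", "NMR")) {
    fx <- fixture_text(seed = 17, platform = platform)
    doc <- parse_mwtab(fx$text)
    expect_length(doc$sections, fx$ground_truth$n_sections)
  }
})

test_that("parsing a fixture round-trips every generated key-value triple", {
  fx <- fixture_text(seed = 29, n_samples = 4, n_metabolites = 6)
  doc <- parse_mwtab(fx$text)
  for (triple in fx$ground_truth$items) {
    expect_identical(get_value(doc, triple$section, triple$key), triple$value)
  }
})

test_that("leading blank lines leave the model unchanged but are flagged", {
  fx <- fixture_text(seed = 2)
  clean <- parse_mwtab(fx$text)
  dirty <- parse_mwtab(paste0("\n\n", fx$text))
  expect_true(doc_equal(clean, dirty))
  expect_true("LEADING_CONTENT" %in% dirty$findings$code)
  expect_false("LEADING_CONTENT" %in% clean$findings$code)
})

test_that("empty or headerless text is a fatal parse error", {
  expect_error(parse_mwtab(""), class = "mwtab_no_file_header")
  expect_error(parse_mwtab("PROJECT_TITLE\tno header here"),
               class = "mwtab_no_file_header")
})

test_that("parse-write-parse is a fixed point and section headers are countable", {
  fx <- fixture_text(seed = 41, n_samples = 3, n_metabolites = 5, platform = "NMR")
  doc <- parse_mwtab(fx$text)
  txt2 <- write_mwtab(doc)
  expect_true(doc_equal(doc, parse_mwtab(txt2)))
  expect_identical(txt2, write_mwtab(parse_mwtab(txt2)))

  # line-count oracle: one '#' header per ordinary section, plus the file
  # header and #END
  lines <- scan_lines(txt2)
  hash_lines <- grep("^#", lines)
  expect_length(hash_lines, length(doc$sections) - 1L + 2L)
})

test_that("an empty units value is written and preserved for the validator", {
  fx <- fixture_text(seed = 3, n_samples = 2, n_metabolites = 3)
  broken <- inject_corruption(fx$text, "EMPTY_UNITS")$text
  doc <- parse_mwtab(broken)
  dt <- doc$sections$MS_METABOLITE_DATA$data_table
  expect_identical(dt$units, "")
  rewritten <- write_mwtab(doc)
  expect_true(any(grepl("^MS_METABOLITE_DATA:UNITS$", scan_lines(rewritten))))
  expect_identical(parse_mwtab(rewritten)$sections$MS_METABOLITE_DATA$data_table$units, "")
})

test_that("the JSON representation round-trips the model exactly", {
  for (seed in c(1, 8)) {
    fx <- fixture_text(seed = seed, n_samples = 3, n_metabolites = 4,
                       platform = if (seed == 1) "MS" else "NMR")
    doc <- parse_mwtab(fx$text)
    js <- write_json(doc)
    expect_true(doc_equal(doc, parse_json(js)))
  }
})

test_that("JSON output is strict standard JSON with the canonical shape", {
  n <- 5L
  fx <- fixture_text(seed = 19, n_samples = n, n_metabolites = 3)
  js <- write_json(fx$document)
  expect_true(jsonlite::validate(js))
  # independent reading with a plain JSON parser
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(names(obj)[[1]], "METABOLOMICS WORKBENCH")
  expect_length(obj[["SUBJECT_SAMPLE_FACTORS"]], n)
  expect_equal(obj[["SUBJECT_SAMPLE_FACTORS"]][[1]][["Sample ID"]], "S001")
  data_sec <- obj[["MS_METABOLITE_DATA"]]
  expect_equal(data_sec$Units, "peak area")
  expect_length(data_sec$Samples, n)
  expect_length(data_sec$Data, 3L)
  # all scalars are strings: matrix values arrive unquoted nowhere
  expect_true(is.character(data_sec$Data[[1]][[2]]))
})

test_that("structurally foreign JSON raises a mapping error naming the key", {
  js <- write_json(fixture_text(seed = 4, n_samples = 2, n_metabolites = 2)$document)
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  obj[["SUBJECT_SAMPLE_FACTORS"]] <- list(bad = "object not array")
  bad <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  expect_error(parse_json(bad), class = "mwtab_mapping_error")
  expect_error(parse_json(bad), "SUBJECT_SAMPLE_FACTORS")
  expect_error(parse_json("[1, 2]"), class = "mwtab_mapping_error")
  expect_error(parse_json("{ not json"), class = "mwtab_json_syntax")
})

test_that("mwTab -> JSON -> mwTab reproduces the canonical rendering", {
  fx <- fixture_text(seed = 37, n_samples = 4, n_metabolites = 5)
  doc <- parse_mwtab(fx$text)
  back <- parse_json(write_json(doc))
  expect_identical(write_mwtab(back), write_mwtab(doc))
})

test_that("information parity holds between the two serializations", {
  fx <- fixture_text(seed = 53, n_samples = 3, n_metabolites = 4)
  doc <- parse_mwtab(fx$text)
  from_json <- parse_json(write_json(doc))
  # identical (section, key, value) triples and table cells
  expect_identical(
    lapply(doc$sections, function(s) s$items),
    lapply(from_json$sections, function(s) s$items)
  )
  expect_identical(
    doc$sections$MS_METABOLITE_DATA$data_table$rows,
    from_json$sections$MS_METABOLITE_DATA$data_table$rows
  )
})

test_that("tables left open are closed at the section boundary and flagged", {
  fx <- fixture_text(seed = 6, n_samples = 2, n_metabolites = 3)
  lines <- scan_lines(fx$text)
  lines <- lines[!grepl("^MS_METABOLITE_DATA_END$", lines)]
  doc <- parse_mwtab(paste(lines, collapse = "\n"))
  expect_true("TABLE_WITHOUT_END" %in% doc$findings$code)
  dt <- doc$sections$MS_METABOLITE_DATA$data_table
  expect_length(dt$feature_ids, 3L)
})

test_that("items outside any section are quarantined and flagged", {
  txt <- paste(
    "#METABOLOMICS WORKBENCH",
    "STRAY_KEY\tstray value",
    "#PROJECT",
    "PR:PROJECT_TITLE\tT",
    "#END", sep = "\n")
  doc <- parse_mwtab(txt)
  expect_true("ORPHAN_ITEM" %in% doc$findings$code)
  expect_true("UNATTRIBUTED" %in% section_names(doc))
  expect_true("STRAY_KEY" %in% names(doc$sections$UNATTRIBUTED$items))
})
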