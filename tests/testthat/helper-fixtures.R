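# shared helpers: every fixture is generated in code at test time

# one fixture rendered to text, with its ground truth
fixture_text <- function(seed = 1L, n_samples = 6L, n_metabolites = 20L,
                         platform = "MS", ...) {
  fx <- generate_document(fixture_spec(seed = seed, n_samples = n_samples,
                                       n_metabolites = n_metabolites,
                                       platform = platform, ...))
  fx$text <- write_mwtab(fx$document)
  fx
}

# a tiny handwritten file, independent of the generator and the writer
minimal_mwtab <- function() {
  paste(
    "#METABOLOMICS WORKBENCH STUDY_ID:ST000001 ANALYSIS_ID:AN000001",
    "VERSION\t1",
    "CREATED_ON\t2016-09-17",
    "#PROJECT",
    "PR:PROJECT_TITLE\tTiny project",
    "PR:PROJECT_SUMMARY\tpart A",
    "PR:PROJECT_SUMMARY\tpart B",
    "#END",
    sep = "\n"
  )
}

# independent oracle: raw line scan of mwTab text (no package parser)
scan_lines <- function(text) strsplit(text, "\r\n|\n|\r")[[1]]

# value fragments of a repeated (continuation) key, by raw regex scan
scan_item_fragments <- function(text, key) {
  lines <- scan_lines(text)
  hits <- grep(paste0("^", key, "[ \t]"), lines, value = TRUE)
  sub(paste0("^", key, "[ \t]+"), "", hits)
}

expect_issue_codes <- function(issues, expected) {
  expect_setequal(unique(issues$code), expected)
}
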