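#' Synthetic mwTab fixtures with known ground truth
#'
#' A deterministic generator of valid mwTab documents plus a corruption
#' injector reproducing the defect classes observed in deposited
#' repository files (leading blank lines, missing `#END`, empty
#' mandatory units, missing required metadata fields, malformed
#' subject-sample-factor rows, ragged table rows, case-variant unit
#' names). Together they form a self-contained test bed: every
#' uncorrupted fixture validates with zero findings, and every injected
#' corruption maps to a documented expected issue-code set.
#'
#' @name fixtures
NULL

#' Specify a synthetic fixture
#'
#' @param seed integer seed; all randomness in [generate_document()]
#'   flows from it.
#' @param n_samples number of samples (1 to 10^4).
#' @param n_metabolites number of features / bins (1 to 10^5).
#' @param platform `"MS"` or `"NMR"`; selects the analysis metadata
#'   block and the results-table type.
#' @param n_factors number of experimental factors (>= 0).
#' @param include_optional_keys also populate optional schema keys.
#' @return an object of class `mwtab_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_samples = 6L, n_metabolites = 20L,
                         platform = c("MS", "NMR"), n_factors = 1L,
                         include_optional_keys = FALSE) {
  platform <- match.arg(platform)
  seed <- as.integer(seed)
  n_samples <- as.integer(n_samples)
  n_metabolites <- as.integer(n_metabolites)
  n_factors <- as.integer(n_factors)
  if (is.na(n_samples) || n_samples < 1L || n_samples > 10000L) {
    stop_mwtab("FIXTURE_BOUNDS", "n_samples must be between 1 and 10^4")
  }
  if (is.na(n_metabolites) || n_metabolites < 1L || n_metabolites > 100000L) {
    stop_mwtab("FIXTURE_BOUNDS", "n_metabolites must be between 1 and 10^5")
  }
  if (is.na(n_factors) || n_factors < 0L) {
    stop_mwtab("FIXTURE_BOUNDS", "n_factors must be >= 0")
  }
  structure(list(seed = seed, n_samples = n_samples,
                 n_metabolites = n_metabolites, platform = platform,
                 n_factors = n_factors,
                 include_optional_keys = isTRUE(include_optional_keys)),
            class = "mwtab_fixture_spec")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_fixture_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

METABOLITE_POOL <- c(
  "alanine", "arginine", "asparagine", "aspartate", "citrate", "creatine",
  "cysteine", "fumarate", "glucose", "glutamate", "glutamine", "glycine",
  "histidine", "isoleucine", "lactate", "leucine", "lysine", "malate",
  "methionine", "myo-inositol", "ornithine", "phenylalanine", "proline",
  "pyruvate", "serine", "succinate", "taurine", "threonine", "tryptophan",
  "tyrosine", "uracil", "urea", "valine", "xanthine", "adenosine",
  "inosine", "hypoxanthine", "choline", "betaine", "carnitine"
)

SUMMARY_WORDS <- c(
  "metabolite", "profiling", "of", "plasma", "samples", "collected", "from",
  "subjects", "under", "controlled", "dietary", "conditions", "to",
  "characterize", "pathway", "level", "responses", "and", "identify",
  "candidate", "biomarkers", "across", "treatment", "groups", "using",
  "targeted", "and", "untargeted", "assays", "with", "replicate",
  "measurements", "for", "quality", "control"
)

random_sentence <- function(n_words) {
  words <- sample(SUMMARY_WORDS, n_words, replace = TRUE)
  paste(words, collapse = " ")
}

#' Generate one synthetic document with ground truth
#'
#' Produces a complete, schema-valid document: header with synthetic
#' ST/AN identifiers, every required key of every schema-covered block
#' populated, `n_samples` subject-sample-factor records, and a
#' platform-appropriate results table (`n_metabolites` x `n_samples`
#' pseudo-random decimal values stored as text, fixed units string).
#' Byte-identical output for identical spec + seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `document` (an [mwtab_document()]) and
#'   `ground_truth`: the emitted `(section, key, value)` triples
#'   (`items`), factor records (`ssf`), sample labels (`samples`),
#'   feature ids (`features`), value matrix cells (`rows`), `units` and
#'   ids (`study_id`, `analysis_id`).
#' @export
#' @examples
#' fx <- generate_document(fixture_spec(seed = 42, n_samples = 4))
#' fx$ground_truth$units
generate_document <- function(spec) {
  stopifnot(inherits(spec, "mwtab_fixture_spec"))
  with_fixture_seed(spec$seed, build_fixture(spec))
}

build_fixture <- function(spec) {
  num <- spec$seed %% 900000L + 1L
  study_id <- sprintf("ST%06d", num)
  analysis_id <- sprintf("AN%06d", num)

  # long enough to wrap into several continuation lines at the default
  # 80-character width
  summary_text <- random_sentence(45L)

  secs <- list()
  add <- function(name, items) {
    secs[[length(secs) + 1L]] <<- section(name, items = items)
  }
  add(HEADER_SECTION, named_chr(
    c(study_id, analysis_id, "1", "2017-08-30"),
    c("STUDY_ID", "ANALYSIS_ID", "VERSION", "CREATED_ON")))

  project <- c(
    PROJECT_TITLE = paste("Metabolomic study", study_id),
    PROJECT_SUMMARY = summary_text,
    INSTITUTE = "University of Example",
    LAST_NAME = "Doe", FIRST_NAME = "Jane",
    ADDRESS = "123 Example Dr, Example City, EX 40000",
    EMAIL = "jane.doe@example.org",
    PHONE = "555-867-5309"
  )
  if (spec$include_optional_keys) {
    project <- c(project,
      PROJECT_TYPE = "Exploratory", DEPARTMENT = "Biochemistry",
      LABORATORY = "Metabolomics Core", FUNDING_SOURCE = "Example Foundation",
      PROJECT_COMMENTS = "synthetic fixture", PUBLICATIONS = "none",
      CONTRIBUTIONS = "study design and analysis", DOI = "10.1000/example")
  }
  add("PROJECT", project)

  add("STUDY", c(
    STUDY_TITLE = paste("Synthetic", spec$platform, "study", study_id),
    STUDY_SUMMARY = random_sentence(20L),
    INSTITUTE = "University of Example",
    LAST_NAME = "Doe", FIRST_NAME = "Jane",
    ADDRESS = "123 Example Dr, Example City, EX 40000",
    EMAIL = "jane.doe@example.org",
    PHONE = "555-867-5309"
  ))
  add("SUBJECT", c(SUBJECT_TYPE = "Mammal", SUBJECT_SPECIES = "Mus musculus"))
  add("COLLECTION", c(COLLECTION_SUMMARY = random_sentence(12L)))
  add("TREATMENT", c(TREATMENT_SUMMARY = random_sentence(12L)))
  add("SAMPLEPREP", c(SAMPLEPREP_SUMMARY = random_sentence(12L)))
  if (identical(spec$platform, "MS")) {
    add("CHROMATOGRAPHY", c(
      CHROMATOGRAPHY_TYPE = "Reversed phase",
      INSTRUMENT_NAME = "Agilent 1290 Infinity",
      COLUMN_NAME = "Waters Acquity BEH C18"))
  }
  add("ANALYSIS", c(ANALYSIS_TYPE = spec$platform))
  if (identical(spec$platform, "MS")) {
    add("MS", c(INSTRUMENT_NAME = "Thermo Q Exactive",
                INSTRUMENT_TYPE = "Orbitrap", MS_TYPE = "ESI",
                ION_MODE = "POSITIVE"))
    units <- "peak area"
  } else {
    add("NMR", c(INSTRUMENT_NAME = "Bruker Avance III",
                 INSTRUMENT_TYPE = "FT-NMR",
                 NMR_EXPERIMENT_TYPE = "1D 1H",
                 SPECTROMETER_FREQUENCY = "600 MHz"))
    units <- "peak intensity"
  }

  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  factor_names <- if (spec$n_factors > 0L) {
    paste0("Factor", seq_len(spec$n_factors))
  } else character()
  factor_levels <- c("control", "treated")
  ssf <- lapply(seq_len(spec$n_samples), function(i) {
    fac <- named_chr(
      vapply(seq_along(factor_names), function(f) {
        factor_levels[[(i + f) %% 2L + 1L]]
      }, ""),
      factor_names)
    ssf_record(subject_type = "-", local_sample_id = samples[[i]],
               factors = fac,
               additional_data = named_chr(paste0(samples[[i]], ".raw"),
                                           "RAW_FILE_NAME"))
  })
  secs[[length(secs) + 1L]] <- section(SSF_SECTION, ssf_records = ssf)

  n_m <- spec$n_metabolites
  if (identical(spec$platform, "MS")) {
    base <- METABOLITE_POOL[(seq_len(n_m) - 1L) %% length(METABOLITE_POOL) + 1L]
    dup <- ave(seq_len(n_m), base, FUN = seq_along)
    features <- ifelse(dup > 1L, paste0(base, "_", dup), base)
    table_name <- "MS_METABOLITE_DATA"
  } else {
    lo <- sprintf("%.2f", 0.04 * seq_len(n_m))
    hi <- sprintf("%.2f", 0.04 * seq_len(n_m) + 0.04)
    features <- paste0(lo, "..", hi)
    table_name <- "NMR_BINNED_DATA"
  }
  rows <- lapply(seq_len(n_m), function(i) {
    sprintf("%.4f", stats::runif(spec$n_samples, 10, 100000))
  })
  factor_row <- if (spec$n_factors > 0L) {
    vapply(ssf, function(r) {
      paste(sprintf("%s:%s", names(r$factors), r$factors), collapse = " | ")
    }, "")
  } else NULL
  secs[[length(secs) + 1L]] <- section(
    table_name,
    data_table = data_table(table_name, units = units, column_names = samples,
                            factor_row = factor_row, feature_ids = features,
                            rows = rows))

  doc <- mwtab_document(sections = secs, source_id = "", end_marker = TRUE)

  items <- list()
  for (sec in secs) {
    for (k in names(sec$items)) {
      items[[length(items) + 1L]] <- list(section = sec$name, key = k,
                                          value = unname(sec$items[[k]]))
    }
  }
  list(
    document = doc,
    ground_truth = list(
      items = items, ssf = ssf, samples = samples, features = features,
      rows = rows, units = units, study_id = study_id,
      analysis_id = analysis_id, n_sections = length(secs),
      platform = spec$platform, summary = summary_text
    )
  )
}

CORRUPTION_CLASSES <- c(
  "LEADING_BLANK_LINES", "MISSING_END", "EMPTY_UNITS", "DROP_REQUIRED_KEY",
  "SSF_MALFORMED", "ROW_ARITY", "UNITS_CASE_VARIANT"
)

#' Inject exactly one defect into mwTab text
#'
#' Reproduces the defect classes seen in deposited repository files.
#' Returns the corrupted text together with the issue codes the
#' validator is expected to (and only to) report for it -- the contract
#' used by the single-fault detection tests. `UNITS_CASE_VARIANT` is the
#' one class with an empty expected set: flipping the case of a units
#' value is invisible to per-file validation and only surfaces when
#' [survey_units()] case-folds a collection.
#'
#' @param text mwTab text that parses cleanly.
#' @param cls one of `LEADING_BLANK_LINES`, `MISSING_END`, `EMPTY_UNITS`,
#'   `DROP_REQUIRED_KEY`, `SSF_MALFORMED`, `ROW_ARITY`,
#'   `UNITS_CASE_VARIANT`.
#' @param seed seed for the injector's choices (which key to drop, which
#'   row to break).
#' @return list with `text` (corrupted) and `expected` (character vector
#'   of issue codes).
#' @export
inject_corruption <- function(text, cls, seed = 1L) {
  cls <- match.arg(cls, CORRUPTION_CLASSES)
  lines <- split_lines(text)
  with_fixture_seed(seed, {
    res <- switch(cls,
      LEADING_BLANK_LINES = {
        k <- sample(1:3, 1L)
        list(lines = c(rep("", k), lines), expected = "LEADING_CONTENT")
      },
      MISSING_END = {
        hit <- grepl("^#\\s*END\\s*$", lines)
        if (!any(hit)) inapplicable(cls, "no '#END' line present")
        list(lines = lines[!hit], expected = "MISSING_END")
      },
      EMPTY_UNITS = {
        hit <- which(grepl("^[A-Z][A-Z0-9_]*:UNITS\\b", lines))
        if (!length(hit)) inapplicable(cls, "no units line present")
        i <- hit[[1]]
        lines[[i]] <- sub("^([A-Z][A-Z0-9_]*:UNITS).*$", "\\1", lines[[i]])
        list(lines = lines, expected = "EMPTY_UNITS")
      },
      DROP_REQUIRED_KEY = {
        req <- project_schema()$required
        present <- req[vapply(req, function(k) {
          any(grepl(paste0("^PR:", k, "\\b"), lines))
        }, TRUE)]
        if (!length(present)) inapplicable(cls, "no required PROJECT keys present")
        key <- sample(present, 1L)
        keep <- !grepl(paste0("^PR:", key, "\\b"), lines)
        list(lines = lines[keep], expected = "MISSING_REQUIRED_FIELD")
      },
      SSF_MALFORMED = {
        hit <- which(grepl("^SUBJECT_SAMPLE_FACTORS[ \t]", lines))
        if (!length(hit)) inapplicable(cls, "no sample-factor rows present")
        i <- if (length(hit) == 1L) hit else sample(hit, 1L)
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3L) inapplicable(cls, "sample-factor row too short")
        parts[[3]] <- ""          # blank the local sample id
        lines[[i]] <- paste(parts, collapse = "\t")
        list(lines = lines, expected = "SSF_MALFORMED")
      },
      ROW_ARITY = {
        rows <- data_row_indices(lines)
        if (!length(rows)) inapplicable(cls, "no table data rows present")
        i <- if (length(rows) == 1L) rows else sample(rows, 1L)
        if (!grepl("\t", lines[[i]], fixed = TRUE)) {
          inapplicable(cls, "data row has a single cell")
        }
        lines[[i]] <- sub("\t[^\t]*$", "", lines[[i]])
        list(lines = lines, expected = "ROW_ARITY")
      },
      UNITS_CASE_VARIANT = {
        hit <- which(grepl("^[A-Z][A-Z0-9_]*:UNITS[ \t]+\\S", lines))
        if (!length(hit)) inapplicable(cls, "no populated units line present")
        i <- hit[[1]]
        lines[[i]] <- toggle_first_alpha_case(lines[[i]])
        list(lines = lines, expected = character())
      }
    )
    list(text = paste0(paste(res$lines, collapse = "\n"), "\n"),
         expected = res$expected)
  })
}

inapplicable <- function(cls, why) {
  stop_mwtab("INAPPLICABLE",
             paste0("corruption class ", cls, " is inapplicable: ", why))
}

# indices of measured-value rows inside *_START/*_END fences, excluding
# the header row and an optional Factors row
data_row_indices <- function(lines) {
  starts <- grep("^[A-Z][A-Z0-9_]*_START$", lines)
  ends <- grep("^[A-Z][A-Z0-9_]*_END$", lines)
  out <- integer()
  for (s in starts) {
    e <- ends[ends > s]
    if (!length(e)) next
    e <- e[[1]]
    body <- seq(s + 1L, e - 1L)
    if (length(body) < 2L) next
    body <- body[-1L]                       # header row
    body <- body[!grepl("^Factors\t", lines[body])]
    out <- c(out, body)
  }
  out
}

toggle_first_alpha_case <- function(line) {
  value_at <- regexpr("(?<=[ \t])[^ \t].*$", line, perl = TRUE)
  value <- regmatches(line, value_at)
  pos <- regexpr("[A-Za-z]", value)
  if (pos == -1L) return(line)
  ch <- substring(value, pos, pos)
  flipped <- if (ch %in% letters) toupper(ch) else tolower(ch)
  substring(value, pos, pos) <- flipped
  regmatches(line, value_at) <- value
  line
}

#' Write a corpus of fixture files to a directory
#'
#' Convenience wrapper used by tests and the `fixtures` CLI subcommand:
#' writes `n` pristine mwTab fixture files (seeded `seed + i`, small
#' seeded sizes, alternating MS/NMR platforms) into `dir`.
#'
#' @param dir output directory (created if missing).
#' @param n number of files.
#' @param seed base seed.
#' @param corruption optional corruption class applied to every file
#'   (see [inject_corruption()]).
#' @return character vector of the written file paths (invisibly).
#' @export
write_fixture_corpus <- function(dir, n = 10L, seed = 1L, corruption = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n)
  for (i in seq_len(n)) {
    s <- seed + i
    sizes <- with_fixture_seed(s * 7L + 13L,
                               c(sample(3:8, 1L), sample(5:20, 1L)))
    spec <- fixture_spec(seed = s, n_samples = sizes[[1]],
                         n_metabolites = sizes[[2]],
                         platform = if (i %% 2L == 0L) "NMR" else "MS")
    text <- write_mwtab(generate_document(spec)$document)
    if (!is.null(corruption)) {
      text <- inject_corruption(text, corruption, seed = s)$text
    }
    paths[[i]] <- file.path(dir, sprintf("fixture_%03d.txt", i))
    writeLines(text, paths[[i]], sep = "")
  }
  invisible(paths)
}
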