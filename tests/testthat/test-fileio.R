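test_that("addresses resolve to the right source kinds", {
  specs <- resolve_source("AN000001")
  expect_length(specs, 1L)
  expect_equal(specs[[1]]$kind, "analysis_id")

  specs <- resolve_source("https://example.org/AN000001.txt")
  expect_equal(specs[[1]]$kind, "url")

  expect_error(resolve_source("AN12x"), class = "mwtab_unrecognized_address")
  expect_error(resolve_source(""), class = "mwtab_unrecognized_address")
  expect_error(resolve_source(file.path(tempdir(), "nope-not-here.txt")),
               class = "mwtab_not_found")
})

test_that("directories resolve to one spec per accepted file, sorted", {
  dir <- withr::local_tempdir()
  write_fixture_corpus(dir, n = 3, seed = 1)
  writeLines("not a fixture", file.path(dir, "notes.log"))
  specs <- suppressMessages(resolve_source(dir))
  expect_length(specs, 3L)
  expect_equal(basename(vapply(specs, function(s) s$address, "")),
               sprintf("fixture_%03d.txt", 1:3))
  expect_true(all(vapply(specs, function(s) s$kind, "") == "local_file"))
})

test_that("archives resolve to member specs whose documents equal the directory's", {
  dir <- withr::local_tempdir()
  write_fixture_corpus(dir, n = 3, seed = 21)
  ref <- read_all(read_files(dir))

  zipf <- file.path(withr::local_tempdir(), "corpus.zip")
  mwtabr:::pack_archive(dir, zipf, "zip")
  specs <- resolve_source(zipf)
  expect_length(specs, 3L)
  expect_true(all(vapply(specs, function(s) s$kind, "") == "archive_member"))
  expect_equal(vapply(specs, function(s) s$compression, ""), rep("zip", 3))
  docs <- read_all(read_files(zipf))
  expect_true(all(mapply(doc_equal, docs, ref)))

  bad <- file.path(tempdir(), "corpus.tar.xz")
  file.create(bad)
  expect_error(resolve_source(bad), class = "mwtab_unsupported_archive")
})

test_that("open_text returns the exact stored text from files and archives", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_corpus(dir, n = 2, seed = 33)
  original <- readChar(paths[[1]], file.size(paths[[1]]))
  spec <- resolve_source(paths[[1]])[[1]]
  expect_identical(open_text(spec), original)

  tbz <- file.path(withr::local_tempdir(), "corpus.tar.bz2")
  mwtabr:::pack_archive(dir, tbz, "bzip2-tar")
  member_spec <- resolve_source(tbz)[[1]]
  expect_identical(open_text(member_spec), original)
})

test_that("network sources fail fast when the configuration forbids them", {
  spec <- resolve_source("AN000001")[[1]]
  t0 <- Sys.time()
  expect_error(open_text(spec, fetch_config(network = FALSE)),
               class = "mwtab_network_disabled")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  # the id expands through the configurable REST template
  cfg <- fetch_config(network = FALSE, rest_template = "https://x.test/%s")
  expect_error(open_text(spec, cfg), "https://x.test/AN000001")
})

test_that("read_files yields documents lazily, one file text at a time", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_corpus(dir, n = 4, seed = 8)
  loads <- 0L
  counting_loader <- function(spec) {
    loads <<- loads + 1L
    readChar(spec$address, file.size(spec$address))
  }
  reader <- read_files(dir, config = fetch_config(text_loader = counting_loader))
  expect_equal(loads, 0L)    # resolution must not materialize any text
  d1 <- read_next(reader)
  expect_equal(loads, 1L)
  expect_s3_class(d1, "mwtab_document")
  rest <- read_all(reader)
  expect_equal(loads, 4L)
  expect_length(rest, 3L)
  expect_null(read_next(reader))
})

test_that("fatally corrupt members become error records, not stream failures", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_corpus(dir, n = 10, seed = 50)
  # two fatal corruptions: strip the file header line entirely
  for (p in paths[c(3, 7)]) {
    lines <- readLines(p)
    writeLines(lines[-1], p)
  }
  res <- read_all(read_files(dir))
  expect_length(res, 10L)
  is_err <- vapply(res, inherits, TRUE, "mwtab_error_record")
  expect_equal(sum(is_err), 2L)
  expect_equal(which(is_err), c(3L, 7L))
  expect_s3_class(res[[3]]$error, "mwtab_no_file_header")

  # fail_fast propagates the parse error instead
  expect_error(read_all(read_files(dir, config = fetch_config(fail_fast = TRUE))),
               class = "mwtab_no_file_header")
})

test_that("mwTab and JSON members are auto-detected by their first character", {
  dir <- withr::local_tempdir()
  fx <- fixture_text(seed = 14, n_samples = 3, n_metabolites = 4)
  writeLines(fx$text, file.path(dir, "a.txt"), sep = "")
  writeLines(write_json(fx$document), file.path(dir, "b.json"))
  docs <- read_all(read_files(dir))
  expect_length(docs, 2L)
  expect_true(doc_equal(docs[[1]], docs[[2]]))
})

test_that("identical content reads model-equal from all four source layouts", {
  dir <- withr::local_tempdir()
  write_fixture_corpus(dir, n = 3, seed = 64)
  ref <- read_all(read_files(dir))
  arch_dir <- withr::local_tempdir()
  for (arch in list(c("corpus.zip", "zip"),
                    c("corpus.tar.gz", "gzip-tar"),
                    c("corpus.tar.bz2", "bzip2-tar"))) {
    path <- file.path(arch_dir, arch[[1]])
    mwtabr:::pack_archive(dir, path, arch[[2]])
    docs <- read_all(read_files(path))
    expect_length(docs, length(ref))
    expect_true(all(mapply(doc_equal, docs, ref)), label = arch[[1]])
  }
})
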