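# Standoff and CoNLL I/O, span validation, category harmonization.

write_standoff_pair <- function(text, ann_lines, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  tp <- file.path(dir, "note.txt")
  ap <- file.path(dir, "note.ann")
  writeLines(text, tp)
  writeLines(ann_lines, ap)
  list(text = tp, ann = ap)
}

test_that("standoff reader parses valid annotations into a document", {
  p <- write_standoff_pair("Seen 01/02/2014.", "T1\tDATE 5 15\t01/02/2014")
  doc <- read_standoff(p$text, p$ann)
  expect_s3_class(doc, "deid_corpus")
  sp <- doc$spans[[1]]
  expect_equal(nrow(sp), 1)
  expect_equal(sp$start, 5L)
  expect_equal(sp$end, 15L)
  expect_equal(sp$category, "DATE")
  expect_equal(sp$surface, "01/02/2014")
})

test_that("standoff reader rejects invalid annotations", {
  p <- write_standoff_pair("Seen 01/02/2014.", "T1\tDATE 5 99\t01/02/2014")
  expect_error(read_standoff(p$text, p$ann), "out of range")

  p <- write_standoff_pair("abcdef", c("T1\tNAME 0 4\tabcd",
                                       "T2\tNAME 2 6\tcdef"))
  expect_error(read_standoff(p$text, p$ann), "overlap")

  p <- write_standoff_pair("Seen 01/02/2014.", "T1\tDATE 5 15\tWRONG")
  expect_error(read_standoff(p$text, p$ann), "surface mismatch")

  p <- write_standoff_pair("abcdef", "T1 NAME 0 4 abcd")  # no tabs
  expect_error(read_standoff(p$text, p$ann), "expected")
})

test_that("category harmonization merges and excludes as specified", {
  expect_equal(harmonize_category("FAX"), "PHONE")
  expect_equal(harmonize_category(c("EMAIL", "URL")), c("WEB", "WEB"))
  expect_equal(harmonize_category(c("HOSPITAL", "ORGANIZATION")),
               c("INSTITUTE", "INSTITUTE"))
  expect_equal(
    harmonize_category(c("DAY-OF-WEEK", "SEASON", "HOLIDAY", "STATE",
                         "COUNTRY")),
    rep("DROP", 5))
  # idempotent over its whole range
  src <- c("FAX", "EMAIL", "HOSPITAL", "SEASON", phi_categories())
  once <- harmonize_category(src)
  expect_equal(harmonize_category(once), once)
  expect_true(all(setdiff(once, "DROP") %in% phi_categories()))
  expect_error(harmonize_category("NOT_A_LABEL"), "admissible")
})

test_that("standoff round-trip is lossless on a generated corpus", {
  corp <- generate_corpus(generator_config(20, seed = 5),
                          style_profile("site_A"))
  dir <- withr::local_tempdir()
  write_standoff(corp, dir)
  back <- read_standoff_dir(dir)
  expect_equal(back$doc_id, corp$doc_id)
  expect_equal(back$text, corp$text)
  for (i in seq_len(nrow(corp)))
    expect_equal(as.data.frame(back$spans[[i]]),
                 as.data.frame(corp$spans[[i]]))
})

test_that("CoNLL round-trip reproduces labeled sequences exactly", {
  corp <- generate_corpus(generator_config(50, seed = 9),
                          style_profile("site_B"))
  tagged <- label_corpus(corp)
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(tagged, path)
  back <- read_conll(path)
  expect_equal(as.data.frame(back), as.data.frame(tagged[names(back)]),
               ignore_attr = TRUE)
})

test_that("CoNLL reader repairs orphan I- tags and flags bad columns", {
  path <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("# doc_id = d1", "He\t0\t2\tO", "Smith\t3\t8\tI-NAME", ""),
             path)
  expect_warning(back <- read_conll(path), "orphan")
  expect_equal(back$tag, c("O", "B-NAME"))

  writeLines(c("bad\tline"), path)
  expect_error(read_conll(path), "4 tab-separated columns")
})

test_that("empty corpus writes an empty CoNLL file", {
  path <- withr::local_tempfile(fileext = ".conll")
  empty <- tibble::tibble(doc_id = character(), sentence_id = integer(),
                          token = character(), start = integer(),
                          end = integer(), tag = character())
  write_conll(empty, path)
  expect_equal(nrow(read_conll(path)), 0)
})

test_that("corpus merging preserves counts and resolves id collisions", {
  mk <- function(n, prefix) deid_corpus(paste0(prefix, seq_len(n)),
                                        rep("note text", n))
  a <- mk(997, "a"); b <- mk(233, "b")
  expect_equal(nrow(merge_corpora(a, b)), 1230)
  expect_equal(merge_corpora(a, a[0, ])$doc_id, a$doc_id)
  clash <- merge_corpora(mk(3, "a"), mk(2, "a"))
  expect_equal(nrow(clash), 5)
  expect_false(anyDuplicated(clash$doc_id) > 0)
})
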