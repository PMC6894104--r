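# Word shape, part-of-speech, edit distance and fuzzy gazetteer lookup.

test_that("word shape maps character classes and collapses runs", {
  expect_equal(word_shape("Smith"), "Aaaaa|Aa")
  expect_equal(word_shape("32610"), "00000|0")
  expect_equal(word_shape("H&P"), "A&A|A&A")
  expect_equal(word_shape(c("McDonald", "x1")), c("AaAaaaaa|AaAa", "a0|a0"))
  expect_error(word_shape(""), "empty")
})

test_that("part-of-speech tagging is deterministic with full coverage", {
  expect_equal(pos_tag(c("the", "patient")), c("DT", "NN"))
  expect_equal(pos_tag(character(0)), character(0))
  expect_equal(pos_tag(c("Smith", "walked", "quickly", "321", ".")),
               c("NNP", "VBD", "RB", "CD", "."))
  # length preservation and tagset closure on random token soups
  set.seed(7)
  pool <- c(letters, "the", "on", "Smith", "walking", "123", "/", "-", "A1c")
  for (i in 1:50) {
    toks <- sample(pool, sample(1:25, 1), replace = TRUE)
    tags <- pos_tag(toks)
    expect_length(tags, length(toks))
    expect_true(all(tags %in% deidtag:::pos_tagset()))
    expect_identical(tags, pos_tag(toks))
  }
})

test_that("Damerau-Levenshtein distance matches the recursive definition", {
  expect_equal(damerau_levenshtein("gainesville", "gainesvile"), 1)
  expect_equal(damerau_levenshtein("ab", "ba"), 1)  # transposition
  expect_equal(damerau_levenshtein("", "abc"), 3)
  set.seed(21)
  for (i in 1:80) {
    a <- paste(sample(c("a", "b", "c"), sample(0:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("a", "b", "c"), sample(0:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(damerau_levenshtein(a, b), brute_dl(a, b))
  }
})

test_that("fuzzy lookup distinguishes exact, partial and missing matches", {
  city <- dictionary("cities", "CITY", c("gainesville", "lake butler"))
  res <- fuzzy_lookup(c("Gainesville"), list(city))
  expect_equal(unlist(res), c(kb_category = "CITY", kb_boundary = "B",
                              kb_condition = "EXACT"))
  # one edit away (verified against the brute-force distance)
  expect_equal(brute_dl("gainesvile", "gainesville"), 1)
  res <- fuzzy_lookup(c("Gainesvile"), list(city))
  expect_equal(res$kb_condition, "PARTIAL")
  expect_equal(res$kb_category, "CITY")
  res <- fuzzy_lookup(c("aspirin"), list(city))
  expect_equal(unlist(res), c(kb_category = "NONE", kb_boundary = "O",
                              kb_condition = "NONE"))
})

test_that("multi-word entries get B/I boundaries and prefix partials", {
  inst <- dictionary("inst", "INSTITUTE",
                     "north lake medical center", priority = 2L)
  res <- fuzzy_lookup(c("seen", "at", "North", "Lake", "Medical", "Center"),
                      list(inst))
  expect_equal(res$kb_boundary, c("O", "O", "B", "I", "I", "I"))
  expect_equal(res$kb_condition[3:6], rep("EXACT", 4))
  # a strict prefix covering at least half the words is a PARTIAL match
  res <- fuzzy_lookup(c("North", "Lake", "closed"), list(inst))
  expect_equal(res$kb_boundary, c("B", "I", "O"))
  expect_equal(res$kb_condition[1:2], rep("PARTIAL", 2))
  # under half the words is no match
  res <- fuzzy_lookup(c("North", "closed"), list(inst))
  expect_equal(res$kb_boundary, c("O", "O"))
})

test_that("digit-only dictionaries never match fuzzily", {
  zips <- dictionary("zips", "ZIP", c("32601", "32603"), fuzzy = FALSE)
  expect_equal(fuzzy_lookup("32601", list(zips))$kb_condition, "EXACT")
  expect_equal(fuzzy_lookup("32602", list(zips))$kb_condition, "NONE")
})

test_that("lookup invariants: length, BIO grammar, casing, graceful empty", {
  dicts <- builtin_dictionaries(style_profile("site_A"))
  set.seed(3)
  vocabpool <- c(style_profile("site_A")$vocab$cities, "the", "seen", "at",
                 "Lakewod", "Springs", "aspirin")
  words <- unlist(strsplit(vocabpool, " "))
  for (i in 1:25) {
    toks <- sample(words, sample(1:12, 1), replace = TRUE)
    res <- fuzzy_lookup(toks, dicts)
    expect_equal(nrow(res), length(toks))
    # boundary stream is grammar-valid: I only after B/I
    prev <- c("O", res$kb_boundary[-length(toks)])
    expect_false(any(res$kb_boundary == "I" & prev == "O"))
    # the three streams agree on whether a token is inside a match
    expect_equal(res$kb_category == "NONE", res$kb_boundary == "O")
    expect_equal(res$kb_category == "NONE", res$kb_condition == "NONE")
    # exact matches are invariant to casing
    res_up <- fuzzy_lookup(toupper(toks), dicts)
    expect_equal(res$kb_condition == "EXACT", res_up$kb_condition == "EXACT")
  }
  expect_warning(res <- fuzzy_lookup(c("Gainesville"), list()), "NONE")
  expect_equal(res$kb_category, "NONE")
})

test_that("priority rank breaks ties between equal-length matches", {
  d1 <- dictionary("city", "CITY", "springfield", priority = 2L)
  d2 <- dictionary("name", "NAME", "springfield", priority = 1L)
  res <- fuzzy_lookup("Springfield", list(d1, d2))
  expect_equal(res$kb_category, "NAME")
  # longer matches beat priority
  d3 <- dictionary("inst", "INSTITUTE", "springfield general", priority = 5L)
  res <- fuzzy_lookup(c("Springfield", "General"), list(d1, d2, d3))
  expect_equal(res$kb_category, c("INSTITUTE", "INSTITUTE"))
})
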