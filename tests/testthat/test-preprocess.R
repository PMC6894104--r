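# Typo repair with offset provenance, sentence splitting, tokenization,
# span <-> BIO conversion.

test_that("run-together words split at lexicon-gated case transitions", {
  r <- correct_typos("gave prnInsulin today", lexicon = c("prn", "insulin"))
  expect_equal(r$text, "gave prn Insulin today")
  expect_equal(correct_typos("aspirin 81mg", lexicon = c("aspirin"))$text,
               "aspirin 81mg")
  # no gate word in the lexicon -> untouched
  expect_equal(correct_typos("McDonald", lexicon = c("prn"))$text, "McDonald")
  # flanking run of length 1 never splits
  expect_equal(correct_typos("aBig day", lexicon = c("big"))$text, "aBig day")
})

test_that("offset maps project annotations between coordinate systems", {
  orig <- "gave prnInsulin today"
  r <- correct_typos(orig, lexicon = c("insulin"))
  # "Insulin" sits at 9..16 in corrected, 8..15 in original
  proj <- project_offsets(r$map, 9L, 16L, from = "corrected")
  expect_equal(substr0(orig, proj$start, proj$end), "Insulin")
  # and back: an original span over "Insulin" lands after the inserted space
  back <- project_offsets(r$map, proj$start, proj$end, from = "original")
  expect_equal(back$start, 9L)
  expect_equal(back$end, 16L)
  # boundaries are monotone and total
  expect_true(all(diff(r$map$boundaries) >= 0))
  expect_equal(length(r$map$boundaries), nchar(r$text) + 1L)
})

test_that("sentence spans tile the non-whitespace text", {
  s <- split_sentences("He is well. RTC 2 wks.")
  expect_equal(nrow(s), 2)
  expect_equal(nrow(split_sentences("")), 0)
  note <- paste(sprintf("Line %d is here.", 1:20), collapse = "\n")
  s20 <- split_sentences(note)
  expect_equal(nrow(s20), 20)
  # every non-whitespace char is inside exactly one span
  covered <- unlist(purrr::map2(s20$start, s20$end, seq))
  nonws <- which(strsplit(note, "")[[1]] != " " &
                   strsplit(note, "")[[1]] != "\n") - 1L
  expect_true(all(nonws %in% (covered - 1L)))
})

test_that("tokenizer splits into letter runs, digit runs, single marks", {
  expect_equal(tokenize("01/02/2014")$token, c("01", "/", "02", "/", "2014"))
  expect_equal(tokenize("(352)265-1234")$token,
               c("(", "352", ")", "265", "-", "1234"))
  # offsets always slice back to the surface, whitespace reconstructs
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, "(", ")", "/", "-", ".", " ", " ")
  for (i in 1:200) {
    txt <- paste(sample(alphabet, sample(1:40, 1), replace = TRUE),
                 collapse = "")
    tok <- tokenize(txt)
    if (nrow(tok) == 0) next
    expect_equal(substr0(txt, tok$start, tok$end), tok$token)
    expect_equal(paste(tok$token, collapse = ""), gsub(" ", "", txt))
  }
})

test_that("spans convert to BIO tags with whole-token boundary snapping", {
  tokens <- tibble::tibble(doc_id = "d", sentence_id = 1L,
                           token = c("John", "Smith", ","),
                           start = c(0L, 5L, 10L), end = c(4L, 10L, 11L))
  spans <- tibble::tibble(doc_id = "d", start = 0L, end = 10L,
                          category = "NAME")
  tagged <- spans_to_bio(tokens, spans)
  expect_equal(tagged$tag, c("B-NAME", "I-NAME", "O"))
  expect_equal(spans_to_bio(tokens, spans[0, ])$tag, rep("O", 3))
  # partial overlap labels the whole token (over-masking, never under)
  snapped <- spans_to_bio(tokens, dplyr::mutate(spans, start = 2L, end = 7L))
  expect_equal(snapped$tag, c("B-NAME", "I-NAME", "O"))
  expect_equal(attr(snapped, "snapped"), 1L)
  # a span over no token is dropped with a warning
  expect_warning(
    dropped <- spans_to_bio(tokens, dplyr::mutate(spans, start = 4L, end = 5L)),
    "dropped")
  expect_equal(attr(dropped, "dropped"), 1L)
})

test_that("BIO runs convert back to spans, repairing orphan I- tags", {
  tokens <- tibble::tibble(doc_id = "d", sentence_id = 1L,
                           token = c("01", "/", "02", "done"),
                           start = c(0L, 2L, 3L, 6L), end = c(2L, 3L, 5L, 10L),
                           tag = c("B-DATE", "I-DATE", "I-DATE", "O"))
  sp <- bio_to_spans(tokens)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$start, 0L); expect_equal(sp$end, 5L)
  expect_equal(sp$category, "DATE")
  tokens$tag <- "O"
  expect_equal(nrow(bio_to_spans(tokens)), 0)
  tokens$tag <- c("O", "I-NAME", "O", "O")
  expect_warning(sp2 <- bio_to_spans(tokens), "orphan")
  expect_equal(sp2$category, "NAME")
})

test_that("span -> BIO -> span round-trips on generated documents", {
  corp <- generate_corpus(generator_config(40, seed = 13),
                          style_profile("site_A"))
  tagged <- label_corpus(corp)
  back <- bio_to_spans(tagged, corp)
  gold <- tidyr::unnest(corp[, c("doc_id", "spans")], "spans")
  gold <- dplyr::arrange(gold, doc_id, start)
  expect_equal(as.data.frame(back), as.data.frame(gold))
})

test_that("token offsets survive typo injection through the offset map", {
  corp <- generate_corpus(generator_config(30, seed = 77, typo_rate = 0.3),
                          style_profile("site_A"))
  toks <- preprocess_corpus(corp)
  # every token's original-text slice equals its surface: inserted spaces
  # never land inside a token
  text <- stats::setNames(corp$text, corp$doc_id)
  expect_equal(substr0(text[toks$doc_id], toks$start, toks$end), toks$token,
               ignore_attr = TRUE)
})
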