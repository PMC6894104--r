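# Synthetic surrogate-note generator and its two institution styles.

test_that("generation is byte-identical for a fixed seed and style", {
  cfg <- generator_config(8, seed = 99)
  a1 <- generate_corpus(cfg, style_profile("site_A"))
  a2 <- generate_corpus(cfg, style_profile("site_A"))
  expect_identical(a1$text, a2$text)
  expect_identical(a1$spans, a2$spans)
  b <- generate_corpus(cfg, style_profile("site_B"))
  expect_false(identical(a1$text, b$text))
})

test_that("category weights drive the span distribution", {
  only_date <- generate_corpus(
    generator_config(15, seed = 3,
                     category_weights = c(DATE = 1)),
    style_profile("site_A"))
  sp <- dplyr::bind_rows(only_date$spans)
  expect_gt(nrow(sp), 0)
  expect_true(all(sp$category == "DATE"))
})

test_that("default category proportions track the reference counts", {
  corp <- generate_corpus(generator_config(500, seed = 7),
                          style_profile("site_A"))
  sp <- dplyr::bind_rows(corp$spans)
  counts <- table(factor(sp$category, levels = phi_categories()))
  ref <- phi_category_counts()
  w <- ref$uf_training + ref$uf_validation + ref$uf_test
  p <- stats::setNames(w / sum(w), ref$category)[names(counts)]
  n <- sum(counts)
  # exact multinomial band: |count - np| <= 3 sqrt(np(1-p))
  dev <- abs(as.vector(counts) - n * p)
  band <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(dev <= pmax(band, 3)))
  expect_gt(n / nrow(corp), 4)  # PHI-dense enough to train on
})

test_that("the two styles share no formats and almost no vocabulary", {
  a <- style_profile("site_A"); b <- style_profile("site_B")
  expect_length(intersect(a$date_formats, b$date_formats), 0)
  expect_length(intersect(a$phone_formats, b$phone_formats), 0)
  expect_length(intersect(a$id_formats, b$id_formats), 0)
  va <- unlist(a$vocab); vb <- unlist(b$vocab)
  overlap <- length(intersect(tolower(va), tolower(vb))) /
    min(length(va), length(vb))
  expect_lte(overlap, 0.2)
})

test_that("generated corpora survive the pipeline cleanly at typo rate 0", {
  corp <- generate_corpus(generator_config(25, seed = 55),
                          style_profile("site_B"))
  expect_no_warning(tagged <- label_corpus(corp))
  expect_equal(attr(tagged, "dropped"), 0L)
  expect_equal(attr(tagged, "snapped"), 0L)
  expect_no_warning(token_features(tagged, builtin_dictionaries(
    style_profile("site_B"))))
  # gold spans align exactly to token boundaries
  back <- bio_to_spans(tagged, corp)
  expect_equal(nrow(back), sum(vapply(corp$spans, nrow, 1L)))
})

test_that("typo injection deletes spaces but keeps annotations exact", {
  text <- "Seen with John Smith at the clinic on 03/17/2015 today."
  spans <- tibble::tibble(start = c(10L, 38L), end = c(20L, 48L),
                          category = c("NAME", "DATE"),
                          surface = c("John Smith", "03/17/2015"))
  set.seed(1)
  r <- deidtag:::inject_typos(text, spans, rate = 1)
  # every eligible space goes; spaces inside the NAME span are protected
  expect_lt(nchar(r$text), nchar(text))
  expect_equal(substr0(r$text, r$spans$start, r$spans$end), r$spans$surface)
  expect_true(grepl("John Smith", r$text, fixed = TRUE))
  # at rate 0 nothing changes
  r0 <- deidtag:::inject_typos(text, spans, rate = 0)
  expect_identical(r0$text, text)
  expect_identical(r0$spans, spans)
  # a generated corpus with typos still validates and is PHI-complete
  typod <- generate_corpus(generator_config(15, seed = 8, typo_rate = 0.4),
                           style_profile("site_A"))
  expect_gt(sum(vapply(typod$spans, nrow, 1L)), 0)
})

test_that("planted prediction errors are recovered exactly", {
  corp <- generate_corpus(generator_config(20, seed = 6),
                          style_profile("site_A"))
  gold <- tidyr::unnest(corp[, c("doc_id", "spans")], "spans")
  # all-zero spec reproduces the gold spans
  same <- plant_prediction_errors(corp, list(), seed = 1)
  expect_equal(nrow(same), nrow(gold))
  expect_equal(sum(unlist(classify_errors(gold, same))), 0L)
  # removing three spans plants exactly three false negatives
  fn3 <- plant_prediction_errors(corp, list(false_negative = 3), seed = 2)
  expect_equal(nrow(fn3), nrow(gold) - 3)
  expect_equal(classify_errors(gold, fn3)$false_negative, 3L)
  # an infeasible request errors out
  expect_error(
    plant_prediction_errors(corp, list(false_negative = nrow(gold) + 1)),
    "needs")
})
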