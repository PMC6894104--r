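# Strict/relaxed matching, precision/recall/F1, error taxonomy.

span_tbl <- function(start, end, category, doc_id = "d1") {
  tibble::tibble(doc_id = doc_id, start = as.integer(start),
                 end = as.integer(end), category = category)
}

micro_of <- function(counts) {
  prf <- compute_prf(counts)
  prf[prf$category == "micro", ]
}

test_that("strict matching requires identical offsets and category", {
  gold <- span_tbl(0, 10, "NAME")
  expect_equal(sum(match_spans(gold, gold, "strict")$tp), 1)
  pred <- span_tbl(0, 8, "NAME")
  cs <- match_spans(gold, pred, "strict")
  expect_equal(sum(cs$tp), 0)
  expect_equal(sum(cs$fp), 1)
  expect_equal(sum(cs$fn), 1)
  cr <- match_spans(gold, pred, "relax")
  expect_equal(sum(cr$tp), 1)
  # same offsets, different category: no credit in either mode
  pred2 <- span_tbl(0, 10, "DATE")
  expect_equal(sum(match_spans(gold, pred2, "relax")$tp), 0)
  expect_error(match_spans(dplyr::bind_rows(gold, span_tbl(5, 15, "NAME")),
                           pred, "strict"), "overlapping")
})

test_that("relaxed counts equal the optimal one-to-one matching", {
  set.seed(31)
  for (r in 1:60) {
    gold <- random_span_list(40, 5)
    pred <- random_span_list(40, 5)
    gold$doc_id <- pred$doc_id <- "d1"
    counts <- match_spans(gold, pred, "relax")
    # brute-force optimum per category
    expected_tp <- 0L
    for (cat in unique(c(gold$category, pred$category))) {
      g <- gold[gold$category == cat, ]; p <- pred[pred$category == cat, ]
      if (nrow(g) == 0 || nrow(p) == 0) next
      adj <- lapply(seq_len(nrow(g)), function(i)
        which(pmin(g$end[i], p$end) - pmax(g$start[i], p$start) > 0))
      expected_tp <- expected_tp + brute_matching(adj, nrow(p))
    }
    expect_equal(sum(counts$tp), expected_tp)
    expect_equal(sum(counts$tp) + sum(counts$fn), nrow(gold))
    expect_equal(sum(counts$tp) + sum(counts$fp), nrow(pred))
    # relax dominates strict on the same predictions
    expect_gte(sum(counts$tp), sum(match_spans(gold, pred, "strict")$tp))
  }
})

test_that("precision/recall/F1 use the 0/0 -> 0 convention and pool micro", {
  z <- compute_prf(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  counts <- tibble::tibble(category = c("DATE", "NAME"),
                           tp = c(8L, 2L), fp = c(2L, 3L), fn = c(1L, 2L))
  prf <- compute_prf(counts)
  m <- prf[prf$category == "micro", ]
  expect_equal(m$precision, 10 / 15)
  expect_equal(m$recall, 10 / 13)
  # micro pooling is invariant to splitting the corpus before pooling
  half1 <- dplyr::mutate(counts, tp = c(5L, 1L), fp = c(1L, 2L),
                         fn = c(0L, 1L))
  half2 <- dplyr::mutate(counts, tp = tp - half1$tp, fp = fp - half1$fp,
                         fn = fn - half1$fn)
  pooled <- dplyr::bind_rows(half1, half2) |>
    dplyr::group_by(category) |>
    dplyr::summarise(tp = sum(tp), fp = sum(fp), fn = sum(fn))
  expect_equal(micro_of(pooled)$f1, m$f1)
})

test_that("F1 reproduces published operating points to four decimals", {
  ops <- benchmark_operating_points()
  expect_equal(nrow(ops), 42)
  expect_true(all(abs(f1_score(ops$precision, ops$recall) - ops$f1) <= 1e-4))
})

test_that("error taxonomy assigns each span exactly one class", {
  gold <- dplyr::bind_rows(span_tbl(0, 11, "NAME"),    # "Xxx Yyy Jr."
                           span_tbl(20, 27, "ID"),
                           span_tbl(40, 45, "DATE"))
  pred <- dplyr::bind_rows(span_tbl(0, 7, "NAME"),     # suffix missed
                           span_tbl(20, 27, "PHONE"),  # ID read as PHONE
                           span_tbl(60, 63, "DATE"))   # spurious "1/2"
  tx <- classify_errors(gold, pred)
  expect_equal(tx$boundary_mismatch, 1L)
  expect_equal(tx$wrong_category, 1L)
  expect_equal(tx$false_positive, 1L)
  expect_equal(tx$false_negative, 1L)
  # perfect predictions: no errors at all
  tx0 <- classify_errors(gold, gold)
  expect_equal(sum(unlist(tx0)), 0L)
})

test_that("corpus evaluation pools documents and validates alignment", {
  corp <- generate_corpus(generator_config(10, seed = 41),
                          style_profile("site_A"))
  gold <- tidyr::unnest(corp[, c("doc_id", "spans")], "spans")
  ev <- evaluate_corpus(corp, gold)
  expect_s3_class(ev, "deid_eval")
  expect_equal(ev$strict$f1[ev$strict$category == "micro"], 1)
  expect_equal(ev$relax$f1[ev$relax$category == "micro"], 1)
  expect_equal(sum(unlist(ev$taxonomy)), 0L)
  # empty predictions: zero precision/recall, all gold spans missed
  ev0 <- evaluate_corpus(corp, gold[0, ])
  m <- ev0$strict[ev0$strict$category == "micro", ]
  expect_equal(c(m$precision, m$recall, m$f1), c(0, 0, 0))
  expect_equal(m$fn, nrow(gold))
  expect_equal(ev0$taxonomy$false_negative, nrow(gold))
  # relax micro F1 never drops below strict on the same predictions
  planted <- plant_prediction_errors(corp, list(boundary_mismatch = 5),
                                     seed = 2)
  ev2 <- evaluate_corpus(corp, planted)
  expect_gte(ev2$relax$f1[ev2$relax$category == "micro"],
             ev2$strict$f1[ev2$strict$category == "micro"])
  expect_error(
    evaluate_corpus(corp, dplyr::mutate(gold, doc_id = "nope")),
    "unknown doc_id")
})

test_that("evaluation results tidy, glance, plot and serialize", {
  corp <- generate_corpus(generator_config(6, seed = 43),
                          style_profile("site_A"))
  pred <- plant_prediction_errors(corp, list(false_negative = 2), seed = 1)
  ev <- evaluate_corpus(corp, pred)
  td <- tidy(ev)
  expect_true(all(c("strict", "relax") %in% td$mode))
  g <- glance(ev)
  expect_equal(g$false_negative, 2L)
  expect_true(all(unlist(g[, c("strict_f1", "relax_f1")]) <= 1))
  expect_s3_class(autoplot(ev), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$taxonomy$false_negative, 2L)
})
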