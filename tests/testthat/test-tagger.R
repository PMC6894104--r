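# CRF layer, input encoding, training regimes, checkpoints, prediction.

test_that("CRF log-likelihood matches closed forms and enumeration", {
  # uniform scores over 3 tags, T = 1: every path equally likely
  em <- matrix(0, 1, 3); tr <- matrix(0, 5, 5)
  expect_equal(crf_log_likelihood(em, tr, 1L), log(1 / 3))
  set.seed(14)
  for (r in 1:40) {
    T <- sample(1:4, 1); K <- sample(2:5, 1)
    em <- matrix(rnorm(T * K), T, K)
    tr <- matrix(rnorm((K + 2)^2), K + 2, K + 2)
    tags <- sample(seq_len(K), T, replace = TRUE)
    b <- brute_crf(em, tr, tags)
    ll <- crf_log_likelihood(em, tr, tags)
    expect_equal(ll, b$ll, tolerance = 1e-9)
    expect_lte(ll, 1e-12)
    expect_true(exp(ll) > 0 && exp(ll) <= 1 + 1e-12)
  }
  expect_error(crf_log_likelihood(matrix(0, 2, 3), matrix(0, 5, 5),
                                  c(1L, 9L)), "out of range")
})

test_that("Viterbi decoding matches enumeration and breaks ties low", {
  # dominant per-position emissions with neutral transitions
  em <- rbind(c(9, 0, 0), c(0, 9, 0), c(0, 0, 9))
  v <- viterbi_decode(em, matrix(0, 5, 5))
  expect_equal(v$path, c(1L, 2L, 3L))
  # an exact two-path tie resolves to the lexicographically smaller path
  em <- matrix(0, 2, 3)
  v <- viterbi_decode(em, matrix(0, 5, 5))
  expect_equal(v$path, c(1L, 1L))
  expect_equal(viterbi_decode(matrix(0, 0, 3), matrix(0, 5, 5))$path,
               integer(0))
  set.seed(15)
  for (r in 1:40) {
    T <- sample(1:4, 1); K <- sample(2:5, 1)
    em <- matrix(rnorm(T * K), T, K)
    tr <- matrix(rnorm((K + 2)^2), K + 2, K + 2)
    b <- brute_crf(em, tr)
    v <- viterbi_decode(em, tr)
    expect_equal(v$path, b$best_path)
    expect_equal(v$score, b$best_score, tolerance = 1e-9)
  }
})

test_that("input width follows the configured embedding dimensions", {
  hp <- hyperparams()
  expect_equal(input_width(hp), 400L)           # word 300 + char 50 + 20+15+15
  expect_equal(input_width(hp, 0, 0), 350L)     # features disabled
  expect_equal(input_width(small_hp(), 1, 2), 25L + 16L + 8L + 12L)
})

test_that("hyperparameter defaults carry the published configuration", {
  hp <- hyperparams()
  expect_equal(hp$word_dim, 300L)
  expect_equal(hp$char_dim, 25L)
  expect_equal(hp$char_lstm_out, 25L)
  expect_equal(hp$word_lstm_out, 100L)
  expect_equal(hp$semantic_feat_dim, 20L)
  expect_equal(hp$lexical_feat_dim, 15L)
  expect_equal(hp$lr, 0.005)
  expect_equal(hp$momentum, 0.9)
  expect_equal(hp$dropout, 0.5)
  expect_equal(hp$grad_clip, c(-5, 5))
  expect_equal(hp$epochs_scratch, 30L)
  expect_equal(hp$epochs_finetune, 15L)
  expect_error(hyperparams(bogus = 1), "unknown hyperparameter")
})

one_sentence_corpus <- function(n = 10) {
  deid_corpus(
    paste0("d", seq_len(n)),
    rep("Seen in clinic on 03/17/2015 for follow up.", n),
    rep(list(tibble::tibble(start = 18L, end = 28L, category = "DATE")), n))
}

test_that("training is deterministic and epochs = 0 keeps initialization", {
  corp <- one_sentence_corpus(3)
  hp <- small_hp()
  m1 <- train_tagger(corp, hp = hp, epochs = 2, seed = 5)
  m2 <- train_tagger(corp, hp = hp, epochs = 2, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- train_tagger(corp, hp = hp, epochs = 2, seed = 6)
  expect_false(identical(m3$params, m1$params))
  m0a <- train_tagger(corp, hp = hp, epochs = 0, seed = 5)
  m0b <- train_tagger(corp, hp = hp, epochs = 0, seed = 5)
  expect_identical(m0a$params, m0b$params)
  expect_length(m0a$loss, 0)
})

test_that("a model overfits one repeated sentence and recovers its gold", {
  corp <- one_sentence_corpus(10)
  m <- train_tagger(corp, hp = small_hp(), epochs = 15, seed = 3)
  expect_true(all(diff(m$loss[1:5]) < 0))
  pred <- predict(m, subset_corpus(corp, 1))
  expect_equal(nrow(pred), 1)
  expect_equal(pred$start, 18L)
  expect_equal(pred$end, 28L)
  expect_equal(pred$category, "DATE")
  # prediction is pure
  expect_identical(pred, predict(m, subset_corpus(corp, 1)))
})

test_that("checkpoints reload to bit-identical weights and predictions", {
  corp <- one_sentence_corpus(5)
  m <- train_tagger(corp, hp = small_hp(), epochs = 3, seed = 8,
                    dictionaries = builtin_dictionaries())
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  expect_true(file.exists(file.path(dir, "weights.rds")))
  expect_true(file.exists(file.path(dir, "model.json")))
  m2 <- load_checkpoint(dir)
  expect_identical(m$params, m2$params)
  expect_identical(m$vocab$word, m2$vocab$word)
  expect_identical(predict(m, corp), predict(m2, corp))
})

test_that("fine-tuning continues from base weights with chained provenance", {
  corp <- one_sentence_corpus(5)
  base <- train_tagger(corp, hp = small_hp(), epochs = 3, seed = 8)
  # zero fine-tune epochs: predictions identical to the base model
  ft0 <- fine_tune(base, corp, epochs = 0)
  expect_identical(suppressWarnings(predict(ft0, corp)),
                   suppressWarnings(predict(base, corp)))
  # new words in the target corpus get fresh rows, old rows are reused
  corp2 <- deid_corpus("new1", "Reviewed with Quixotic Zephyrmont today.",
                       list(tibble::tibble(start = 14L, end = 33L,
                                           category = "NAME")))
  ft <- fine_tune(base, corp2, epochs = 2)
  expect_gt(length(ft$vocab$word), length(base$vocab$word))
  expect_equal(ft$provenance$regime, "fine_tune")
  expect_length(ft$provenance$corpora, 2)
  # the base model is untouched by fine-tuning
  expect_identical(suppressWarnings(predict(base, corp)),
                   suppressWarnings(predict(ft0, corp)))
})

test_that("label-set compatibility is enforced for fine-tuning", {
  corp <- one_sentence_corpus(3)
  base <- train_tagger(corp, hp = small_hp(), epochs = 1, seed = 8)
  broken <- base
  broken$vocab$tag <- c(broken$vocab$tag, "B-EXTRA")
  expect_error(fine_tune(broken, corp, epochs = 1), "label-set mismatch")
})

test_that("degenerate inputs are rejected or return empty predictions", {
  expect_error(train_tagger(one_sentence_corpus(1)[0, ]), "empty")
  m <- train_tagger(one_sentence_corpus(3), hp = small_hp(), epochs = 1,
                    seed = 1)
  empty <- deid_corpus("e1", "")
  expect_equal(nrow(predict(m, empty)), 0)
})

test_that("the model trains with the feature layer disabled (ablation)", {
  corp <- one_sentence_corpus(6)
  m <- train_tagger(corp, hp = small_hp(), epochs = 10, features = FALSE,
                    seed = 4)
  expect_equal(m$config$input_width, 25L + 16L)
  expect_length(m$vocab$feat, 0)
  pred <- predict(m, subset_corpus(corp, 1))
  expect_equal(pred$category, "DATE")
})

test_that("unseen tokens and feature values map to reserved indices", {
  corp <- one_sentence_corpus(3)
  m <- train_tagger(corp, hp = small_hp(), epochs = 1, seed = 2)
  toks <- token_features(preprocess_corpus(
    deid_corpus("x", "Zzzqq glorp 03/17/2015.")))
  enc <- deidtag:::encode_sentences(toks, m$vocab, m$config$streams,
                                    with_tags = FALSE)
  unk_word <- match("UNKNOWN", m$vocab$word)
  expect_equal(enc[[1]]$word_ids[1], unk_word)
  # the unseen shape value maps to the <UNK> feature slot (index 1)
  shape_stream <- which(names(m$vocab$feat) == "shape")
  expect_true(1L %in% enc[[1]]$feat_ids[, shape_stream])
})

test_that("tidy and glance expose transitions and training summary", {
  m <- train_tagger(one_sentence_corpus(3), hp = small_hp(), epochs = 2,
                    seed = 2)
  td <- tidy(m)
  expect_equal(nrow(td), (21 + 2)^2)
  expect_true(all(c("from", "to", "score") %in% names(td)))
  g <- glance(m)
  expect_equal(g$epochs, 2L)
  expect_equal(g$n_tags, 21L)
})
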