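# Shared fixtures and independent oracles. Expensive objects (corpora,
# trained taggers) are built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# reduced-dimension configuration used for all training fixtures
small_hp <- function(...) {
  hyperparams(word_dim = 25, char_dim = 8, char_lstm_out = 8,
              word_lstm_out = 16, semantic_feat_dim = 8,
              lexical_feat_dim = 6, ...)
}

subset_corpus <- function(corpus, idx) {
  out <- corpus[idx, ]
  class(out) <- class(corpus)
  out
}

site_a_corpus <- function() {
  fixture("site_a_corpus", function()
    generate_corpus(generator_config(250, seed = 101), style_profile("site_A")))
}

site_b_corpus <- function() {
  fixture("site_b_corpus", function()
    generate_corpus(generator_config(110, seed = 202), style_profile("site_B")))
}

# Cross-institute experiment: per seed, the five strict micro F1 scores of
# the study design (within-site, zero-shot, fine-tuned, merged, target-only).
# Built once and shared by the end-to-end and customization tests.
cross_institute_results <- function() {
  fixture("cross_institute", function() {
    hp <- small_hp()
    styA <- style_profile("site_A"); styB <- style_profile("site_B")
    dictsA <- builtin_dictionaries(styA); dictsB <- builtin_dictionaries(styB)
    corpA <- site_a_corpus(); corpB <- site_b_corpus()
    trainA <- subset_corpus(corpA, 1:200); testA <- subset_corpus(corpA, 201:250)
    trainB <- subset_corpus(corpB, 1:60); testB <- subset_corpus(corpB, 61:110)
    strict_f1 <- function(model, test) {
      ev <- evaluate_corpus(test, suppressWarnings(predict(model, test)))
      ev$strict$f1[ev$strict$category == "micro"]
    }
    rows <- lapply(c(11L, 22L, 33L), function(seed) {
      mA <- train_tagger(trainA, hp = hp, dictionaries = dictsA, seed = seed)
      mFT <- fine_tune(mA, trainB, dictionaries = c(dictsA, dictsB),
                       seed = seed)
      mM <- train_tagger(merge_corpora(trainA, trainB), hp = hp,
                         dictionaries = c(dictsA, dictsB), seed = seed)
      mB <- train_tagger(trainB, hp = hp, dictionaries = dictsB, seed = seed)
      tibble::tibble(
        seed = seed,
        a_within = strict_f1(mA, testA),
        b_zero_shot = strict_f1(mA, testB),
        b_fine_tuned = strict_f1(mFT, testB),
        b_merged = strict_f1(mM, testB),
        b_target_only = strict_f1(mB, testB))
    })
    dplyr::bind_rows(rows)
  })
}

# --- independent oracles ---------------------------------------------------

# CRF quantities by exhaustive path enumeration (small T, K only).
brute_crf <- function(em, tr, tags = NULL) {
  T <- nrow(em); K <- ncol(em); S <- K + 1; E <- K + 2
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  sc <- apply(paths, 1, function(y) {
    s <- tr[S, y[1]] + sum(em[cbind(seq_len(T), y)]) + tr[y[T], E]
    if (T > 1) s <- s + sum(tr[cbind(y[-T], y[-1])])
    s
  })
  logZ <- max(sc) + log(sum(exp(sc - max(sc))))
  best <- which(sc == max(sc))
  bp <- paths[best, , drop = FALSE]
  ord <- do.call(order, as.data.frame(bp))
  out <- list(logZ = logZ, best_path = unname(bp[ord[1], ]),
              best_score = max(sc), sum_prob = sum(exp(sc - logZ)))
  if (!is.null(tags)) {
    gold <- tr[S, tags[1]] + sum(em[cbind(seq_len(T), tags)]) + tr[tags[T], E]
    if (T > 1) gold <- gold + sum(tr[cbind(tags[-T], tags[-1])])
    out$ll <- gold - logZ
  }
  out
}

# Damerau-Levenshtein (optimal string alignment) by naive recursion.
brute_dl <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    cost <- if (x[i] == y[j]) 0L else 1L
    d <- min(rec(i - 1, j) + 1L, rec(i, j - 1) + 1L, rec(i - 1, j - 1) + cost)
    if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j])
      d <- min(d, rec(i - 2, j - 2) + 1L)
    d
  }
  rec(length(x), length(y))
}

# Size of the optimal 1-to-1 overlap matching by exhaustive recursion.
brute_matching <- function(adj, n_right) {
  rec <- function(l, used) {
    if (l > length(adj)) return(0L)
    best <- rec(l + 1L, used)
    for (r in adj[[l]]) {
      if (!used[r]) {
        used2 <- used; used2[r] <- TRUE
        best <- max(best, 1L + rec(l + 1L, used2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, n_right))
}

# Random disjoint span list over [0, len) for matching oracles.
random_span_list <- function(len, n_max, categories = c("DATE", "NAME")) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0)
    return(tibble::tibble(start = integer(), end = integer(),
                          category = character()))
  cuts <- sort(sample.int(len, min(2L * n, len)))
  cuts <- cuts[seq_len(2L * (length(cuts) %/% 2L))]
  if (length(cuts) < 2)
    return(tibble::tibble(start = integer(), end = integer(),
                          category = character()))
  starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- starts < ends
  tibble::tibble(start = as.integer(starts[keep] - 1L),
                 end = as.integer(ends[keep] - 1L),
                 category = sample(categories, sum(keep), replace = TRUE))
}
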