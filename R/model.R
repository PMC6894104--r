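# Model container: hyperparameters, vocabularies, parameter initialization
# and input encoding for the BiLSTM-CRF tagger.

#' Tagger hyperparameters
#'
#' Returns the tagger's hyperparameter set. The defaults are the published
#' operating configuration of the model: 300-dim word embeddings, 25-dim
#' character embeddings, bidirectional character LSTM with 25 output units
#' per direction and word LSTM with 100 per direction, 20-dim embeddings for
#' semantic (knowledge) features and 15-dim for lexical features, SGD with
#' learning rate 0.005, momentum 0.9, dropout 0.5 on the word-LSTM input,
#' gradient clipping to [-5, 5], 30 epochs from scratch and 15 for
#' fine-tuning, no early stopping. Every value can be overridden.
#'
#' @param ... Named overrides of any default.
#' @return A `deid_hyperparams` list.
#' @export
#' @examples
#' hyperparams(word_dim = 25, epochs_scratch = 5)
hyperparams <- function(...) {
  hp <- list(
    word_dim = 300L, char_dim = 25L, char_lstm_out = 25L,
    word_lstm_out = 100L, semantic_feat_dim = 20L, lexical_feat_dim = 15L,
    lr = 0.005, momentum = 0.9, dropout = 0.5, grad_clip = c(-5.0, 5.0),
    epochs_scratch = 30L, epochs_finetune = 15L, seed = 42L)
  over <- list(...)
  bad <- setdiff(names(over), names(hp))
  if (length(bad) > 0)
    abort(paste0("unknown hyperparameter(s): ", paste(bad, collapse = ", ")))
  hp[names(over)] <- over
  structure(hp, class = "deid_hyperparams")
}

all_bio_tags <- function() {
  cats <- phi_categories()
  c("O", paste0("B-", cats), paste0("I-", cats))
}

kb_composite_values <- function() {
  cats <- phi_categories()
  vals <- c("NONE:O:NONE")
  for (cat in cats)
    for (b in c("B", "I"))
      for (cond in c("EXACT", "PARTIAL"))
        vals <- c(vals, paste(cat, b, cond, sep = ":"))
  vals
}

#' Width of the word-LSTM input vector
#'
#' Per token, the word LSTM consumes the concatenation of the word vector,
#' the bidirectional character encoding (two final states), one embedding per
#' semantic (knowledge) feature stream and one per lexical feature stream.
#'
#' @param hp A [hyperparams()] object.
#' @param n_semantic Number of semantic feature streams (default 1: the
#'   composite knowledge stream).
#' @param n_lexical Number of lexical streams (default 2: part-of-speech and
#'   word shape).
#' @return Integer width.
#' @export
#' @examples
#' input_width(hyperparams())            # 400
#' input_width(hyperparams(), 0, 0)      # 350, features disabled
input_width <- function(hp, n_semantic = 1L, n_lexical = 2L) {
  as.integer(hp$word_dim + 2L * hp$char_lstm_out +
               n_semantic * hp$semantic_feat_dim +
               n_lexical * hp$lexical_feat_dim)
}

# Stream descriptors: name, dim, fixed value inventory (NULL = learned from
# the training corpus).
feature_stream_spec <- function(hp, features, has_kb, kb_wiring) {
  if (!features) return(list())
  streams <- list(
    list(name = "pos", dim = hp$lexical_feat_dim, values = pos_tagset()),
    list(name = "shape", dim = hp$lexical_feat_dim, values = NULL))
  if (has_kb) {
    if (kb_wiring == "composite") {
      streams <- c(streams, list(
        list(name = "kb", dim = hp$semantic_feat_dim,
             values = kb_composite_values())))
    } else {
      streams <- c(streams, list(
        list(name = "kb_category", dim = hp$semantic_feat_dim,
             values = c("NONE", phi_categories())),
        list(name = "kb_match", dim = hp$semantic_feat_dim,
             values = c("O:NONE", "B:EXACT", "B:PARTIAL", "I:EXACT",
                        "I:PARTIAL"))))
    }
  }
  streams
}

# Values of each feature stream for a featurized token table.
stream_values <- function(tokens, stream_name) {
  switch(stream_name,
    pos = tokens$pos,
    shape = tokens$shape,
    kb = paste(tokens$kb_category, tokens$kb_boundary, tokens$kb_condition,
               sep = ":"),
    kb_category = tokens$kb_category,
    kb_match = paste(tokens$kb_boundary, tokens$kb_condition, sep = ":"),
    abort(paste0("unknown feature stream: ", stream_name)))
}

runif_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# LSTM parameter block: input weights, recurrent weights, bias with the
# forget-gate slice initialized to 1 (standard stabilization).
init_lstm <- function(H, D) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(W = runif_mat(4 * H, D), U = runif_mat(4 * H, H), b = b)
}

init_params <- function(vocab, hp, stream_dims) {
  dw <- hp$word_dim; dc <- hp$char_dim
  Hc <- hp$char_lstm_out; Hw <- hp$word_lstm_out
  D <- dw + 2L * Hc + sum(stream_dims)
  K <- length(vocab$tag)
  cf <- init_lstm(Hc, dc); cb <- init_lstm(Hc, dc)
  wf <- init_lstm(Hw, D); wb <- init_lstm(Hw, D)
  list(
    Eword = runif_mat(length(vocab$word), dw),
    Echar = runif_mat(length(vocab$char), dc),
    Efeat = lapply(seq_along(stream_dims), function(k)
      runif_mat(length(vocab$feat[[k]]), stream_dims[k])),
    cfW = cf$W, cfU = cf$U, cfb = cf$b,
    cbW = cb$W, cbU = cb$U, cbb = cb$b,
    wfW = wf$W, wfU = wf$U, wfb = wf$b,
    wbW = wb$W, wbU = wb$U, wbb = wb$b,
    outW = runif_mat(K, 2L * Hw), outb = rep(0, K),
    trans = matrix(0, K + 2L, K + 2L))
}

char_inventory <- function(tokens) {
  sort(unique(c(strsplit(rawToChar(as.raw(32:126)), "")[[1]],
                unlist(strsplit(tokens, "")))))
}

build_vocab <- function(tokens, streams, embeddings = NULL) {
  word <- if (!is.null(embeddings)) {
    names(embeddings$vocab)
  } else {
    unique(c("UNKNOWN", sort(unique(tokens$token))))
  }
  feat <- lapply(streams, function(s) {
    vals <- if (is.null(s$values)) sort(unique(stream_values(tokens, s$name)))
            else s$values
    unique(c("<UNK>", vals))
  })
  names(feat) <- vapply(streams, `[[`, "", "name")
  list(word = word, char = unique(c("<UNK>", char_inventory(tokens$token))),
       feat = feat, tag = all_bio_tags())
}

# Token surface -> word index: exact form, then case-folded, then UNKNOWN.
word_ids_for <- function(surfaces, word_vocab) {
  idx <- match(surfaces, word_vocab)
  fold <- is.na(idx)
  if (any(fold)) idx[fold] <- match(tolower(surfaces[fold]), word_vocab)
  unk <- match("UNKNOWN", word_vocab)
  idx[is.na(idx)] <- unk
  idx
}

# Encode a featurized token table into per-sentence id lists for the C++
# core. Unseen feature values and characters map to the reserved <UNK> slot.
encode_sentences <- function(tokens, vocab, streams, with_tags = TRUE) {
  key <- paste(tokens$doc_id, tokens$sentence_id)
  groups <- split(seq_len(nrow(tokens)), factor(key, levels = unique(key)))
  word_idx <- word_ids_for(tokens$token, vocab$word)
  char_split <- strsplit(tokens$token, "")
  char_idx <- lapply(char_split, function(ch) {
    ix <- match(ch, vocab$char)
    ix[is.na(ix)] <- 1L
    as.integer(ix)
  })
  nfs <- length(streams)
  feat_idx <- matrix(1L, nrow(tokens), nfs)
  if (nfs > 0) {
    for (k in seq_len(nfs)) {
      v <- stream_values(tokens, streams[[k]]$name)
      ix <- match(v, vocab$feat[[k]])
      ix[is.na(ix)] <- 1L
      feat_idx[, k] <- ix
    }
  }
  tag_idx <- if (with_tags) {
    ti <- match(tokens$tag, vocab$tag)
    if (anyNA(ti)) abort("tag outside the BIO tag inventory")
    ti
  } else NULL
  lapply(groups, function(ix) {
    list(word_ids = as.integer(word_idx[ix]),
         char_ids = char_idx[ix],
         feat_ids = feat_idx[ix, , drop = FALSE],
         tag_ids = if (with_tags) as.integer(tag_idx[ix]) else integer(0),
         rows = ix)
  })
}

#' Log-likelihood of a tag path under a linear-chain CRF
#'
#' Computes `score(path) - log(sum over all paths)` for per-token, per-tag
#' emission scores and a transition matrix with start/stop states. Always
#' non-positive; `exp()` of it is the path's probability.
#'
#' @param emissions Numeric matrix, `T x K` (tokens by tags).
#' @param transitions Numeric `(K+2) x (K+2)` matrix; row = from, column =
#'   to; index `K+1` is the start state, `K+2` the stop state.
#' @param tags Integer vector of length `T`, values in `1..K`.
#' @return Scalar log-likelihood.
#' @export
crf_log_likelihood <- function(emissions, transitions, tags) {
  emissions <- as.matrix(emissions)
  res <- cpp_crf_nll(emissions, as.matrix(transitions), as.integer(tags),
                     FALSE)
  -res$nll
}

#' Best tag path under a linear-chain CRF
#'
#' Viterbi decoding of the highest-scoring tag path; exact ties are broken
#' toward the lexicographically smallest tag-index path.
#'
#' @inheritParams crf_log_likelihood
#' @return A list with `path` (integer tag indices, length `T`) and `score`
#'   (unnormalized path score).
#' @export
viterbi_decode <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  if (nrow(emissions) == 0) return(list(path = integer(0), score = 0))
  res <- cpp_viterbi(emissions, as.matrix(transitions))
  list(path = as.integer(res$path), score = res$score)
}
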