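# Training, fine-tuning, prediction and checkpointing of the BiLSTM-CRF
# tagger.

#' Train the BiLSTM-CRF de-identification tagger
#'
#' Fits the sequence model (character BiLSTM, word BiLSTM over concatenated
#' word/character/feature embeddings, CRF output layer) with per-sentence
#' stochastic gradient descent: momentum, element-wise gradient clipping,
#' dropout on the word-LSTM input during training only, and no early
#' stopping. Training is deterministic for a fixed seed.
#'
#' @param corpus A `deid_corpus` with gold annotations.
#' @param hp Hyperparameters from [hyperparams()].
#' @param epochs Number of epochs; defaults to `hp$epochs_scratch` (or
#'   `hp$epochs_finetune` when `init` is given).
#' @param features Use the feature-embedding layer (part-of-speech and word
#'   shape; plus knowledge lookup when `dictionaries` are supplied).
#' @param dictionaries Optional list of [dictionary()] objects for the
#'   knowledge feature stream.
#' @param embeddings Optional pretrained [load_vectors()] matrix used to
#'   initialize (and fine-tune) the word embedding table.
#' @param kb_wiring `"composite"` embeds category/boundary/condition as one
#'   knowledge stream; `"separate"` embeds category and boundary+condition
#'   as two streams.
#' @param lexicon Known-word lexicon for typo repair; `NULL` disables it.
#' @param init An existing `deid_model` to continue training from
#'   (fine-tuning); new words and feature values found in `corpus` get fresh
#'   embedding rows.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; defaults to `hp$seed`.
#' @param verbose Print per-epoch mean loss.
#' @return A `deid_model`.
#' @export
train_tagger <- function(corpus, hp = hyperparams(), epochs = NULL,
                         features = TRUE, dictionaries = NULL,
                         embeddings = NULL, kb_wiring = c("composite",
                                                          "separate"),
                         lexicon = deid_lexicon(), init = NULL,
                         seed = hp$seed, verbose = FALSE) {
  kb_wiring <- match.arg(kb_wiring)
  if (is.null(corpus) || nrow(corpus) == 0) abort("empty training corpus")
  if (!is.null(init)) {
    stopifnot(inherits(init, "deid_model"))
    hp <- init$hp
    features <- init$config$features
    kb_wiring <- init$config$kb_wiring
    if (is.null(dictionaries)) dictionaries <- init$dictionaries
    if (!identical(init$vocab$tag, all_bio_tags())) {
      diff <- c(setdiff(init$vocab$tag, all_bio_tags()),
                setdiff(all_bio_tags(), init$vocab$tag))
      abort(paste0("label-set mismatch between base model and tagger: ",
                   paste(diff, collapse = ", ")))
    }
  }
  if (is.null(epochs))
    epochs <- if (is.null(init)) hp$epochs_scratch else hp$epochs_finetune
  epochs <- as.integer(epochs)

  tokens <- label_corpus(corpus, lexicon)
  if (nrow(tokens) == 0) abort("corpus contains no tokens")
  has_kb <- !is.null(dictionaries) && length(dictionaries) > 0
  streams <- feature_stream_spec(hp, features, has_kb, kb_wiring)
  if (features) tokens <- token_features(tokens,
                                         if (has_kb) dictionaries else NULL)

  rng <- .save_rng()
  on.exit(.restore_rng(rng), add = TRUE)
  set.seed(as.integer(seed))

  if (is.null(init)) {
    vocab <- build_vocab(tokens, streams, embeddings)
    stream_dims <- vapply(streams, function(s) as.integer(s$dim), 1L)
    params <- init_params(vocab, hp, stream_dims)
    if (!is.null(embeddings)) {
      if (ncol(embeddings$vectors) != hp$word_dim)
        abort(sprintf("embedding dimension %d != word_dim %d",
                      ncol(embeddings$vectors), hp$word_dim))
      params$Eword <- unname(embeddings$vectors)
    }
  } else {
    vocab <- init$vocab
    params <- init$params
    # grow vocabularies with unseen words / feature values / characters
    new_words <- setdiff(unique(tokens$token), vocab$word)
    new_words <- new_words[is.na(match(tolower(new_words), vocab$word))]
    if (length(new_words) > 0) {
      vocab$word <- c(vocab$word, new_words)
      params$Eword <- rbind(params$Eword,
                            runif_mat(length(new_words), hp$word_dim))
    }
    new_chars <- setdiff(char_inventory(tokens$token), vocab$char)
    if (length(new_chars) > 0) {
      vocab$char <- c(vocab$char, new_chars)
      params$Echar <- rbind(params$Echar,
                            runif_mat(length(new_chars), hp$char_dim))
    }
    for (k in seq_along(streams)) {
      vals <- unique(stream_values(tokens, streams[[k]]$name))
      new_vals <- setdiff(vals, vocab$feat[[k]])
      if (length(new_vals) > 0) {
        vocab$feat[[k]] <- c(vocab$feat[[k]], new_vals)
        params$Efeat[[k]] <- rbind(params$Efeat[[k]],
                                   runif_mat(length(new_vals),
                                             streams[[k]]$dim))
      }
    }
  }

  sents <- encode_sentences(tokens, vocab, streams, with_tags = TRUE)
  D <- input_width(hp,
                   n_semantic = sum(grepl("^kb", names(vocab$feat))),
                   n_lexical = sum(!grepl("^kb", names(vocab$feat))))

  # deep-copy: the epoch driver updates the matrices in place, and a base
  # model passed through `init` must stay untouched
  dup <- function(p) if (is.list(p)) lapply(p, dup) else p + 0
  params <- dup(params)
  vel <- rapply(params, function(q) q * 0, how = "replace")
  keep <- 1 - hp$dropout
  loss_hist <- numeric(epochs)
  nomask <- matrix(numeric(0), 0, 0)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(sents))
    masks <- lapply(sents, function(s) {
      if (keep < 1) {
        Tn <- length(s$word_ids)
        matrix(rbinom(D * Tn, 1L, keep) / keep, D, Tn)
      } else nomask
    })
    tot <- tryCatch(
      cpp_train_epoch(params, vel, sents, ord, masks, hp$lr, hp$momentum,
                      hp$grad_clip[1], hp$grad_clip[2]),
      error = function(e)
        abort(sprintf("training aborted at epoch %d: %s", ep,
                      conditionMessage(e))))
    loss_hist[ep] <- tot / length(sents)
    if (verbose)
      inform(sprintf("epoch %d/%d  mean sentence loss %.4f", ep, epochs,
                     loss_hist[ep]))
  }

  provenance <- list(
    corpora = list(list(doc_ids = corpus$doc_id, n_docs = nrow(corpus))),
    epochs = epochs, seed = as.integer(seed),
    regime = if (is.null(init)) "scratch" else "fine_tune")
  if (!is.null(init)) {
    provenance$corpora <- c(init$provenance$corpora, provenance$corpora)
    provenance$parent <- init$provenance[c("epochs", "seed", "regime")]
  }

  structure(list(
    params = params, vocab = vocab, hp = hp,
    config = list(features = features, kb_wiring = kb_wiring,
                  streams = streams, input_width = D,
                  lexicon = lexicon),
    dictionaries = dictionaries,
    provenance = provenance,
    loss = loss_hist), class = "deid_model")
}

#' Fine-tune a trained tagger on a new corpus
#'
#' Continues training from the base model's weights at the same optimizer
#' settings — the customization strategy that re-uses pretrained parameters
#' instead of re-initializing. Words, characters and feature values unseen
#' by the base model receive fresh embedding rows; provenance chains to the
#' base model.
#'
#' @param base A trained `deid_model`.
#' @param corpus Target-site training corpus.
#' @param epochs Defaults to the base model's `epochs_finetune` (15).
#' @param seed Seed for shuffling/dropout; defaults to the base model's.
#' @param ... Passed to [train_tagger()].
#' @return A `deid_model`.
#' @export
fine_tune <- function(base, corpus, epochs = NULL,
                      seed = base$provenance$seed, ...) {
  stopifnot(inherits(base, "deid_model"))
  train_tagger(corpus, init = base, epochs = epochs, seed = seed, ...)
}

#' @export
print.deid_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) {
    if (is.list(p)) sum(vapply(p, length, 1L)) else length(p)
  }, 1L))
  cat(sprintf(
    "<deid_model: %d parameters, input width %d, %d-word vocabulary>\n",
    np, x$config$input_width, length(x$vocab$word)))
  cat(sprintf("  regime: %s, epochs: %d, seed: %d\n",
              x$provenance$regime, x$provenance$epochs, x$provenance$seed))
  invisible(x)
}

#' Predict PHI spans in a corpus
#'
#' Runs the full pipeline on each document: pre-processing, featurization,
#' per-sentence Viterbi decoding, and BIO-to-span conversion. Output spans
#' are valid and disjoint, in original-text coordinates.
#'
#' @param object A trained `deid_model`.
#' @param corpus A `deid_corpus` (annotations, if present, are ignored).
#' @param ... Unused.
#' @return A span tibble (`doc_id`, `start`, `end`, `category`, `surface`).
#' @export
predict.deid_model <- function(object, corpus, ...) {
  empty <- tibble(doc_id = character(), start = integer(), end = integer(),
                  category = character(), surface = character())
  if (is.null(corpus) || nrow(corpus) == 0) return(empty)
  tokens <- preprocess_corpus(corpus, object$config$lexicon)
  if (nrow(tokens) == 0) return(empty)
  has_kb <- !is.null(object$dictionaries) && length(object$dictionaries) > 0
  if (object$config$features)
    tokens <- token_features(tokens,
                             if (has_kb) object$dictionaries else NULL)
  sents <- encode_sentences(tokens, object$vocab, object$config$streams,
                            with_tags = FALSE)
  tokens$tag <- "O"
  paths <- cpp_predict_batch(object$params, unname(sents))
  for (i in seq_along(sents))
    tokens$tag[sents[[i]]$rows] <- object$vocab$tag[as.integer(paths[[i]])]
  bio_to_spans(tokens, corpus)
}

#' Save a model checkpoint
#'
#' Writes the checkpoint directory: `weights.rds` (all trainable weights,
#' bit-exact) and `model.json` (vocabularies, hyperparameters, feature
#' configuration, dictionaries, training provenance).
#'
#' @param model A `deid_model`.
#' @param dir Checkpoint directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "deid_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  side <- list(
    vocab = model$vocab, hp = unclass(model$hp),
    config = model$config[c("features", "kb_wiring", "input_width",
                            "lexicon")],
    dictionaries = lapply(model$dictionaries, function(d)
      d[c("name", "category", "entries", "priority", "fuzzy")]),
    provenance = model$provenance, loss = model$loss)
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return A `deid_model` whose predictions are identical to the saved
#'   model's.
#' @export
load_checkpoint <- function(dir) {
  wpath <- file.path(dir, "weights.rds")
  jpath <- file.path(dir, "model.json")
  if (!file.exists(wpath) || !file.exists(jpath))
    abort(paste0("not a checkpoint directory: ", dir))
  params <- readRDS(wpath)
  side <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  vocab <- list(word = side$vocab$word, char = side$vocab$char,
                feat = as.list(side$vocab$feat), tag = side$vocab$tag)
  hp <- do.call(hyperparams, as.list(side$hp))
  # stream descriptors are recoverable from the feature vocabularies
  streams <- lapply(names(vocab$feat), function(nm) {
    list(name = nm,
         dim = if (grepl("^kb", nm)) hp$semantic_feat_dim
               else hp$lexical_feat_dim,
         values = NULL)
  })
  dicts <- NULL
  dd <- side$dictionaries
  if (!is.null(dd) && length(dd) > 0 && length(dd$name) > 0) {
    dicts <- lapply(seq_along(dd$name), function(i)
      dictionary(dd$name[i], dd$category[i],
                 unlist(dd$entries[[i]]),
                 priority = dd$priority[i], fuzzy = dd$fuzzy[i]))
  }
  structure(list(
    params = params, vocab = vocab, hp = hp,
    config = list(features = side$config$features,
                  kb_wiring = side$config$kb_wiring,
                  streams = streams,
                  input_width = side$config$input_width,
                  lexicon = side$config$lexicon),
    dictionaries = dicts,
    provenance = side$provenance, loss = side$loss),
    class = "deid_model")
}

#' @rdname tidy
#' @title Tidy and summarize fitted taggers and evaluations
#' @description `tidy()` on a `deid_model` returns the learned CRF
#'   transition scores in long form; `glance()` returns a one-row training
#'   summary.
#' @param x A `deid_model`.
#' @param ... Unused.
#' @export
tidy.deid_model <- function(x, ...) {
  tags <- c(x$vocab$tag, "<START>", "<STOP>")
  tr <- x$params$trans
  tibble(from = rep(tags, times = length(tags)),
         to = rep(tags, each = length(tags)),
         score = as.vector(tr))
}

#' @rdname tidy
#' @export
glance.deid_model <- function(x, ...) {
  tibble(epochs = x$provenance$epochs,
         regime = x$provenance$regime,
         final_loss = tail(x$loss, 1),
         input_width = x$config$input_width,
         n_words = length(x$vocab$word),
         n_tags = length(x$vocab$tag),
         seed = x$provenance$seed)
}
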