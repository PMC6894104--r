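# Pretrained word-vector I/O.
#
# Plain-text word2vec / fastText format: optional first line "count dim",
# then one token per line followed by its space-separated vector. Tokens
# absent from the vocabulary are served the UNKNOWN row at prediction time.

#' Load pretrained word vectors
#'
#' Reads a plain-text vector file (word2vec or fastText convention, with or
#' without the `count dim` header). Duplicate tokens keep their first
#' occurrence (with a warning); the vector dimension is inferred from the
#' first row and enforced. If the file has no `UNKNOWN` token, a row is
#' sampled uniformly in [-0.25, 0.25] from the stated seed.
#'
#' @param path Vector file path.
#' @param unknown_seed Seed for the sampled `UNKNOWN` row (default 1).
#' @return A `deid_embeddings` object: list with `vocab` (named index),
#'   `vectors` (matrix, rows = tokens) and `dim`.
#' @export
load_vectors <- function(path, unknown_seed = 1L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty vector file: ", path))
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  declared <- NULL
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    declared <- as.integer(first)
    lines <- lines[-1]
    if (length(lines) == 0) abort(paste0("header but no vectors in ", path))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  dim <- length(parts[[1]]) - 1L
  if (dim < 1) abort(sprintf("%s: line %d: no vector values", path, 1L))
  bad <- which(lengths(parts) != dim + 1L)
  if (length(bad) > 0)
    abort(sprintf("%s: line %d: expected %d values, found %d", path,
                  bad[1] + !is.null(declared), dim,
                  lengths(parts)[bad[1]] - 1L))
  if (!is.null(declared) && declared[1] != length(parts))
    abort(sprintf("%s: header declares %d vectors but file has %d", path,
                  declared[1], length(parts)))
  if (!is.null(declared) && declared[2] != dim)
    abort(sprintf("%s: header declares dimension %d but rows have %d", path,
                  declared[2], dim))
  words <- vapply(parts, `[[`, "", 1L)
  dup <- duplicated(words)
  if (any(dup)) {
    warn(sprintf("%d duplicate token(s) in %s; first occurrence kept",
                 sum(dup), path))
    parts <- parts[!dup]; words <- words[!dup]
  }
  vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                nrow = length(parts), ncol = dim, byrow = TRUE)
  if (anyNA(vec)) abort(paste0(path, ": non-numeric vector value"))
  rownames(vec) <- words
  if (!"UNKNOWN" %in% words) {
    rng <- .save_rng()
    set.seed(unknown_seed)
    unk <- runif(dim, -0.25, 0.25)
    .restore_rng(rng)
    vec <- rbind(vec, UNKNOWN = unk)
    words <- c(words, "UNKNOWN")
  }
  structure(list(vocab = setNames(seq_along(words), words), vectors = vec,
                 dim = dim),
            class = "deid_embeddings")
}

#' @export
print.deid_embeddings <- function(x, ...) {
  cat(sprintf("<word embeddings: %d tokens x %d dims>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Look up word vectors with UNKNOWN fallback
#'
#' Tries the exact surface form, then the case-folded form, then returns the
#' `UNKNOWN` row — the replacement applied to every out-of-vocabulary word
#' at prediction time. Pure: never mutates the matrix.
#'
#' @param words Character vector.
#' @param embeddings A `deid_embeddings` from [load_vectors()].
#' @return A matrix with one row per word.
#' @export
embedding_lookup <- function(words, embeddings) {
  stopifnot(inherits(embeddings, "deid_embeddings"))
  idx <- embeddings$vocab[words]
  fold <- is.na(idx)
  if (any(fold)) idx[fold] <- embeddings$vocab[tolower(words[fold])]
  idx[is.na(idx)] <- embeddings$vocab[["UNKNOWN"]]
  out <- embeddings$vectors[idx, , drop = FALSE]
  rownames(out) <- words
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
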