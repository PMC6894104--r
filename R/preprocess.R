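# Pre-processing: run-together-word repair with offset provenance, sentence
# splitting, tokenization, and span <-> BIO conversion.
#
# All offsets are 0-based, half-open. Because the only text edit is the
# insertion of spaces, every token of the corrected text maps to a contiguous
# identical slice of the original text, so downstream components can work in
# original-text coordinates throughout.

#' Default known-word lexicon
#'
#' A small list of common clinical and general words used to gate
#' run-together-word repair. Supply your own (one word per line) via
#' [read_lexicon()] for site-specific vocabulary.
#'
#' @return Character vector of lowercase words.
#' @export
deid_lexicon <- function() {
  path <- system.file("extdata", "clinical_lexicon.txt", package = "deidtag")
  tolower(readLines(path, warn = FALSE))
}

#' Read a lexicon file (one word per line)
#'
#' @param path File path.
#' @return Character vector of lowercase words.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  w <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  tolower(w[nzchar(w)])
}

new_offset_map <- function(corrected, boundaries) {
  structure(list(corrected = corrected, boundaries = as.integer(boundaries)),
            class = "deid_offset_map")
}

#' @export
print.deid_offset_map <- function(x, ...) {
  cat(sprintf("<offset map: %d corrected chars -> %d original chars>\n",
              nchar(x$corrected), x$boundaries[length(x$boundaries)]))
  invisible(x)
}

#' Repair run-together words
#'
#' The most common typographic error in clinical notes is a missing space
#' between two words (e.g. `"prnInsulin"`). A space is inserted at each
#' lowercase-to-uppercase transition whose flanking alphabetic runs both have
#' length >= 2 and at least one of which (case-folded) occurs in the
#' known-word lexicon. The returned offset map projects every annotation
#' between corrected-text and original-text coordinates.
#'
#' @param text Input string.
#' @param lexicon Character vector of known words (case-folded at use).
#' @return A list with elements `text` (corrected string) and `map`
#'   (a `deid_offset_map`).
#' @export
#' @examples
#' correct_typos("gave prnInsulin today", lexicon = c("prn", "insulin"))$text
correct_typos <- function(text, lexicon = deid_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  lexicon <- tolower(lexicon)
  ins <- integer(0)  # original offsets where a space is inserted before
  if (nchar(text) > 0) {
    runs <- gregexpr("[[:alpha:]]+", text)[[1]]
    if (runs[1] != -1) {
      lens <- attr(runs, "match.length")
      for (r in seq_along(runs)) {
        word <- substr(text, runs[r], runs[r] + lens[r] - 1)
        # piece boundaries at every lowercase->uppercase transition
        cuts <- gregexpr("(?<=[a-z])(?=[A-Z])", word, perl = TRUE)[[1]]
        if (cuts[1] == -1) next
        bounds <- c(1L, as.integer(cuts), nchar(word) + 1L)
        pieces <- substring(word, bounds[-length(bounds)], bounds[-1] - 1L)
        for (p in seq_len(length(pieces) - 1L)) {
          left <- pieces[p]; right <- pieces[p + 1]
          if (nchar(left) >= 2 && nchar(right) >= 2 &&
              (tolower(left) %in% lexicon || tolower(right) %in% lexicon)) {
            # 0-based original offset of the first char of `right`
            ins <- c(ins, (runs[r] - 1L) + bounds[p + 1] - 1L)
          }
        }
      }
    }
  }
  n <- nchar(text)
  if (length(ins) == 0) {
    return(list(text = text, map = new_offset_map(text, 0:n)))
  }
  ins <- sort(unique(ins))
  pieces <- substring(text, c(0L, ins) + 1L, c(ins, n))
  corrected <- paste(pieces, collapse = " ")
  # boundary offsets walk 0..n, with the offset duplicated at each insertion
  # (the boundary before and after an inserted space map to the same
  # original position)
  boundaries <- integer(0)
  prev <- 0L
  for (k in seq_along(ins)) {
    boundaries <- c(boundaries, prev:(ins[k] - 1L), ins[k])
    prev <- ins[k]
  }
  boundaries <- c(boundaries, prev:n)
  stopifnot(length(boundaries) == nchar(corrected) + 1L)
  list(text = corrected, map = new_offset_map(corrected, boundaries))
}

#' Project offsets through an offset map
#'
#' Maps a half-open character span between corrected-text and original-text
#' coordinates. The map is piecewise monotone and total over the corrected
#' text; at an insertion point, a span start maps after the inserted space
#' and a span end before it, so round trips are exact for spans that do not
#' contain an inserted character.
#'
#' @param map A `deid_offset_map` from [correct_typos()].
#' @param start,end Integer vectors of 0-based half-open offsets.
#' @param from Coordinate system of the input: `"corrected"` (default) or
#'   `"original"`.
#' @return A tibble with projected `start` and `end`.
#' @export
project_offsets <- function(map, start, end,
                            from = c("corrected", "original")) {
  from <- match.arg(from)
  stopifnot(inherits(map, "deid_offset_map"), length(start) == length(end))
  b <- map$boundaries
  if (from == "corrected") {
    if (any(start < 0L | end > nchar(map$corrected) | start > end))
      abort("offsets out of range for corrected text")
    tibble(start = b[start + 1L], end = b[end + 1L])
  } else {
    n_orig <- b[length(b)]
    if (any(start < 0L | end > n_orig | start > end))
      abort("offsets out of range for original text")
    # start: last boundary with value == start; end: first with value == end
    s <- vapply(start, function(o) max(which(b == o)) - 1L, 1L)
    e <- vapply(end, function(o) min(which(b == o)) - 1L, 1L)
    tibble(start = as.integer(s), end = as.integer(e))
  }
}

#' Split text into sentence spans
#'
#' Newlines (clinical list items, headers) are hard sentence boundaries;
#' within a line, a sentence ends at a run of `.?!` followed by whitespace
#' and an uppercase letter, digit or opening parenthesis. A period after a
#' single capital letter (an initial, as in `"J. Smith"`) is not a sentence
#' boundary. Returned spans are trimmed of surrounding whitespace and tile
#' all non-whitespace text.
#'
#' @param text Input string.
#' @return A tibble with 0-based half-open columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  out <- tibble(start = integer(), end = integer())
  if (!nzchar(text)) return(out)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  nl <- if (nl[1] == -1) integer(0) else as.integer(nl) - 1L
  starts <- c(0L, nl + 1L)
  ends <- c(nl, nchar(text))
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_along(starts)) {
    if (starts[i] >= ends[i]) next
    line <- substr0(text, starts[i], ends[i])
    cutm <- gregexpr("(?<![^[:alpha:]][A-Z])(?<!^[A-Z])[.?!]+(?=[ \t]+[A-Z0-9(])",
                     line, perl = TRUE)[[1]]
    cut_end <- if (cutm[1] == -1) integer(0) else
      as.integer(cutm) + attr(cutm, "match.length") - 1L  # 1-based last char
    seg_s <- c(0L, cut_end)                # 0-based offsets within line
    seg_e <- c(cut_end, nchar(line))
    for (j in seq_along(seg_s)) {
      seg <- substr0(line, seg_s[j], seg_e[j])
      lead <- nchar(sub("[[:space:]]*$", "", seg))   # trailing trimmed length
      first_ns <- regexpr("[^[:space:]]", seg)
      if (first_ns == -1) next
      s_abs <- starts[i] + seg_s[j] + as.integer(first_ns) - 1L
      e_abs <- starts[i] + seg_s[j] + lead
      res_s <- c(res_s, s_abs); res_e <- c(res_e, e_abs)
    }
  }
  tibble(start = res_s, end = res_e)
}

#' Tokenize a sentence
#'
#' Tokens are maximal runs of letters, maximal runs of digits, or single
#' non-alphanumeric marks; whitespace separates tokens. The aggressive
#' splitting keeps punctuation-laced PHIs (phone numbers, dates, IDs) in
#' clean single-class pieces. Concatenating surfaces with the original
#' whitespace reconstructs the sentence.
#'
#' @param text Sentence string.
#' @param base_offset Offset of `text` within its document; added to all
#'   token offsets.
#' @return A tibble with columns `token`, `start`, `end` (0-based, half-open,
#'   absolute when `base_offset` is given).
#' @export
#' @examples
#' tokenize("(352)265-1234")$token
tokenize <- function(text, base_offset = 0L) {
  r <- token_runs(text, base_offset)
  tibble(token = r$token, start = r$start, end = r$end)
}

# plain-list tokenizer core (the hot path avoids per-sentence tibbles)
token_runs <- function(text, base_offset = 0L) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- list(token = character(), start = integer(), end = integer())
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[[:alpha:]]+|[[:digit:]]+|[^[:alpha:][:digit:][:space:]]",
                text)[[1]]
  if (m[1] == -1) return(empty)
  len <- attr(m, "match.length")
  start <- as.integer(m) - 1L + as.integer(base_offset)
  list(token = substring(text, m, m + len - 1L),
       start = start, end = start + len)
}

#' Pre-process a corpus into a token table
#'
#' Runs typo repair, sentence splitting and tokenization over every document
#' and returns one long token table in original-text coordinates (token
#' offsets are projected back through the offset map, so annotations apply
#' unchanged).
#'
#' @param corpus A `deid_corpus`.
#' @param lexicon Known-word lexicon for [correct_typos()]; `NULL` disables
#'   typo repair.
#' @return A tibble with columns `doc_id`, `sentence_id`, `token`, `start`,
#'   `end`.
#' @export
preprocess_corpus <- function(corpus, lexicon = deid_lexicon()) {
  res <- purrr::map2(corpus$doc_id, corpus$text, function(id, text) {
    if (is.null(lexicon)) {
      corr <- list(text = text, map = NULL)
    } else {
      corr <- correct_typos(text, lexicon)
    }
    sents <- split_sentences(corr$text)
    if (nrow(sents) == 0)
      return(tibble(doc_id = character(), sentence_id = integer(),
                    token = character(), start = integer(), end = integer()))
    toks <- purrr::map2(sents$start, sents$end, function(s, e) {
      token_runs(substr0(corr$text, s, e), base_offset = s)
    })
    n_per <- vapply(toks, function(x) length(x$token), 1L)
    toks <- toks[n_per > 0]
    n_per <- n_per[n_per > 0]
    token <- unlist(lapply(toks, `[[`, "token"), use.names = FALSE)
    start <- unlist(lapply(toks, `[[`, "start"), use.names = FALSE)
    end <- unlist(lapply(toks, `[[`, "end"), use.names = FALSE)
    if (!is.null(corr$map)) {
      proj <- project_offsets(corr$map, start, end, from = "corrected")
      start <- proj$start; end <- proj$end
    }
    tibble(doc_id = id, sentence_id = rep(seq_along(toks), n_per),
           token = token, start = start, end = end)
  })
  bind_rows(res)
}

#' Convert annotation spans to BIO tags over tokens
#'
#' The first token overlapping a span receives `B-<category>`, subsequent
#' overlapping tokens `I-<category>`, all others `O`. A span edge falling
#' inside a token labels the whole token (boundary snapping: for
#' de-identification it is safer to over-mask than under-mask); snapped
#' spans are counted in the `snapped` attribute. A span overlapping no token
#' raises a warning and is counted in the `dropped` attribute.
#'
#' @param tokens Token table (from [preprocess_corpus()]); may hold several
#'   documents (column `doc_id`).
#' @param spans Span table with `start`, `end`, `category` and, for
#'   multi-document input, `doc_id`.
#' @return `tokens` with an added `tag` column; attributes `dropped` and
#'   `snapped` give span counts.
#' @export
spans_to_bio <- function(tokens, spans) {
  if (!"doc_id" %in% names(tokens)) tokens$doc_id <- "doc1"
  if (!"doc_id" %in% names(spans)) spans$doc_id <- "doc1"
  tokens$tag <- "O"
  dropped <- 0L; snapped <- 0L
  for (id in unique(tokens$doc_id)) {
    ti <- which(tokens$doc_id == id)
    sp <- spans[spans$doc_id == id, , drop = FALSE]
    if (nrow(sp) == 0) next
    ts <- tokens$start[ti]; te <- tokens$end[ti]
    taken <- rep(FALSE, length(ti))
    for (k in seq_len(nrow(sp))) {
      ov <- which(ts < sp$end[k] & te > sp$start[k] & !taken)
      if (length(ov) == 0) { dropped <- dropped + 1L; next }
      if (ts[ov[1]] != sp$start[k] || te[ov[length(ov)]] != sp$end[k])
        snapped <- snapped + 1L
      taken[ov] <- TRUE
      tokens$tag[ti[ov[1]]] <- paste0("B-", sp$category[k])
      if (length(ov) > 1)
        tokens$tag[ti[ov[-1]]] <- paste0("I-", sp$category[k])
    }
  }
  if (dropped > 0)
    warn(sprintf("%d span(s) overlapped no token and were dropped", dropped))
  attr(tokens, "dropped") <- dropped
  attr(tokens, "snapped") <- snapped
  tokens
}

#' Convert BIO-tagged tokens back to spans
#'
#' Each maximal `B-X (I-X)*` run becomes one span from the first token's
#' start to the last token's end. Orphan `I-X` tags are repaired by
#' promotion to `B-X` (with a warning), as in [read_conll()].
#'
#' @param tokens Tagged token table (`doc_id`, `sentence_id`, `token`,
#'   `start`, `end`, `tag`).
#' @param text Optional named character vector (names = doc ids) used to fill
#'   span surfaces; also accepts a `deid_corpus`.
#' @return A span tibble with columns `doc_id`, `start`, `end`, `category`,
#'   `surface`.
#' @export
bio_to_spans <- function(tokens, text = NULL) {
  if (!"doc_id" %in% names(tokens)) tokens$doc_id <- "doc1"
  if (!"sentence_id" %in% names(tokens)) tokens$sentence_id <- 1L
  if (inherits(text, "deid_corpus") || is.data.frame(text))
    text <- setNames(text$text, text$doc_id)
  if (nrow(tokens) == 0)
    return(tibble(doc_id = character(), start = integer(), end = integer(),
                  category = character(), surface = character()))
  key <- paste(tokens$doc_id, tokens$sentence_id)
  tokens$tag <- check_tag_grammar(tokens$tag, key, repair = TRUE)
  is_b <- startsWith(tokens$tag, "B-")
  is_i <- startsWith(tokens$tag, "I-")
  run_id <- cumsum(is_b)
  run_id[!(is_b | is_i)] <- NA
  idx <- which(!is.na(run_id))
  if (length(idx) == 0)
    return(tibble(doc_id = character(), start = integer(), end = integer(),
                  category = character(), surface = character()))
  grp <- split(idx, run_id[idx])
  first <- vapply(grp, `[[`, 1L, 1L)
  last <- vapply(grp, function(ix) ix[length(ix)], 1L)
  out <- tibble(doc_id = tokens$doc_id[first],
                start = tokens$start[first],
                end = tokens$end[last],
                category = sub("^B-", "", tokens$tag[first]))
  out <- arrange(out, .data$doc_id, .data$start)
  out$surface <- if (is.null(text)) NA_character_ else
    substr0(text[out$doc_id], out$start, out$end)
  out
}

#' Tokenize and BIO-label an annotated corpus
#'
#' Convenience wrapper: [preprocess_corpus()] followed by [spans_to_bio()]
#' on the gold annotations.
#'
#' @inheritParams preprocess_corpus
#' @return A tagged token table.
#' @export
label_corpus <- function(corpus, lexicon = deid_lexicon()) {
  tokens <- preprocess_corpus(corpus, lexicon)
  spans <- tidyr::unnest(corpus[, c("doc_id", "spans")], "spans")
  spans_to_bio(tokens, spans)
}
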