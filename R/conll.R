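# CoNLL-style token file I/O.
#
# Dialect: one token per line "surface<TAB>start<TAB>end<TAB>tag", a blank
# line between sentences, and a "# doc_id = <id>" comment before each
# document so multi-document corpora round-trip.

#' Write labeled token sequences to a CoNLL-style file
#'
#' @param tokens A tibble with columns `doc_id`, `sentence_id`, `token`,
#'   `start`, `end`, `tag` (as produced by [spans_to_bio()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conll <- function(tokens, path) {
  stopifnot(all(c("token", "start", "end", "tag") %in% names(tokens)))
  if (!"doc_id" %in% names(tokens)) tokens$doc_id <- "doc1"
  if (!"sentence_id" %in% names(tokens)) tokens$sentence_id <- 1L
  check_tag_grammar(tokens$tag, tokens$sentence_id, repair = FALSE)
  lines <- character(0)
  if (nrow(tokens) > 0) {
    docs <- split(tokens, factor(tokens$doc_id, levels = unique(tokens$doc_id)))
    lines <- unlist(lapply(docs, function(d) {
      sents <- split(d, factor(d$sentence_id, levels = unique(d$sentence_id)))
      body <- unlist(lapply(sents, function(s) {
        c(sprintf("%s\t%d\t%d\t%s", s$token, s$start, s$end, s$tag), "")
      }), use.names = FALSE)
      c(sprintf("# doc_id = %s", d$doc_id[1]), body)
    }), use.names = FALSE)
  }
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write CoNLL file: ", path))
  invisible(path)
}

#' Read a CoNLL-style token file
#'
#' Reads the dialect written by [write_conll()]. Orphan `I-X` tags (an `I-X`
#' not preceded by `B-X`/`I-X` of the same category) are repaired by
#' promotion to `B-X`, with a warning.
#'
#' @param path Input path.
#' @return A tibble with columns `doc_id`, `sentence_id`, `token`, `start`,
#'   `end`, `tag`.
#' @export
read_conll <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  doc <- "doc1"; sent <- 1L; in_sent <- FALSE
  recs <- vector("list", length(lines)); nr <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "# doc_id = ")) {
      doc <- sub("^# doc_id = ", "", ln)
      sent <- 1L; in_sent <- FALSE
      next
    }
    if (!nzchar(ln)) {
      if (in_sent) { sent <- sent + 1L; in_sent <- FALSE }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      abort(sprintf("%s: line %d: expected 4 tab-separated columns, found %d",
                    path, i, length(f)))
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en))
      abort(sprintf("%s: line %d: non-integer offsets", path, i))
    nr <- nr + 1L
    recs[[nr]] <- list(doc_id = doc, sentence_id = sent, token = f[1],
                       start = st, end = en, tag = f[4])
    in_sent <- TRUE
  }
  if (nr == 0L)
    return(tibble(doc_id = character(), sentence_id = integer(),
                  token = character(), start = integer(), end = integer(),
                  tag = character()))
  out <- bind_rows(lapply(recs[seq_len(nr)], as_tibble))
  key <- paste(out$doc_id, out$sentence_id)
  out$tag <- check_tag_grammar(out$tag, key, repair = TRUE)
  out
}

# Validate (or repair) the BIO grammar within each sentence: I-X may only
# follow B-X or I-X of the same category.
check_tag_grammar <- function(tags, sentence_key, repair = TRUE) {
  bad_form <- !grepl("^(O|[BI]-[A-Z]+)$", tags)
  if (any(bad_form))
    abort(paste0("malformed BIO tag(s): ",
                 paste(unique(tags[bad_form]), collapse = ", ")))
  prev_tag <- c("O", tags[-length(tags)])
  new_sent <- c(TRUE, sentence_key[-1] != sentence_key[-length(sentence_key)])
  prev_tag[new_sent] <- "O"
  is_i <- startsWith(tags, "I-")
  cat <- sub("^[BI]-", "", tags)
  prev_cat <- sub("^[BI]-", "", prev_tag)
  orphan <- is_i & (prev_tag == "O" | prev_cat != cat)
  if (any(orphan)) {
    if (!repair)
      abort(sprintf("invalid tag grammar: orphan %s at position %d",
                    tags[which(orphan)[1]], which(orphan)[1]))
    warn(sprintf("repaired %d orphan I- tag(s) by promotion to B-", sum(orphan)))
    # promote left-to-right; a repaired B- legitimizes a following I-
    for (i in which(orphan)) {
      prev_ok <- i > 1 && !new_sent[i] &&
        sub("^[BI]-", "", tags[i - 1]) == cat[i] && tags[i - 1] != "O"
      if (!prev_ok) tags[i] <- sub("^I-", "B-", tags[i])
    }
  }
  tags
}
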