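# Lexical and knowledge-based token features.
#
# Lexical: a Penn-style part-of-speech tag from a deterministic rule/lexicon
# tagger, and a word-shape abstraction. Knowledge-based: fuzzy gazetteer
# lookup emitting semantic category, BIO match boundary and EXACT/PARTIAL
# match condition per token. All features are categorical strings consumed
# by the tagger's feature-embedding layer.

#' Word shape of tokens
#'
#' Maps uppercase letters to `A`, lowercase to `a`, digits to `0`; all other
#' characters are kept verbatim. The composite value `"full|collapsed"`
#' appends a variant with repeated symbols squeezed to one, so `"Smith"`
#' becomes `"Aaaaa|Aa"`.
#'
#' @param tokens Character vector of non-empty tokens.
#' @return Character vector of composite shape strings.
#' @export
#' @examples
#' word_shape(c("Smith", "32610", "H&P"))
word_shape <- function(tokens) {
  stopifnot(is.character(tokens))
  if (any(!nzchar(tokens) | is.na(tokens)))
    abort("word_shape: empty token")
  full <- gsub("[[:digit:]]", "0",
               gsub("[[:lower:]]", "a", gsub("[[:upper:]]", "A", tokens)))
  collapsed <- gsub("(.)\\1+", "\\1", full)
  paste0(full, "|", collapsed)
}

.pos_closed <- local({
  list(
    DT = c("the", "a", "an", "this", "that", "these", "those", "no", "each",
           "every", "some", "any"),
    IN = c("in", "on", "of", "at", "for", "with", "by", "from", "as", "into",
           "during", "after", "before", "over", "under", "per", "since",
           "without"),
    TO = "to",
    CC = c("and", "or", "but", "nor"),
    PRP = c("he", "she", "it", "they", "i", "you", "we", "him", "her",
            "them", "us", "me"),
    `PRP$` = c("his", "her", "their", "my", "your", "our", "its"),
    MD = c("will", "can", "may", "should", "must", "would", "could",
           "might", "shall"),
    VBZ = c("is", "has", "does", "was"),
    VBP = c("are", "am", "have", "do"),
    VBD = c("were", "did", "had"),
    VB = "be",
    VBN = c("been", "given", "seen", "noted", "started", "performed"),
    RB = c("not", "well", "very", "again", "here", "there", "now", "today",
           "currently", "daily", "twice")
  )
})

#' Part-of-speech tags for a sentence of tokens
#'
#' A small deterministic tagger over a fixed Penn-style tagset: closed-class
#' words from a built-in lexicon, `CD` for digit runs, punctuation tagged as
#' itself (or `SYM`), suffix heuristics (`-ly` adverbs, `-ing`/`-ed` verb
#' forms, plural nouns), capitalized tokens as proper nouns, `NN` as the
#' default and `X` as the unknown fallback. Deterministic: the same token
#' sequence always yields the same tags.
#'
#' @param tokens Character vector of token surfaces (one sentence).
#' @return Character vector of tags, one per token.
#' @export
#' @examples
#' pos_tag(c("the", "patient"))
pos_tag <- function(tokens) {
  stopifnot(is.character(tokens))
  n <- length(tokens)
  if (n == 0) return(character(0))
  tags <- rep("X", n)
  low <- tolower(tokens)
  for (tg in names(.pos_closed)) {
    hit <- low %in% .pos_closed[[tg]] & tags == "X"
    tags[hit] <- tg
  }
  digit <- grepl("^[0-9]+$", tokens) & tags == "X"
  tags[digit] <- "CD"
  punct1 <- nchar(tokens) == 1L & grepl("^[^[:alnum:]]$", tokens) & tags == "X"
  if (any(punct1)) {
    p <- tokens[punct1]
    tags[punct1] <- ifelse(p %in% c(".", ",", ":", ";", "(", ")", "#", "$"),
                           ifelse(p == ";", ":", p), "SYM")
  }
  alpha <- grepl("^[[:alpha:]]+$", tokens)
  open <- tags == "X" & alpha
  cap <- open & grepl("^[A-Z]", tokens)
  tags[cap] <- "NNP"
  open <- tags == "X" & alpha
  tags[open & grepl("ly$", low)] <- "RB"
  open <- tags == "X" & alpha
  tags[open & grepl("ing$", low) & nchar(tokens) > 4] <- "VBG"
  open <- tags == "X" & alpha
  tags[open & grepl("ed$", low) & nchar(tokens) > 3] <- "VBD"
  open <- tags == "X" & alpha
  tags[open & grepl("[^su]s$", low) & nchar(tokens) > 3] <- "NNS"
  tags[tags == "X" & alpha] <- "NN"
  tags[tags == "X"] <- "X"
  tags
}

# Fixed tagset for the feature-embedding vocabulary.
pos_tagset <- function() {
  c("X", names(.pos_closed), "CD", ".", ",", ":", "(", ")", "#", "$", "SYM",
    "NNP", "RB", "VBG", "VBD", "NNS", "NN")
}

#' Build a gazetteer dictionary
#'
#' @param name Dictionary name.
#' @param category Target PHI category (one of [phi_categories()]).
#' @param entries Character vector of (possibly multi-word) entries;
#'   case-folded at load, empties dropped.
#' @param priority Integer rank; lower wins ties in [fuzzy_lookup()].
#' @param fuzzy Allow PARTIAL (edit-distance / prefix) matches. Digit-only
#'   entries such as zip codes should use `fuzzy = FALSE`: an edit distance
#'   on digit strings invites false partial matches.
#' @return A `deid_dictionary` object.
#' @export
dictionary <- function(name, category, entries, priority = 1L, fuzzy = TRUE) {
  stopifnot(is.character(entries))
  if (!category %in% phi_categories())
    abort(paste0("category must be one of: ",
                 paste(phi_categories(), collapse = ", ")))
  entries <- tolower(trimws(entries))
  entries <- unique(entries[nzchar(entries)])
  if (length(entries) == 0) abort("dictionary has no non-empty entries")
  toks <- strsplit(entries, "[[:space:]]+")
  structure(list(name = name, category = category, entries = entries,
                 entry_tokens = toks, priority = as.integer(priority),
                 fuzzy = isTRUE(fuzzy)),
            class = "deid_dictionary")
}

#' Read a dictionary file (one entry per line)
#'
#' @param path UTF-8 text file, one entry per line.
#' @inheritParams dictionary
#' @return A `deid_dictionary`.
#' @export
read_dictionary <- function(path, category, name = basename(path),
                            priority = 1L, fuzzy = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dictionary(name, category, readLines(path, encoding = "UTF-8", warn = FALSE),
             priority = priority, fuzzy = fuzzy)
}

#' Damerau-Levenshtein distance (optimal string alignment)
#'
#' Edit distance counting insertions, deletions, substitutions and
#' transpositions of adjacent characters, each at cost 1 (optimal string
#' alignment variant: no substring is edited twice).
#'
#' @param a,b Strings.
#' @return Integer distance.
#' @export
#' @examples
#' damerau_levenshtein("gainesville", "gainesvile")
damerau_levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in 1:n) {
    for (j in 1:m) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
      if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j])
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
    }
  }
  d[n + 1, m + 1]
}

#' Precompute dictionary match tables for a token inventory
#'
#' Builds, once per corpus, the per-dictionary lookup tables
#' [fuzzy_lookup()] consults for every sentence: exact and fuzzy
#' single-entry hits and multi-word anchor positions over the unique
#' (case-folded) tokens. Fuzzy candidates are prefiltered with vectorized
#' plain edit distance (Damerau-Levenshtein distance 1 implies Levenshtein
#' distance at most 2) before the exact distance is confirmed.
#'
#' @param uniq Character vector of unique case-folded tokens.
#' @param dictionaries List of [dictionary()] objects.
#' @return An opaque cache list consumed by [fuzzy_lookup()].
#' @export
dict_cache <- function(uniq, dictionaries) {
  if (inherits(dictionaries, "deid_dictionary"))
    dictionaries <- list(dictionaries)
  nz <- length(uniq)
  eligible <- nchar(uniq) >= 5 & !grepl("^[0-9]+$", uniq)
  per_dict <- lapply(dictionaries, function(d) {
    one <- lengths(d$entry_tokens) == 1L
    singles <- d$entries[one]
    multis <- d$entry_tokens[!one]
    exact1 <- uniq %in% singles
    fuzzy1 <- rep(FALSE, nz)
    if (d$fuzzy && any(eligible)) {
      sing5 <- singles[nchar(singles) >= 5 & !grepl("^[0-9]+$", singles)]
      if (length(sing5) > 0) {
        cand_i <- which(eligible & !exact1)
        if (length(cand_i) > 0) {
          dm <- utils::adist(uniq[cand_i], sing5)
          ldiff <- abs(outer(nchar(uniq[cand_i]), nchar(sing5), "-"))
          hit <- which(dm <= 2 & ldiff <= 1, arr.ind = TRUE)
          if (nrow(hit) > 0) {
            ok <- vapply(seq_len(nrow(hit)), function(r)
              damerau_levenshtein(uniq[cand_i[hit[r, 1]]],
                                  sing5[hit[r, 2]]) <= 1L, TRUE)
            fuzzy1[cand_i[unique(hit[ok, 1])]] <- TRUE
          }
        }
      }
    }
    anchor <- matrix(FALSE, nz, length(multis))
    for (m in seq_along(multis)) {
      ew1 <- multis[[m]][1]
      anchor[, m] <- uniq == ew1
      if (d$fuzzy && nchar(ew1) >= 5 && !grepl("^[0-9]+$", ew1)) {
        cand_i <- which(eligible & !anchor[, m] &
                          abs(nchar(uniq) - nchar(ew1)) <= 1)
        if (length(cand_i) > 0) {
          dm <- utils::adist(uniq[cand_i], ew1)[, 1]
          cand_i <- cand_i[dm <= 2]
          ok <- vapply(uniq[cand_i], function(u)
            damerau_levenshtein(u, ew1) <= 1L, TRUE)
          anchor[cand_i[ok], m] <- TRUE
        }
      }
    }
    list(exact1 = exact1, fuzzy1 = fuzzy1, multis = multis, anchor = anchor)
  })
  list(uniq = uniq, dicts = per_dict)
}

# TRUE if token matches entry token under the fuzzy rule: exact, or (both
# length >= 5 and neither digit-only) within Damerau-Levenshtein distance 1.
.fuzzy_token_match <- function(tok, ent, allow_fuzzy) {
  if (tok == ent) return(TRUE)
  if (!allow_fuzzy) return(FALSE)
  if (nchar(tok) < 5 || nchar(ent) < 5) return(FALSE)
  if (grepl("^[0-9]+$", tok) || grepl("^[0-9]+$", ent)) return(FALSE)
  if (abs(nchar(tok) - nchar(ent)) > 1) return(FALSE)
  damerau_levenshtein(tok, ent) <= 1
}

#' Knowledge-based features from fuzzy dictionary lookup
#'
#' Scans a token sequence for longest leftmost matches of dictionary
#' entries. A match is `EXACT` when every token equals the aligned entry
#' word case-insensitively, `PARTIAL` when some token differs but is within
#' Damerau-Levenshtein distance 1 (tokens of length >= 5, non-numeric) or
#' when the tokens exactly match a strict prefix covering at least half the
#' words of a multi-word entry. Competing matches at the same position are
#' resolved by length (longer wins), then `EXACT` over `PARTIAL`, then lower
#' dictionary priority rank. Matched runs are annotated with the
#' dictionary's category and B/I boundaries; unmatched tokens get
#' `NONE`/`O`/`NONE`.
#'
#' @param tokens Character vector of token surfaces (one sentence).
#' @param dictionaries A list of [dictionary()] objects (or a single one).
#' @param .cache Optional precomputed [dict_cache()] over the corpus token
#'   inventory; [token_features()] supplies one so per-sentence lookups stay
#'   cheap.
#' @return A tibble with columns `kb_category`, `kb_boundary`,
#'   `kb_condition`, one row per token.
#' @export
fuzzy_lookup <- function(tokens, dictionaries, .cache = NULL) {
  if (inherits(dictionaries, "deid_dictionary"))
    dictionaries <- list(dictionaries)
  n <- length(tokens)
  out <- tibble(kb_category = rep("NONE", n), kb_boundary = rep("O", n),
                kb_condition = rep("NONE", n))
  if (length(dictionaries) == 0) {
    warn("no dictionaries loaded; knowledge features are all NONE")
    return(out)
  }
  if (n == 0) return(out)
  low <- tolower(tokens)
  if (is.null(.cache)) .cache <- dict_cache(unique(low), dictionaries)
  uix <- match(low, .cache$uniq)

  # candidate matches per start position: list of (len, exact, priority, cat)
  cands <- vector("list", n)
  add <- function(pos, len, exact, priority, category) {
    cands[[pos]][[length(cands[[pos]]) + 1L]] <<-
      list(len = len, exact = exact, priority = priority, category = category)
  }

  for (di in seq_along(dictionaries)) {
    d <- dictionaries[[di]]
    cc <- .cache$dicts[[di]]
    for (i in which(cc$exact1[uix])) add(i, 1L, TRUE, d$priority, d$category)
    for (i in which(cc$fuzzy1[uix])) add(i, 1L, FALSE, d$priority, d$category)
    for (m in seq_along(cc$multis)) {
      ew <- cc$multis[[m]]
      L <- length(ew)
      for (i in which(cc$anchor[uix, m])) {
        if (i + L - 1L <= n) {
          seg <- low[i:(i + L - 1L)]
          if (all(seg == ew)) {
            add(i, L, TRUE, d$priority, d$category)
          } else if (d$fuzzy &&
                     all(vapply(seq_len(L), function(k)
                       .fuzzy_token_match(seg[k], ew[k], TRUE), TRUE))) {
            add(i, L, FALSE, d$priority, d$category)
          }
        }
        # strict prefix (>= half the words, fewer than all)
        if (d$fuzzy && low[i] == ew[1]) {
          for (k in seq.int(ceiling(L / 2), L - 1L)) {
            if (k < 1L || i + k - 1L > n) next
            if (all(low[i:(i + k - 1L)] == ew[seq_len(k)]))
              add(i, k, FALSE, d$priority, d$category)
          }
        }
      }
    }
  }

  i <- 1L
  while (i <= n) {
    best <- NULL
    for (cand in cands[[i]]) best <- .better_match(best, cand)
    if (is.null(best)) { i <- i + 1L; next }
    idx <- i:(i + best$len - 1L)
    out$kb_category[idx] <- best$category
    out$kb_boundary[idx] <- c("B", rep("I", best$len - 1L))
    out$kb_condition[idx] <- if (best$exact) "EXACT" else "PARTIAL"
    i <- i + best$len
  }
  out
}

.better_match <- function(best, cand) {
  if (is.null(best)) return(cand)
  if (cand$len != best$len) return(if (cand$len > best$len) cand else best)
  if (cand$exact != best$exact) return(if (cand$exact) cand else best)
  if (cand$priority != best$priority)
    return(if (cand$priority < best$priority) cand else best)
  best
}

#' Compute all feature streams for a token table
#'
#' Adds part-of-speech, word-shape and (when dictionaries are given)
#' knowledge-lookup columns to a token table, sentence by sentence.
#'
#' @param tokens Token table with `doc_id`, `sentence_id`, `token`.
#' @param dictionaries Optional list of [dictionary()] objects.
#' @return `tokens` with added columns `pos`, `shape` and, when requested,
#'   `kb_category`, `kb_boundary`, `kb_condition`.
#' @export
token_features <- function(tokens, dictionaries = NULL) {
  tokens$pos <- pos_tag(tokens$token)
  tokens$shape <- word_shape(tokens$token)
  if (!is.null(dictionaries)) {
    if (inherits(dictionaries, "deid_dictionary"))
      dictionaries <- list(dictionaries)
    key <- paste(tokens$doc_id, tokens$sentence_id)
    groups <- split(seq_len(nrow(tokens)), factor(key, levels = unique(key)))
    cache <- dict_cache(unique(tolower(tokens$token)), dictionaries)
    tokens$kb_category <- NA_character_
    tokens$kb_boundary <- NA_character_
    tokens$kb_condition <- NA_character_
    for (ix in groups) {
      kb <- fuzzy_lookup(tokens$token[ix], dictionaries, .cache = cache)
      tokens$kb_category[ix] <- kb$kb_category
      tokens$kb_boundary[ix] <- kb$kb_boundary
      tokens$kb_condition[ix] <- kb$kb_condition
    }
  }
  tokens
}
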