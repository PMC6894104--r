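# Corpus containers and standoff I/O.
#
# A corpus is a tibble with one row per document:
#   doc_id    character, unique
#   note_type character
#   text      character
#   spans     list of tibbles (start, end, category, surface)
# Offsets are 0-based, half-open; `surface` always equals the text slice.

new_span_tbl <- function(start = integer(), end = integer(),
                         category = character(), surface = character()) {
  tibble(start = as.integer(start), end = as.integer(end),
         category = as.character(category), surface = as.character(surface))
}

#' Assemble a de-identification corpus
#'
#' Builds the corpus container used throughout the package: a tibble with one
#' row per document and a `spans` list-column of PHI annotations. All inputs
#' are validated against the span invariants (offsets in range, surface equal
#' to the text slice, spans sorted and pairwise disjoint).
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param text Character vector of note texts.
#' @param spans List of span tibbles (columns `start`, `end`, `category`,
#'   `surface`; `surface` may be omitted and is then filled from `text`).
#' @param note_type Character vector of note types (recycled).
#' @return A `deid_corpus` tibble.
#' @export
deid_corpus <- function(doc_id, text, spans = NULL, note_type = "NOTE") {
  stopifnot(is.character(doc_id), is.character(text),
            length(doc_id) == length(text))
  if (anyDuplicated(doc_id))
    abort("doc_id values must be unique within a corpus")
  if (is.null(spans)) spans <- rep(list(new_span_tbl()), length(doc_id))
  stopifnot(length(spans) == length(doc_id))
  note_type <- rep_len(as.character(note_type), length(doc_id))
  spans <- lapply(seq_along(spans), function(i) {
    validate_spans(spans[[i]], text[i], doc_id[i])
  })
  out <- tibble(doc_id = doc_id, note_type = note_type, text = text,
                spans = spans)
  class(out) <- c("deid_corpus", class(out))
  out
}

#' Slice text by 0-based, half-open offsets
#'
#' The offset convention used by every span in the package: `substr0(x, s,
#' e)` returns the characters at positions `s .. e-1`.
#'
#' @param text Character vector.
#' @param start,end Integer offset vectors (0-based, end exclusive).
#' @return Character vector of slices.
#' @export
#' @examples
#' substr0("Seen 01/02/2014.", 5, 15)
substr0 <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' Validate a span table against its document text
#'
#' Checks the span invariants: `0 <= start < end <= nchar(text)`, surfaces
#' equal to the text slice, categories in the harmonized set, spans sorted by
#' start and pairwise disjoint. Returns the (sorted, surface-filled) span
#' tibble or aborts with an informative error.
#'
#' @param spans Tibble with columns `start`, `end`, `category` and optionally
#'   `surface`.
#' @param text The document text the spans annotate.
#' @param doc_id Identifier used in error messages.
#' @return The validated span tibble.
#' @export
validate_spans <- function(spans, text, doc_id = "<doc>") {
  spans <- as_tibble(spans)
  need <- c("start", "end", "category")
  if (!all(need %in% names(spans)))
    abort(paste0(doc_id, ": spans need columns ", paste(need, collapse = ", ")))
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  if (nrow(spans) == 0) return(new_span_tbl())
  n <- nchar(text)
  bad <- which(spans$start < 0L | spans$end > n | spans$start >= spans$end)
  if (length(bad) > 0)
    abort(sprintf("%s: span %d [%d,%d) out of range for text of length %d",
                  doc_id, bad[1], spans$start[bad[1]], spans$end[bad[1]], n))
  badcat <- setdiff(unique(spans$category), phi_categories())
  if (length(badcat) > 0)
    abort(paste0(doc_id, ": unharmonized categories: ",
                 paste(badcat, collapse = ", ")))
  spans <- arrange(spans, .data$start, .data$end)
  if (nrow(spans) > 1 && any(spans$start[-1] < spans$end[-nrow(spans)]))
    abort(paste0(doc_id, ": overlapping spans"))
  slice <- substr0(text, spans$start, spans$end)
  if (!"surface" %in% names(spans) || all(is.na(spans$surface))) {
    spans$surface <- slice
  } else if (any(spans$surface != slice)) {
    i <- which(spans$surface != slice)[1]
    abort(sprintf(
      "%s: surface mismatch at span [%d,%d): annotation '%s' vs text '%s'",
      doc_id, spans$start[i], spans$end[i], spans$surface[i], slice[i]))
  }
  spans[, c("start", "end", "category", "surface")]
}

#' Read a document from standoff annotation files
#'
#' Reads a plain-text note plus a companion tab-separated annotation file
#' with lines `id<TAB>category start end<TAB>surface` and returns a validated
#' one-row corpus. Offsets are 0-based, half-open. Out-of-range offsets,
#' surface mismatches and overlapping spans are rejected with errors naming
#' the offending line.
#'
#' @param text_path Path to the UTF-8 note text.
#' @param ann_path Path to the annotation file.
#' @param doc_id Document id; default the text file name without extension.
#' @param note_type Note type string.
#' @param harmonize If `TRUE`, source labels are passed through
#'   [harmonize_category()] and `DROP`ped annotations are removed.
#' @return A `deid_corpus` with one row.
#' @export
read_standoff <- function(text_path, ann_path,
                          doc_id = sub("\\.[^.]*$", "", basename(text_path)),
                          note_type = "NOTE", harmonize = FALSE) {
  if (!file.exists(text_path)) abort(paste0("no such file: ", text_path))
  if (!file.exists(ann_path)) abort(paste0("no such file: ", ann_path))
  text <- paste(readLines(text_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  spans <- new_span_tbl()
  if (length(lines) > 0) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad) > 0)
      abort(sprintf("%s: line %d: expected 'id<TAB>category start end<TAB>surface'",
                    ann_path, bad[1]))
    mid <- vapply(parts, `[[`, "", 2L)
    mp <- strsplit(trimws(mid), "[[:space:]]+")
    bad <- which(lengths(mp) != 3L)
    if (length(bad) > 0)
      abort(sprintf("%s: line %d: malformed 'category start end' field",
                    ann_path, bad[1]))
    category <- vapply(mp, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(mp, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(mp, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start < 0L | end > nchar(text) |
                   start >= end)
    if (length(bad) > 0)
      abort(sprintf("%s: line %d: offsets [%s,%s) out of range for text of length %d",
                    ann_path, bad[1], vapply(mp, `[[`, "", 2L)[bad[1]],
                    vapply(mp, `[[`, "", 3L)[bad[1]], nchar(text)))
    surface <- vapply(parts, function(p)
      if (length(p) >= 3L) p[[3L]] else NA_character_, "")
    if (harmonize) {
      category <- harmonize_category(category)
      keep <- category != "DROP"
      category <- category[keep]; start <- start[keep]; end <- end[keep]
      surface <- surface[keep]
    }
    spans <- new_span_tbl(start, end, category, surface)
  }
  deid_corpus(doc_id, text, list(spans), note_type)
}

#' Write a corpus to standoff files
#'
#' Emits, for each document, `<doc_id>.txt` and `<doc_id>.ann` (lines
#' `Tn<TAB>category start end<TAB>surface`) under `dir`. The inverse of
#' [read_standoff()].
#'
#' @param corpus A `deid_corpus`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a tibble of written paths.
#' @export
write_standoff <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map2(corpus$doc_id, seq_len(nrow(corpus)), function(id, i) {
    tp <- file.path(dir, paste0(id, ".txt"))
    ap <- file.path(dir, paste0(id, ".ann"))
    writeLines(corpus$text[i], tp, useBytes = TRUE)
    sp <- corpus$spans[[i]]
    lines <- if (nrow(sp) == 0) character() else
      sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(sp)), sp$category,
              sp$start, sp$end, sp$surface)
    writeLines(lines, ap, useBytes = TRUE)
    c(text = tp, ann = ap)
  })
  invisible(tibble(doc_id = corpus$doc_id,
                   text = vapply(paths, `[[`, "", 1L),
                   ann = vapply(paths, `[[`, "", 2L)))
}

#' Read a directory of standoff files into a corpus
#'
#' @param dir Directory holding paired `*.txt` / `*.ann` files.
#' @inheritParams read_standoff
#' @return A `deid_corpus`.
#' @export
read_standoff_dir <- function(dir, harmonize = FALSE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txts) == 0) abort(paste0("no .txt files under ", dir))
  docs <- lapply(txts, function(tp) {
    ap <- sub("\\.txt$", ".ann", tp)
    if (!file.exists(ap)) abort(paste0("missing annotation file: ", ap))
    read_standoff(tp, ap, harmonize = harmonize)
  })
  out <- bind_rows(docs)
  class(out) <- c("deid_corpus", class(out))
  out
}

#' Concatenate two corpora
#'
#' Joins two corpora into one, the merge-and-retrain route of cross-institute
#' customization. Colliding document ids in `b` are suffixed so counts are
#' preserved; shuffling is left to the (seeded) trainer.
#'
#' @param a,b `deid_corpus` tibbles.
#' @return A `deid_corpus` with `nrow(a) + nrow(b)` documents.
#' @export
merge_corpora <- function(a, b) {
  if (is.null(b) || nrow(b) == 0) return(a)
  if (is.null(a) || nrow(a) == 0) return(b)
  clash <- b$doc_id %in% a$doc_id
  if (any(clash)) {
    b$doc_id[clash] <- paste0(b$doc_id[clash], "_b")
    while (any(b$doc_id %in% a$doc_id) || anyDuplicated(b$doc_id)) {
      clash2 <- b$doc_id %in% a$doc_id | duplicated(b$doc_id)
      b$doc_id[clash2] <- paste0(b$doc_id[clash2], "x")
    }
  }
  out <- bind_rows(a, b)
  class(out) <- c("deid_corpus", setdiff(class(out), "deid_corpus"))
  out
}
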