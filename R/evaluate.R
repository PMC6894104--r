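# Strict/relaxed span matching, precision/recall/F1, and the four-way error
# taxonomy (boundary mismatch, wrong category, false positive, false
# negative).

# Maximum bipartite matching by augmenting paths. `adj` is a list: for each
# left node, the integer vector of compatible right nodes, ordered by
# preference (largest overlap first). Left nodes are processed in order
# (gold spans left-to-right).
max_bipartite_matching <- function(adj, n_right) {
  match_r <- rep(NA_integer_, n_right)
  aug <- function(l, st) {
    for (r in adj[[l]]) {
      if (st$visited[r]) next
      st$visited[r] <- TRUE
      if (is.na(match_r[r]) || aug(match_r[r], st)) {
        match_r[r] <<- l
        return(TRUE)
      }
    }
    FALSE
  }
  for (l in seq_along(adj)) {
    st <- new.env(parent = emptyenv())
    st$visited <- rep(FALSE, n_right)
    aug(l, st)
  }
  match_r
}

overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

check_span_list <- function(spans, what) {
  spans <- as_tibble(spans)
  if (!"doc_id" %in% names(spans)) spans$doc_id <- "doc1"
  if (nrow(spans) == 0) return(spans)
  spans <- arrange(spans, .data$doc_id, .data$start, .data$end)
  by_doc <- split(seq_len(nrow(spans)), spans$doc_id)
  for (ix in by_doc) {
    s <- spans$start[ix]; e <- spans$end[ix]
    if (length(ix) > 1 && any(s[-1] < e[-length(e)]))
      abort(paste0("overlapping spans within the ", what, " list"))
  }
  spans
}

#' Match predicted against gold spans
#'
#' Counts true positives, false positives and false negatives per category.
#' In `strict` mode a prediction matches only with identical offsets and
#' category; in `relax` mode at least one character of overlap with the same
#' category suffices. Matching is one-to-one: pairs are resolved by exact
#' maximum bipartite matching, processing gold spans left-to-right with
#' largest-overlap preference, so the counts equal the optimal assignment.
#'
#' @param gold,pred Span tibbles (`start`, `end`, `category`, optionally
#'   `doc_id`).
#' @param mode `"strict"` or `"relax"`.
#' @return A tibble of `category`, `tp`, `fp`, `fn` (one row per category in
#'   the ten-category inventory).
#' @export
match_spans <- function(gold, pred, mode = c("strict", "relax")) {
  mode <- match.arg(mode)
  gold <- check_span_list(gold, "gold")
  pred <- check_span_list(pred, "predicted")
  cats <- phi_categories()
  out <- tibble(category = cats, tp = 0L, fp = 0L, fn = 0L)
  docs <- union(unique(gold$doc_id), unique(pred$doc_id))
  for (d in docs) {
    g <- gold[gold$doc_id == d, , drop = FALSE]
    p <- pred[pred$doc_id == d, , drop = FALSE]
    for (ci in seq_along(cats)) {
      gc <- g[g$category == cats[ci], , drop = FALSE]
      pc <- p[p$category == cats[ci], , drop = FALSE]
      if (nrow(gc) == 0 && nrow(pc) == 0) next
      tp <- 0L
      if (nrow(gc) > 0 && nrow(pc) > 0) {
        if (mode == "strict") {
          tp <- sum(!is.na(match(paste(gc$start, gc$end),
                                 paste(pc$start, pc$end))))
        } else {
          adj <- lapply(seq_len(nrow(gc)), function(i) {
            ov <- overlap_len(gc$start[i], gc$end[i], pc$start, pc$end)
            cand <- which(ov > 0L)
            cand[order(-ov[cand], pc$start[cand])]
          })
          tp <- sum(!is.na(max_bipartite_matching(adj, nrow(pc))))
        }
      }
      out$tp[ci] <- out$tp[ci] + tp
      out$fp[ci] <- out$fp[ci] + nrow(pc) - tp
      out$fn[ci] <- out$fn[ci] + nrow(gc) - tp
    }
  }
  out
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2PR/(P+R)`, with the `0/0 -> 0` convention for the
#' degenerate case.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from match counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`, each with the
#' `0/0 -> 0` convention. When the input has a `category` column, a pooled
#' `micro` row is appended: micro-averaging sums the counts over categories
#' before dividing.
#'
#' @param counts A tibble with columns `tp`, `fp`, `fn` and optionally
#'   `category` (from [match_spans()]).
#' @return The input plus `precision`, `recall`, `f1` columns (and a `micro`
#'   row when per-category).
#' @export
compute_prf <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0))
    abort("negative match counts")
  if ("category" %in% names(counts)) {
    micro <- tibble(category = "micro", tp = sum(counts$tp),
                    fp = sum(counts$fp), fn = sum(counts$fn))
    counts <- bind_rows(counts, micro)
  }
  counts$precision <- ifelse(counts$tp + counts$fp == 0, 0,
                             counts$tp / (counts$tp + counts$fp))
  counts$recall <- ifelse(counts$tp + counts$fn == 0, 0,
                          counts$tp / (counts$tp + counts$fn))
  counts$f1 <- f1_score(counts$precision, counts$recall)
  counts
}

#' Classify prediction errors into the four-way taxonomy
#'
#' Pairs gold and predicted spans and assigns each non-correct span exactly
#' one class: an overlapping pair with the same category but different
#' offsets is a `boundary_mismatch`; an overlapping pair with different
#' categories is a `wrong_category`; a prediction overlapping no gold span
#' is a `false_positive`; a gold span overlapped by no prediction is a
#' `false_negative`. Exact matches (same offsets and category) are correct
#' and excluded. Same-category pairs are preferred when resolving overlaps.
#'
#' @inheritParams match_spans
#' @return A tibble with columns `boundary_mismatch`, `wrong_category`,
#'   `false_positive`, `false_negative`.
#' @export
classify_errors <- function(gold, pred) {
  gold <- check_span_list(gold, "gold")
  pred <- check_span_list(pred, "predicted")
  bm <- wc <- fp <- fn <- 0L
  docs <- union(unique(gold$doc_id), unique(pred$doc_id))
  for (d in docs) {
    g <- gold[gold$doc_id == d, , drop = FALSE]
    p <- pred[pred$doc_id == d, , drop = FALSE]
    g_free <- rep(TRUE, nrow(g)); p_free <- rep(TRUE, nrow(p))
    # stage 1: exact matches are correct, not errors
    if (nrow(g) > 0 && nrow(p) > 0) {
      keyg <- paste(g$start, g$end, g$category)
      keyp <- paste(p$start, p$end, p$category)
      hit <- match(keyg, keyp)
      ok <- !is.na(hit)
      g_free[ok] <- FALSE
      p_free[hit[ok]] <- FALSE
    }
    # stage 2: same-category overlaps -> boundary mismatch
    gi <- which(g_free); pi <- which(p_free)
    if (length(gi) > 0 && length(pi) > 0) {
      adj <- lapply(gi, function(i) {
        ov <- overlap_len(g$start[i], g$end[i], p$start[pi], p$end[pi])
        cand <- which(ov > 0L & p$category[pi] == g$category[i])
        cand[order(-ov[cand])]
      })
      mr <- max_bipartite_matching(adj, length(pi))
      matched_r <- which(!is.na(mr))
      bm <- bm + length(matched_r)
      p_free[pi[matched_r]] <- FALSE
      g_free[gi[mr[matched_r]]] <- FALSE
    }
    # stage 3: remaining overlaps -> wrong category
    gi <- which(g_free); pi <- which(p_free)
    if (length(gi) > 0 && length(pi) > 0) {
      adj <- lapply(gi, function(i) {
        ov <- overlap_len(g$start[i], g$end[i], p$start[pi], p$end[pi])
        cand <- which(ov > 0L)
        cand[order(-ov[cand])]
      })
      mr <- max_bipartite_matching(adj, length(pi))
      matched_r <- which(!is.na(mr))
      wc <- wc + length(matched_r)
      p_free[pi[matched_r]] <- FALSE
      g_free[gi[mr[matched_r]]] <- FALSE
    }
    fp <- fp + sum(p_free)
    fn <- fn + sum(g_free)
  }
  tibble(boundary_mismatch = bm, wrong_category = wc,
         false_positive = fp, false_negative = fn)
}

#' Evaluate predictions over a corpus
#'
#' Pools match counts over all documents and reports per-category and
#' micro-averaged precision/recall/F1 in both strict and relaxed modes,
#' plus the four-way error taxonomy.
#'
#' @param gold A `deid_corpus` with gold spans, or a span tibble with
#'   `doc_id`.
#' @param pred Predicted spans with `doc_id` (from [predict.deid_model()]).
#' @return A `deid_eval` object (list of tibbles `strict`, `relax`,
#'   `taxonomy`) with [tidy()], [glance()] and [autoplot()] methods.
#' @export
evaluate_corpus <- function(gold, pred) {
  if (inherits(gold, "deid_corpus") ||
      (is.data.frame(gold) && "spans" %in% names(gold))) {
    gold_ids <- gold$doc_id
    gold <- tidyr::unnest(gold[, c("doc_id", "spans")], "spans")
  } else {
    gold <- as_tibble(gold)
    gold_ids <- unique(gold$doc_id)
  }
  pred <- as_tibble(pred)
  if (!"doc_id" %in% names(pred)) pred$doc_id <- gold_ids[1]
  stray <- setdiff(unique(pred$doc_id), gold_ids)
  if (length(stray) > 0)
    abort(paste0("predictions for unknown doc_id(s): ",
                 paste(stray, collapse = ", ")))
  strict <- compute_prf(match_spans(gold, pred, "strict"))
  relax <- compute_prf(match_spans(gold, pred, "relax"))
  taxonomy <- classify_errors(gold, pred)
  structure(list(strict = strict, relax = relax, taxonomy = taxonomy,
                 n_docs = length(gold_ids)),
            class = "deid_eval")
}

#' @export
print.deid_eval <- function(x, ...) {
  ms <- x$strict[x$strict$category == "micro", ]
  mr <- x$relax[x$relax$category == "micro", ]
  cat(sprintf("<deid_eval over %d documents>\n", x$n_docs))
  cat(sprintf("  strict micro P/R/F1: %.4f / %.4f / %.4f\n",
              ms$precision, ms$recall, ms$f1))
  cat(sprintf("  relax  micro P/R/F1: %.4f / %.4f / %.4f\n",
              mr$precision, mr$recall, mr$f1))
  cat("  errors:", paste(names(x$taxonomy), unlist(x$taxonomy),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.deid_eval <- function(x, ...) {
  bind_rows(mutate(x$strict, mode = "strict"),
            mutate(x$relax, mode = "relax"))
}

#' @rdname tidy
#' @export
glance.deid_eval <- function(x, ...) {
  ms <- x$strict[x$strict$category == "micro", ]
  mr <- x$relax[x$relax$category == "micro", ]
  tibble(strict_precision = ms$precision, strict_recall = ms$recall,
         strict_f1 = ms$f1, relax_precision = mr$precision,
         relax_recall = mr$recall, relax_f1 = mr$f1,
         boundary_mismatch = x$taxonomy$boundary_mismatch,
         wrong_category = x$taxonomy$wrong_category,
         false_positive = x$taxonomy$false_positive,
         false_negative = x$taxonomy$false_negative)
}

#' Write a machine-readable evaluation report
#'
#' @param eval A `deid_eval`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(eval, path) {
  stopifnot(inherits(eval, "deid_eval"))
  jsonlite::write_json(
    list(strict = eval$strict, relax = eval$relax,
         taxonomy = as.list(eval$taxonomy), n_docs = eval$n_docs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
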