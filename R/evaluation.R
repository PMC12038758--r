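# Evaluation: strict- and soft-boundary span pairing, note-level confusion,
# precision/recall/F, AUC-ROC, inter-annotator agreement.

#' Construct a match-count record
#'
#' @param tp,fp,fn True positive, false positive and false negative counts.
#' @param tn True negative count; `NA` for span-level tasks, which have no
#'   notion of a true negative span.
#' @return A one-row tibble of class `prom_match_counts`.
#' @export
match_counts <- function(tp, fp, fn, tn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, is.na(tn) || tn >= 0)
  structure(
    tibble::tibble(
      tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn)
    ),
    class = c("prom_match_counts", "tbl_df", "tbl", "data.frame")
  )
}

prep_span_sets <- function(gold, pred) {
  need <- c("start", "end", "prom_id")
  stopifnot_cols(gold, need, "gold")
  stopifnot_cols(pred, need, "pred")
  has_note <- "note_id" %in% names(gold) || "note_id" %in% names(pred)
  if (has_note) {
    if (!("note_id" %in% names(gold)) || !("note_id" %in% names(pred))) {
      abort("note_id must be present in both span sets or neither")
    }
  } else {
    gold$note_id <- "note"
    pred$note_id <- "note"
  }
  list(gold = gold, pred = pred)
}

#' Strict-boundary span pairing
#'
#' A predicted span counts as a true positive only when its start, end and
#' PROM attribute all equal a gold span's, paired one-to-one. Unmatched gold
#' spans are false negatives; unmatched predictions are false positives.
#'
#' @param gold,pred Span tibbles with `start`, `end`, `prom_id` and
#'   optionally `note_id` (pairing is within note when present).
#' @return A [match_counts()] record (no true negatives at span level).
#' @export
pair_spans_strict <- function(gold, pred) {
  s <- prep_span_sets(gold, pred)
  key <- function(d) paste(d$note_id, d$start, d$end, d$prom_id, sep = "\r")
  gk <- table(key(s$gold))
  pk <- table(key(s$pred))
  shared <- intersect(names(gk), names(pk))
  tp <- sum(pmin(gk[shared], pk[shared]))
  match_counts(tp = tp, fp = nrow(s$pred) - tp, fn = nrow(s$gold) - tp)
}

#' Soft-boundary span pairing
#'
#' A gold/predicted pair matches when their character ranges overlap by at
#' least `min_overlap` positions and their PROM attributes agree. Pairing is
#' one-to-one and maximises the number of matches: candidate pairs are taken
#' greedily by overlap length (ties by earliest gold start) and the pairing
#' is then completed by augmenting paths, so the result equals the
#' maximum bipartite matching.
#'
#' @inheritParams pair_spans_strict
#' @param min_overlap Minimum character overlap for a candidate pair
#'   (default 1).
#' @return A [match_counts()] record.
#' @export
pair_spans_soft <- function(gold, pred, min_overlap = 1L) {
  s <- prep_span_sets(gold, pred)
  notes <- union(unique(s$gold$note_id), unique(s$pred$note_id))
  tp <- 0L
  for (nid in notes) {
    g <- s$gold[s$gold$note_id == nid, ]
    p <- s$pred[s$pred$note_id == nid, ]
    tp <- tp + soft_match_size(g, p, min_overlap)
  }
  match_counts(tp = tp, fp = nrow(s$pred) - tp, fn = nrow(s$gold) - tp)
}

# Maximum one-to-one matching size between gold and pred spans of one note.
soft_match_size <- function(g, p, min_overlap = 1L) {
  if (nrow(g) == 0 || nrow(p) == 0) return(0L)
  edges <- NULL
  for (i in seq_len(nrow(g))) {
    ov <- pmin(g$end[i], p$end) - pmax(g$start[i], p$start)
    ok <- which(ov >= min_overlap & p$prom_id == g$prom_id[i])
    if (length(ok) > 0) {
      edges <- rbind(edges, cbind(i, ok, ov[ok]))
    }
  }
  if (is.null(edges)) return(0L)
  edges <- edges[order(-edges[, 3], g$start[edges[, 1]]), , drop = FALSE]
  # Greedy seed in the documented order...
  match_g <- rep(NA_integer_, nrow(g))
  match_p <- rep(NA_integer_, nrow(p))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (is.na(match_g[i]) && is.na(match_p[j])) {
      match_g[i] <- j
      match_p[j] <- i
    }
  }
  # ...then complete to a maximum matching by augmenting paths.
  adj <- split(edges[, 2], edges[, 1])
  try_augment <- function(i, visited) {
    for (j in adj[[as.character(i)]]) {
      if (!visited[j]) {
        visited[j] <- TRUE
        if (is.na(match_p[j]) ||
            Recall(match_p[j], visited)$found) {
          match_p[j] <<- i
          match_g[i] <<- j
          return(list(found = TRUE))
        }
      }
    }
    list(found = FALSE)
  }
  for (i in which(is.na(match_g))) {
    if (!is.null(adj[[as.character(i)]])) {
      try_augment(i, rep(FALSE, nrow(p)))
    }
  }
  sum(!is.na(match_g))
}

#' Note-level confusion counts
#'
#' Compares gold and predicted binary "documented PROM use" labels note by
#' note.
#'
#' @param gold,pred Data frames with `visit_id` and a logical `label` column
#'   (for convenience, `gold_label` or `prom_positive` are also recognised).
#' @return A [match_counts()] record including true negatives.
#' @export
note_confusion <- function(gold, pred) {
  pick_label <- function(d, what) {
    for (col in c("label", "gold_label", "prom_positive")) {
      if (col %in% names(d)) {
        return(tibble::tibble(visit_id = d$visit_id, label = as.logical(d[[col]])))
      }
    }
    abort(sprintf("%s needs a label column (label/gold_label/prom_positive)", what))
  }
  g <- pick_label(gold, "gold")
  p <- pick_label(pred, "pred")
  if (!setequal(g$visit_id, p$visit_id) || nrow(g) != nrow(p)) {
    abort("id mismatch: gold and pred must cover the same visit_ids")
  }
  j <- dplyr::inner_join(g, p, by = "visit_id", suffix = c("_gold", "_pred"))
  match_counts(
    tp = sum(j$label_gold & j$label_pred),
    fp = sum(!j$label_gold & j$label_pred),
    fn = sum(j$label_gold & !j$label_pred),
    tn = sum(!j$label_gold & !j$label_pred)
  )
}

#' Precision, recall, F-measure (and accuracy) from match counts
#'
#' All metrics are reported as percentages in `[0, 100]`. When a denominator
#' is zero (no predicted positives, or no gold positives), the affected
#' metric is reported as 0 with a structured warning of class
#' `promnlp_zero_denominator`.
#'
#' @param counts A [match_counts()] record (or any one-row data frame / named
#'   list with `tp`, `fp`, `fn` and optionally `tn`).
#' @return A one-row tibble of class `prom_eval` with the counts plus
#'   `precision`, `recall`, `f_measure` and `accuracy` (`NA` without `tn`).
#' @export
precision_recall_f <- function(counts) {
  ct <- as.list(counts)
  tp <- ct$tp; fp <- ct$fp; fn <- ct$fn
  tn <- ct$tn %||% NA_integer_
  zero_warn <- function(which) {
    warn(
      sprintf("%s undefined (zero denominator); reported as 0", which),
      class = "promnlp_zero_denominator"
    )
  }
  precision <- if (tp + fp == 0) { zero_warn("precision"); 0 } else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0) { zero_warn("recall"); 0 } else 100 * tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  total <- tp + fp + fn + ifelse(is.na(tn), 0L, tn)
  accuracy <- if (!is.na(tn) && total > 0) 100 * (tp + tn) / total else NA_real_
  structure(
    tibble::tibble(
      tp = tp, fp = fp, fn = fn, tn = tn,
      precision = precision, recall = recall,
      f_measure = f, accuracy = accuracy
    ),
    class = c("prom_eval", "tbl_df", "tbl", "data.frame")
  )
}

#' F-measure from a precision/recall pair
#'
#' Harmonic mean `2PR/(P+R)` of two percentages, reported to one decimal —
#' the convention used for printed evaluation tables.
#'
#' @param precision,recall Percentages in `[0, 100]` (vectorised).
#' @return F-measure percentage(s), rounded to one decimal.
#' @export
f_from_pr <- function(precision, recall) {
  if (any(precision < 0 | precision > 100 | recall < 0 | recall > 100,
          na.rm = TRUE)) {
    abort("precision and recall must be percentages in [0, 100]")
  }
  out <- numeric(length(precision))
  zero <- (precision + recall) == 0
  if (any(zero)) {
    warn("F-measure undefined when precision and recall are both 0; reported as 0",
         class = "promnlp_zero_denominator")
  }
  out[!zero] <- 2 * precision[!zero] * recall[!zero] /
    (precision[!zero] + recall[!zero])
  round(out, 1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability of the score
#' ranking, with ties counted half, and reported as a percentage.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1); both classes must be present.
#' @return AUC-ROC as a percentage.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC-ROC")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  100 * auc
}

#' Inter-annotator agreement between two span sets
#'
#' Agreement is summarised as the F-measure of a soft-boundary,
#' attribute-constrained pairing of the two annotators' spans (symmetric in
#' the two annotators by construction of F). Notes present for one annotator
#' but not the other are treated as annotated empty.
#'
#' @param a_spans,b_spans Span tibbles with `note_id`, `start`, `end`,
#'   `prom_id`.
#' @param a_name,b_name Annotator labels for the output.
#' @return A one-row tibble with `annotator_a`, `annotator_b`, `iaa_percent`
#'   and `n_notes`.
#' @export
interannotator_agreement <- function(a_spans, b_spans, a_name = "A", b_name = "B") {
  stopifnot_cols(a_spans, c("note_id", "start", "end", "prom_id"), "a_spans")
  stopifnot_cols(b_spans, c("note_id", "start", "end", "prom_id"), "b_spans")
  notes_a <- unique(a_spans$note_id)
  notes_b <- unique(b_spans$note_id)
  if (length(notes_a) > 0 && length(notes_b) > 0 &&
      length(intersect(notes_a, notes_b)) == 0) {
    abort("disjoint note sets: the annotators share no notes")
  }
  counts <- pair_spans_soft(a_spans, b_spans)
  f <- if (counts$tp + counts$fp == 0 || counts$tp + counts$fn == 0) {
    if (counts$tp + counts$fp + counts$fn == 0) 100 else 0
  } else {
    p <- 100 * counts$tp / (counts$tp + counts$fp)
    r <- 100 * counts$tp / (counts$tp + counts$fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  tibble::tibble(
    annotator_a = a_name,
    annotator_b = b_name,
    iaa_percent = f,
    n_notes = length(union(notes_a, notes_b))
  )
}
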