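test_that("strict pairing requires identical offsets and attribute", {
  gold <- tibble::tibble(start = c(10L, 40L), end = c(20L, 55L),
                         prom_id = c("odi", "ndi"))
  same <- pair_spans_strict(gold, gold)
  expect_equal(same$tp, 2)
  expect_equal(same$fp, 0)
  expect_equal(same$fn, 0)

  # same offsets, different attribute: both a miss and a false alarm
  wrong_attr <- dplyr::mutate(gold[1, ], prom_id = "ndi")
  res <- pair_spans_strict(gold[1, ], wrong_attr)
  expect_equal(c(res$tp, res$fp, res$fn), c(0, 1, 1))

  shifted <- dplyr::mutate(gold[1, ], start = start + 1L, end = end + 1L)
  res2 <- pair_spans_strict(gold[1, ], shifted)
  expect_equal(c(res2$tp, res2$fp, res2$fn), c(0, 1, 1))
})

test_that("soft pairing accepts any overlap with matching attribute", {
  gold <- tibble::tibble(start = 10L, end = 35L, prom_id = "odi")
  contained <- tibble::tibble(start = 10L, end = 38L, prom_id = "odi")
  expect_equal(pair_spans_soft(gold, contained)$tp, 1)

  disjoint <- tibble::tibble(start = 40L, end = 50L, prom_id = "odi")
  res <- pair_spans_soft(gold, disjoint)
  expect_equal(c(res$tp, res$fp, res$fn), c(0, 1, 1))

  # two gold spans vs one prediction overlapping both: one-to-one pairing
  gold2 <- tibble::tibble(start = c(0L, 12L), end = c(10L, 20L),
                          prom_id = "odi")
  wide <- tibble::tibble(start = 5L, end = 15L, prom_id = "odi")
  res2 <- pair_spans_soft(gold2, wide)
  expect_equal(c(res2$tp, res2$fn), c(1, 1))
})

test_that("soft pairing equals brute-force maximum matching (<= 6 spans)", {
  set.seed(47)
  for (rep in 1:120) {
    gold <- random_span_set(sample(0:6, 1))
    pred <- random_span_set(sample(0:6, 1))
    got <- pair_spans_soft(gold, pred)$tp
    expect_equal(got, oracle_max_matching(gold, pred),
                 info = paste("rep", rep))
  }
})

test_that("relaxing boundaries never lowers tp, precision or recall", {
  set.seed(53)
  for (rep in 1:60) {
    gold <- random_span_set(sample(1:6, 1))
    pred <- random_span_set(sample(1:6, 1))
    strict <- pair_spans_strict(gold, pred)
    soft <- pair_spans_soft(gold, pred)
    expect_gte(soft$tp, strict$tp)
    ms <- suppressWarnings(precision_recall_f(strict))
    mf <- suppressWarnings(precision_recall_f(soft))
    expect_gte(mf$precision, ms$precision)
    expect_gte(mf$recall, ms$recall)
  }
})

test_that("note confusion counts match a brute-force tally", {
  set.seed(59)
  ids <- sprintf("V%03d", 1:80)
  g <- tibble::tibble(visit_id = ids, label = runif(80) < 0.3)
  p <- tibble::tibble(visit_id = sample(ids), label = runif(80) < 0.5)
  res <- note_confusion(g, p)
  merged <- merge(g, p, by = "visit_id")
  expect_equal(res$tp, sum(merged$label.x & merged$label.y))
  expect_equal(res$fp, sum(!merged$label.x & merged$label.y))
  expect_equal(res$fn, sum(merged$label.x & !merged$label.y))
  expect_equal(res$tn, sum(!merged$label.x & !merged$label.y))
  expect_equal(res$tp + res$fp + res$fn + res$tn, 80)

  expect_error(note_confusion(g, p[1:40, ]), "id mismatch")
})

test_that("precision/recall/F formulas and degenerate conventions", {
  m <- precision_recall_f(match_counts(tp = 1, fp = 1, fn = 0))
  expect_equal(m$precision, 50)
  expect_equal(m$recall, 100)
  expect_equal(m$f_measure, 2 * 50 * 100 / 150)

  w <- testthat::capture_warnings(z <- precision_recall_f(match_counts(0, 0, 0)))
  expect_length(w, 2)  # precision and recall are each flagged
  expect_match(w, "undefined", all = TRUE)
  expect_equal(c(z$precision, z$recall, z$f_measure), c(0, 0, 0))

  # F bounds and zero law on random counts
  set.seed(61)
  for (rep in 1:50) {
    cts <- match_counts(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    m <- suppressWarnings(precision_recall_f(cts))
    expect_gte(m$f_measure, min(m$precision, m$recall))
    expect_lte(m$f_measure, max(m$precision, m$recall) + 1e-9)
    expect_equal(m$f_measure == 0, cts$tp == 0)
  }

  acc <- precision_recall_f(match_counts(40, 5, 2, 53))
  expect_equal(acc$accuracy, 93)
})

test_that("f_from_pr matches the harmonic-mean identity", {
  expect_warning(expect_equal(f_from_pr(0, 0), 0),
                 class = "promnlp_zero_denominator")
  for (x in c(0.1, 12.5, 50, 81.1, 100)) {
    expect_equal(f_from_pr(x, x), round(x, 1))
  }
  expect_error(f_from_pr(101, 50), "\\[0, 100\\]")
})

test_that("rank-based AUC equals the all-pairs concordance oracle", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 100)
  expect_error(auc_roc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(67)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- runif(n) < 0.5
    if (sum(labels) == 0 || sum(!labels) == 0) next
    expect_equal(auc_roc(scores, labels), oracle_auc(scores, labels))
  }

  # independent scores: AUC near 50
  set.seed(71)
  scores <- runif(2000)
  labels <- runif(2000) < 0.5
  expect_lt(abs(auc_roc(scores, labels) - 50), 3)
})

test_that("inter-annotator agreement is symmetric and bounded", {
  a <- tibble::tibble(note_id = c("n1", "n1", "n2"),
                      start = c(0L, 20L, 5L), end = c(10L, 30L, 9L),
                      prom_id = c("odi", "ndi", "odi"))
  expect_equal(interannotator_agreement(a, a)$iaa_percent, 100)

  b_empty <- a[0, ]
  expect_equal(suppressWarnings(interannotator_agreement(a, b_empty))$iaa_percent, 0)

  b <- dplyr::mutate(a, start = start + 2L, end = end + 2L)
  ab <- interannotator_agreement(a, b)
  ba <- interannotator_agreement(b, a)
  expect_equal(ab$iaa_percent, ba$iaa_percent)
  expect_gte(ab$iaa_percent, 0)
  expect_lte(ab$iaa_percent, 100)

  disjoint <- dplyr::mutate(a, note_id = paste0("x", note_id))
  expect_error(interannotator_agreement(a, disjoint), "disjoint")
})
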