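test_that("merging notes preserves text, order and length accounting", {
  one <- tiny_raw_notes()[1, ]
  one$text <- "SOAP text"
  merged <- merge_visit_notes(one)
  expect_equal(merged$body, "SOAP text")
  expect_equal(stringr::str_count(merged$body, stringr::fixed(note_delimiter())), 0)

  # length conservation: len(body) = sum(len) + (k-1) * len(delimiter)
  two <- tiny_raw_notes()[1:2, ]
  two$text <- c(strrep("a", 100), strrep("b", 50))
  delim <- strrep("#", 5)
  merged <- merge_visit_notes(two, delimiter = delim)
  expect_equal(nchar(merged$body), 155)
  expect_equal(stringr::str_count(merged$body, stringr::fixed(delim)), 1)
  # service-order then note_id order is recorded
  expect_equal(merged$source_note_ids[[1]], c("N1", "N2"))

  set.seed(41)
  for (k in 2:5) {
    notes <- tiny_raw_notes()[rep(1, k), ]
    notes$note_id <- sprintf("N%02d", seq_len(k))
    notes$text <- vapply(sample(3:40, k), function(n) strrep("x", n), "")
    m <- merge_visit_notes(notes, delimiter = "<|>")
    expect_equal(nchar(m$body), sum(nchar(notes$text)) + (k - 1) * 3)
  }
})

test_that("merging rejects empty input and mixed visits", {
  expect_error(merge_visit_notes(tiny_raw_notes()[0, ]), "no notes")
  mixed <- tiny_raw_notes()
  mixed$visit_id <- c("V1", "V1", "V2")
  expect_error(merge_visit_notes(mixed), "visit mismatch")
})

test_that("metadata headers carry the visit position phrase and round-trip", {
  v <- tiny_visit()
  header <- build_metadata_header(v)
  expect_match(header, "visit 3 of 6", fixed = TRUE)
  expect_match(header, header_delimiter(), fixed = TRUE)

  parsed <- parse_metadata_header(header)
  for (f in names(v)) {
    expect_equal(parsed[[f]], v[[f]], info = f)
  }

  # first visit: no days-since-previous field
  v1 <- tiny_visit()
  v1$visit_index <- 1L
  v1$days_since_prev <- NA_integer_
  h1 <- build_metadata_header(v1)
  expect_false(grepl("days_since_prev", h1))
  expect_true(is.na(parse_metadata_header(h1)$days_since_prev))
})

test_that("visit categories are exclusive, exhaustive and precedence-ordered", {
  d0 <- as.Date("2018-01-01")
  mk <- function(dates) {
    tibble::tibble(patient_id = "P1", service_date = dates)
  }

  single <- assign_visit_categories(mk(d0))
  expect_equal(as.character(single$category), "FIRST_CONSULT")

  gapped <- assign_visit_categories(mk(d0 + c(0, 10, 75, 90)))
  expect_equal(
    as.character(gapped$category),
    c("FIRST_CONSULT", "PRE_GAP", "POST_GAP", "FINAL_WITHIN_YEAR")
  )

  plain <- assign_visit_categories(mk(d0 + c(0, 7, 14)))
  expect_equal(
    as.character(plain$category),
    c("FIRST_CONSULT", "INTERMEDIATE", "FINAL_WITHIN_YEAR")
  )

  expect_error(assign_visit_categories(mk(d0)[0, ]), "empty")
  expect_error(assign_visit_categories(mk(d0 + c(5, 0))), "sorted")

  # property: exactly one category each; every >gap interval flanked by
  # pre/post visits unless overridden by first/final precedence
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    intervals <- sample(c(3:20, 70:90), n - 1, replace = TRUE)
    visits <- suppressWarnings(
      assign_visit_categories(mk(d0 + c(0, cumsum(intervals))))
    )
    expect_equal(sum(table(visits$category)), n)
    expect_false(anyNA(visits$category))
    gaps <- which(intervals > 60)
    for (g in gaps) {
      expect_true(as.character(visits$category[g]) %in%
                    c("PRE_GAP", "FIRST_CONSULT"))
      # PRE_GAP outranks POST_GAP, so a visit between two long gaps
      # keeps the pre-gap label
      expect_true(as.character(visits$category[g + 1]) %in%
                    c("POST_GAP", "FINAL_WITHIN_YEAR", "PRE_GAP"))
    }
  }
})

test_that("gap threshold is strict and configurable", {
  d0 <- as.Date("2018-01-01")
  v <- tibble::tibble(patient_id = "P1", service_date = d0 + c(0, 30, 90, 100))
  # 60-day interval exactly: not a gap under the strict-> rule
  expect_equal(as.character(assign_visit_categories(v)$category[2]),
               "INTERMEDIATE")
  # smaller threshold turns it into one
  expect_equal(as.character(assign_visit_categories(v, gap_days = 59)$category[2]),
               "PRE_GAP")
})

test_that("whitespace token counts match an independent split-and-count oracle", {
  expect_equal(whitespace_token_count(""), 0L)
  expect_equal(whitespace_token_count("a  b\tc\n"), 3L)
  expect_equal(whitespace_token_count("   "), 0L)

  set.seed(11)
  pieces <- c("alpha", "b", "gamma42", "x-y", "...")
  gaps <- c(" ", "  ", "\t", "\n", " \n ")
  texts <- replicate(40, {
    n <- sample(0:30, 1)
    if (n == 0) return("")
    paste0(
      paste(sample(pieces, n, replace = TRUE),
            sample(gaps, n, replace = TRUE), sep = "", collapse = ""),
      ""
    )
  })
  expect_equal(whitespace_token_count(texts), oracle_token_count(texts))
})

test_that("stratified sampling balances categories and maximises facilities", {
  set.seed(3)
  corpus <- tibble::tibble(
    visit_id = sprintf("V%04d", 1:500),
    category = sample(visit_categories(), 500, replace = TRUE),
    facility_id = sample(sprintf("F%02d", 1:30), 500, replace = TRUE)
  )
  ids <- stratified_annotation_sample(corpus, n = 300, seed = 5)
  expect_equal(length(ids), 300)
  counts <- table(corpus$category[match(ids, corpus$visit_id)])
  expect_lte(max(counts) - min(counts), 1)

  # determinism
  expect_identical(ids, stratified_annotation_sample(corpus, n = 300, seed = 5))

  # undersized corpus: everything returned, with a warning
  expect_warning(
    small <- stratified_annotation_sample(corpus[1:10, ], n = 300, seed = 5),
    "returning all"
  )
  expect_setequal(small, corpus$visit_id[1:10])

  expect_error(stratified_annotation_sample(corpus, n = 0, seed = 1), "positive")

  # facility coverage: facilities B and C are rare, so a single draw usually
  # misses one; repeated draws keep the one covering all three facilities
  toy <- tibble::tibble(
    visit_id = sprintf("T%02d", 1:40),
    category = rep(c("FIRST_CONSULT", "INTERMEDIATE"), each = 20),
    facility_id = c("B", rep("A", 19), "C", rep("A", 19))
  )
  picked <- stratified_annotation_sample(toy, n = 6, seed = 2, draws = 300)
  expect_equal(dplyr::n_distinct(toy$facility_id[match(picked, toy$visit_id)]), 3)
})

test_that("group length comparison: omnibus, pairwise count and Bonferroni", {
  # five identically distributed groups: no evidence of difference
  same <- tibble::tibble(
    group = rep(letters[1:5], each = 20),
    tokens = rep(1:20, times = 5)
  )
  res <- compare_group_lengths(same, group, tokens)
  expect_gt(glance(res)$p_value, 0.99)
  expect_equal(sum(tidy(res)$significant), 0)
  expect_equal(res$n_comparisons, 10)  # k(k-1)/2 for k = 5

  # two well-separated shifted groups
  set.seed(9)
  shifted <- tibble::tibble(
    group = rep(c("lo", "hi"), each = 200),
    tokens = c(rnorm(200, 100, 10), rnorm(200, 130, 10))
  )
  res2 <- compare_group_lengths(shifted, group, tokens)
  expect_lt(glance(res2)$p_value, 0.001)
  expect_true(all(tidy(res2)$significant))

  expect_error(
    compare_group_lengths(same[c(1, 21:100), ], group, tokens),
    "at least 2 observations"
  )
  expect_error(
    compare_group_lengths(same[1:20, ], group, tokens),
    "at least 2 groups"
  )
})

test_that("prepare_corpus yields one categorised, headed note per visit", {
  raw <- tibble::tibble(
    note_id = c("N1", "N2", "N3", "N4"),
    visit_id = c("V1", "V1", "V2", "V3"),
    patient_id = c("P1", "P1", "P1", "P2"),
    service_date = as.Date(c("2018-01-01", "2018-01-01", "2018-01-15", "2018-02-01")),
    facility_id = "F001",
    author_role = "dc",
    text = c("visit one resident", "visit one attending", "visit two", "other patient")
  )
  corpus <- prepare_corpus(raw)
  expect_equal(nrow(corpus), 3)
  expect_equal(sort(unique(corpus$visit_id)), c("V1", "V2", "V3"))
  expect_match(corpus$header[corpus$visit_id == "V1"], "visit 1 of 2", fixed = TRUE)
  expect_equal(corpus$tokens, whitespace_token_count(corpus$body))
  expect_equal(
    stringr::str_count(corpus$body[corpus$visit_id == "V1"],
                       stringr::fixed(note_delimiter())),
    1
  )
})

test_that("token length stats include the overflow bin", {
  df <- tibble::tibble(
    grp = rep(c("a", "b"), each = 3),
    tok = c(100, 2500, 300, 50, 60, 70)
  )
  st <- token_length_stats(df, tok, grp)
  expect_equal(st$overflow_count[st$group_label == "a"], 1)
  expect_equal(st$overflow_count[st$group_label == "b"], 0)
  expect_equal(st$n, c(3, 3))
})
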