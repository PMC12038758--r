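test_that("candidate spans: exact hits, multi-measure notes, negatives", {
  sp <- find_candidate_spans("Oswestry Disability Index score 24", the_catalog)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$prom_id, "odi")
  expect_equal(sp$surface, "Oswestry Disability Index")
  expect_equal(sp$start, 0L)
  expect_equal(sp$end, 25L)

  sp2 <- find_candidate_spans("ODI improved; Bournemouth back 31/70", the_catalog)
  expect_setequal(sp2$prom_id, c("odi", "bournemouth_back"))

  expect_equal(nrow(find_candidate_spans("no instruments here", the_catalog)), 0)
  expect_equal(nrow(find_candidate_spans("", the_catalog)), 0)
})

test_that("overlapping candidates resolve longest-first", {
  sp <- find_candidate_spans("Neck Bournemouth Questionnaire 12/70", the_catalog)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$prom_id, "bournemouth_neck")
  expect_equal(sp$surface, "Neck Bournemouth Questionnaire")
})

test_that("offset integrity: every surface equals the body slice", {
  cfg <- sim_config(n_patients = 25, prom_prevalence = 0.5,
                    excluded_mention_rate = 0.3, typo_rate = 0.3, seed = 17)
  corp <- generate_corpus(cfg, the_catalog)
  res <- annotate_corpus(corp, the_catalog)
  for (i in seq_len(nrow(res))) {
    sp <- res$spans[[i]]
    if (nrow(sp) > 0) {
      expect_equal(stringr::str_sub(corp$body[i], sp$start + 1, sp$end),
                   sp$surface)
    }
  }
})

test_that("section detection covers the body with correct dispositions", {
  body <- "Subjective: feels better\nObjective: normal exam"
  secs <- detect_sections(body, the_rules)
  expect_equal(secs$label, c("subjective", "objective"))
  expect_equal(secs$body_end[1], secs$header_start[2])
  expect_equal(secs$body_end[2], nchar(body))

  headerless <- detect_sections("free text with no headers at all", the_rules)
  expect_equal(headerless$label, "preamble")
  expect_equal(headerless$disposition, "include")

  pre <- detect_sections("intro text\nPlan: continue care", the_rules)
  expect_equal(pre$label, c("preamble", "plan"))
  expect_equal(pre$body_start[1], 0L)
  expect_equal(pre$body_end[1], pre$header_start[2])
})

test_that("the in-line include trigger re-opens an excluded section", {
  secs <- detect_sections(goals_of_care_example(), the_rules)
  expect_equal(secs$label, c("goals_of_care", "outcome_measures"))
  expect_equal(secs$disposition, c("exclude", "include"))

  res <- annotate_note(goals_of_care_example(), the_catalog, the_rules)
  expect_true(res$prom_positive)
  expect_equal(res$spans$surface, "ODI")
  expect_equal(res$spans$section_label, "outcome_measures")
})

test_that("section filter keeps include spans and audits dropped ones", {
  body <- "Plan: repeat ODI next visit\n\nMedications: no ODI interactions"
  spans <- find_candidate_spans(body, the_catalog)
  expect_equal(nrow(spans), 2)
  secs <- detect_sections(body, the_rules)
  kept <- apply_section_filter(spans, secs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$section_label, "plan")
  dropped <- attr(kept, "dropped")
  expect_equal(nrow(dropped), 1)
  expect_equal(dropped$section_label, "medications")

  empty <- apply_section_filter(spans[0, ], secs)
  expect_equal(nrow(empty), 0)
})

test_that("annotate_note composes the pipeline and casts to a note label", {
  positive <- "Subjective: pain improving\nPlan: Neck Disability Index collected"
  res <- annotate_note(positive, the_catalog, the_rules)
  expect_true(res$prom_positive)
  expect_true(res$per_prom[["ndi"]])
  expect_false(any(res$per_prom[setdiff(names(res$per_prom), "ndi")]))

  legend_only <- "Subjective: stable\nAbbreviations: ODI - Oswestry Disability Index"
  res2 <- annotate_note(legend_only, the_catalog, the_rules)
  expect_false(res2$prom_positive)
  expect_gt(nrow(res2$dropped), 0)

  res3 <- annotate_note("", the_catalog, the_rules)
  expect_false(res3$prom_positive)
  expect_equal(nrow(res3$spans), 0)
})

test_that("annotation is deterministic and monotone under lexicon growth", {
  body <- "Plan: ODI and Bournemouth Questionnaire collected; Headache Impact Test due"
  r1 <- annotate_note(body, the_catalog, the_rules)
  r2 <- annotate_note(body, the_catalog, the_rules)
  expect_identical(r1$spans, r2$spans)

  # removing a definition never adds spans elsewhere; restoring it only adds
  smaller <- the_catalog
  smaller$definitions <- smaller$definitions[smaller$definitions$prom_id != "hit6", ]
  r_small <- annotate_note(body, smaller, the_rules)
  key <- function(s) paste(s$start, s$end, s$prom_id)
  expect_true(all(key(r_small$spans) %in% key(r1$spans)))
  expect_gt(nrow(r1$spans), nrow(r_small$spans))
})

test_that("prevalence percentages are reported to one decimal", {
  res <- tibble::tibble(
    visit_id = sprintf("V%03d", 1:300),
    prom_positive = c(rep(TRUE, 53), rep(FALSE, 247)),
    category = rep(visit_categories(), 60)
  )
  prev <- corpus_prevalence(res)
  expect_equal(prev$prevalence_pct, 17.7)
  expect_equal(prev$n, 300)

  none <- dplyr::mutate(res, prom_positive = FALSE)
  expect_equal(corpus_prevalence(none)$prevalence_pct, 0.0)

  strat <- corpus_prevalence(res, category)
  expect_equal(nrow(strat), 6)
  expect_equal(strat$stratum[1], "overall")

  expect_error(corpus_prevalence(res[0, ]), "empty")
})

test_that("kept spans never sit in excluded sections (audited exhaustively)", {
  cfg <- sim_config(n_patients = 30, prom_prevalence = 0.4,
                    excluded_mention_rate = 0.5, seed = 29)
  corp <- generate_corpus(cfg, the_catalog)
  compiled <- promnlp:::compile_catalog(the_catalog, fuzz_policy())
  for (i in seq_len(nrow(corp))) {
    res <- annotate_note(corp$body[i], the_catalog, the_rules,
                         compiled = compiled)
    if (nrow(res$spans) > 0) {
      secs <- res$sections
      region_start <- ifelse(is.na(secs$header_start), secs$body_start,
                             secs$header_start)
      gov <- findInterval(res$spans$start, region_start)
      expect_true(all(secs$disposition[gov] == "include"))
    }
  }
})
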