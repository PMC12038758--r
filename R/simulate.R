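# Synthetic sectioned clinic notes with gold-standard span annotations.
# The generator emulates the *structure* the pipeline consumes — SOAP-style
# sections, abbreviation legends, metadata headers, visit sequences with
# care gaps, controlled PROM-mention prevalence — not clinical narrative.

# Filler sentences are deliberately free of catalog terms (and of anything
# within one edit of a fuzzy-eligible alias token) so that planted mentions
# are the only matchable content.
sim_fillers <- function() {
  c(
    "patient reports gradual improvement since the last visit.",
    "palpation reveals mild paraspinal tenderness on the left.",
    "active range of motion is within normal limits today.",
    "spinal manipulation performed to the lumbar region.",
    "patient tolerated treatment well without adverse reaction.",
    "home stretching routine reviewed and demonstrated.",
    "posture advice given regarding prolonged sitting.",
    "moist heat applied for ten minutes before treatment.",
    "gait is steady and symmetric without antalgia.",
    "follow up scheduled in two weeks to reassess progress.",
    "sleep remains intermittently disrupted by discomfort.",
    "no new neurological symptoms reported today.",
    "soft tissue work performed to the cervical musculature.",
    "patient denies numbness or tingling in the extremities.",
    "work duties resumed without restriction this week."
  )
}

sim_mention_templates <- function() {
  c(
    "Patient completed the %s at today's visit.",
    "%s was administered and reviewed with the patient.",
    "Repeat %s collected to track progress.",
    "Baseline %s recorded in the chart."
  )
}

sim_med_lines <- function() {
  c(
    "ibuprofen 400 mg as needed for discomfort.",
    "cyclobenzaprine 5 mg at bedtime.",
    "acetaminophen 500 mg twice daily.",
    "topical menthol gel applied to the low back."
  )
}

sim_legend_lines <- function() {
  c(
    "ROM - range of motion.",
    "HEP - home exercise program.",
    "STM - soft tissue mobilization.",
    "WNL - within normal limits."
  )
}

# Section skeletons: headers in order, with dispositions implied by the
# default section rules. Exclude-disposition sections appear in some
# skeletons so that section filtering is routinely exercised.
sim_templates <- function() {
  list(
    c("Subjective", "Objective", "Assessment", "Plan"),
    c("Subjective", "Objective", "Medications", "Assessment", "Plan"),
    c("History", "Examination", "Assessment", "Plan", "Abbreviations"),
    c("Subjective", "Objective", "Assessment", "Plan", "Patient Education")
  )
}

sim_exclude_headers <- function() {
  c("Medications", "Abbreviations", "Goals of Care", "Patient Education")
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the shape of a chiropractic visit-note corpus: a
#' geometric visits-per-patient distribution with median 5, 17% of notes
#' carrying a PROM mention, a quarter of patients with at least one care gap
#' longer than 60 days, and first-consult notes roughly twice as long as
#' intermediate ones.
#'
#' @param n_patients Number of simulated patients.
#' @param visit_geom_prob Success probability of the geometric
#'   visits-per-patient distribution (`1 + rgeom`); the default 0.13 gives a
#'   median of 5 visits.
#' @param prom_prevalence Probability a note carries 1-3 genuine PROM
#'   mentions (default 0.17).
#' @param gap_probability Probability a patient's history contains at least
#'   one inter-visit interval exceeding 60 days (default 0.25).
#' @param typo_rate Per-token probability that a planted alias token of 5+
#'   characters receives a single-character typo (substitution, deletion or
#'   adjacent transposition).
#' @param excluded_mention_rate Probability that a PROM-negative note carries
#'   a catalog term only inside an excluded section (a decoy).
#' @param facility_count Number of distinct facility codes.
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @return An object of class `prom_sim_config`.
#' @export
sim_config <- function(n_patients = 100, visit_geom_prob = 0.13,
                       prom_prevalence = 0.17, gap_probability = 0.25,
                       typo_rate = 0, excluded_mention_rate = 0.05,
                       facility_count = 20, seed = 1) {
  rates <- c(prom_prevalence, gap_probability, typo_rate, excluded_mention_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must be in [0, 1]")
  if (n_patients < 1) abort("n_patients must be >= 1")
  structure(
    list(
      n_patients = as.integer(n_patients),
      visit_geom_prob = visit_geom_prob,
      prom_prevalence = prom_prevalence,
      gap_probability = gap_probability,
      typo_rate = typo_rate,
      excluded_mention_rate = excluded_mention_rate,
      facility_count = as.integer(facility_count),
      seed = as.integer(seed)
    ),
    class = "prom_sim_config"
  )
}

#' Generate one patient's visit history
#'
#' Visit dates ascend from a consultation date and stay within 365 days of
#' it. Routine inter-visit intervals are 3-21 days; with probability
#' `gap_probability` one interval is drawn from 61-120 days, guaranteeing a
#' care gap. Uses the current RNG state ([generate_corpus()] seeds it once
#' from the config).
#'
#' @param config A [sim_config()].
#' @param patient_id Identifier for the patient.
#' @param consult_date Date of the first (consultation) visit.
#' @return A tibble of visits with categories assigned by
#'   [assign_visit_categories()].
#' @export
generate_patient_history <- function(config, patient_id = "P0001",
                                     consult_date = as.Date("2018-01-02")) {
  n_visits <- 1L + stats::rgeom(1, config$visit_geom_prob)
  has_gap <- stats::runif(1) < config$gap_probability
  # a care gap needs at least two visits; honour the configured rate exactly
  if (has_gap) n_visits <- max(n_visits, 2L)
  facility <- sprintf("F%03d", sample.int(config$facility_count, 1))
  if (n_visits > 1) {
    intervals <- sample(3:21, n_visits - 1, replace = TRUE)
    if (has_gap) {
      # prefer a mid-history gap so the flanking pre/post visits are not
      # swallowed by the first/final category precedence
      gap_at <- if (n_visits >= 4) {
        sample(rep(2:(n_visits - 2), 2), 1)
      } else {
        sample.int(n_visits - 1, 1)
      }
      intervals[gap_at] <- sample(61:120, 1)
    }
    offsets <- c(0, cumsum(intervals))
    keep <- offsets <= 365
    if (config$gap_probability > 0 && !any(intervals[keep[-1]] > 60) &&
        any(intervals > 60)) {
      # the gap was truncated away; force it onto the first interval
      intervals[1] <- sample(61:120, 1)
      offsets <- c(0, cumsum(intervals))
      keep <- offsets <= 365
    }
    offsets <- offsets[keep]
  } else {
    offsets <- 0
  }
  visits <- tibble::tibble(
    visit_id = sprintf("%s-V%02d", patient_id, seq_along(offsets)),
    patient_id = patient_id,
    service_date = consult_date + offsets,
    facility_id = facility
  )
  assign_visit_categories(visits, gap_days = 60)
}

apply_typo <- function(token) {
  n <- nchar(token)
  chars <- strsplit(token, "", fixed = TRUE)[[1]]
  kind <- sample(c("substitute", "delete", "transpose"), 1)
  pos <- sample.int(n, 1)
  if (kind == "substitute") {
    repl <- sample(setdiff(letters, tolower(chars[pos])), 1)
    chars[pos] <- repl
  } else if (kind == "delete") {
    chars <- chars[-pos]
  } else {
    if (pos == n) pos <- n - 1L
    chars[c(pos, pos + 1L)] <- chars[c(pos + 1L, pos)]
  }
  paste(chars, collapse = "")
}

sample_surface <- function(catalog, typo_rate) {
  i <- sample.int(nrow(catalog$definitions), 1)
  def <- catalog$definitions[i, ]
  abbrs <- def$abbreviations[[1]]
  use_abbr <- length(abbrs) > 0 && stats::runif(1) < 0.4
  if (use_abbr) {
    surface <- sample(abbrs, 1)
  } else {
    surface <- sample(def$aliases[[1]], 1)
    if (typo_rate > 0 && isTRUE(def$allow_fuzzy)) {
      toks <- strsplit(surface, " ", fixed = TRUE)[[1]]
      mutate <- nchar(toks) >= 5 & stats::runif(length(toks)) < typo_rate
      toks[mutate] <- vapply(toks[mutate], apply_typo, character(1))
      surface <- paste(toks, collapse = " ")
    }
  }
  list(prom_id = def$prom_id, surface = surface)
}

#' Generate one synthetic clinic note with gold annotations
#'
#' Assembles a sectioned SOAP-style note from a sampled skeleton. With
#' probability `prom_prevalence` the note receives 1-3 PROM mentions planted
#' in include-disposition sections, with gold character offsets recorded at
#' construction. A PROM-negative note may instead receive a decoy — a
#' catalog term placed only inside an excluded section (abbreviation legend
#' or medication list) — with probability `excluded_mention_rate`.
#' First-consult notes draw roughly twice as many filler sentences as other
#' visits.
#'
#' @param visit One visit row (from [generate_patient_history()]).
#' @param config A [sim_config()].
#' @param catalog The PROM catalog to plant mentions from.
#' @return A one-row tibble: visit metadata, `header`, `body`, `gold_spans`
#'   (list-column, `source = "human"`), `gold_label`, `has_decoy` and
#'   `decoy_spans`.
#' @export
generate_note <- function(visit, config, catalog = load_prom_catalog()) {
  positive <- stats::runif(1) < config$prom_prevalence
  decoy <- !positive && stats::runif(1) < config$excluded_mention_rate
  skeleton <- sim_templates()[[sample.int(length(sim_templates()), 1)]]
  if (decoy && !any(skeleton %in% sim_exclude_headers())) {
    skeleton <- c(skeleton, "Abbreviations")
  }
  is_consult <- as.character(visit$category) == "FIRST_CONSULT"
  include_idx <- which(!(skeleton %in% sim_exclude_headers()))

  n_mentions <- if (positive) sample.int(3, 1) else 0L
  mention_sections <- if (n_mentions > 0) {
    sample(rep(include_idx, 2), n_mentions)
  } else {
    integer(0)
  }
  decoy_section <- if (decoy) {
    excl <- which(skeleton %in% sim_exclude_headers())
    excl[sample.int(length(excl), 1)]
  } else {
    0L
  }

  parts <- character(0)
  cursor <- 0L
  gold <- list()
  decoys <- list()
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }

  for (si in seq_along(skeleton)) {
    hdr <- skeleton[si]
    if (si > 1) add("\n\n")
    add(paste0(hdr, ":"))
    add("\n")
    n_fill <- if (is_consult) sample(3:6, 1) else sample(1:3, 1)
    if (hdr == "Medications") {
      lines <- sample(sim_med_lines(), min(n_fill, 4))
    } else if (hdr == "Abbreviations") {
      lines <- sample(sim_legend_lines(), min(n_fill, 4))
    } else {
      lines <- sample(sim_fillers(), n_fill, replace = TRUE)
    }
    add(paste(lines, collapse = " "))
    for (m in which(mention_sections == si)) {
      pick <- sample_surface(catalog, config$typo_rate)
      template <- sample(sim_mention_templates(), 1)
      halves <- strsplit(template, "%s", fixed = TRUE)[[1]]
      add(paste0(" ", halves[1]))
      start <- cursor
      add(pick$surface)
      gold[[length(gold) + 1L]] <- tibble::tibble(
        start = start, end = cursor, surface = pick$surface,
        prom_id = pick$prom_id, match_kind = NA_character_, source = "human"
      )
      add(halves[2])
    }
    if (decoy && decoy_section == si) {
      pick <- sample_surface(catalog, typo_rate = 0)
      add(" ")
      start <- cursor
      add(pick$surface)
      decoys[[length(decoys) + 1L]] <- tibble::tibble(
        start = start, end = cursor, surface = pick$surface,
        prom_id = pick$prom_id, match_kind = NA_character_, source = "human"
      )
      add(" - tracked on the standard intake form.")
    }
  }
  body <- paste(parts, collapse = "")
  gold_spans <- if (length(gold) > 0) {
    dplyr::arrange(purrr::list_rbind(gold), .data$start)
  } else {
    span_tibble()
  }
  decoy_spans <- if (length(decoys) > 0) purrr::list_rbind(decoys) else span_tibble()
  out <- visit
  out$header <- build_metadata_header(visit)
  out$body <- body
  out$gold_spans <- list(gold_spans)
  out$gold_label <- nrow(gold_spans) > 0
  out$has_decoy <- nrow(decoy_spans) > 0
  out$decoy_spans <- list(decoy_spans)
  out
}

#' Generate a full synthetic corpus with gold annotations and a manifest
#'
#' Seeds the RNG once from the config, so the corpus is a pure, bit-identical
#' function of its configuration.
#'
#' @inheritParams generate_note
#' @return A tibble with one row per visit note (see [generate_note()]) and a
#'   `"manifest"` attribute recording the seed, a config hash and per-stratum
#'   counts; retrieve it with [corpus_manifest()].
#' @export
generate_corpus <- function(config, catalog = load_prom_catalog()) {
  corpus <- with_seed(config$seed, {
    consults <- as.Date("2017-10-01") + sample(0:730, config$n_patients,
                                               replace = TRUE)
    purrr::map(seq_len(config$n_patients), function(i) {
      history <- generate_patient_history(
        config,
        patient_id = sprintf("P%05d", i),
        consult_date = consults[i]
      )
      purrr::map(seq_len(nrow(history)), function(v) {
        generate_note(history[v, ], config, catalog)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  attr(corpus, "manifest") <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_patients = config$n_patients,
    n_notes = nrow(corpus),
    n_positive = sum(corpus$gold_label),
    category_counts = as.list(table(as.character(corpus$category)))
  )
  corpus
}

#' @rdname generate_corpus
#' @param corpus A corpus from [generate_corpus()].
#' @export
corpus_manifest <- function(corpus) {
  attr(corpus, "manifest")
}

#' Select a high-probability training subset by programmatic labeling
#'
#' Picks `n` notes that the rule-based matcher flags positive, to enrich
#' positive prevalence in a training pool before human review.
#'
#' @param corpus A corpus tibble with `visit_id`.
#' @param results Matcher output for the same corpus (from
#'   [annotate_corpus()]), or a logical vector of matcher labels in corpus
#'   order.
#' @param n Target subset size (default 200).
#' @return The subset of `corpus` rows (first `n` matcher-positives in corpus
#'   order); all of them, with a warning, when fewer than `n` are positive.
#' @export
make_high_probability_set <- function(corpus, results, n = 200) {
  flags <- if (is.logical(results)) {
    results
  } else {
    stopifnot_cols(results, c("visit_id", "prom_positive"), "results")
    results$prom_positive[match(corpus$visit_id, results$visit_id)]
  }
  if (length(flags) != nrow(corpus)) {
    abort("results do not cover the corpus")
  }
  pos <- which(flags)
  if (length(pos) < n) {
    warn(sprintf(
      "only %d matcher-positive notes available (requested %d); returning all",
      length(pos), n
    ))
    return(corpus[pos, ])
  }
  corpus[pos[seq_len(n)], ]
}

#' The worked in-line section example
#'
#' A canned fixture reproducing the documented interplay of an excluded
#' "Goals of Care" section immediately re-opened by an in-line
#' "outcome measures" include trigger, so the PROM abbreviation that follows
#' is kept despite the excluded header.
#'
#' @return A single string.
#' @export
goals_of_care_example <- function() {
  "Goals of Care: Improve outcome measures, reduce ODI by 20%"
}
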