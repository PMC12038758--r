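# Corpus preparation: per-visit note concatenation, metadata headers,
# exclusive visit categories, token-length statistics, stratified sampling.

#' Default delimiters for note concatenation and metadata headers
#'
#' Merged notes are separated with an improbable sigil so that sub-note
#' boundaries survive round-trips through plain text; the metadata header is
#' offset from the clinical body with a second, distinct sigil.
#'
#' @return A single string.
#' @export
note_delimiter <- function() {
  "<<<~NOTE-BREAK~8f3a9c1d~>>>"
}

#' @rdname note_delimiter
#' @export
header_delimiter <- function() {
  "<<<~HEADER-END~2b7e5d4a~>>>"
}

#' Visit category levels, in precedence order
#'
#' Every visit receives exactly one of five exclusive categories. When more
#' than one definition applies (a single-visit patient is both the first
#' consultation and the final visit of the year), the earlier level in this
#' vector wins.
#'
#' @return Character vector of the five category labels.
#' @export
visit_categories <- function() {
  c("FIRST_CONSULT", "FINAL_WITHIN_YEAR", "PRE_GAP", "POST_GAP", "INTERMEDIATE")
}

#' Merge all raw notes for one visit into a single clinic note
#'
#' Multiple notes (e.g. a resident note and an attending note) can describe
#' the same visit. This joins their texts, in service order with ties broken
#' by `note_id`, into one body separated by a delimiter, yielding a 1-to-1
#' visit-to-note relationship.
#'
#' @param notes A data frame of raw notes sharing one `visit_id`, with columns
#'   `note_id`, `visit_id`, `patient_id`, `service_date`, `facility_id`,
#'   `text` (and optionally `author_role`).
#' @param delimiter String inserted between consecutive sub-note texts.
#' @return A one-row tibble with `visit_id`, `patient_id`, `service_date`,
#'   `facility_id`, `body` and a `source_note_ids` list-column recording the
#'   concatenation order.
#' @export
merge_visit_notes <- function(notes, delimiter = note_delimiter()) {
  if (is.null(notes) || nrow(notes) == 0) {
    abort("no notes for visit")
  }
  stopifnot_cols(notes, c("note_id", "visit_id", "patient_id", "service_date",
                          "facility_id", "text"), "notes")
  if (dplyr::n_distinct(notes$visit_id) != 1L) {
    abort("visit mismatch: notes span more than one visit_id")
  }
  notes <- dplyr::arrange(notes, .data$service_date, .data$note_id)
  tibble::tibble(
    visit_id = notes$visit_id[1],
    patient_id = notes$patient_id[1],
    service_date = notes$service_date[1],
    facility_id = notes$facility_id[1],
    body = paste(notes$text, collapse = delimiter),
    source_note_ids = list(notes$note_id)
  )
}

#' Build the visit metadata header for a clinic note
#'
#' The header carries the patient identifier, visit identifier, visit date,
#' facility code, consultation date, the "visit i of t" position phrase, and
#' the day counts to the neighbouring visits when they exist. It is
#' terminated by `delimiter`, which offsets it from the clinical body; the
#' header is never scanned for PROM mentions.
#'
#' @param visit A one-row data frame (or named list) with fields `patient_id`,
#'   `visit_id`, `service_date`, `facility_id`, `consult_date`, `visit_index`,
#'   `visit_total` and optionally `days_since_prev`, `days_to_next`.
#' @param delimiter Header/body delimiter appended as the final line.
#' @return A single string.
#' @seealso [parse_metadata_header()] for the lossless inverse.
#' @export
build_metadata_header <- function(visit, delimiter = header_delimiter()) {
  v <- as.list(visit)
  lines <- c(
    paste0("patient_id: ", v$patient_id),
    paste0("visit_id: ", v$visit_id),
    paste0("visit_date: ", format(as.Date(v$service_date))),
    paste0("facility_id: ", v$facility_id),
    paste0("consult_date: ", format(as.Date(v$consult_date))),
    sprintf("visit %d of %d", as.integer(v$visit_index), as.integer(v$visit_total))
  )
  dsp <- v$days_since_prev
  if (!is.null(dsp) && length(dsp) == 1 && !is.na(dsp)) {
    lines <- c(lines, paste0("days_since_prev: ", as.integer(dsp)))
  }
  dtn <- v$days_to_next
  if (!is.null(dtn) && length(dtn) == 1 && !is.na(dtn)) {
    lines <- c(lines, paste0("days_to_next: ", as.integer(dtn)))
  }
  paste0(paste(lines, collapse = "\n"), "\n", delimiter)
}

#' Parse a metadata header back into visit fields
#'
#' Inverse of [build_metadata_header()]: `parse_metadata_header(build_metadata_header(v))`
#' recovers the metadata fields exactly.
#'
#' @param header Header string (with or without the trailing delimiter line).
#' @param delimiter Header delimiter used when the header was built.
#' @return A one-row tibble with the visit metadata fields; `days_since_prev`
#'   and `days_to_next` are `NA` when the header omits them.
#' @export
parse_metadata_header <- function(header, delimiter = header_delimiter()) {
  body <- stringr::str_replace_all(header, stringr::fixed(delimiter), "")
  lines <- str_trim(strsplit(body, "\n", fixed = TRUE)[[1]])
  lines <- lines[lines != ""]
  get_field <- function(key) {
    hit <- lines[startsWith(lines, paste0(key, ": "))]
    if (length(hit) == 0) NA_character_ else sub(paste0("^", key, ": "), "", hit[1])
  }
  pos <- lines[grepl("^visit [0-9]+ of [0-9]+$", lines)]
  if (length(pos) == 0) {
    abort("header is missing the 'visit i of t' position phrase")
  }
  idx <- as.integer(sub("^visit ([0-9]+) of [0-9]+$", "\\1", pos[1]))
  tot <- as.integer(sub("^visit [0-9]+ of ([0-9]+)$", "\\1", pos[1]))
  dsp <- get_field("days_since_prev")
  dtn <- get_field("days_to_next")
  tibble::tibble(
    patient_id = get_field("patient_id"),
    visit_id = get_field("visit_id"),
    service_date = as.Date(get_field("visit_date")),
    facility_id = get_field("facility_id"),
    consult_date = as.Date(get_field("consult_date")),
    visit_index = idx,
    visit_total = tot,
    days_since_prev = ifelse(is.na(dsp), NA_integer_, as.integer(dsp)),
    days_to_next = ifelse(is.na(dtn), NA_integer_, as.integer(dtn))
  )
}

#' Assign exclusive visit categories within each patient's care episode
#'
#' Visits are tagged into five mutually exclusive categories: first
#' consultation, final visit within one year, visit immediately preceding a
#' care gap, visit immediately following a care gap, and other intermediate
#' visit. A care gap is an inter-visit interval strictly greater than
#' `gap_days`. When several definitions apply to one visit, precedence is
#' `FIRST_CONSULT > FINAL_WITHIN_YEAR > PRE_GAP > POST_GAP > INTERMEDIATE`.
#'
#' @param visits A data frame with at least `patient_id` and `service_date`,
#'   sorted ascending by `service_date` within each patient; the first visit
#'   per patient is the consultation.
#' @param gap_days Care-gap threshold in days (default 60); an interval must
#'   exceed this to count as a gap.
#' @return The input with columns `consult_date`, `visit_index`,
#'   `visit_total`, `days_since_prev`, `days_to_next` and `category` added
#'   (category is a factor over [visit_categories()]).
#' @export
assign_visit_categories <- function(visits, gap_days = 60) {
  if (is.null(visits) || nrow(visits) == 0) {
    abort("empty visit list")
  }
  stopifnot_cols(visits, c("patient_id", "service_date"), "visits")
  ok <- visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(sorted = !is.unsorted(.data$service_date), .groups = "drop")
  if (!all(ok$sorted)) {
    abort("visits must be sorted ascending by service_date within patient")
  }
  out <- visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      consult_date = dplyr::first(.data$service_date),
      visit_index = dplyr::row_number(),
      visit_total = dplyr::n(),
      days_since_prev = as.integer(
        as.Date(.data$service_date) - as.Date(dplyr::lag(.data$service_date))
      ),
      days_to_next = as.integer(
        as.Date(dplyr::lead(.data$service_date)) - as.Date(.data$service_date)
      ),
      category = dplyr::case_when(
        visit_index == 1L ~ "FIRST_CONSULT",
        visit_index == visit_total ~ "FINAL_WITHIN_YEAR",
        !is.na(days_to_next) & days_to_next > gap_days ~ "PRE_GAP",
        !is.na(days_since_prev) & days_since_prev > gap_days ~ "POST_GAP",
        TRUE ~ "INTERMEDIATE"
      )
    ) |>
    dplyr::ungroup()
  if (any(as.Date(out$service_date) > as.Date(out$consult_date) + 365)) {
    warn("some visits fall more than 365 days after the consultation date")
  }
  out$category <- factor(out$category, levels = visit_categories())
  out
}

#' Count whitespace-delimited tokens
#'
#' Note length throughout the package is measured by whitespace splitting:
#' the count is the number of maximal non-whitespace runs.
#'
#' @param text Character vector.
#' @return Integer vector of token counts (0 for empty or all-whitespace).
#' @export
whitespace_token_count <- function(text) {
  n <- stringr::str_count(text, "\\S+")
  n[is.na(text)] <- NA_integer_
  as.integer(n)
}

#' Token-length summary per group
#'
#' @param data A data frame.
#' @param tokens Column of token counts (tidy-eval).
#' @param group Optional grouping column (tidy-eval); omit for one overall row.
#' @param overflow Token count above which a note lands in the overflow bin
#'   (default 2000).
#' @return A tibble with `group_label`, `n`, `mean_tokens`, `sd_tokens`,
#'   `median_tokens` and `overflow_count`.
#' @export
token_length_stats <- function(data, tokens, group = NULL, overflow = 2000) {
  tk <- dplyr::pull(data, {{ tokens }})
  grp <- if (rlang::quo_is_null(rlang::enquo(group))) {
    rep("all", length(tk))
  } else {
    as.character(dplyr::pull(data, {{ group }}))
  }
  tibble::tibble(group_label = grp, tokens = tk) |>
    dplyr::group_by(.data$group_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tokens = mean(.data$tokens),
      sd_tokens = stats::sd(.data$tokens),
      median_tokens = stats::median(.data$tokens),
      overflow_count = sum(.data$tokens > overflow),
      .groups = "drop"
    )
}

#' Draw a stratified annotation sample balanced over visit categories
#'
#' Selects `n` notes with approximately equal counts per visit category
#' (within one, subject to availability), repeating the random draw `draws`
#' times and keeping the draw that covers the largest number of distinct
#' facilities. Deterministic for a given `seed`.
#'
#' @param corpus A data frame with `visit_id`, `category` and `facility_id`.
#' @param n Target sample size (default 300).
#' @param seed Integer seed controlling all randomness.
#' @param draws Number of candidate draws compared on facility coverage.
#' @return Character vector of sampled `visit_id`s.
#' @export
stratified_annotation_sample <- function(corpus, n = 300, seed = 1, draws = 20) {
  if (n <= 0) abort("n must be positive")
  stopifnot_cols(corpus, c("visit_id", "category", "facility_id"), "corpus")
  if (nrow(corpus) == 0) abort("corpus is empty")
  if (nrow(corpus) <= n) {
    warn(sprintf("corpus has only %d notes; returning all of them", nrow(corpus)))
    return(corpus$visit_id)
  }
  cats <- as.character(unique(corpus$category))
  avail <- table(factor(as.character(corpus$category), levels = cats))
  quota <- balanced_quota(avail, n)
  with_seed(seed, {
    best_ids <- NULL
    best_fac <- -1L
    for (d in seq_len(draws)) {
      ids <- unlist(lapply(cats, function(cc) {
        pool <- corpus$visit_id[as.character(corpus$category) == cc]
        sample(pool, quota[[cc]])
      }), use.names = FALSE)
      fac <- dplyr::n_distinct(corpus$facility_id[corpus$visit_id %in% ids])
      if (fac > best_fac) {
        best_fac <- fac
        best_ids <- ids
      }
    }
    best_ids
  })
}

# Split n across strata as evenly as availability allows: per-stratum counts
# differ by at most one unless a stratum runs out, in which case the slack is
# redistributed to strata with spare notes.
balanced_quota <- function(avail, n) {
  k <- length(avail)
  counts <- setNames(rep(0L, k), names(avail))
  remaining <- min(n, sum(avail))
  while (remaining > 0) {
    open <- names(avail)[counts < avail]
    take <- open[order(counts[open])]
    take <- take[seq_len(min(length(take), remaining))]
    counts[take] <- counts[take] + 1L
    remaining <- remaining - length(take)
  }
  counts
}

#' Compare token lengths across groups (rank-based omnibus and post hoc)
#'
#' Runs a Kruskal-Wallis omnibus test across all groups and Dunn's rank-based
#' post hoc z-tests across all group pairs, with a Bonferroni correction over
#' the `m = k(k-1)/2` pairwise comparisons.
#'
#' @param data A data frame.
#' @param group Grouping column (tidy-eval).
#' @param tokens Numeric column of token counts (tidy-eval).
#' @param alpha Family significance level (default 0.05).
#' @return An object of class `prom_length_test`; `glance()` gives the
#'   omnibus row, `tidy()` the pairwise comparisons.
#' @export
compare_group_lengths <- function(data, group, tokens, alpha = 0.05) {
  g <- factor(as.character(dplyr::pull(data, {{ group }})))
  x <- as.numeric(dplyr::pull(data, {{ tokens }}))
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) abort("every group needs at least 2 observations")

  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2)
  m <- ncol(pairs)
  pw <- purrr::map(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group1 = a, group2 = b, z = z, p_value = p)
  }) |> purrr::list_rbind()
  pw$p_adjusted <- pmin(1, pw$p_value * m)
  pw$significant <- pw$p_adjusted < alpha

  structure(
    list(
      omnibus = tibble::tibble(
        statistic = unname(kw$statistic),
        df = unname(kw$parameter),
        p_value = unname(kw$p.value)
      ),
      pairwise = pw,
      alpha = alpha,
      n_comparisons = m
    ),
    class = "prom_length_test"
  )
}

#' @export
print.prom_length_test <- function(x, ...) {
  cat("Rank-based group comparison of token lengths\n")
  cat(sprintf(
    "  Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
    x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value
  ))
  cat(sprintf(
    "  %d pairwise Dunn tests, Bonferroni-adjusted alpha = %.4g, %d significant\n",
    x$n_comparisons, x$alpha / x$n_comparisons, sum(x$pairwise$significant)
  ))
  invisible(x)
}

#' @export
#' @method tidy prom_length_test
tidy.prom_length_test <- function(x, ...) x$pairwise

#' @export
#' @method glance prom_length_test
glance.prom_length_test <- function(x, ...) {
  dplyr::mutate(x$omnibus,
    n_comparisons = x$n_comparisons,
    n_significant = sum(x$pairwise$significant)
  )
}

#' Prepare a visit-level corpus from raw per-author notes
#'
#' End-to-end corpus preparation: merge notes per visit, derive visit order
#' and exclusive categories per patient, and attach a metadata header to each
#' merged note.
#'
#' @inheritParams merge_visit_notes
#' @inheritParams assign_visit_categories
#' @param header_delim Delimiter that offsets the metadata header from the body.
#' @return A tibble with one row per visit: metadata columns, `category`,
#'   `header`, `body`, `source_note_ids` and `tokens` (whitespace token count
#'   of the body).
#' @export
prepare_corpus <- function(notes, gap_days = 60, delimiter = note_delimiter(),
                           header_delim = header_delimiter()) {
  merged <- notes |>
    dplyr::group_by(.data$visit_id) |>
    dplyr::group_split() |>
    purrr::map(merge_visit_notes, delimiter = delimiter) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$patient_id, .data$service_date, .data$visit_id)
  merged <- assign_visit_categories(merged, gap_days = gap_days)
  merged$header <- purrr::pmap_chr(
    merged[c("patient_id", "visit_id", "service_date", "facility_id",
             "consult_date", "visit_index", "visit_total",
             "days_since_prev", "days_to_next")],
    function(...) build_metadata_header(list(...), delimiter = header_delim)
  )
  merged$tokens <- whitespace_token_count(merged$body)
  merged
}
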