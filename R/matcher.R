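# Rule-based pipeline: candidate span matching, section detection,
# section-level exclusion filtering, and the note-level binary cast.

#' Find candidate PROM spans in a note body
#'
#' Scans the clinical body (never the metadata header) for alias,
#' abbreviation and fuzzy matches of every catalog measure, then resolves
#' overlapping candidates: longest match wins, ties go to the earliest start,
#' then catalog order, then match kind (alias before abbreviation before
#' fuzzy). Returned spans are maximal and non-overlapping.
#'
#' @param body Note body text (a single string).
#' @param catalog A [load_prom_catalog()] catalog.
#' @param fuzz A [fuzz_policy()] controlling typo tolerance.
#' @param compiled Optional pre-compiled pattern table from an earlier call
#'   (an optimisation used when annotating a whole corpus); when supplied,
#'   `catalog` and `fuzz` are ignored for pattern construction.
#' @return A tibble of spans with 0-based half-open offsets: `start`, `end`,
#'   `surface`, `prom_id`, `match_kind`, `source = "model"`, sorted by start.
#' @export
find_candidate_spans <- function(body, catalog, fuzz = fuzz_policy(),
                                 compiled = NULL) {
  if (length(body) != 1 || is.na(body) || nchar(body) == 0) {
    return(span_tibble())
  }
  if (is.null(compiled)) compiled <- compile_catalog(catalog, fuzz)
  if (nrow(compiled) == 0) return(span_tibble())

  rx <- compiled[compiled$kind %in% c("alias", "abbreviation"), ]
  cand <- purrr::map(seq_len(nrow(rx)), function(i) {
    m <- gregexpr(rx$pattern[i], body, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble::tibble(
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + attr(m, "match.length"),
      prom_id = rx$prom_id[i],
      match_kind = rx$kind[i],
      catalog_order = rx$catalog_order[i]
    )
  }) |> purrr::list_rbind()

  fz <- compiled[compiled$kind == "fuzzy", ]
  if (nrow(fz) > 0 && fuzz$enabled) {
    cand <- dplyr::bind_rows(cand, fuzzy_candidates(body, fz, fuzz))
  }
  if (is.null(cand) || nrow(cand) == 0) return(span_tibble())

  kind_rank <- match(cand$match_kind, c("alias", "abbreviation", "fuzzy"))
  ord <- order(-(cand$end - cand$start), cand$start, cand$catalog_order, kind_rank)
  cand <- cand[ord, ]
  keep <- logical(nrow(cand))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(cand$start[i] < taken_end & cand$end[i] > taken_start)
    if (!overlaps) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$start), ]
  tibble::tibble(
    start = cand$start,
    end = cand$end,
    surface = span_text(body, cand$start, cand$end),
    prom_id = cand$prom_id,
    match_kind = cand$match_kind,
    source = "model"
  )
}

# Fuzzy alias matching: tokenize the body, trim flanking punctuation from
# each token, and slide a window the length of the alias. Tokens at or above
# the policy's minimum length may differ by up to max_edits
# Damerau-Levenshtein edits; shorter tokens must match exactly
# (case-insensitively). Distances <= 1 are exact DL: adist covers
# substitution/insertion/deletion and the adjacent-transposition case is
# checked explicitly.
fuzzy_candidates <- function(body, fz, fuzz) {
  m <- gregexpr("\\S+", body)[[1]]
  if (m[1] == -1) return(NULL)
  tok_start <- as.integer(m) - 1L
  tok_raw <- substring(body, m, m + attr(m, "match.length") - 1L)
  lead <- nchar(sub("^([[:punct:]]*).*$", "\\1", tok_raw))
  trail <- nchar(sub("^.*?([[:punct:]]*)$", "\\1", tok_raw))
  core <- substr(tok_raw, lead + 1L, nchar(tok_raw) - trail)
  core_start <- tok_start + lead
  core_end <- core_start + nchar(core)
  ok <- nchar(core) > 0
  core <- core[ok]; core_start <- core_start[ok]; core_end <- core_end[ok]
  if (length(core) == 0) return(NULL)
  core_lc <- tolower(core)
  uniq <- unique(core_lc)

  out <- purrr::map(seq_len(nrow(fz)), function(i) {
    al <- fz$tokens[[i]]
    k <- length(al)
    if (length(core) < k) return(NULL)
    al_lc <- tolower(al)
    match_mat <- matrix(FALSE, nrow = k, ncol = length(core))
    for (j in seq_len(k)) {
      if (nchar(al[j]) >= fuzz$min_token_length) {
        hit_u <- uniq[dl_within(al_lc[j], uniq, fuzz$max_edits)]
      } else {
        hit_u <- al_lc[j]
      }
      match_mat[j, ] <- core_lc %in% hit_u
    }
    n_win <- length(core) - k + 1L
    win_ok <- match_mat[1, seq_len(n_win)]
    if (k > 1) {
      for (j in 2:k) {
        win_ok <- win_ok & match_mat[j, seq.int(j, j + n_win - 1L)]
      }
    }
    hits <- which(win_ok)
    if (length(hits) == 0) return(NULL)
    tibble::tibble(
      start = core_start[hits],
      end = core_end[hits + k - 1L],
      prom_id = fz$prom_id[i],
      match_kind = "fuzzy",
      catalog_order = fz$catalog_order[i]
    )
  }) |> purrr::list_rbind()
  out
}

# Is each of `b` within `max_edits` Damerau-Levenshtein edits of `a`?
dl_within <- function(a, b, max_edits = 1L) {
  d <- as.integer(utils::adist(a, b))
  ok <- d <= max_edits
  if (max_edits == 1L) {
    # adist misses pure adjacent transpositions (it scores them 2)
    two <- which(d == 2L & nchar(b) == nchar(a))
    for (i in two) {
      ok[i] <- is_adjacent_transposition(a, b[i])
    }
  }
  ok
}

is_adjacent_transposition <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  diff <- which(ca != cb)
  length(diff) == 2 && diff[2] == diff[1] + 1 &&
    ca[diff[1]] == cb[diff[2]] && ca[diff[2]] == cb[diff[1]]
}

#' Load section header rules from YAML
#'
#' @param path YAML file with a `rules` list of
#'   `{label, pattern, disposition, require_colon}` entries; defaults to the
#'   rule set shipped with the package.
#' @return A tibble of section rules.
#' @export
load_section_rules <- function(path = default_section_rules_path()) {
  raw <- yaml::read_yaml(path)$rules
  if (is.null(raw) || length(raw) == 0) abort("section rules are empty")
  tibble::tibble(
    label = purrr::map_chr(raw, "label"),
    pattern = purrr::map_chr(raw, "pattern"),
    disposition = purrr::map_chr(raw, "disposition"),
    require_colon = purrr::map_lgl(raw, function(r) {
      isTRUE(r$require_colon %||% TRUE)
    })
  )
}

#' @rdname load_section_rules
#' @export
default_section_rules_path <- function() {
  system.file("extdata", "section_rules.yaml", package = "promnlp",
              mustWork = TRUE)
}

#' Segment a note body into labeled sections
#'
#' Every character of the body belongs to exactly one section. Text before
#' the first recognised header forms an implicit `preamble` section with
#' include disposition. A rule with `require_colon = TRUE` matches a
#' line-initial phrase followed by a colon; with `require_colon = FALSE` the
#' phrase opens a section wherever it occurs, even mid-line. The governing
#' section of any offset is the one opened by the nearest preceding header.
#'
#' @param body Note body text.
#' @param rules Section rules from [load_section_rules()].
#' @return A tibble with `label`, `disposition`, `header_start`,
#'   `header_end`, `body_start`, `body_end` (0-based half-open); the
#'   coverage region of a section runs from its header start to its body end.
#' @export
detect_sections <- function(body, rules = load_section_rules()) {
  if (is.null(rules) || nrow(rules) == 0) abort("section rules are empty")
  len <- nchar(body)
  hits <- purrr::map(seq_len(nrow(rules)), function(i) {
    pat <- if (rules$require_colon[i]) {
      paste0("(?im)^[ \\t]*", escape_regex_phrase(rules$pattern[i]), "[ \\t]*:")
    } else {
      paste0("(?i)\\b", escape_regex_phrase(rules$pattern[i]), "\\b")
    }
    m <- gregexpr(pat, body, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble::tibble(
      label = rules$label[i],
      disposition = rules$disposition[i],
      header_start = as.integer(m) - 1L,
      header_end = as.integer(m) - 1L + attr(m, "match.length")
    )
  }) |> purrr::list_rbind()

  if (!is.null(hits) && nrow(hits) > 0) {
    hits <- hits[order(hits$header_start, -(hits$header_end)), ]
    keep <- logical(nrow(hits))
    last_end <- -1L
    for (i in seq_len(nrow(hits))) {
      if (hits$header_start[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- hits$header_end[i]
      }
    }
    hits <- hits[keep, ]
  }

  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble::tibble(
      label = "preamble", disposition = "include",
      header_start = NA_integer_, header_end = NA_integer_,
      body_start = 0L, body_end = len
    ))
  }
  sections <- tibble::tibble(
    label = hits$label,
    disposition = hits$disposition,
    header_start = hits$header_start,
    header_end = hits$header_end,
    body_start = hits$header_end,
    body_end = c(hits$header_start[-1], len)
  )
  if (sections$header_start[1] > 0) {
    sections <- dplyr::bind_rows(
      tibble::tibble(
        label = "preamble", disposition = "include",
        header_start = NA_integer_, header_end = NA_integer_,
        body_start = 0L, body_end = sections$header_start[1]
      ),
      sections
    )
  }
  sections
}

escape_regex_phrase <- function(x) {
  toks <- strsplit(stringr::str_squish(x), " ", fixed = TRUE)[[1]]
  paste(purrr::map_chr(toks, escape_regex), collapse = "[\\s]+")
}

#' Drop spans whose governing section is excluded
#'
#' A span is kept iff the section opened by the nearest preceding header has
#' include disposition. Dropped spans are recorded on the result as the
#' `"dropped"` attribute (an audit trail), each labeled with its section.
#'
#' @param spans Span tibble from [find_candidate_spans()].
#' @param sections Section tibble from [detect_sections()].
#' @return The kept spans with a `section_label` column; dropped spans (with
#'   the same columns) in `attr(, "dropped")`.
#' @export
apply_section_filter <- function(spans, sections) {
  if (nrow(spans) == 0) {
    out <- dplyr::mutate(spans, section_label = character(0))
    attr(out, "dropped") <- out
    return(out)
  }
  region_start <- ifelse(is.na(sections$header_start),
                         sections$body_start, sections$header_start)
  idx <- findInterval(spans$start, region_start)
  if (any(idx == 0)) {
    abort("internal error: span precedes all sections (coverage invariant broken)")
  }
  spans$section_label <- sections$label[idx]
  keep <- sections$disposition[idx] == "include"
  out <- spans[keep, ]
  attr(out, "dropped") <- spans[!keep, ]
  out
}

#' Annotate one clinic note with the full rule-based pipeline
#'
#' Composition of [find_candidate_spans()], [detect_sections()] and
#' [apply_section_filter()], cast to a note-level binary label. Only the
#' clinical body is scanned; the metadata header is never searched.
#'
#' @inheritParams find_candidate_spans
#' @param section_rules Section rules from [load_section_rules()].
#' @param filter_sections Set `FALSE` to skip section filtering (ablation).
#' @return An object of class `prom_note_result`: a list with `spans` (kept
#'   spans with section labels), `dropped`, `sections`, `prom_positive`
#'   (`TRUE` iff any span survives) and `per_prom` (named logical over all
#'   catalog measures).
#' @export
annotate_note <- function(body, catalog, section_rules = load_section_rules(),
                          fuzz = fuzz_policy(), filter_sections = TRUE,
                          compiled = NULL) {
  spans <- find_candidate_spans(body, catalog, fuzz, compiled = compiled)
  sections <- detect_sections(body, section_rules)
  if (filter_sections) {
    kept <- apply_section_filter(spans, sections)
    dropped <- attr(kept, "dropped")
    attr(kept, "dropped") <- NULL
  } else {
    kept <- spans
    kept$section_label <- NA_character_
    dropped <- kept[0, ]
  }
  per_prom <- setNames(
    catalog$definitions$prom_id %in% kept$prom_id,
    catalog$definitions$prom_id
  )
  structure(
    list(
      spans = kept,
      dropped = dropped,
      sections = sections,
      prom_positive = nrow(kept) > 0,
      per_prom = per_prom
    ),
    class = "prom_note_result"
  )
}

#' @export
print.prom_note_result <- function(x, ...) {
  cat(sprintf(
    "Note result: %s (%d span%s kept, %d dropped by section filter)\n",
    if (x$prom_positive) "PROM-positive" else "PROM-negative",
    nrow(x$spans), if (nrow(x$spans) == 1) "" else "s", nrow(x$dropped)
  ))
  if (nrow(x$spans) > 0) print(x$spans)
  invisible(x)
}

#' Annotate every note of a corpus
#'
#' @param corpus A data frame with `visit_id` and `body` columns (e.g. from
#'   [prepare_corpus()] or [generate_corpus()]).
#' @inheritParams annotate_note
#' @return The corpus tibble with list-column `spans`, plus `n_spans` and
#'   `prom_positive`.
#' @export
annotate_corpus <- function(corpus, catalog, section_rules = load_section_rules(),
                            fuzz = fuzz_policy(), filter_sections = TRUE) {
  stopifnot_cols(corpus, c("visit_id", "body"), "corpus")
  compiled <- compile_catalog(catalog, fuzz)
  res <- purrr::map(corpus$body, function(b) {
    annotate_note(b, catalog, section_rules, fuzz,
                  filter_sections = filter_sections, compiled = compiled)
  })
  corpus |>
    dplyr::mutate(
      spans = purrr::map(res, "spans"),
      n_spans = purrr::map_int(.data$spans, nrow),
      prom_positive = purrr::map_lgl(res, "prom_positive")
    )
}

#' PROM documentation prevalence, overall and per stratum
#'
#' @param results A data frame with a logical `prom_positive` column (e.g.
#'   from [annotate_corpus()]).
#' @param strata Optional stratification column (tidy-eval), e.g. `category`.
#' @return A tibble with `stratum`, `n`, `positives` and `prevalence_pct`
#'   (percent, one decimal); the first row is the overall figure.
#' @export
corpus_prevalence <- function(results, strata = NULL) {
  if (is.null(results) || nrow(results) == 0) abort("empty results")
  stopifnot_cols(results, "prom_positive", "results")
  overall <- tibble::tibble(
    stratum = "overall",
    n = nrow(results),
    positives = sum(results$prom_positive),
    prevalence_pct = round(100 * sum(results$prom_positive) / nrow(results), 1)
  )
  if (rlang::quo_is_null(rlang::enquo(strata))) {
    return(overall)
  }
  by_stratum <- results |>
    dplyr::group_by(stratum = as.character({{ strata }})) |>
    dplyr::summarise(
      n = dplyr::n(),
      positives = sum(.data$prom_positive),
      prevalence_pct = round(100 * .data$positives / .data$n, 1),
      .groups = "drop"
    )
  dplyr::bind_rows(overall, by_stratum)
}
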