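# JSONL corpus and standoff-annotation I/O. One JSON object per line;
# note bodies round-trip exactly (JSON escaping preserves newlines), so
# character offsets into the body are stable across serialization.

write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Read and write raw notes as JSONL
#'
#' One raw note per line with fields `note_id`, `visit_id`, `patient_id`,
#' `service_date` (ISO-8601), `facility_id`, `author_role`, `text`.
#'
#' @param path File path.
#' @param notes A data frame of raw notes.
#' @return `read_notes_jsonl()` returns a tibble; the writer returns the path
#'   invisibly.
#' @export
read_notes_jsonl <- function(path) {
  recs <- read_jsonl(path)
  purrr::map(recs, function(r) {
    tibble::tibble(
      note_id = r$note_id,
      visit_id = r$visit_id,
      patient_id = r$patient_id,
      service_date = as.Date(r$service_date),
      facility_id = r$facility_id,
      author_role = r$author_role %||% NA_character_,
      text = r$text
    )
  }) |> purrr::list_rbind()
}

#' @rdname read_notes_jsonl
#' @export
write_notes_jsonl <- function(notes, path) {
  stopifnot_cols(notes, c("note_id", "visit_id", "patient_id", "service_date",
                          "facility_id", "text"), "notes")
  recs <- purrr::map(seq_len(nrow(notes)), function(i) {
    list(
      note_id = notes$note_id[i],
      visit_id = notes$visit_id[i],
      patient_id = notes$patient_id[i],
      service_date = format(as.Date(notes$service_date[i])),
      facility_id = notes$facility_id[i],
      author_role = if ("author_role" %in% names(notes)) notes$author_role[i] else NULL,
      text = notes$text[i]
    )
  })
  write_jsonl(recs, path)
}

#' Read and write a prepared visit-note corpus as JSONL
#'
#' Serialises the merged clinic note together with its visit metadata;
#' offsets into `body` are preserved exactly across a round-trip.
#'
#' @param corpus A corpus tibble (from [prepare_corpus()] or
#'   [generate_corpus()]).
#' @param path File path.
#' @return `read_corpus_jsonl()` returns a tibble; the writer returns the
#'   path invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot_cols(corpus, c("visit_id", "patient_id", "service_date",
                           "facility_id", "body"), "corpus")
  recs <- purrr::map(seq_len(nrow(corpus)), function(i) {
    r <- list(
      visit_id = corpus$visit_id[i],
      patient_id = corpus$patient_id[i],
      service_date = format(as.Date(corpus$service_date[i])),
      facility_id = corpus$facility_id[i],
      consult_date = if ("consult_date" %in% names(corpus)) {
        format(as.Date(corpus$consult_date[i]))
      } else NULL,
      visit_index = corpus$visit_index[i],
      visit_total = corpus$visit_total[i],
      days_since_prev = corpus$days_since_prev[i],
      days_to_next = corpus$days_to_next[i],
      category = as.character(corpus$category[i]),
      header = if ("header" %in% names(corpus)) corpus$header[i] else NULL,
      body = corpus$body[i]
    )
    r[!vapply(r, function(x) is.null(x) || all(is.na(x)), logical(1))]
  })
  write_jsonl(recs, path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  recs <- read_jsonl(path)
  purrr::map(recs, function(r) {
    tibble::tibble(
      visit_id = r$visit_id,
      patient_id = r$patient_id,
      service_date = as.Date(r$service_date),
      facility_id = r$facility_id,
      consult_date = as.Date(r$consult_date %||% NA),
      visit_index = as.integer(r$visit_index %||% NA),
      visit_total = as.integer(r$visit_total %||% NA),
      days_since_prev = as.integer(r$days_since_prev %||% NA),
      days_to_next = as.integer(r$days_to_next %||% NA),
      category = r$category %||% NA_character_,
      header = r$header %||% NA_character_,
      body = r$body
    )
  }) |> purrr::list_rbind()
}

#' Read and write standoff span annotations as JSONL
#'
#' One object per note: `{visit_id, spans: [{start, end, prom_id, source}]}`,
#' with 0-based half-open character offsets into the note body.
#'
#' @param results Either an annotated corpus (with `visit_id` and a `spans`
#'   list-column) or a flat span tibble with a `visit_id` column.
#' @param path File path.
#' @return `read_annotations_jsonl()` returns a flat span tibble with
#'   `note_id`; the writer returns the path invisibly.
#' @export
write_annotations_jsonl <- function(results, path) {
  stopifnot_cols(results, "visit_id", "results")
  if ("spans" %in% names(results)) {
    per_note <- purrr::map2(results$visit_id, results$spans, function(id, sp) {
      list(visit_id = id, spans = sp[c("start", "end", "prom_id", "source")])
    })
  } else {
    stopifnot_cols(results, c("start", "end", "prom_id"), "results")
    split_spans <- split(results, results$visit_id)
    per_note <- purrr::imap(split_spans, function(sp, id) {
      list(visit_id = id, spans = sp[c("start", "end", "prom_id", "source")])
    })
  }
  write_jsonl(per_note, path)
}

#' @rdname write_annotations_jsonl
#' @export
read_annotations_jsonl <- function(path) {
  recs <- read_jsonl(path)
  purrr::map(recs, function(r) {
    sp <- r$spans
    if (is.null(sp) || length(sp) == 0 ||
        (is.data.frame(sp) && nrow(sp) == 0)) {
      return(NULL)
    }
    sp <- tibble::as_tibble(sp)
    sp$note_id <- r$visit_id
    sp
  }) |> purrr::list_rbind()
}
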