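# Internal helpers shared across modules. Span offsets everywhere in the
# package are 0-based, half-open [start, end) into the note body, so
# span_text(body, start, end) == the matched surface.

span_text <- function(body, start, end) {
  stringr::str_sub(body, start + 1L, end)
}

# Empty span table with the canonical column set.
span_tibble <- function() {
  tibble::tibble(
    start = integer(),
    end = integer(),
    surface = character(),
    prom_id = character(),
    match_kind = character(),
    source = character()
  )
}

# Normalize a surface form for lexicon comparisons: case-fold and collapse
# internal whitespace.
normalize_term <- function(x) {
  stringr::str_squish(tolower(x))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a bounded per-cycle seed from a master seed and a counter.
# Arithmetic in doubles (exact below 2^53) to avoid 32-bit overflow when
# cycle seeds are themselves re-expanded.
cycle_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(counter) * 7919) %%
               2147483629)
}

stopifnot_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
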