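# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, O(n^2) scans, textbook DP) and never share code with the
# implementation paths they check.

the_catalog <- load_prom_catalog()
the_rules <- load_section_rules()

# --- oracles ---------------------------------------------------------------

# Token count: split and count non-empty pieces.
oracle_token_count <- function(text) {
  vapply(strsplit(text, "[ \t\r\n\f\v]+"), function(t) sum(nzchar(t)),
         integer(1))
}

# Full Damerau-Levenshtein (optimal string alignment) distance by DP.
oracle_dl_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && ca[i] == cb[j - 1] && ca[i - 1] == cb[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# Maximum bipartite matching size by exhaustive recursion (instances <= 6x6).
oracle_max_matching <- function(gold, pred, min_overlap = 1L) {
  ng <- nrow(gold)
  np <- nrow(pred)
  if (ng == 0 || np == 0) return(0L)
  compatible <- matrix(FALSE, ng, np)
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      ov <- min(gold$end[i], pred$end[j]) - max(gold$start[i], pred$start[j])
      compatible[i, j] <- ov >= min_overlap && gold$prom_id[i] == pred$prom_id[j]
    }
  }
  best <- 0L
  recurse <- function(i, used) {
    if (i > ng) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(i + 1L, used)   # leave gold i unmatched
    for (j in which(compatible[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1L, used)
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, np))
  best
}

# All-pairs concordance AUC (ties counted half).
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  100 * total / (length(pos) * length(neg))
}

# Random non-overlapping span set over a body of `len` characters.
random_span_set <- function(n_spans, len = 200, prom_ids = c("a", "b", "c")) {
  if (n_spans == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          prom_id = character()))
  }
  starts <- sort(sample.int(len - 6, n_spans))
  widths <- sample(2:5, n_spans, replace = TRUE)
  ends <- pmin(starts + widths, c(starts[-1], len))
  ok <- ends > starts
  tibble::tibble(
    start = starts[ok],
    end = ends[ok],
    prom_id = sample(prom_ids, sum(ok), replace = TRUE)
  )
}

# --- small shared fixtures -------------------------------------------------

tiny_raw_notes <- function() {
  tibble::tibble(
    note_id = c("N2", "N1", "N3"),
    visit_id = "V1",
    patient_id = "P1",
    service_date = as.Date("2018-03-01"),
    facility_id = "F001",
    author_role = c("attending", "resident", "attending"),
    text = c("attending note", "resident note", "addendum")
  )
}

tiny_visit <- function() {
  list(
    patient_id = "P1", visit_id = "V3", service_date = as.Date("2018-02-01"),
    facility_id = "F017", consult_date = as.Date("2018-01-01"),
    visit_index = 3L, visit_total = 6L,
    days_since_prev = 14L, days_to_next = 7L
  )
}

# Keyword-separable classification dataset: the generator's gold labels are
# a deterministic function of planted lexical content.
separable_dataset <- function(n, seed, prevalence = 0.4) {
  cfg <- sim_config(
    n_patients = ceiling(n / 6.5) + 20,
    prom_prevalence = prevalence,
    excluded_mention_rate = 0,
    seed = seed
  )
  corp <- generate_corpus(cfg, the_catalog)
  stopifnot(nrow(corp) >= n)
  tibble::tibble(text = corp$body, label = corp$gold_label)[seq_len(n), ]
}
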