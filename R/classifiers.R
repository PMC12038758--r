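# Note-categorization baselines: a linear bag-of-words model, a compact
# convolutional token-embedding network, and a score-averaging ensemble.

bow_tokens <- function(text) {
  text <- tolower(text)
  text <- stringr::str_replace_all(text, "[^a-z0-9']+", " ")
  toks <- strsplit(stringr::str_squish(text), " ", fixed = TRUE)
  lapply(toks, function(t) t[t != ""])
}

doc_ngrams <- function(tokens, ngram_range) {
  out <- character(0)
  for (n in seq(ngram_range[1], ngram_range[2])) {
    if (length(tokens) >= n) {
      if (n == 1) {
        out <- c(out, tokens)
      } else {
        idx <- seq_len(length(tokens) - n + 1)
        grams <- tokens[idx]
        for (j in 2:n) grams <- paste(grams, tokens[idx + j - 1], sep = "_")
        out <- c(out, grams)
      }
    }
  }
  out
}

#' Bag-of-words featurizer
#'
#' Builds a deterministic (sorted) n-gram vocabulary from the training texts
#' and the corresponding sparse document-term count matrix. Tokenization is
#' lowercase with non-alphanumeric characters treated as separators.
#'
#' @param texts Character vector of documents.
#' @param ngram_range Inclusive n-gram orders, default `c(1, 2)` (unigrams
#'   and bigrams).
#' @param min_count Minimum total corpus count for a term to enter the
#'   vocabulary.
#' @return An object of class `prom_bow`: list with `vocabulary` (sorted
#'   character), `counts` (sparse docs x terms matrix), `ngram_range`,
#'   `min_count`.
#' @export
featurize_bow <- function(texts, ngram_range = c(1, 2), min_count = 1) {
  if (length(texts) == 0) abort("no texts to featurize")
  grams <- lapply(bow_tokens(texts), doc_ngrams, ngram_range = ngram_range)
  if (all(lengths(grams) == 0)) abort("all texts are empty after tokenization")
  totals <- table(unlist(grams, use.names = FALSE))
  vocabulary <- sort(names(totals)[totals >= min_count])
  obj <- structure(
    list(vocabulary = vocabulary, ngram_range = ngram_range,
         min_count = min_count),
    class = "prom_bow"
  )
  obj$counts <- bow_matrix(obj, texts, grams = grams)
  obj
}

# Project documents onto an existing vocabulary (OOV terms are dropped).
bow_matrix <- function(features, texts, grams = NULL) {
  if (is.null(grams)) {
    grams <- lapply(bow_tokens(texts), doc_ngrams,
                    ngram_range = features$ngram_range)
  }
  vocab <- features$vocabulary
  triplets <- purrr::imap(grams, function(g, i) {
    idx <- match(g, vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return(NULL)
    tb <- table(idx)
    cbind(i = i, j = as.integer(names(tb)), x = as.integer(tb))
  })
  triplets <- do.call(rbind, triplets)
  if (is.null(triplets)) {
    return(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(length(texts), length(vocab)), dimnames = list(NULL, vocab)
    ))
  }
  Matrix::sparseMatrix(
    i = triplets[, "i"], j = triplets[, "j"], x = triplets[, "x"],
    dims = c(length(texts), length(vocab)), dimnames = list(NULL, vocab)
  )
}

#' Train a note-categorization classifier
#'
#' Three architectures are available:
#' \describe{
#'   \item{`bow`}{ridge-regularized logistic regression on 1-2 gram counts
#'     (via glmnet), with the regularization strength chosen on the
#'     development set by F-measure;}
#'   \item{`cnn`}{a compact convolutional network — learned token embeddings,
#'     one 1-D convolution layer with ReLU, max-pooling over positions and a
#'     logistic head — trained by Adam, with the epoch snapshot chosen on the
#'     development set;}
#'   \item{`ensemble`}{a convex combination of the two scores with the weight
#'     tuned on the development set.}
#' }
#' All state (vocabulary, weights, tuned hyperparameters) derives only from
#' the train and development portions. Training is deterministic given
#' `seed`.
#'
#' @param kind `"bow"`, `"cnn"` or `"ensemble"`.
#' @param train,dev Data frames with `text` and logical `label` columns;
#'   the training portion must contain both classes.
#' @param hyperparams Named list of overrides (see Details in the package
#'   vignette); `threshold` sets the positive-call cutoff (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `prom_classifier`.
#' @export
train_model <- function(kind = c("bow", "cnn", "ensemble"), train, dev,
                        hyperparams = list(), seed = 1) {
  kind <- match.arg(kind)
  stopifnot_cols(train, c("text", "label"), "train")
  stopifnot_cols(dev, c("text", "label"), "dev")
  if (dplyr::n_distinct(train$label) < 2) {
    abort("single-class training data: both classes are required")
  }
  threshold <- hyperparams$threshold %||% 0.5
  state <- switch(kind,
    bow = train_bow(train, dev, hyperparams, seed),
    cnn = train_cnn(train, dev, hyperparams, seed),
    ensemble = train_ensemble(train, dev, hyperparams, seed)
  )
  structure(
    list(kind = kind, state = state, threshold = threshold, seed = seed),
    class = "prom_classifier"
  )
}

train_bow <- function(train, dev, hp, seed) {
  features <- featurize_bow(
    train$text,
    ngram_range = hp$ngram_range %||% c(1, 2),
    min_count = hp$min_count %||% 1
  )
  x <- features$counts
  if (ncol(x) < 2) abort("bag-of-words vocabulary is too small to fit")
  y <- as.numeric(train$label)
  # explicit grid: glmnet's automatic ridge path starts far too strong for
  # sparse count features, leaving every model under-confident
  lambda <- hp$lambda %||% 10^seq(2, -4, length.out = hp$nlambda %||% 30)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  xdev <- bow_matrix(features, dev$text)
  probs <- predict(fit, xdev, type = "response")
  fscores <- apply(probs, 2, function(p) {
    dev_f(dev$label, p >= (hp$threshold %||% 0.5))
  })
  best <- which.max(fscores)
  beta <- as.numeric(fit$beta[, best])
  list(
    features = features[c("vocabulary", "ngram_range", "min_count")],
    intercept = fit$a0[[best]],
    beta = beta,
    lambda = fit$lambda[best]
  )
}

# Dev-set F-measure used for hyperparameter selection (0 when degenerate).
dev_f <- function(labels, pred) {
  tp <- sum(labels & pred)
  fp <- sum(!labels & pred)
  fn <- sum(labels & !pred)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  200 * p * r / (p + r)
}

train_ensemble <- function(train, dev, hp, seed) {
  bow <- train_bow(train, dev, hp, seed)
  cnn <- train_cnn(train, dev, hp, seed)
  s_bow <- score_bow(bow, dev$text)
  s_cnn <- score_cnn(cnn, dev$text)
  weights <- seq(0, 1, by = 0.1)
  fscores <- purrr::map_dbl(weights, function(w) {
    dev_f(dev$label, (w * s_bow + (1 - w) * s_cnn) >= (hp$threshold %||% 0.5))
  })
  list(bow = bow, cnn = cnn, weight = weights[which.max(fscores)])
}

score_bow <- function(state, text) {
  features <- structure(state$features, class = "prom_bow")
  x <- bow_matrix(features, text)
  as.numeric(stats::plogis(as.numeric(x %*% state$beta) + state$intercept))
}

#' Predicted probability of documented PROM use
#'
#' @param model A trained [train_model()] classifier.
#' @param text Character vector of note texts.
#' @return Numeric scores in `[0, 1]`; the positive label corresponds to
#'   `score >= model$threshold`.
#' @export
predict_proba <- function(model, text) {
  if (!inherits(model, "prom_classifier")) {
    abort("model must be a trained prom_classifier")
  }
  switch(model$kind,
    bow = score_bow(model$state, text),
    cnn = score_cnn(model$state, text),
    rule = purrr::map_dbl(text, function(b) {
      res <- annotate_note(b, model$state$catalog, model$state$section_rules,
                           model$state$fuzz, compiled = model$state$compiled)
      as.numeric(res$prom_positive)
    }),
    ensemble = {
      w <- model$state$weight
      w * score_bow(model$state$bow, text) +
        (1 - w) * score_cnn(model$state$cnn, text)
    }
  )
}

#' @export
predict.prom_classifier <- function(object, text, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, text)
  if (type == "prob") p else p >= object$threshold
}

#' @export
print.prom_classifier <- function(x, ...) {
  cat(sprintf("prom_classifier: %s (threshold %.2f, seed %s)\n",
              x$kind, x$threshold, format(x$seed)))
  invisible(x)
}

#' @export
#' @method glance prom_classifier
glance.prom_classifier <- function(x, ...) {
  vocab_size <- switch(x$kind,
    bow = length(x$state$features$vocabulary),
    cnn = length(x$state$vocab),
    ensemble = length(x$state$bow$features$vocabulary)
  )
  tibble::tibble(
    kind = x$kind, threshold = x$threshold,
    vocabulary_size = vocab_size, seed = x$seed
  )
}

#' @export
#' @method tidy prom_classifier
tidy.prom_classifier <- function(x, ...) {
  if (x$kind != "bow") {
    abort("tidy() coefficients are only available for the bow classifier")
  }
  tibble::tibble(
    term = c("(Intercept)", x$state$features$vocabulary),
    estimate = c(x$state$intercept, x$state$beta)
  ) |> dplyr::filter(.data$estimate != 0 | .data$term == "(Intercept)")
}

#' Build a trainer closure for the cross-validation drivers
#'
#' @inheritParams train_model
#' @return A function `(train, dev, seed) -> prom_classifier` suitable for
#'   [monte_carlo_cv()] and [repeated_kfold_cv()].
#' @export
classifier_trainer <- function(kind = c("bow", "cnn", "ensemble"),
                               hyperparams = list()) {
  kind <- match.arg(kind)
  function(train, dev, seed) {
    train_model(kind, train, dev, hyperparams = hyperparams, seed = seed)
  }
}

#' A deterministic rule-based "trainer" for comparison runs
#'
#' Wraps the rule-based pipeline in the trainer interface: it ignores the
#' training and development portions entirely and emits hard 0/1 scores, so
#' AUC-ROC is not meaningful for it.
#'
#' @param catalog,section_rules,fuzz Pipeline configuration.
#' @return A trainer function for the CV drivers.
#' @export
rule_based_trainer <- function(catalog = load_prom_catalog(),
                               section_rules = load_section_rules(),
                               fuzz = fuzz_policy()) {
  compiled <- compile_catalog(catalog, fuzz)
  function(train, dev, seed) {
    structure(
      list(
        kind = "rule", threshold = 0.5,
        state = list(catalog = catalog, section_rules = section_rules,
                     fuzz = fuzz, compiled = compiled),
        seed = seed
      ),
      class = "prom_classifier"
    )
  }
}
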