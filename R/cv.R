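# Cross-validation: Monte Carlo splits and repeated (optionally stratified)
# k-fold schemes, with per-cycle metrics and 95% confidence intervals.

# Evaluate one trained model on one test portion, returning a metric row.
cv_cycle_metrics <- function(model, test, cycle) {
  scores <- predict_proba(model, test$text)
  thr <- model$threshold %||% 0.5
  pred_lab <- scores >= thr
  counts <- match_counts(
    tp = sum(test$label & pred_lab),
    fp = sum(!test$label & pred_lab),
    fn = sum(test$label & !pred_lab),
    tn = sum(!test$label & !pred_lab)
  )
  metrics <- suppressWarnings(precision_recall_f(counts))
  auc <- if (sum(test$label) > 0 && sum(!test$label) > 0) {
    auc_roc(scores, test$label)
  } else {
    NA_real_
  }
  tibble::tibble(
    cycle = cycle,
    precision = metrics$precision,
    recall = metrics$recall,
    f_measure = metrics$f_measure,
    accuracy = metrics$accuracy,
    auc_roc = auc
  )
}

new_prom_cv <- function(scheme, per_cycle, seed, ci_method = "normal") {
  metrics <- c("precision", "recall", "f_measure", "accuracy", "auc_roc")
  summary <- purrr::map(metrics, function(mm) {
    v <- per_cycle[[mm]]
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NULL)
    dplyr::mutate(summarize_cycles(v, method = ci_method), metric = mm,
                  .before = 1)
  }) |> purrr::list_rbind()
  structure(
    list(
      scheme = scheme,
      cycles = nrow(per_cycle),
      per_cycle = per_cycle,
      summary = summary,
      seed = seed,
      ci_method = ci_method
    ),
    class = "prom_cv"
  )
}

#' Monte Carlo cross-validation
#'
#' Runs `cycles` independent random partitions of the dataset into
#' train/development/test portions (default 75%/15%/10%), trains via
#' `trainer(train, dev, seed)` each cycle, and evaluates precision, recall,
#' F-measure, accuracy and AUC-ROC on the held-out test portion. The master
#' seed expands to per-cycle seeds by a counter, so results are fully
#' reproducible.
#'
#' @param dataset A data frame with `text` and logical `label` columns; at
#'   least 20 rows.
#' @param trainer A function `(train, dev, seed) -> model` whose result works
#'   with [predict_proba()]; see [classifier_trainer()].
#' @param cycles Number of simulation cycles (default 100).
#' @param split Train/dev/test proportions summing to 1.
#' @param seed Master integer seed.
#' @param ci_method `"normal"` (mean +/- 1.96 sd/sqrt(n)) or `"percentile"`.
#' @return An object of class `prom_cv`; see [summarize_cycles()], `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
monte_carlo_cv <- function(dataset, trainer, cycles = 100,
                           split = c(0.75, 0.15, 0.10), seed = 1,
                           ci_method = "normal") {
  stopifnot_cols(dataset, c("text", "label"), "dataset")
  if (nrow(dataset) < 20) abort("dataset must have at least 20 items")
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-8) {
    abort("split must be three proportions summing to 1")
  }
  n <- nrow(dataset)
  n_train <- round(split[1] * n)
  n_dev <- round(split[2] * n)
  n_test <- n - n_train - n_dev
  if (n_test < 1) abort("test portion is empty under this split")
  per_cycle <- purrr::map(seq_len(cycles), function(cy) {
    cs <- cycle_seed(seed, cy)
    with_seed(cs, {
      perm <- sample.int(n)
      train <- dataset[perm[seq_len(n_train)], ]
      dev <- dataset[perm[n_train + seq_len(n_dev)], ]
      test <- dataset[perm[(n_train + n_dev + 1):n], ]
      model <- trainer(train, dev, cs)
      cv_cycle_metrics(model, test, cy)
    })
  }) |> purrr::list_rbind()
  new_prom_cv("monte_carlo", per_cycle, seed, ci_method)
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, items are partitioned into `k` folds (stratified partitioning
#' deals each label class round-robin, keeping per-fold prevalence within
#' one item of the global rate). Each cycle rotates the test fold, uses the
#' next fold as the development set and the remaining `k - 2` folds for
#' training, giving `k * repeats` cycles (100 at the defaults).
#'
#' @inheritParams monte_carlo_cv
#' @param k Number of folds (default 10; must be at least 3 so train,
#'   development and test roles are disjoint).
#' @param repeats Number of repeated partitions (default 10).
#' @param stratified Preserve label prevalence per fold?
#' @return An object of class `prom_cv`.
#' @export
repeated_kfold_cv <- function(dataset, trainer, k = 10, repeats = 10,
                              stratified = FALSE, seed = 1,
                              ci_method = "normal") {
  stopifnot_cols(dataset, c("text", "label"), "dataset")
  if (k < 3) abort("k must be at least 3 (train/dev/test roles)")
  n <- nrow(dataset)
  if (n < k) abort("dataset smaller than k")
  per_cycle <- purrr::map(seq_len(repeats), function(rep_i) {
    rs <- cycle_seed(seed, rep_i)
    folds <- with_seed(rs, make_folds(dataset$label, k, stratified))
    purrr::map(seq_len(k), function(f) {
      cy <- (rep_i - 1L) * k + f
      dev_fold <- f %% k + 1L
      test <- dataset[folds == f, ]
      dev <- dataset[folds == dev_fold, ]
      train <- dataset[!(folds %in% c(f, dev_fold)), ]
      model <- with_seed(cycle_seed(rs, f), trainer(train, dev, cycle_seed(rs, f)))
      cv_cycle_metrics(model, test, cy)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  scheme <- if (stratified) "stratified_kfold" else "kfold"
  new_prom_cv(scheme, per_cycle, seed, ci_method)
}

# Fold assignment; stratified deals each class round-robin after shuffling.
make_folds <- function(labels, k, stratified) {
  n <- length(labels)
  folds <- integer(n)
  if (stratified) {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

#' Summarise per-cycle metric values with a 95% confidence interval
#'
#' @param values Numeric vector of per-cycle values (at least 2).
#' @param method `"normal"` for mean +/- 1.96 sd/sqrt(n) (the default) or
#'   `"percentile"` for the 2.5/97.5 empirical quantiles.
#' @return A one-row tibble with `mean`, `ci_low`, `ci_high`, `sd`, `n`.
#' @export
summarize_cycles <- function(values, method = c("normal", "percentile")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 cycle values")
  m <- mean(values)
  s <- stats::sd(values)
  if (method == "normal") {
    half <- 1.96 * s / sqrt(length(values))
    lo <- m - half
    hi <- m + half
  } else {
    q <- stats::quantile(values, c(0.025, 0.975), names = FALSE)
    lo <- q[1]
    hi <- q[2]
  }
  tibble::tibble(mean = m, ci_low = lo, ci_high = hi, sd = s, n = length(values))
}

#' @export
print.prom_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d cycles (seed %s, %s CI)\n",
              x$scheme, x$cycles, format(x$seed), x$ci_method))
  if (!is.null(x$summary)) {
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-10s %5.1f (%.1f-%.1f)\n",
                  s$metric[i], s$mean[i], s$ci_low[i], s$ci_high[i]))
    }
  }
  invisible(x)
}

#' @export
#' @method tidy prom_cv
tidy.prom_cv <- function(x, ...) x$summary

#' @export
#' @method glance prom_cv
glance.prom_cv <- function(x, ...) {
  wide <- x$summary |>
    dplyr::select("metric", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
  dplyr::bind_cols(
    tibble::tibble(scheme = x$scheme, cycles = x$cycles, seed = x$seed),
    wide
  )
}

#' @export
#' @method autoplot prom_cv
autoplot.prom_cv <- function(object, ...) {
  long <- object$per_cycle |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c("precision", "recall", "f_measure", "auc_roc")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  summ <- object$summary
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_pointrange(
      data = summ[summ$metric %in% long$metric, ],
      ggplot2::aes(x = .data$metric, y = .data$mean,
                   ymin = .data$ci_low, ymax = .data$ci_high),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = NULL, y = "percent",
      title = sprintf("%s cross-validation (%d cycles)",
                      object$scheme, object$cycles)
    )
}
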