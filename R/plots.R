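# Plot helpers.

#' Histogram of note token lengths with an overflow bin
#'
#' Notes longer than `overflow` tokens are pooled into a single rightmost
#' bin, keeping the bulk of the distribution readable despite the long right
#' tail typical of clinic notes.
#'
#' @param data A data frame.
#' @param tokens Column of token counts (tidy-eval).
#' @param group Optional faceting column (tidy-eval), e.g. visit category.
#' @param overflow Overflow threshold in tokens (default 2000).
#' @param binwidth Histogram bin width (default 100 tokens).
#' @return A ggplot object.
#' @export
plot_token_lengths <- function(data, tokens, group = NULL, overflow = 2000,
                               binwidth = 100) {
  tk <- pmin(dplyr::pull(data, {{ tokens }}), overflow + binwidth / 2)
  df <- tibble::tibble(tokens = tk)
  has_group <- !rlang::quo_is_null(rlang::enquo(group))
  if (has_group) {
    df$group <- as.character(dplyr::pull(data, {{ group }}))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tokens)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = overflow, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("tokens (overflow bin: > %d)", overflow),
      y = "notes"
    )
  if (has_group) p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  p
}
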