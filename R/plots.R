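# Optional ggplot2 renderings of the screen outputs.

#' Plot the screen heatmap
#'
#' @param heatmap Result of [aggregate_screen()].
#' @return A ggplot object (E2 rows, nucleophile columns, fill = mean
#'   discharge percentage).
#' @export
plot_screen_heatmap <- function(heatmap) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_screen_heatmap requires ggplot2")
  }
  m <- heatmap$matrix
  df <- data.frame(e2 = rep(rownames(m), ncol(m)),
                   nucleophile = rep(colnames(m), each = nrow(m)),
                   discharge = as.vector(m), stringsAsFactors = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = df$nucleophile, y = df$e2,
                                   fill = df$discharge)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% discharge", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot time-course means with SD error bars
#'
#' @param tc Result of [time_course()].
#' @return A ggplot object faceted by E2, one line per nucleophile.
#' @export
plot_time_course <- function(tc) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_time_course requires ggplot2")
  }
  lo <- tc$mean - ifelse(is.na(tc$sd), 0, tc$sd)
  hi <- tc$mean + ifelse(is.na(tc$sd), 0, tc$sd)
  ggplot2::ggplot(tc, ggplot2::aes(x = tc$time_min, y = tc$mean,
                                   colour = tc$nucleophile)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = lo, ymax = hi)) +
    ggplot2::facet_wrap(~e2) +
    ggplot2::labs(x = "time (min)", y = "% discharge",
                  colour = "nucleophile") +
    ggplot2::theme_minimal()
}
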