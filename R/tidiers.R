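#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted decoder
#'
#' Returns the band-score table with selection status: one row per screening
#' sub-band with its pseudo-F, rank, and whether it entered the model.
#'
#' @param x an `mi_tsm` model.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mi_tsm <- function(x, ...) {
  tbl <- x$band_scores
  tbl$selected <- tbl$rank <= x$G
  tbl
}

#' Glance at a fitted decoder
#'
#' @param x an `mi_tsm` model.
#' @param ... unused.
#' @return A one-row tibble: `G`, `C`, `n_merged_bands`, `n_dmfb_windows`,
#'   `n_time_windows`, `n_features`, `cv_accuracy` (training CV of the
#'   chosen hyperparameters).
#' @export
glance.mi_tsm <- function(x, ...) {
  cvrow <- x$cv_table[x$cv_table$G == x$G & x$cv_table$C == x$C, ]
  tibble::tibble(
    G = x$G, C = x$C, n_merged_bands = nrow(x$merged),
    n_dmfb_windows = nrow(x$dmfb$bands),
    n_time_windows = nrow(x$config$time_windows),
    n_features = x$n_features, cv_accuracy = cvrow$cv_accuracy[1L])
}

#' Tidy an evaluation result
#'
#' @param x an `mi_eval` from [evaluate_session_transfer()].
#' @param ... unused.
#' @return The per-class accuracy tibble.
#' @export
tidy.mi_eval <- function(x, ...) x$per_class

#' @export
glance.mi_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_trials = sum(x$confusion),
                 n_classes = nrow(x$confusion))
}

#' Plot sub-band pseudo-F scores
#'
#' Bar chart of the screening pseudo-F per sub-band; selected bands (when
#' the table comes from [tidy.mi_tsm()]) are highlighted.
#'
#' @param object a `band_score_table` or the tibble from [tidy.mi_tsm()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.band_score_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$f_lo + df$f_hi) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$F_stat))
  if ("selected" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$selected),
                               width = min(df$f_hi - df$f_lo) * 0.9) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey70"),
                                 name = "selected")
  } else {
    p <- p + ggplot2::geom_col(fill = "#2166ac",
                               width = min(df$f_hi - df$f_lo) * 0.9)
  }
  p + ggplot2::labs(x = "frequency (Hz)", y = "pseudo-F") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object an `mi_eval` result.
#' @param ... unused.
#' @return A ggplot heatmap of the confusion matrix.
#' @export
autoplot.mi_eval <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    true = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    n = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey80", high = "#2166ac") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
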