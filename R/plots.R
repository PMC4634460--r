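#' Plot a record with its APG and fiducials
#'
#' Two stacked panels: the filtered PPG and its second derivative (APG),
#' with a-wave (circles) and b-wave (triangles) positions marked.
#'
#' @param record A [ppg_record()].
#' @param fiducials Optional [fiducial_set()].
#' @param window Time window in seconds to display, e.g. `c(2, 8)`.
#' @param low,high,order Filter design.
#' @return A ggplot object.
#' @export
plot_ppg_record <- function(record, fiducials = NULL, window = NULL,
                            low = 0.5, high = 7, order = 2) {
  stopifnot(inherits(record, "ppg_record"))
  p <- process_signal(record, low = low, high = high, order = order)
  t <- (seq_len(record$n_samples) - 1) / record$fs
  df <- tibble::tibble(
    time_s = rep(t, 2L),
    value = c(p$ppg_filtered, p$apg),
    panel = rep(c("filtered PPG (a.u.)", "APG (a.u./s²)"), each = record$n_samples)
  )
  df$panel <- factor(df$panel, levels = unique(df$panel))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s, stage %s", record$subject_id, record$stage)) +
    ggplot2::theme_minimal()
  if (!is.null(fiducials) && fiducials$n_beats > 0L) {
    marks <- tibble::tibble(
      time_s = c(fiducials$a, fiducials$b) / record$fs,
      value = c(p$apg[fiducials$a + 1L], p$apg[fiducials$b + 1L]),
      wave = c(rep("a", length(fiducials$a)), rep("b", length(fiducials$b))),
      panel = factor(levels(df$panel)[2L], levels = levels(df$panel))
    )
    g <- g + ggplot2::geom_point(
      data = marks,
      ggplot2::aes(shape = .data$wave, colour = .data$wave), size = 2
    )
  }
  if (!is.null(window)) g <- g + ggplot2::coord_cartesian(xlim = window)
  g
}

#' @export
autoplot.heat_screen <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = -log10(.data$p_value),
                                     y = stats::reorder(.data$feature, -.data$p_value),
                                     colour = .data$comparison,
                                     shape = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")), linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  shape = "Holm-significant",
                  title = "Feature separability (baseline vs post-exercise)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.heat_classification <- function(object, ...) {
  oa <- glance(object)
  ggplot2::ggplot(oa, ggplot2::aes(x = .data$oa,
                                   y = stats::reorder(.data$feature, .data$oa))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 50, yend = .data$feature),
                          colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = 50, linetype = 2) +
    ggplot2::labs(x = "overall accuracy (%)", y = NULL,
                  title = "Leave-one-out overall accuracy by feature") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a feature pair with the LDA boundary
#'
#' Plots two features against each other for the baseline and one
#' post-exercise stage, with the linear-discriminant decision boundary
#' fitted on all shown records.
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param cols Two feature column names.
#' @param stage Post-exercise stage to contrast with `BE`.
#' @return A ggplot object.
#' @export
plot_feature_pair <- function(features, cols = c("energy_aa_ppg", "rmssd"),
                              stage = "E1") {
  stopifnot(length(cols) == 2L, all(cols %in% names(features)))
  sub <- features[features$stage %in% c("BE", stage), ]
  sub <- sub[complete.cases(sub[, cols]), ]
  y <- factor(ifelse(sub$stage == "BE", "BE", as.character(stage)))
  fit <- MASS::lda(as.matrix(sub[, cols]), grouping = y)
  w <- fit$scaling[, 1L]
  mid <- colMeans(fit$means)
  g <- ggplot2::ggplot(sub, ggplot2::aes(x = .data[[cols[1L]]],
                                         y = .data[[cols[2L]]],
                                         colour = .data$stage,
                                         shape = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = sprintf("BE vs %s", stage)) +
    ggplot2::theme_minimal()
  if (abs(w[2L]) > 1e-12) {
    slope <- -w[1L] / w[2L]
    g <- g + ggplot2::geom_abline(intercept = mid[2L] - slope * mid[1L],
                                  slope = slope, linetype = 2)
  }
  g
}
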