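#' Plot a sequence-context logo
#'
#' Information-content bars per offset with letters of the dominant
#' residues stacked by their share of the column's information, in
#' the style of a text sequence logo.
#'
#' @param object A [build_logo()] result.
#' @param min_frequency Residues below this column frequency are
#'   pooled and left unlabelled (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cit_logo
#' @export
autoplot.cit_logo <- function(object, min_frequency = 0.05, ...) {
  long <- tidy(object)
  long <- dplyr::filter(long, .data$frequency >= min_frequency,
                        !is.na(.data$information))
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$offset),
    bits = .data$frequency * .data$information,
    top = .data$frequency == max(.data$frequency)
  )
  long <- dplyr::arrange(dplyr::ungroup(long), .data$offset,
                         .data$frequency)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$bits,
                                     fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::geom_text(
      data = dplyr::filter(long, .data$top),
      ggplot2::aes(label = .data$residue,
                   y = .data$information + 0.15),
      size = 3
    ) +
    ggplot2::labs(x = "offset from citrullinated R",
                  y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a spectrum with its matched fragment ions
#'
#' Peak profile with matched peaks highlighted and labelled by ion.
#'
#' @param object A [match_peaks()] result.
#' @param spec The [spectrum()] the match was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_result
#' @export
autoplot.match_result <- function(object, spec, ...) {
  stopifnot(inherits(spec, "spectrum"))
  peaks <- spec$peaks
  matched <- tidy(object)
  matched$label <- ifelse(matched$series %in% c("b", "y"),
                          paste0(matched$series, matched$index),
                          matched$series)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = peaks,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                   yend = .data$intensity),
      colour = "grey70"
    ) +
    ggplot2::geom_segment(
      data = matched,
      ggplot2::aes(x = .data$peak_mz, xend = .data$peak_mz, y = 0,
                   yend = .data$intensity),
      colour = "firebrick"
    ) +
    ggplot2::geom_text(
      data = matched,
      ggplot2::aes(x = .data$peak_mz, y = .data$intensity,
                   label = .data$label),
      vjust = -0.4, size = 2.8, colour = "firebrick"
    ) +
    ggplot2::labs(x = "m/z", y = "intensity", title = spec$id) +
    ggplot2::theme_minimal()
}

#' Plot fold changes across the time course
#'
#' Dot plot of log2 fold change per record at 1 h and 24 h, coloured
#' by category, with the decision thresholds drawn.
#'
#' @param object Output of [categorize_changes()].
#' @param up,down The thresholds used (drawn as reference lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_changes <- function(object, up = 1.5, down = 1 / 1.5, ...) {
  long <- tidyr::pivot_longer(
    object,
    cols = c("fc_value_1h", "fc_value_24h"),
    names_to = "timepoint", values_to = "fc"
  )
  long$timepoint <- ifelse(long$timepoint == "fc_value_1h", "1 h", "24 h")
  long$category <- ifelse(long$timepoint == "1 h", long$category_1h,
                          long$category_24h)
  long <- dplyr::filter(long, !is.na(.data$fc))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint,
                                     y = log2(.data$fc),
                                     colour = .data$category)) +
    ggplot2::geom_hline(yintercept = log2(c(down, up)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2) +
    ggplot2::labs(x = NULL, y = "log2 fold change vs control") +
    ggplot2::theme_minimal()
}
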