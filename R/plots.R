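#' Plot a PPM validation as per-tier fit rates
#'
#' Grouped bars of the percentage of promoters fitting each model tier in
#' the positive and negative training sets.
#'
#' @param object A `ppm_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppm_validation
#' @export
autoplot.ppm_validation <- function(object, ...) {
  r <- tidy.ppm_validation(object) |>
    dplyr::select("tier", positive = "pos_rate_pct",
                  negative = "neg_rate_pct") |>
    tidyr::pivot_longer(c("positive", "negative"), names_to = "set",
                        values_to = "rate_pct") |>
    dplyr::mutate(tier = factor(.data$tier, levels = unname(tier_labels)),
                  set = factor(.data$set, levels = c("positive", "negative")))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$tier, y = .data$rate_pct,
                                  fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_fill_manual(values = c(positive = "grey20",
                                          negative = "grey70")) +
    ggplot2::labs(x = NULL, y = "promoters fitting the model (%)",
                  fill = "training set") +
    ggplot2::theme_minimal()
}

#' Promoter structure plot
#'
#' Draws each window as a horizontal line over signed promoter coordinates
#' with its binding-site hits as triangles: filled pointing up for
#' forward-orientation sites, open pointing down for reverse — the
#' conventional depiction of homotypic site clusters around a TSS.
#'
#' @param windows A window tibble.
#' @param motif Motif name(s) to display (default `"canonical"`).
#' @return A ggplot object.
#' @export
plot_promoter_structure <- function(windows, motif = "canonical") {
  hits <- scan_windows(windows, motif)
  lev <- windows$window_id
  frame <- tibble::tibble(
    window_id = factor(lev, levels = rev(lev)),
    gene = windows$gene_symbol,
    xmin = -windows$upstream, xmax = windows$downstream
  )
  hits <- dplyr::mutate(hits,
                        window_id = factor(.data$window_id, levels = rev(lev)))
  ggplot2::ggplot(frame) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                       y = .data$window_id,
                                       yend = .data$window_id),
                          colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(
      data = hits,
      ggplot2::aes(x = .data$signed_start, y = .data$window_id,
                   shape = .data$orientation, fill = .data$orientation),
      size = 3
    ) +
    ggplot2::scale_shape_manual(values = c(forward = 24, reverse = 25)) +
    ggplot2::scale_fill_manual(values = c(forward = "black",
                                          reverse = "white")) +
    ggplot2::scale_y_discrete(labels = stats::setNames(frame$gene,
                                                       frame$window_id)) +
    ggplot2::labs(x = "position relative to TSS (nt)", y = NULL) +
    ggplot2::theme_minimal()
}
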