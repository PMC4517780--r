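# ggplot2 views of gated populations: the flow-style DNA histogram, the
# two-dimensional gating scatters, and phase-distribution bars.

#' Plot the normalised-DNA histogram
#'
#' The flow-cytometry-style DNA-content histogram (default 300 bins over
#' normalised DNA 0-4, so G1 sits at 1 and G2/M at 2).
#'
#' @param records Gated tibble with `norm_dna` (e.g. `run$singlets`).
#' @param bins,max_dna Passed to [dna_histogram()].
#' @return A ggplot.
#' @export
plot_dna_histogram <- function(records, bins = 300, max_dna = 4) {
  h <- dna_histogram(records, bins = bins, max_dna = max_dna)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = max_dna / bins, fill = "grey30") +
    ggplot2::labs(x = "Normalised DNA content", y = "Nuclei") +
    ggplot2::theme_classic()
}

#' Gating scatter plots
#'
#' Normalised DNA versus log EdU sum (`y = "log_edu"`) or versus pHH3
#' mean on a log axis (`y = "phh3"`), coloured by assigned phase when
#' present, with the relevant gate rectangles overlaid.
#'
#' @param records Gated tibble (needs `norm_dna` and the y feature).
#' @param y `"log_edu"` or `"phh3"`.
#' @param spec Optional [gate_spec()] whose rectangles to draw.
#' @return A ggplot.
#' @export
plot_gate_scatter <- function(records, y = c("log_edu", "phh3"), spec = NULL) {
  y <- match.arg(y)
  ycol <- if (y == "log_edu") "log_edu" else "phh3_mean"
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$norm_dna, y = .data[[ycol]]))
  p <- if ("phase" %in% names(records)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$phase),
                            size = 0.4, alpha = 0.6)
  } else {
    p + ggplot2::geom_point(size = 0.4, alpha = 0.6, colour = "grey30")
  }
  if (!is.null(spec)) {
    rects <- gate_rectangles(spec, "norm_dna", ycol, records)
    if (nrow(rects))
      p <- p + ggplot2::geom_rect(
        data = rects,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = .data$ymin, ymax = .data$ymax),
        inherit.aes = FALSE, fill = NA, colour = "black",
        linetype = "dashed")
  }
  p <- p + ggplot2::labs(x = "Normalised DNA content",
                         y = if (y == "log_edu") "log10 EdU sum" else "pHH3 mean")
  if (y == "phh3") p <- p + ggplot2::scale_y_log10()
  p + ggplot2::theme_classic()
}

# finite drawing rectangles for gates referencing both plotted features
gate_rectangles <- function(spec, xcol, ycol, records) {
  lim <- function(v, lo, hi) c(max(lo, min(v, na.rm = TRUE)),
                               min(hi, max(v, na.rm = TRUE)))
  purrr::map_dfr(names(spec$gates), function(ph) {
    g <- spec$gates[[ph]]
    if (!all(c(xcol, ycol) %in% names(g))) return(tibble())
    xr <- lim(records[[xcol]], g[[xcol]][1], g[[xcol]][2])
    yr <- lim(records[[ycol]], g[[ycol]][1], g[[ycol]][2])
    tibble(phase = ph, xmin = xr[1], xmax = xr[2],
           ymin = yr[1], ymax = yr[2])
  })
}

#' Plot phase distributions
#'
#' Bar chart of per-condition phase fractions with replicate-well SD
#' error bars (from [aggregate_phase_distribution()] output or a
#' `cyclegate_run`).
#'
#' @param x Aggregated distribution tibble or a `cyclegate_run`.
#' @param condition Condition column name.
#' @return A ggplot.
#' @export
plot_phase_distribution <- function(x, condition = "condition") {
  if (inherits(x, "cyclegate_run")) x <- x$conditions
  ggplot2::ggplot(x, ggplot2::aes(x = .data$phase, y = .data$mean_fraction,
                                  fill = .data[[condition]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = "Cell-cycle phase", y = "Fraction of singlets") +
    ggplot2::theme_classic()
}

#' @rdname plot_phase_distribution
#' @param object A `cyclegate_run`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.cyclegate_run <- function(object, ...) {
  plot_phase_distribution(object)
}

#' @export
ggplot2::autoplot
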