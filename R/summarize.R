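#' Summarize an evaluation into report tables and plots
#'
#' Builds a forest-plot-ready hazard table (with the "excess hazard"
#' phrasing: a hazard ratio of 3.42 implies 2.42 greater hazard above the
#' low-risk reference), a ggplot forest plot, and log likelihood-ratio
#' lead-time curves. When \code{out_dir} is given, writes hazards.csv,
#' leadtime.csv, report.csv and PNG plots there.
#'
#' @param results a [fit_time_varying_cox()] result (or NULL)
#' @param curves a [compute_lead_time_lr()] result (or NULL)
#' @param out_dir optional output directory
#' @return list with \code{report} (data.frame), \code{forest_plot},
#'   \code{lead_time_plot} (ggplot objects or NULL)
#' @export
summarize_evaluation <- function(results = NULL, curves = NULL,
                                 out_dir = NULL) {
  report <- NULL
  forest <- NULL
  ltplot <- NULL

  if (!is.null(results)) {
    report <- data.frame(results)
    report$excess_hazard <- report$hr - 1
    forest <- ggplot2::ggplot(report,
      ggplot2::aes(x = .data$hr, y = .data$covariate)) +
      ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                           xmax = .data$ci_high),
                              height = 0.2) +
      ggplot2::geom_point(size = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "hazard ratio (log scale)", y = NULL,
                    title = "Time-varying Cox model") +
      ggplot2::theme_minimal()
  }
  if (!is.null(curves) && nrow(curves)) {
    ltplot <- ggplot2::ggplot(curves,
      ggplot2::aes(x = .data$h, y = .data$log_lr, color = .data$system)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~level) +
      ggplot2::labs(x = "hours before event (h)", y = "log L(x, h)",
                    title = "Lead-time likelihood ratio") +
      ggplot2::theme_minimal()
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report)) {
      utils::write.csv(report, file.path(out_dir, "report.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(results),
                       file.path(out_dir, "hazards.csv"), row.names = FALSE)
    }
    if (!is.null(curves)) {
      utils::write.csv(data.frame(curves),
                       file.path(out_dir, "leadtime.csv"), row.names = FALSE)
    }
    for (p in list(forest = forest, leadtime = ltplot)) {
      if (is.null(p)) next
      nm <- if (identical(p, forest)) "forest.png" else "leadtime.png"
      try(suppressMessages(ggplot2::ggsave(file.path(out_dir, nm), p,
                                           width = 7, height = 5,
                                           dpi = 120)),
          silent = TRUE)
    }
  }
  list(report = report, forest_plot = forest, lead_time_plot = ltplot)
}
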