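#' Plot a metric series
#'
#' @param ms a [metric_series] (or named list of them, drawn as coloured
#'   lines).
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_metric_series <- function(ms, title = NULL) {
  if (inherits(ms, "metric_series")) ms <- setNames(list(ms), attr(ms, "name"))
  df <- do.call(rbind, lapply(names(ms), function(nm)
    data.frame(series = nm, time = ms[[nm]]$time, value = ms[[nm]]$value)))
  units <- attr(ms[[1]], "units")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = units, title = title, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.metric_series <- function(object, ...) {
  plot_metric_series(object, title = attr(object, "name"))
}

#' Plot a demon sprint ledger
#'
#' Collective-variable trace over sprints, accepted sprints highlighted.
#'
#' @param stats a `demon_stats` object.
#' @return a ggplot object.
#' @export
plot_demon_stats <- function(stats) {
  df <- as.data.frame(stats$sprints)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sprint, y = .data$cv_after,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_step(data = df[df$accepted, ],
                       ggplot2::aes(x = .data$sprint, y = .data$cv_after),
                       colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = "sprint", y = "CV: RMSD to guidepost (A)",
                  colour = "accepted") +
    ggplot2::theme_minimal()
}

# variant comparison panels written by cmd_analyze
.plot_panels <- function(variant_series, outdir) {
  if (!length(variant_series)) return(invisible(NULL))
  panels <- list(cleft = "cleft CoM1-CoM2 distance",
                 pocket_sasa = "Ser65 pocket SASA",
                 pocket_waters = "pocket water count",
                 rep_ring1 = "Tyr391-Cys238 distance")
  for (nm in names(panels)) {
    series <- lapply(variant_series, `[[`, nm)
    series <- series[!vapply(series, is.null, TRUE)]
    if (!length(series)) next
    gg <- plot_metric_series(series, title = panels[[nm]])
    ggplot2::ggsave(file.path(outdir, sprintf("panel_%s.pdf", nm)), gg,
                    width = 6, height = 4)
  }
  invisible(NULL)
}

#' @importFrom rlang .data
NULL
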