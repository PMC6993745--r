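## Specification-curve dashboard and participants-per-spec plots.
##
## Figures are data-faithful rather than pixel-faithful: a ranked coefficient
## panel (teal = significant, pink = not) above a decision-indicator
## dashboard whose tick marks identify, for every specification, exactly one
## option per analytical decision. Both panels share the x ordering.

decision_rows <- function(results) {
  opts <- list(sleep_measure = sleep_measures,
               tech_measure = tech_measures,
               control_set = control_sets)
  rows <- list()
  pos <- 0
  for (dec in names(opts)) {
    for (o in opts[[dec]]) {
      pos <- pos + 1
      hit <- results[[dec]] == o
      if (any(hit))
        rows[[length(rows) + 1]] <- data.frame(
          rank = results$rank[hit], day_type = results$day_type[hit],
          decision = dec, option = o, y = pos, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  labs <- unique(out[, c("option", "y")])
  attr(out, "breaks") <- labs$y
  attr(out, "labels") <- labs$option
  out
}

#' Plot the specification curve dashboard
#'
#' @param curve An `sca_curve` (optionally with bootstrap CIs attached via
#'   [add_bootstrap()]).
#' @param colors Length-2 named vector of colors for significant /
#'   non-significant specifications.
#' @return Object of class `sca_curve_plot`, a list of two ggplot objects
#'   (`curve`, `dashboard`); its `print` method draws them stacked.
#' @export
plot_curve <- function(curve,
                       colors = c(significant = "#17a2a2",
                                  nonsignificant = "#ef7fbf")) {
  res <- curve$results
  if (is.null(res) || nrow(res) == 0) validation_error("curve is empty")
  res$sig <- ifelse(is.na(res$significant), "nonsignificant",
                    ifelse(res$significant, "significant", "nonsignificant"))
  # rank within day type so the two facets are independently ordered curves
  res <- do.call(rbind, lapply(split(res, res$day_type), function(d) {
    d$rank <- rank(d$beta, ties.method = "first", na.last = "keep")
    d
  }))
  p_top <- ggplot2::ggplot(res[res$status == "ok", ],
                           ggplot2::aes(x = .data$rank, y = .data$beta,
                                        color = .data$sig))
  if (!is.null(res$ci_lower))
    p_top <- p_top +
      ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_lower,
                                           ymax = .data$ci_upper),
                              alpha = 0.35, linewidth = 0.3)
  p_top <- p_top +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = unname(colors),
                                breaks = NULL,
                                limits = c("significant", "nonsignificant")) +
    ggplot2::facet_wrap(~day_type, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "standardized beta") +
    ggplot2::theme_minimal(base_size = 9)

  dash <- decision_rows(res[res$status == "ok", ])
  p_bottom <- ggplot2::ggplot(dash,
                              ggplot2::aes(x = .data$rank, y = .data$y)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_reverse(breaks = attr(dash, "breaks"),
                             labels = attr(dash, "labels")) +
    ggplot2::facet_wrap(~day_type, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "specification (ranked by beta)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)

  structure(list(curve = p_top, dashboard = p_bottom),
            class = "sca_curve_plot")
}

#' @export
print.sca_curve_plot <- function(x, ...) {
  grid::grid.newpage()
  top_vp <- grid::viewport(y = 0.7, height = 0.6)
  bot_vp <- grid::viewport(y = 0.2, height = 0.4)
  print(x$curve, vp = top_vp)
  print(x$dashboard, vp = bot_vp)
  invisible(x)
}

#' Plot the analysed sample size per specification
#'
#' Per-specification n in the same ranked x ordering as the curve, faceted by
#' day type.
#'
#' @inheritParams plot_curve
#' @return A ggplot object.
#' @export
plot_n_per_spec <- function(curve) {
  res <- curve$results
  if (is.null(res) || nrow(res) == 0) validation_error("curve is empty")
  res <- res[res$status == "ok", ]
  res <- do.call(rbind, lapply(split(res, res$day_type), function(d) {
    d$rank <- rank(d$beta, ties.method = "first", na.last = "keep")
    d
  }))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$rank, y = .data$n)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~day_type, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "specification (ranked by beta)",
                  y = "participants analysed") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Save a figure in raster and vector formats
#'
#' @param p A ggplot or `sca_curve_plot`.
#' @param path_stem File path without extension; writes `.png` and `.pdf`.
#' @param width,height Size in inches.
#' @return Invisibly, the written file paths.
#' @export
save_figure <- function(p, path_stem, width = 8, height = 6) {
  paths <- character(0)
  for (ext in c("pdf", "png")) {
    path <- paste0(path_stem, ".", ext)
    ok <- tryCatch({
      if (ext == "pdf") grDevices::pdf(path, width = width, height = height)
      else grDevices::png(path, width = width * 100, height = height * 100,
                          res = 100)
      print(p)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warning(sprintf("could not write %s: %s", path, conditionMessage(e)))
      FALSE
    })
    if (ok) paths <- c(paths, path)
  }
  invisible(paths)
}
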