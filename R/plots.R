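# ggplot2 display methods for the result types.

#' Plot per-cell GFP values against the AC-like threshold
#'
#' Jittered per-cell GFP values by condition and role, with the control-AC
#' mean and the AC-like threshold (one SD below it) drawn as horizontal
#' lines — the standard display for threshold-classified fluorescence.
#'
#' @param cells Measurement tibble with `condition` (or `clone_id`), `role`
#'   and `gfp_value` columns (e.g. after [name_cells()]).
#' @param model An `ac_threshold` from [fit_ac_threshold()].
#' @param role Role(s) to display.
#' @return A ggplot object.
#' @export
plot_ac_like <- function(cells, model, role = "alpha2") {
  stopifnot(inherits(model, "ac_threshold"))
  if (!"condition" %in% names(cells) && "clone_id" %in% names(cells)) {
    cells$condition <- cells$clone_id
  }
  df <- cells[cells$role %in% role & !cells$excluded, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$gfp_value)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = model$threshold, ymax = Inf,
                      fill = "pink", alpha = 0.3) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = model$mu_ac, colour = "red") +
    ggplot2::geom_hline(yintercept = model$threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "GFP integrated intensity (AU)",
                  title = "AC-like threshold classification",
                  subtitle = "solid: control-AC mean; dashed: mean - 1 SD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn plot_ac_like `autoplot` method for `ac_threshold`; requires
#'   the measurement tibble via `cells`.
#' @param object An `ac_threshold`.
#' @param ... Passed to `plot_ac_like()`.
#' @method autoplot ac_threshold
#' @export
autoplot.ac_threshold <- function(object, cells, ...) {
  plot_ac_like(cells, object, ...)
}

#' Plot a screen report
#'
#' Mean GFP-positive cells per animal for every clone, colored by hit
#' status, with the strict-criterion line at 2 — the per-round screen
#' summary display.
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_report
#' @export
autoplot.screen_report <- function(object, ...) {
  df <- object$clones
  df$status <- dplyr::case_when(
    df$type == "negative_control" ~ "negative control",
    df$type == "positive_control" ~ "positive control",
    df$hit ~ "hit",
    TRUE ~ "no hit"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clone_id, y = .data$mean_count,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "negative control" = "magenta", "positive control" = "grey40",
      "hit" = "darkgreen", "no hit" = "black"
    )) +
    ggplot2::labs(x = NULL, y = "mean GFP-positive cells per animal",
                  colour = NULL,
                  title = "RNAi screen: per-clone penetrance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
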