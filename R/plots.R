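#' Plot an invasion trajectory
#'
#' Draws the four cytotype frequencies against time in generations, with the
#' pre-invasion symbiont equilibrium as a dashed reference line. The figure
#' is a convenience view of the tidy table; the CSV written by
#' [write_trajectory_csv()] is the tested artifact.
#'
#' @param object A `cyto_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("generation", "p", "q", "r", "s")],
    cols = c("p", "q", "r", "s"),
    names_to = "cytotype", values_to = "frequency")
  labels <- c(p = "resident mito + symbiont", q = "resident mito, uninfected",
              r = "novel mito + symbiont", s = "novel mito, uninfected")
  ggplot(long, aes(x = .data$generation, y = .data$frequency,
                   colour = .data$cytotype)) +
    geom_hline(yintercept = attr(object, "baseline"), linetype = "dashed",
               colour = "grey40") +
    geom_line(linewidth = 0.8) +
    scale_colour_hue(labels = labels) +
    labs(x = "generation", y = "cytotype frequency", colour = NULL) +
    theme_minimal()
}

#' Plot a parameter-sweep phase diagram
#'
#' Heatmap of the equilibrium novel-mitotype frequency `N* = r* + s*` over
#' the swept parameter plane, with cells where the symbiont cannot persist
#' left blank.
#'
#' @param object A `cyto_sweep`.
#' @param fill Column to map to fill: `"mutant_freq"` (default), `"p_star"`
#'   or `"symbiont_freq"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_sweep <- function(object, fill = "mutant_freq", ...) {
  axes <- attr(object, "axes")
  ggplot(as_tibble(object),
         aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
             fill = .data[[fill]])) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    labs(x = axes[1], y = axes[2], fill = fill) +
    theme_minimal()
}

#' @rdname autoplot.cyto_trajectory
#' @param x A `cyto_trajectory`.
#' @export
plot_trajectory <- function(x, ...) autoplot(x, ...)

#' @rdname autoplot.cyto_sweep
#' @param x A `cyto_sweep`.
#' @export
plot_sweep <- function(x, fill = "mutant_freq", ...) autoplot(x, fill = fill, ...)
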