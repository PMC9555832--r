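# ggplot2 views of states and trajectories.

#' Plot a population grid
#'
#' Tile map of the lattice: occupied cells filled by allele color (initial
#' alleles basic, mutants neon), empty cells white, barriers black.  Row 0
#' is drawn at the top, matching the text-mask orientation.
#'
#' @param object A `population_state`.
#' @param palette Palette from [genie_palette()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_state <- function(object, palette = genie_palette(), ...) {
  df <- as_tibble(object)
  cols <- assign_colors(object, palette)
  df <- left_join(df, cols, by = c("allele" = "allele_id"))
  df$fill <- ifelse(df$state == "barrier", "black",
                    ifelse(df$state == "empty", "white", df$color))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$fill)) +
    ggplot2::geom_tile(color = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("generation %d: %d individuals, %d allele(s)",
                      object$generation, population_size(object),
                      n_alleles(object))
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}

#' @export
plot.population_state <- function(x, ...) print(autoplot(x, ...))

#' Plot an allele trajectory
#'
#' `type = "count"`: distinct-allele count over generations, one line per
#' component (component 0 is the pooled view).  `type = "frequency"`:
#' per-allele frequency lines, faceted by component.
#'
#' @param object An allele-trajectory tibble.
#' @param type `"count"` or `"frequency"`.
#' @param component Optional component id(s) to keep.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allele_trajectory <- function(object, type = c("count", "frequency"),
                                       component = NULL, ...) {
  type <- match.arg(type)
  df <- as_tibble(object)
  if (!is.null(component)) df <- filter(df, .data$component_id %in% component)
  if ("phase" %in% names(df)) {
    df$series <- paste(df$phase, df$component_id, sep = " / comp ")
  } else {
    df$series <- paste("comp", df$component_id)
  }
  if (type == "count") {
    counts <- df |>
      group_by(.data$series, .data$generation) |>
      summarise(n_alleles = dplyr::n_distinct(.data$allele_id), .groups = "drop")
    ggplot2::ggplot(counts, ggplot2::aes(.data$generation, .data$n_alleles,
                                         color = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "generation", y = "distinct alleles", color = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$frequency,
                                     group = .data$allele_id,
                                     color = factor(.data$allele_id))) +
      ggplot2::geom_line(show.legend = FALSE) +
      ggplot2::facet_wrap(~series) +
      ggplot2::labs(x = "generation", y = "allele frequency") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.fixation_run <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("this fixation_run was produced with record = FALSE; no trajectory to plot")
  }
  autoplot(object$trajectory, ...)
}

#' @export
autoplot.scenario_result <- function(object, ...) {
  autoplot(object$trajectory, ...)
}
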