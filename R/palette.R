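# Display palette: 18 basic colors for initial alleles, 6 neon colors for
# mutant alleles, cycling with reuse when alleles outnumber the palette.

#' The default allele palette
#'
#' 18 basic colors for alleles present since initialization and 6 neon
#' colors for alleles created later by mutation (spontaneous or forced), so
#' new variants stand out on the grid at a glance.  When a class holds more
#' alleles than its palette, colors cycle.
#'
#' @return A list with character vectors `basic` (length 18) and `neon`
#'   (length 6).
#' @export
genie_palette <- function() {
  list(
    basic = c(
      "#E6194B", "#3CB44B", "#4363D8", "#F58231", "#911EB4", "#46F0F0",
      "#F032E6", "#BCF60C", "#FABEBE", "#008080", "#E6BEFF", "#9A6324",
      "#FFFAC8", "#800000", "#AAFFC3", "#808000", "#FFD8B1", "#000075"
    ),
    neon = c(
      "#39FF14", "#FF073A", "#00FFFF", "#FF00FF", "#FFFF00", "#FF6EC7"
    )
  )
}

#' Assign display colors to alleles
#'
#' Alleles are split into *initial* (id below the state's
#' `init_allele_cutoff`, i.e. created by the urn) and *mutant* (created by
#' step mutation or [force_mutation()]).  Initial alleles receive the basic
#' colors in first-seen order, cycling modulo 18; mutant alleles receive
#' the neon colors, cycling modulo 6.
#'
#' @param x A `population_state`, or an allele-trajectory tibble (then
#'   `init_cutoff` must be given; first-seen order is by first generation of
#'   appearance, ties by allele id).
#' @param palette A palette list as from [genie_palette()].
#' @param init_cutoff Allele ids below this are "initial".  Taken from the
#'   state when `x` is a `population_state`.
#' @return A tibble `allele_id`, `origin` (`"initial"`/`"mutant"`), `color`.
#' @export
assign_colors <- function(x, palette = genie_palette(), init_cutoff = NULL) {
  stopifnot(length(palette$basic) == 18, length(palette$neon) == 6)
  if (inherits(x, "population_state")) {
    ids <- sort(unique(x$allele[x$cell_state == CELL_OCCUPIED]))
    init_cutoff <- x$init_allele_cutoff
  } else if (is.data.frame(x)) {
    if (is.null(init_cutoff)) {
      abort("`init_cutoff` is required when `x` is a trajectory")
    }
    first_seen <- x |>
      group_by(.data$allele_id) |>
      summarise(first = min(.data$generation), .groups = "drop") |>
      arrange(.data$first, .data$allele_id)
    ids <- first_seen$allele_id
  } else {
    abort("`x` must be a population_state or a trajectory tibble")
  }
  origin <- ifelse(ids < init_cutoff, "initial", "mutant")
  color <- character(length(ids))
  for (cls in c("initial", "mutant")) {
    pal <- if (cls == "initial") palette$basic else palette$neon
    k <- which(origin == cls)
    if (length(k) > 0) color[k] <- pal[(seq_along(k) - 1L) %% length(pal) + 1L]
  }
  tibble(allele_id = ids, origin = origin, color = color)
}
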