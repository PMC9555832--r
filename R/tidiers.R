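# broom-style tidiers for fitted/derived result objects.

#' Tidy a fixation run
#'
#' One row per connected component with its size, occupancy, fixation
#' status, fixed allele and first-fixation generation.
#'
#' @param x A `fixation_run` from [run_until_fixation()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fixation_run <- function(x, ...) as_tibble(x$report)

#' @rdname tidy.fixation_run
#' @return `glance()` returns a one-row tibble: number of components,
#'   global fixation flag, generations to (global) fixation, final distinct
#'   allele count, total steps, no-op events, and whether the generation cap
#'   was hit.
#' @export
glance.fixation_run <- function(x, ...) {
  tibble(
    n_components = nrow(x$report),
    global_fixed = x$global_fixed,
    generations_to_fixation = x$generations_to_fixation,
    n_alleles = n_alleles(x$state),
    steps = x$state$step_count,
    noop_events = x$state$noop_count,
    cap_hit = x$cap_hit
  )
}

#' Tidy a scenario result
#'
#' For the fixation-driven experiments (1-3) this is the per-phase,
#' per-component fixation table; for experiment 4 (no fixation) it is the
#' per-phase final distinct-allele count.
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scenario_result <- function(x, ...) {
  if (!is.null(x$fixation)) return(as_tibble(x$fixation))
  x$trajectory |>
    group_by(.data$phase) |>
    filter(.data$generation == max(.data$generation)) |>
    summarise(n_alleles = dplyr::n_distinct(.data$allele_id), .groups = "drop")
}

#' @rdname tidy.scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble(
    scenario = x$scenario,
    seed = x$seed,
    n_events = nrow(x$events),
    n_phases = dplyr::n_distinct(x$trajectory$phase),
    end_generation = max(x$trajectory$generation),
    cap_hit = x$cap_hit
  )
}
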