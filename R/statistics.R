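# Trajectory recording, allele-frequency spectra, fixation detection
# (global and per connected component), and replicate fixation-time studies.

#' Component labelling of a live state
#'
#' Convenience wrapper: [connected_components()] of the grid under the
#' state's current barrier set.
#'
#' @param state A `population_state`.
#' @return A tibble `component_id`, `row`, `col` covering every non-barrier
#'   cell.
#' @export
state_components <- function(state) {
  stopifnot(inherits(state, "population_state"))
  connected_components(state$grid, mask_of(state))
}

check_components_current <- function(state, components) {
  idx <- sort(cell_index0(state$grid, as_cell_matrix(components)))
  if (!identical(idx, sort(open_index0(state)))) {
    abort(paste0(
      "component labeling is stale: its cells do not match the state's ",
      "current non-barrier cells (recompute with state_components())"
    ))
  }
  invisible(components)
}

#' Allele spectrum per connected component
#'
#' Exact allele counts and within-component frequencies over the occupied
#' cells.  With `pooled = TRUE` an additional set of rows with
#' `component_id = 0` aggregates all components — the global view.
#'
#' @param state A `population_state`.
#' @param components Optional labelling from [state_components()]; it must
#'   match the state's current barriers or a consistency error is raised.
#' @param pooled Add the pooled (`component_id = 0`) rows?  Defaults to
#'   `TRUE` when there is more than one component.
#' @return A tibble `component_id`, `allele_id`, `count`, `frequency`,
#'   sorted by component then allele id.  Within each component the counts
#'   sum to its occupied cells and the frequencies to 1.
#' @export
allele_spectrum <- function(state, components = NULL, pooled = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (is.null(components)) {
    components <- state_components(state)
  } else {
    check_components_current(state, components)
  }
  occ <- state$cell_state == CELL_OCCUPIED
  idx <- which(occ) - 1L
  cells <- tibble(
    row = idx %/% state$grid$cols, col = idx %% state$grid$cols,
    allele_id = state$allele[occ]
  )
  cells <- inner_join(cells, components, by = c("row", "col"))
  per_comp <- cells |>
    count(.data$component_id, .data$allele_id, name = "count") |>
    group_by(.data$component_id) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup()
  if (is.null(pooled)) pooled <- max(components$component_id, 0L) > 1L
  if (pooled) {
    glob <- cells |>
      count(.data$allele_id, name = "count") |>
      mutate(component_id = 0L, frequency = .data$count / sum(.data$count))
    per_comp <- bind_rows(glob, per_comp)
  }
  arrange(per_comp, .data$component_id, .data$allele_id) |>
    select("component_id", "allele_id", "count", "frequency")
}

#' Number of distinct alleles among occupied cells
#' @param state A `population_state`.
#' @return Integer count.
#' @export
n_alleles <- function(state) {
  dplyr::n_distinct(state$allele[state$cell_state == CELL_OCCUPIED])
}

#' Is a component (or the whole population) fixed?
#'
#' A component is fixed when all of its occupied cells carry one and the
#' same allele.  Empty cells are ignored (they carry nothing); a component
#' with no occupied cell has undefined fixation and raises an error.
#'
#' @param state A `population_state`.
#' @param component A component id from the labelling, or `NULL` to test
#'   all occupied cells pooled together (global fixation in the monomorphic
#'   sense).
#' @param components Optional labelling from [state_components()].
#' @return `TRUE` or `FALSE`.
#' @export
is_fixed <- function(state, component = NULL, components = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (is.null(component)) {
    al <- state$allele[state$cell_state == CELL_OCCUPIED]
  } else {
    if (is.null(components)) components <- state_components(state)
    cc <- components[components$component_id == component, ]
    if (nrow(cc) == 0) abort(sprintf("no component with id %s", component))
    idx <- cell_index0(state$grid, as_cell_matrix(cc))
    keep <- state$cell_state[idx + 1L] == CELL_OCCUPIED
    al <- state$allele[idx + 1L][keep]
  }
  if (length(al) == 0) {
    abort("component has no occupied cells: fixation is undefined")
  }
  all(al == al[1])
}

#' Per-component fixation report
#'
#' @param state A `population_state`.
#' @param components Optional labelling from [state_components()].
#' @param fixed_generations Optional named/ordered integer vector of
#'   first-fixation generations per component (as produced by the fixation
#'   loops); `NA` where unknown.
#' @return A tibble with one row per component: `component_id`, `n_cells`,
#'   `n_occupied`, `fixed`, `fixed_allele_id`, and (when supplied)
#'   `generations_to_fixation`.  The attribute `global_fixed` is `TRUE` iff
#'   every component with occupied cells is fixed.
#' @export
fixation_report <- function(state, components = NULL, fixed_generations = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (is.null(components)) components <- state_components(state)
  ids <- sort(unique(components$component_id))
  rows <- lapply(ids, function(k) {
    cc <- components[components$component_id == k, ]
    idx <- cell_index0(state$grid, as_cell_matrix(cc))
    al <- state$allele[idx + 1L][state$cell_state[idx + 1L] == CELL_OCCUPIED]
    fixed <- length(al) > 0 && all(al == al[1])
    tibble(
      component_id = k, n_cells = nrow(cc), n_occupied = length(al),
      fixed = fixed,
      fixed_allele_id = if (fixed) al[1] else NA_integer_
    )
  })
  out <- bind_rows(rows)
  if (!is.null(fixed_generations)) {
    out$generations_to_fixation <- as.integer(fixed_generations)[seq_along(ids)]
  }
  attr(out, "global_fixed") <- all(out$fixed[out$n_occupied > 0]) &&
    any(out$n_occupied > 0)
  out
}

# One generation's trajectory rows.
spectrum_snapshot <- function(state, components) {
  sp <- allele_spectrum(state, components)
  sp$generation <- state$generation
  select(sp, "generation", "component_id", "allele_id", "count", "frequency")
}

as_allele_trajectory <- function(x) {
  class(x) <- c("allele_trajectory", class(x))
  x
}

# Core fixation loop operating on an existing state.  Both paths use the
# same C++ kernel in the same order, so a given seed yields identical
# results with or without recording (tested).
finish_fixation_run <- function(state, mu, record = TRUE,
                                max_generations = state$config$max_generations,
                                phase = NULL) {
  comps <- state_components(state)
  ids <- sort(unique(comps$component_id))
  K <- length(ids)
  start_gen <- state$generation
  if (record) {
    comp_idx <- lapply(ids, function(k) {
      cell_index0(state$grid, as_cell_matrix(comps[comps$component_id == k, ])) + 1L
    })
    fixed_gen <- rep(NA_integer_, K)
    traj <- list()
    repeat {
      g <- state$generation
      traj[[length(traj) + 1L]] <- spectrum_snapshot(state, comps)
      for (k in seq_len(K)) {
        if (is.na(fixed_gen[k])) {
          al <- state$allele[comp_idx[[k]]]
          al <- al[state$cell_state[comp_idx[[k]]] == CELL_OCCUPIED]
          if (length(al) > 0 && all(al == al[1])) fixed_gen[k] <- g
        }
      }
      if (all(!is.na(fixed_gen))) { cap_hit <- FALSE; break }
      if (g - start_gen >= max_generations) { cap_hit <- TRUE; break }
      state <- run_generation(state, mu)
    }
    trajectory <- as_allele_trajectory(bind_rows(traj))
    if (!is.null(phase)) {
      trajectory <- mutate(trajectory, phase = phase, .before = 1)
    }
  } else {
    comp_vec <- rep(0L, n_cells(state$grid))
    midx <- cell_index0(state$grid, as_cell_matrix(comps)) + 1L
    comp_vec[midx] <- comps$component_id
    res <- cpp_run_until_fixed(
      state$cell_state, state$allele, state$grid$rows, state$grid$cols,
      open_index0(state), comp_vec, state$config$steps_per_generation,
      max_generations, mu, state$next_allele_id, state$noop_count, start_gen
    )
    state$cell_state <- res$cell_state
    state$allele <- res$allele
    state$next_allele_id <- res$next_allele_id
    state$noop_count <- res$noop_count
    state$step_count <- state$step_count +
      as.numeric(res$generations_run) * state$config$steps_per_generation
    state$generation <- state$generation + res$generations_run
    fixed_gen <- res$fixed_generation
    cap_hit <- res$cap_hit
    trajectory <- NULL
  }
  report <- fixation_report(state, state_components(state), fixed_gen)
  structure(
    list(
      report = report, trajectory = trajectory, state = state,
      global_fixed = isTRUE(attr(report, "global_fixed")),
      generations_to_fixation = if (all(!is.na(fixed_gen))) max(fixed_gen) else NA_integer_,
      cap_hit = cap_hit, mu = mu
    ),
    class = "fixation_run"
  )
}

#' Run a population until every component is fixed
#'
#' Initializes a population and iterates generations until each connected
#' component is monomorphic (or `max_generations` is reached, which sets
#' `cap_hit` rather than erroring).  Fixation is evaluated on generation
#' snapshots, so a fixation that happens mid-generation is reported at the
#' next snapshot.  With `mu > 0` permanent fixation is not guaranteed; the
#' loop then stops at the first monomorphic snapshot, which is an
#' approximation because new mutants can arise immediately afterwards.
#'
#' @param config A [sim_config()].
#' @param mask Optional [barrier_mask()] applied before initialization.
#' @param mu Running mutation probability (default: the config's `run_mu`;
#'   `mu = 0` is the recommended pure-drift setting).
#' @param record Record the per-generation allele trajectory?  Turning it
#'   off uses a batched path that is much faster for replicate studies.
#' @param init `"hoppe"` (urn initialization, the default) or
#'   `"distinct"` (each cell its own allele).
#' @param alleles Optional explicit allele vector (overrides `init`).
#' @return A `fixation_run` object: a list with `report` (per-component
#'   tibble including `generations_to_fixation`), `trajectory` (or `NULL`),
#'   `state`, `global_fixed`, `generations_to_fixation` (generation at which
#'   the last component fixed), and `cap_hit`.
#' @examples
#' fr <- run_until_fixation(sim_config(rows = 8, cols = 8, seed = 1), mu = 0)
#' tidy(fr)
#' @export
run_until_fixation <- function(config, mask = NULL, mu = NULL, record = TRUE,
                               init = "hoppe", alleles = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mu <- check_mu(if (is.null(mu)) config$run_mu else mu)
  state <- init_population(config, mask, init, alleles)
  finish_fixation_run(state, mu, record, config$max_generations)
}

#' @export
print.fixation_run <- function(x, ...) {
  cat(sprintf(
    "<fixation_run> %d component(s) | global_fixed: %s | generations to fixation: %s%s\n",
    nrow(x$report), x$global_fixed,
    ifelse(is.na(x$generations_to_fixation), "NA", x$generations_to_fixation),
    if (x$cap_hit) " | generation cap hit" else ""
  ))
  invisible(x)
}

#' Replicate fixation-time study
#'
#' Runs `n_reps` independent seeded simulations (replicate r uses seed
#' `base_seed + r - 1`) and returns one row per replicate with the global
#' fixation generation — the first generation snapshot at which every
#' tracked component is monomorphic — and, when a single component is
#' tracked, the identity of the allele that fixed in it.
#'
#' @inheritParams run_until_fixation
#' @param n_reps Number of replicates.
#' @param base_seed Seed of the first replicate.
#' @param component Optional single component id to track instead of all
#'   components (the rest of the grid still evolves; only the stop rule and
#'   the reported generation change).
#' @param barriers_after_init Optional cells turned into barriers *after*
#'   initialization, mirroring an interactive session in which the full
#'   grid is urn-initialized and barriers are then drawn (population drops
#'   by one per previously occupied cell).  A `mask`, in contrast, excludes
#'   cells before initialization.
#' @return A tibble `replicate`, `seed`, `generations_to_fixation`,
#'   `fixed_allele_id`, `cap_hit`.
#' @export
replicate_fixation_times <- function(config, mask = NULL, mu = 0, n_reps,
                                     base_seed, init = "hoppe",
                                     alleles = NULL, component = NULL,
                                     barriers_after_init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mu <- check_mu(mu)
  n_reps <- check_count(n_reps, "n_reps")
  # Geometry (barriers, hence components) is identical across replicates, so
  # the labelling is computed once from a throwaway state.
  cfg0 <- config
  cfg0$seed <- NULL
  proto <- init_population(cfg0, mask, init = "distinct",
                           alleles = NULL)
  if (!is.null(barriers_after_init)) proto <- add_barrier(proto, barriers_after_init)
  comps <- state_components(proto)
  comp_vec <- rep(0L, n_cells(proto$grid))
  if (is.null(component)) {
    comp_vec[cell_index0(proto$grid, as_cell_matrix(comps)) + 1L] <-
      comps$component_id
    first_cell <- NA_integer_
    single <- max(comps$component_id) == 1L
    if (single) first_cell <- cell_index0(proto$grid, as_cell_matrix(comps))[1] + 1L
  } else {
    cc <- comps[comps$component_id == component, ]
    if (nrow(cc) == 0) abort(sprintf("no component with id %s", component))
    comp_vec[cell_index0(proto$grid, as_cell_matrix(cc)) + 1L] <- 1L
    first_cell <- cell_index0(proto$grid, as_cell_matrix(cc))[1] + 1L
    single <- TRUE
  }
  open0 <- open_index0(proto)

  seeds <- as.integer(base_seed + seq_len(n_reps) - 1L)
  gen <- integer(n_reps)
  fixed_allele <- integer(n_reps)
  cap <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[r]
    state <- init_population(cfg, mask, init, alleles)
    if (!is.null(barriers_after_init)) {
      state <- add_barrier(state, barriers_after_init)
    }
    res <- cpp_run_until_fixed(
      state$cell_state, state$allele, state$grid$rows, state$grid$cols,
      open0, comp_vec, cfg$steps_per_generation, cfg$max_generations, mu,
      state$next_allele_id, state$noop_count, state$generation
    )
    fg <- res$fixed_generation
    gen[r] <- if (anyNA(fg)) NA_integer_ else max(fg)
    cap[r] <- res$cap_hit
    fixed_allele[r] <- if (single && !is.na(fg[1])) res$allele[first_cell] else NA_integer_
  }
  tibble(
    replicate = seq_len(n_reps), seed = seeds,
    generations_to_fixation = gen, fixed_allele_id = fixed_allele,
    cap_hit = cap
  )
}
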