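# The stochastic engine: simulation configs, Hoppe's-urn / deterministic
# initialization, the death-birth step kernel (C++ backed), generation
# batching, forced mutation, and live barrier edits.

CELL_EMPTY <- 0L
CELL_OCCUPIED <- 1L
CELL_BARRIER <- 2L

cell_state_labels <- c("empty", "occupied", "barrier")

#' Simulation configuration
#'
#' Bundles every run parameter.  Defaults reproduce the standard model: a
#' 32 x 32 grid (1024 individuals), initialization mutation rate
#' `init_mu = 0.001` (so the urn's dispersion is theta = 2 N mu = 2.048),
#' running mutation rate 0, and generations of 2000 death/birth steps.
#'
#' @param rows,cols Grid dimensions.
#' @param init_mu Per-birth mutation probability used only to set the
#'   Hoppe-urn dispersion theta = 2 N `init_mu` at initialization.
#' @param run_mu Per-birth mutation probability during the run (default 0:
#'   pure drift).
#' @param steps_per_generation Death/birth events per generation snapshot.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param max_generations Cap on generations for fixation loops; hitting it
#'   is reported (`cap_hit`), never an error.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(seed = 1)
#' @export
sim_config <- function(rows = 32L, cols = 32L, init_mu = 0.001, run_mu = 0,
                       steps_per_generation = 2000L, seed = NULL,
                       max_generations = 100000L) {
  cfg <- list(
    grid = grid_spec(rows, cols),
    init_mu = init_mu, run_mu = run_mu,
    steps_per_generation = steps_per_generation,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    max_generations = max_generations
  )
  problems <- validate_config(cfg)
  if (nrow(problems) > 0) {
    abort(paste0(
      "invalid simulation config:\n",
      paste0("  - ", problems$field, ": ", problems$problem, collapse = "\n")
    ))
  }
  cfg$steps_per_generation <- as.integer(steps_per_generation)
  cfg$max_generations <- as.integer(max_generations)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d x %d grid | init_mu %g | run_mu %g | %d steps/generation | seed %s | cap %d generations\n",
    x$grid$rows, x$grid$cols, x$init_mu, x$run_mu, x$steps_per_generation,
    if (is.null(x$seed)) "none" else x$seed, x$max_generations
  ))
  invisible(x)
}

check_mu <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0 || mu > 1) {
    abort("mutation probability `mu` must be a single value in [0, 1]")
  }
  as.numeric(mu)
}

new_population_state <- function(grid, cell_state, allele, next_allele_id,
                                 init_allele_cutoff, config,
                                 init_params = NULL) {
  structure(
    list(
      grid = grid,
      cell_state = as.integer(cell_state),
      allele = as.integer(allele),
      next_allele_id = as.integer(next_allele_id),
      init_allele_cutoff = as.integer(init_allele_cutoff),
      generation = 0L,
      step_count = 0,
      noop_count = 0,
      config = config,
      init_params = init_params
    ),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "<population_state> %d x %d | %d occupied, %d empty, %d barrier | %d distinct allele(s) | generation %d (%.0f steps)\n",
    x$grid$rows, x$grid$cols,
    sum(x$cell_state == CELL_OCCUPIED), sum(x$cell_state == CELL_EMPTY),
    sum(x$cell_state == CELL_BARRIER),
    dplyr::n_distinct(x$allele[x$cell_state == CELL_OCCUPIED]),
    x$generation, x$step_count
  ))
  invisible(x)
}

#' View a population state as a tibble
#'
#' One row per cell with 0-based coordinates, the cell state
#' (`"occupied"`, `"empty"`, `"barrier"`) and the allele id (`NA` for
#' non-occupied cells).
#'
#' @param x A `population_state`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `state`, `allele`.
#' @export
as_tibble.population_state <- function(x, ...) {
  idx <- seq_len(n_cells(x$grid)) - 1L
  tibble(
    row = idx %/% x$grid$cols,
    col = idx %% x$grid$cols,
    state = cell_state_labels[x$cell_state + 1L],
    allele = x$allele
  )
}

open_index0 <- function(state) which(state$cell_state != CELL_BARRIER) - 1L

#' Number of occupied cells
#' @param state A `population_state`.
#' @return Integer count of occupied cells.
#' @export
population_size <- function(state) sum(state$cell_state == CELL_OCCUPIED)

#' Rebuild the barrier mask implied by a state
#' @param state A `population_state`.
#' @return A [barrier_mask()] marking the state's barrier cells.
#' @export
mask_of <- function(state) {
  idx <- which(state$cell_state == CELL_BARRIER) - 1L
  barrier_mask(state$grid, as.data.frame(index0_cells(state$grid, idx)))
}

#' Draw an allele configuration from Hoppe's urn
#'
#' Sequential construction of an infinite-alleles sample: individual 1
#' always carries allele 1; individual i+1 carries a brand-new allele with
#' probability theta / (theta + i) and otherwise copies a uniformly chosen
#' earlier individual.  The resulting partition of `n` individuals into
#' allele classes follows the Ewens sampling formula with parameter
#' `theta`, so the expected number of distinct alleles is
#' sum_{i=0}^{n-1} theta / (theta + i).
#'
#' @param n Number of individuals.
#' @param theta Non-negative dispersion parameter (theta = 2 N mu).
#' @return A list with `alleles` (integer vector of length `n`, ids
#'   starting at 1 in order of first appearance) and `n_alleles`.
#' @export
hoppe_urn_draw <- function(n, theta) {
  n <- check_count(n, "n")
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta < 0) {
    abort("`theta` must be a single non-negative number")
  }
  alleles <- integer(n)
  next_id <- 1L
  for (i in seq_len(n)) {
    if (i == 1L) {
      # First draw is always novel; no random number is consumed.
      alleles[i] <- next_id
      next_id <- next_id + 1L
    } else if (runif(1) < theta / (theta + i - 1)) {
      alleles[i] <- next_id
      next_id <- next_id + 1L
    } else {
      alleles[i] <- alleles[sample.int(i - 1L, 1L)]
    }
  }
  list(alleles = alleles, n_alleles = next_id - 1L)
}

init_state_common <- function(config, mask, alleles, n_alleles, init_params) {
  grid <- config$grid
  barrier <- if (is.null(mask)) integer(0) else {
    stopifnot(identical(mask$grid, grid))
    mask_index0(mask)
  }
  open0 <- setdiff(seq_len(n_cells(grid)) - 1L, barrier)
  cs <- rep(CELL_OCCUPIED, n_cells(grid))
  cs[barrier + 1L] <- CELL_BARRIER
  al <- rep(NA_integer_, n_cells(grid))
  al[open0 + 1L] <- alleles
  new_population_state(grid, cs, al, n_alleles + 1L, n_alleles + 1L, config,
                       init_params)
}

#' Initialize a population from Hoppe's urn
#'
#' Creates one individual per non-barrier cell.  The urn dispersion is
#' theta = 2 N `init_mu`, where N counts the non-barrier cells, and urn
#' outputs are placed on the open cells in row-major order.  If the config
#' carries a seed, `set.seed()` is called first, so the whole subsequent run
#' is reproducible from the config alone.
#'
#' @param config A [sim_config()].
#' @param mask Optional [barrier_mask()] of cells excluded from the
#'   population (they stay `BARRIER`).
#' @return A `population_state` at generation 0.
#' @examples
#' st <- hoppe_urn_init(sim_config(seed = 1))
#' population_size(st)
#' @export
hoppe_urn_init <- function(config, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- config$grid
  n_open <- n_cells(grid) - if (is.null(mask)) 0L else nrow(mask$cells)
  if (n_open == 0) abort("all cells are barriers: cannot initialize a population")
  theta <- 2 * n_open * config$init_mu
  urn <- hoppe_urn_draw(n_open, theta)
  init_state_common(config, mask, urn$alleles, urn$n_alleles,
                    list(N = n_open, theta = theta))
}

#' Deterministic initializations
#'
#' `distinct_allele_init()` gives every occupied cell its own allele
#' (ids 1..N in row-major order) — the natural start for fixation-probability
#' experiments where one cell's allele is tracked.  `manual_allele_init()`
#' places a caller-supplied allele vector on the open cells in row-major
#' order.  Both honour `config$seed` so the following run is reproducible.
#'
#' @param config A [sim_config()].
#' @param mask Optional [barrier_mask()].
#' @param alleles Positive integer vector, one entry per non-barrier cell in
#'   row-major order.
#' @return A `population_state` at generation 0.
#' @export
distinct_allele_init <- function(config, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_open <- n_cells(config$grid) - if (is.null(mask)) 0L else nrow(mask$cells)
  if (n_open == 0) abort("all cells are barriers: cannot initialize a population")
  init_state_common(config, mask, seq_len(n_open), n_open,
                    list(N = n_open, theta = NA_real_))
}

#' @rdname distinct_allele_init
#' @export
manual_allele_init <- function(config, alleles, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_open <- n_cells(config$grid) - if (is.null(mask)) 0L else nrow(mask$cells)
  if (n_open == 0) abort("all cells are barriers: cannot initialize a population")
  alleles <- as.integer(alleles)
  if (length(alleles) != n_open || any(is.na(alleles)) || any(alleles < 1)) {
    abort(sprintf("`alleles` must be %d positive integers (one per open cell)", n_open))
  }
  init_state_common(config, mask, alleles, max(alleles),
                    list(N = n_open, theta = NA_real_))
}

# Shared dispatch used by run_until_fixation() and replicate helpers.
init_population <- function(config, mask = NULL, init = "hoppe", alleles = NULL) {
  if (!is.null(alleles)) return(manual_allele_init(config, alleles, mask))
  switch(init,
    hoppe = hoppe_urn_init(config, mask),
    distinct = distinct_allele_init(config, mask),
    abort("`init` must be \"hoppe\" or \"distinct\" (or supply `alleles`)")
  )
}

advance_steps <- function(state, n_steps, mu) {
  res <- cpp_sim_steps(
    state$cell_state, state$allele, state$grid$rows, state$grid$cols,
    open_index0(state), as.numeric(n_steps), mu, state$next_allele_id,
    state$noop_count
  )
  state$cell_state <- res$cell_state
  state$allele <- res$allele
  state$next_allele_id <- res$next_allele_id
  state$noop_count <- res$noop_count
  state$step_count <- state$step_count + n_steps
  state
}

#' One death/birth event
#'
#' The elementary Moran/voter update: a target cell is chosen uniformly
#' among all non-barrier cells; its occupant (if any) dies, leaving the cell
#' momentarily empty; a parent is chosen uniformly among the target's
#' occupied Moore neighbours, and its offspring takes the cell, copying the
#' parent's allele with probability `1 - mu` or carrying a brand-new allele
#' with probability `mu` (infinite-alleles mutation).  If the target has no
#' occupied neighbour the event is a no-op: an occupied target's individual
#' survives and an empty target stays empty, so population size never drops
#' through the kernel.  The dying individual is never its own parent.
#'
#' @param state A `population_state`.
#' @param mu Per-birth mutation probability; defaults to the config's
#'   `run_mu`.
#' @return The updated state (`step_count` always advances by 1).
#' @export
step <- function(state, mu = NULL) {
  stopifnot(inherits(state, "population_state"))
  mu <- check_mu(if (is.null(mu)) state$config$run_mu else mu)
  advance_steps(state, 1L, mu)
}

#' Run one generation
#'
#' Applies `steps_per_generation` death/birth events (the config's value,
#' default 2000) and advances the generation clock by one.  A generation is
#' the snapshot granularity: trajectories and fixation checks look at the
#' population once per generation.
#'
#' @inheritParams step
#' @return The updated state.
#' @export
run_generation <- function(state, mu = NULL) {
  stopifnot(inherits(state, "population_state"))
  mu <- check_mu(if (is.null(mu)) state$config$run_mu else mu)
  state <- advance_steps(state, state$config$steps_per_generation, mu)
  state$generation <- state$generation + 1L
  state
}

#' Run several generations, optionally recording the trajectory
#'
#' @inheritParams step
#' @param n_generations Number of generations to run.
#' @param record If `TRUE`, the allele spectrum is recorded at every
#'   generation snapshot from the current one through the last.
#' @return A list with `state` (the advanced state) and `trajectory` (an
#'   allele-trajectory tibble, or `NULL` when `record = FALSE`).
#' @export
run_generations <- function(state, n_generations, mu = NULL, record = TRUE) {
  stopifnot(inherits(state, "population_state"))
  n_generations <- check_count(n_generations, "n_generations")
  mu <- check_mu(if (is.null(mu)) state$config$run_mu else mu)
  traj <- NULL
  if (record) {
    comps <- state_components(state)
    rows <- vector("list", n_generations + 1L)
    rows[[1]] <- spectrum_snapshot(state, comps)
    for (g in seq_len(n_generations)) {
      state <- run_generation(state, mu)
      rows[[g + 1L]] <- spectrum_snapshot(state, comps)
    }
    traj <- as_allele_trajectory(bind_rows(rows))
  } else {
    for (g in seq_len(n_generations)) state <- run_generation(state, mu)
  }
  list(state = state, trajectory = traj)
}

#' Force mutations into chosen cells
#'
#' Immediately replaces the allele of each listed occupied cell with its own
#' brand-new unique allele (k cells receive k new ids, assigned in list
#' order).  Population size is unchanged and no random numbers are drawn.
#'
#' @param state A `population_state`.
#' @param cells Occupied-cell coordinates (0-based `(row, col)` rows).
#' @return The updated state.
#' @export
force_mutation <- function(state, cells) {
  stopifnot(inherits(state, "population_state"))
  m <- as_cell_matrix(cells)
  if (nrow(m) == 0) return(state)
  check_in_grid(state$grid, m)
  idx <- cell_index0(state$grid, m)
  st <- state$cell_state[idx + 1L]
  if (any(st != CELL_OCCUPIED)) {
    i <- which(st != CELL_OCCUPIED)[1]
    abort(sprintf(
      "force_mutation(): cell (%d, %d) is not occupied (state: %s)",
      m[i, 1], m[i, 2], cell_state_labels[st[i] + 1L]
    ))
  }
  new_ids <- state$next_allele_id + seq_len(nrow(m)) - 1L
  state$allele[idx + 1L] <- new_ids
  state$next_allele_id <- state$next_allele_id + nrow(m)
  state
}

#' Edit barriers on a live population
#'
#' `add_barrier(state, cells)` turns occupied or empty cells into barriers;
#' a previously occupied cell's individual is removed, so population size
#' declines by one per such cell.  `remove_barrier(state, cells)` turns
#' barrier cells into *empty* (not occupied) cells: removal does not
#' resurrect anyone, but empty cells are valid death/birth targets, so
#' neighbours replicate into them through the ordinary kernel and the
#' reopened ground is recolonized.
#'
#' @param state A `population_state`.
#' @param cells Coordinates to convert.
#' @return The updated state.
#' @export
add_barrier <- function(state, cells) {
  stopifnot(inherits(state, "population_state"))
  m <- as_cell_matrix(cells)
  if (nrow(m) == 0) return(state)
  check_in_grid(state$grid, m)
  idx <- cell_index0(state$grid, m)
  st <- state$cell_state[idx + 1L]
  if (any(st == CELL_BARRIER)) {
    i <- which(st == CELL_BARRIER)[1]
    abort(sprintf("add_barrier(): cell (%d, %d) is already a barrier", m[i, 1], m[i, 2]))
  }
  state$cell_state[idx + 1L] <- CELL_BARRIER
  state$allele[idx + 1L] <- NA_integer_
  state
}

#' @rdname add_barrier
#' @export
remove_barrier <- function(state, cells) {
  stopifnot(inherits(state, "population_state"))
  m <- as_cell_matrix(cells)
  if (nrow(m) == 0) return(state)
  check_in_grid(state$grid, m)
  idx <- cell_index0(state$grid, m)
  st <- state$cell_state[idx + 1L]
  if (any(st != CELL_BARRIER)) {
    i <- which(st != CELL_BARRIER)[1]
    abort(sprintf(
      "remove_barrier(): cell (%d, %d) is not a barrier (state: %s)",
      m[i, 1], m[i, 2], cell_state_labels[st[i] + 1L]
    ))
  }
  state$cell_state[idx + 1L] <- CELL_EMPTY
  state
}

#' Occupied Moore neighbours of a cell
#'
#' The subset of [moore_neighbors()] whose state is `occupied` — exactly the
#' candidate parents for a death/birth event at `cell`.  Barrier and empty
#' cells never parent offspring.
#'
#' @param state A `population_state`.
#' @param cell A 0-based `(row, col)` pair.
#' @return A tibble with columns `row`, `col`.
#' @export
occupied_neighbors <- function(state, cell) {
  stopifnot(inherits(state, "population_state"))
  nb <- moore_neighbors(state$grid, cell)
  idx <- cell_index0(state$grid, as_cell_matrix(nb))
  nb[state$cell_state[idx + 1L] == CELL_OCCUPIED, ]
}
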