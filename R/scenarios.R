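# The four classroom experiments as scripted, seeded, reproducible runs,
# plus a generic event-log replay that reproduces any of them bit-identically.
#
# Timeline convention (shared by the scripts and by replay_scenario): the
# population is initialized, a snapshot is recorded, and any events stamped
# with the current generation are then applied, followed immediately by a
# post-event snapshot under the new component labelling.  Each event batch
# therefore opens a new trajectory "phase".

new_event_log <- function() {
  tibble(
    generation = integer(0), action = character(0),
    cells = list()
  )
}

log_event <- function(events, generation, action, cells) {
  bind_rows(events, tibble(
    generation = as.integer(generation), action = action,
    cells = list(as.data.frame(as_cell_matrix(cells)))
  ))
}

apply_event <- function(state, action, cells) {
  switch(action,
    add_barrier = add_barrier(state, cells),
    remove_barrier = remove_barrier(state, cells),
    force_mutation = force_mutation(state, cells),
    abort(sprintf("unknown event action '%s'", action))
  )
}

new_scenario_result <- function(scenario, seed, config, events, trajectory,
                                fixation, final_states, runs, cap_hit) {
  structure(
    list(
      scenario = scenario, seed = seed, config = config, events = events,
      trajectory = trajectory, fixation = fixation,
      final_states = final_states, runs = runs, cap_hit = cap_hit
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> %s | seed %s | %d event(s) | %d trajectory row(s)%s\n",
    x$scenario, x$seed, nrow(x$events), nrow(x$trajectory),
    if (x$cap_hit) " | generation cap hit" else ""
  ))
  invisible(x)
}

with_phase <- function(report, phase) {
  mutate(report, phase = phase, .before = 1)
}

#' Default cross-barrier geometry
#'
#' One full horizontal barrier line and one full vertical barrier line,
#' splitting the grid into four quadrants of roughly equal size (on 32 x 32
#' with lines at row 15 / column 15: 15x15, 15x16, 16x15 and 16x16 cells).
#' The corridor is a short contiguous segment of the vertical line.
#'
#' @param grid A [grid_spec()].
#' @param barrier_row,barrier_col 0-based line positions.
#' @return A data frame of barrier cells (`row`, `col`).
#' @export
cross_barrier_cells <- function(grid, barrier_row = 15L, barrier_col = 15L) {
  unique(rbind(
    data.frame(row = barrier_row, col = seq_len(grid$cols) - 1L),
    data.frame(row = seq_len(grid$rows) - 1L, col = barrier_col)
  ))
}

#' @rdname cross_barrier_cells
#' @param rows Rows of the vertical-line cells removed to open the corridor
#'   (default: the midpoint of the upper segment).
#' @export
corridor_cells <- function(barrier_col = 15L, rows = 6:8) {
  data.frame(row = as.integer(rows), col = as.integer(barrier_col))
}

#' Classroom experiment 1: drift on the unmodified grid
#'
#' Runs the default model — 32 x 32 urn-initialized population, no
#' barriers, running mutation rate 0 — until one allele reaches fixation,
#' recording the allele-count and allele-frequency trajectory and the
#' number of generations to fixation.
#'
#' @param seed Integer seed; the whole experiment replays bit-identically
#'   from it.
#' @return A `scenario_result`.
#' @export
activity1_defaults <- function(seed) {
  cfg <- sim_config(seed = seed)
  state <- hoppe_urn_init(cfg)
  run <- finish_fixation_run(state, mu = 0, record = TRUE, phase = "run")
  new_scenario_result(
    scenario = "activity1", seed = seed, config = cfg,
    events = new_event_log(), trajectory = run$trajectory,
    fixation = with_phase(run$report, "run"),
    final_states = list(run = run$state),
    runs = list(list(
      label = "run", phases = "run", config = cfg, mu = 0,
      events = new_event_log(), end_generation = run$state$generation
    )),
    cap_hit = run$cap_hit
  )
}

#' Classroom experiment 2: absolute barriers, then a corridor
#'
#' Phase 1: the full grid is urn-initialized, a horizontal and a vertical
#' barrier line are drawn (four completely isolated quadrants; population
#' drops by one per barrier cell), and drift runs until every quadrant is
#' fixed.  Phase 2: a corridor is opened by removing a contiguous segment
#' of the vertical barrier, reconnecting two quadrants, and the run
#' continues until the joined component fixes again.  Quadrants never
#' touched by the corridor keep their phase-1 allele.
#'
#' @inheritParams activity1_defaults
#' @param barrier_row,barrier_col 0-based barrier line positions.
#' @param corridor Cells removed to open the corridor (default: 3 cells at
#'   the midpoint of the vertical line's upper segment, joining the two top
#'   quadrants).
#' @return A `scenario_result` whose `fixation` table has one row per
#'   component per phase.
#' @export
activity2_absolute_barriers <- function(seed, barrier_row = 15L,
                                        barrier_col = 15L,
                                        corridor = corridor_cells(barrier_col)) {
  cfg <- sim_config(seed = seed)
  state <- hoppe_urn_init(cfg)
  setup_snap <- mutate(spectrum_snapshot(state, state_components(state)),
                       phase = "setup", .before = 1)
  bars <- cross_barrier_cells(cfg$grid, barrier_row, barrier_col)
  events <- log_event(new_event_log(), 0L, "add_barrier", bars)
  state <- add_barrier(state, bars)

  ph1 <- finish_fixation_run(state, mu = 0, record = TRUE, phase = "phase1")
  g1 <- ph1$state$generation
  events <- log_event(events, g1, "remove_barrier", corridor)
  state <- remove_barrier(ph1$state, corridor)

  ph2 <- finish_fixation_run(state, mu = 0, record = TRUE, phase = "phase2")
  new_scenario_result(
    scenario = "activity2", seed = seed, config = cfg, events = events,
    trajectory = as_allele_trajectory(
      bind_rows(setup_snap, ph1$trajectory, ph2$trajectory)
    ),
    fixation = bind_rows(
      with_phase(ph1$report, "phase1"), with_phase(ph2$report, "phase2")
    ),
    final_states = list(run = ph2$state),
    runs = list(list(
      label = "run", phases = c("setup", "phase1", "phase2"), config = cfg,
      mu = 0, events = events, end_generation = ph2$state$generation
    )),
    cap_hit = ph1$cap_hit || ph2$cap_hit
  )
}

#' Classroom experiment 3: partial barriers (pre-opened corridor)
#'
#' The cross barriers are drawn and the corridor is opened *before* the run
#' starts, so gene flow between the two corridor-connected quadrants is
#' possible from generation 0 while the other two quadrants stay isolated.
#' The run continues until every component is fixed; the fixation table
#' flags the corridor-connected component.
#'
#' @inheritParams activity2_absolute_barriers
#' @return A `scenario_result`; `fixation` carries a logical `connected`
#'   column (`TRUE` for the merged, corridor-connected component).
#' @export
activity3_partial_barriers <- function(seed, barrier_row = 15L,
                                       barrier_col = 15L,
                                       corridor = corridor_cells(barrier_col)) {
  cfg <- sim_config(seed = seed)
  state <- hoppe_urn_init(cfg)
  setup_snap <- mutate(spectrum_snapshot(state, state_components(state)),
                       phase = "setup", .before = 1)
  bars <- cross_barrier_cells(cfg$grid, barrier_row, barrier_col)
  events <- log_event(new_event_log(), 0L, "add_barrier", bars)
  events <- log_event(events, 0L, "remove_barrier", corridor)
  state <- add_barrier(state, bars)
  state <- remove_barrier(state, corridor)

  run <- finish_fixation_run(state, mu = 0, record = TRUE, phase = "run")
  comps <- state_components(run$state)
  corridor_m <- as_cell_matrix(corridor)
  corr_comp <- unique(
    comps$component_id[cell_index0(cfg$grid, as_cell_matrix(comps)) %in%
                         cell_index0(cfg$grid, corridor_m)]
  )
  fixation <- with_phase(run$report, "run")
  fixation$connected <- fixation$component_id %in% corr_comp
  new_scenario_result(
    scenario = "activity3", seed = seed, config = cfg, events = events,
    trajectory = as_allele_trajectory(bind_rows(setup_snap, run$trajectory)),
    fixation = fixation,
    final_states = list(run = run$state),
    runs = list(list(
      label = "run", phases = c("setup", "run"), config = cfg, mu = 0,
      events = events, end_generation = run$state$generation
    )),
    cap_hit = run$cap_hit
  )
}

#' Classroom experiment 4: raising and lowering the mutation rate
#'
#' Fixed-length runs (default 200 generations) of the default grid at each
#' mutation rate in `mu_values`, every run starting from the same seeded
#' urn initialization so the trajectories are directly comparable.  Higher
#' running mutation rates hold more alleles in mutation-drift balance; at
#' `mu = 0` the allele count can only decay.
#'
#' @inheritParams activity1_defaults
#' @param mu_values Running mutation probabilities to compare.
#' @param n_generations Length of each run.
#' @return A `scenario_result`; trajectory phases are labelled `"mu=<value>"`.
#' @export
activity4_mutation_rates <- function(seed, mu_values = c(0, 0.001, 0.01),
                                     n_generations = 200L) {
  for (mu in mu_values) check_mu(mu)
  cfg <- sim_config(seed = seed)
  trajs <- list()
  finals <- list()
  runs <- list()
  for (mu in mu_values) {
    label <- paste0("mu=", format(mu))
    state <- hoppe_urn_init(cfg)
    res <- run_generations(state, n_generations, mu = mu, record = TRUE)
    trajs[[label]] <- mutate(res$trajectory, phase = label, .before = 1)
    finals[[label]] <- res$state
    runs[[length(runs) + 1L]] <- list(
      label = label, phases = label, config = cfg, mu = mu,
      events = new_event_log(), end_generation = n_generations
    )
  }
  new_scenario_result(
    scenario = "activity4", seed = seed, config = cfg,
    events = new_event_log(),
    trajectory = as_allele_trajectory(bind_rows(trajs)),
    fixation = NULL, final_states = finals, runs = runs, cap_hit = FALSE
  )
}

replay_run <- function(run) {
  state <- hoppe_urn_init(run$config)
  epoch <- 1L
  comps <- state_components(state)
  traj <- list()
  repeat {
    g <- state$generation
    snap <- mutate(spectrum_snapshot(state, comps),
                   phase = run$phases[epoch], .before = 1)
    traj[[length(traj) + 1L]] <- snap
    due <- run$events[run$events$generation == g, ]
    if (nrow(due) > 0 && epoch < length(run$phases)) {
      for (i in seq_len(nrow(due))) {
        state <- apply_event(state, due$action[i], due$cells[[i]])
      }
      epoch <- epoch + 1L
      comps <- state_components(state)
      traj[[length(traj) + 1L]] <- mutate(spectrum_snapshot(state, comps),
                                          phase = run$phases[epoch], .before = 1)
    }
    if (g >= run$end_generation) break
    state <- run_generation(state, run$mu)
  }
  list(trajectory = as_allele_trajectory(bind_rows(traj)), state = state)
}

#' Replay a scenario from its event log
#'
#' Re-executes a [activity1_defaults()]-family result purely from its
#' stored config (including the seed), event log and end generation — no
#' fixation detection is involved, so this is an independent path through
#' the engine.  Under the same seed the replay is bit-identical to the
#' original: same trajectory rows, same final allele layout.
#'
#' @param result A `scenario_result`.
#' @return A list with `trajectory` (all runs bound together, with the
#'   original phase labels) and `final_states` (named like the original's).
#' @export
replay_scenario <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  outs <- lapply(result$runs, replay_run)
  names(outs) <- vapply(result$runs, function(r) r$label, character(1))
  list(
    trajectory = as_allele_trajectory(
      bind_rows(lapply(outs, function(o) o$trajectory))
    ),
    final_states = lapply(outs, function(o) o$state)
  )
}

#' Quadrant fixation times: inside the barred grid vs an independent run
#'
#' Replicates the phase-1 situation of [activity2_absolute_barriers()]
#' (full-grid urn initialization, then cross barriers) and records the
#' designated quadrant's fixation generation; alongside it runs an
#' independent small-grid population matched to that quadrant.  Because
#' absolute barriers stop all gene flow, the two arms should be draws from
#' the same distribution — provided the comparator really matches, which
#' takes two calibrations:
#'
#' * **Initial diversity.** The quadrant's initial alleles are a size-n
#'   subsample of the full grid's Hoppe urn; by the sampling consistency of
#'   the Ewens distribution such a subsample is itself Ewens with the
#'   *same* theta.  The comparator therefore uses
#'   `init_mu = theta_full / (2 n_quadrant)`.
#' * **Event clock.** Inside the barred grid a quadrant of n cells receives
#'   on average `2000 n / n_open` death/birth events per generation, so the
#'   comparator's `steps_per_generation` is set to `round(2000 n / n_open)`.
#'
#' @param n_reps Replicates per arm.
#' @param base_seed Seed of the first replicate (the comparator arm is
#'   offset by `n_reps`).
#' @param quadrant Component id of the tracked quadrant (1 = top-left).
#' @param barrier_row,barrier_col Barrier line positions.
#' @return A tibble `arm`, `replicate`, `generations_to_fixation` with
#'   `arm` in `"within_barred_grid"`, `"independent_quadrant"`.
#' @export
activity2_quadrant_study <- function(n_reps = 500L, base_seed, quadrant = 1L,
                                     barrier_row = 15L, barrier_col = 15L) {
  cfg <- sim_config()
  bars <- cross_barrier_cells(cfg$grid, barrier_row, barrier_col)
  inside <- replicate_fixation_times(
    cfg, mu = 0, n_reps = n_reps, base_seed = base_seed,
    component = quadrant, barriers_after_init = bars
  )

  # Geometry of the tracked quadrant (components are rectangles here).
  mask <- barrier_mask(cfg$grid, bars)
  comps <- connected_components(cfg$grid, mask)
  qc <- comps[comps$component_id == quadrant, ]
  if (nrow(qc) == 0) abort(sprintf("no component with id %s", quadrant))
  q_rows <- length(unique(qc$row))
  q_cols <- length(unique(qc$col))
  n_quad <- nrow(qc)
  n_open <- n_cells(cfg$grid) - nrow(mask$cells)
  theta_full <- 2 * n_cells(cfg$grid) * cfg$init_mu

  comp_cfg <- sim_config(
    rows = q_rows, cols = q_cols,
    init_mu = theta_full / (2 * n_quad),
    steps_per_generation = max(1L, round(cfg$steps_per_generation * n_quad / n_open)),
    max_generations = cfg$max_generations
  )
  indep <- replicate_fixation_times(
    comp_cfg, mu = 0, n_reps = n_reps, base_seed = base_seed + n_reps
  )
  bind_rows(
    tibble(arm = "within_barred_grid", replicate = inside$replicate,
           generations_to_fixation = inside$generations_to_fixation),
    tibble(arm = "independent_quadrant", replicate = indep$replicate,
           generations_to_fixation = indep$generations_to_fixation)
  )
}
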