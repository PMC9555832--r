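# Configuration files (JSON/YAML), trajectory CSV, state-snapshot JSON,
# event-log JSON, and run manifests.

config_keys <- c(
  "rows", "cols", "init_mu", "run_mu", "steps_per_generation", "seed",
  "max_generations", "barrier_mask"
)

config_as_list <- function(config) {
  out <- list(
    rows = config$grid$rows, cols = config$grid$cols,
    init_mu = config$init_mu, run_mu = config$run_mu,
    steps_per_generation = config$steps_per_generation,
    max_generations = config$max_generations
  )
  if (!is.null(config$seed)) out$seed <- config$seed
  if (!is.null(config$barrier_mask_path)) out$barrier_mask <- config$barrier_mask_path
  out
}

#' Validate a simulation configuration
#'
#' Total validation: every problem in the document becomes one diagnostic
#' row; nothing throws, so a config can be fully linted before a run.
#' Accepts either a raw named list (as read from a file) or a
#' [sim_config()].
#'
#' @param x Named list or `sim_config`.
#' @return A tibble with columns `field` and `problem`; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(x) {
  if (inherits(x, "sim_config")) {
    x <- config_as_list(x)
  }
  probs <- list()
  note <- function(field, problem) {
    probs[[length(probs) + 1L]] <<- tibble(field = field, problem = problem)
  }
  is_count <- function(v) {
    is.numeric(v) && length(v) == 1 && !is.na(v) && v >= 1 && v == as.integer(v)
  }
  for (f in c("rows", "cols", "steps_per_generation", "max_generations")) {
    if (!is.null(x[[f]]) && !is_count(x[[f]])) {
      note(f, "must be a single positive integer")
    }
  }
  for (f in c("init_mu", "run_mu")) {
    v <- x[[f]]
    if (!is.null(v) &&
        (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)) {
      note(f, "must be a probability in [0, 1]")
    }
  }
  if (!is.null(x$seed) &&
      (!is.numeric(x$seed) || length(x$seed) != 1 || is.na(x$seed) ||
       x$seed != as.integer(x$seed))) {
    note("seed", "must be a single integer")
  }
  if (!is.null(x$barrier_mask) &&
      (!is.character(x$barrier_mask) || length(x$barrier_mask) != 1)) {
    note("barrier_mask", "must be a single file path")
  }
  if (length(probs) == 0) {
    tibble(field = character(0), problem = character(0))
  } else {
    bind_rows(probs)
  }
}

#' Read and write configuration files
#'
#' `load_config()` reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) document
#' with the keys `rows`, `cols`, `init_mu`, `run_mu`,
#' `steps_per_generation`, `seed`, `max_generations`, `barrier_mask` (a
#' path to a text mask, resolved relative to the config file).  Missing
#' keys take the model defaults (32, 32, 0.001, 0, 2000); unknown keys are
#' rejected; an empty document yields the full default configuration.
#' `dump_config()` writes a resolved config back out, and
#' `load_config(dump_config(x))` returns `x`.
#'
#' @param path File path; the extension selects the format.
#' @return `load_config()` returns a [sim_config()] (with
#'   `$barrier_mask_path` set when the document names a mask).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (!nzchar(trimws(txt))) {
    list()
  } else if (ext == "json") {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::yaml.load(txt)
  } else {
    abort(sprintf("unsupported config format '.%s' (use .json or .yaml)", ext))
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  problems <- validate_config(raw)
  if (nrow(problems) > 0) {
    abort(paste0(
      "invalid config ", path, ":\n",
      paste0("  - ", problems$field, ": ", problems$problem, collapse = "\n")
    ))
  }
  cfg <- sim_config(
    rows = raw$rows %||% 32L, cols = raw$cols %||% 32L,
    init_mu = raw$init_mu %||% 0.001, run_mu = raw$run_mu %||% 0,
    steps_per_generation = raw$steps_per_generation %||% 2000L,
    seed = raw$seed,
    max_generations = raw$max_generations %||% 100000L
  )
  if (!is.null(raw$barrier_mask)) {
    p <- raw$barrier_mask
    if (!file.exists(p)) p <- file.path(dirname(path), raw$barrier_mask)
    cfg$barrier_mask_path <- p
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config A [sim_config()].
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- config_as_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    abort(sprintf("unsupported config format '.%s' (use .json or .yaml)", ext))
  }
  invisible(path)
}

#' Trajectory CSV input/output
#'
#' Long-format CSV with header
#' `generation,component_id,allele_id,count,frequency` (a leading `phase`
#' column is preserved when present, as written by the scenario scripts).
#' Rows are sorted by `(generation, component_id, allele_id)` and
#' frequencies are serialized to 10 significant digits, so
#' `read_trajectory(write_trajectory(x))` reproduces `x` to that precision.
#'
#' @param trajectory An allele-trajectory tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory tibble.
#' @export
write_trajectory <- function(trajectory, path) {
  need <- c("generation", "component_id", "allele_id", "count", "frequency")
  if (!all(need %in% names(trajectory))) {
    abort(paste0("trajectory must have columns ", paste(need, collapse = ", ")))
  }
  out <- arrange(as_tibble(trajectory), .data$generation, .data$component_id,
                 .data$allele_id)
  out$frequency <- sprintf("%.10g", out$frequency)
  keep <- c(intersect("phase", names(out)), need)
  readr::write_csv(out[keep], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(sprintf("trajectory file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("generation", "component_id", "allele_id", "count", "frequency")
  if (!all(need %in% names(x))) {
    abort(sprintf("malformed trajectory CSV %s: missing column(s) %s", path,
                  paste(setdiff(need, names(x)), collapse = ", ")))
  }
  for (f in c("generation", "component_id", "allele_id", "count")) {
    x[[f]] <- as.integer(x[[f]])
  }
  x$frequency <- as.numeric(x$frequency)
  as_allele_trajectory(x)
}

#' State snapshots as JSON
#'
#' A snapshot holds the grid dimensions, the clocks, the allele-id
#' counters, the config echo and one record per cell
#' (`{row, col, state, allele}`).  `read_snapshot()` rebuilds a
#' `population_state` from it; the RNG stream itself is not part of a
#' snapshot (reproducibility is seed-based, from the config).
#'
#' @param state A `population_state`.
#' @param path File path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()` a
#'   `population_state`.
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "population_state"))
  x <- list(
    rows = state$grid$rows, cols = state$grid$cols,
    generation = state$generation, step_count = state$step_count,
    noop_count = state$noop_count,
    next_allele_id = state$next_allele_id,
    init_allele_cutoff = state$init_allele_cutoff,
    config = config_as_list(state$config),
    cells = as.data.frame(as_tibble(state))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) abort(sprintf("snapshot file not found: %s", path))
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- sim_config(
    rows = x$config$rows, cols = x$config$cols, init_mu = x$config$init_mu,
    run_mu = x$config$run_mu,
    steps_per_generation = x$config$steps_per_generation,
    seed = x$config$seed, max_generations = x$config$max_generations
  )
  cells <- x$cells
  code <- match(cells$state, cell_state_labels) - 1L
  ord <- order(cells$row * x$cols + cells$col)
  st <- new_population_state(
    cfg$grid, code[ord],
    if (is.null(cells$allele)) rep(NA_integer_, nrow(cells)) else as.integer(cells$allele[ord]),
    x$next_allele_id, x$init_allele_cutoff, cfg
  )
  st$generation <- as.integer(x$generation)
  st$step_count <- x$step_count
  st$noop_count <- x$noop_count %||% 0
  st
}

#' Event-schedule JSON input/output
#'
#' Timed barrier and forced-mutation edits as a JSON list of
#' `{generation, action, cells}` objects, `action` one of `"add_barrier"`,
#' `"remove_barrier"`, `"force_mutation"` and `cells` a list of
#' `{row, col}` coordinates.
#'
#' @param events Event tibble (`generation`, `action`, list-column `cells`).
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   event tibble.
#' @export
write_events <- function(events, path) {
  x <- lapply(seq_len(nrow(events)), function(i) {
    list(
      generation = events$generation[i], action = events$action[i],
      cells = events$cells[[i]]
    )
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("events file not found: %s", path))
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- new_event_log()
  for (ev in x) {
    cells <- bind_rows(lapply(ev$cells, function(cl) {
      data.frame(row = as.integer(cl$row), col = as.integer(cl$col))
    }))
    out <- log_event(out, ev$generation, ev$action, cells)
  }
  out
}

#' Write a run manifest
#'
#' A manifest records everything needed to reproduce a run's outputs
#' byte-identically: the resolved config (with seed), the RNG generator
#' name, the package version, the generation span, and the paths of the
#' files the run wrote.
#'
#' @param path File path.
#' @param config The [sim_config()] used.
#' @param start_generation,end_generation Generation span of the run.
#' @param outputs Named character vector of output file paths.
#' @param events_file Optional path of the event-log JSON.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()` a
#'   named list.
#' @export
write_manifest <- function(path, config, start_generation, end_generation,
                           outputs = character(0), events_file = NULL) {
  x <- list(
    package = "driftgrid",
    version = as.character(packageVersion("driftgrid")),
    generator = RNGkind()[1],
    config = config_as_list(config),
    start_generation = start_generation,
    end_generation = end_generation,
    events = events_file,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
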