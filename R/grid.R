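# Lattice geometry: grid specs, Moore neighbourhoods with hard edges,
# barrier masks, connected components, and the '#'/'.' text-mask format.
#
# Coordinates are 0-based (row, col), row-major, row 0 at the top.  The
# scalar cell index used internally is idx = row * cols + col (0-based);
# R vectors are addressed at idx + 1.

#' Define a rectangular lattice
#'
#' A grid specification is the geometry every other object refers back to.
#' Cells are addressed by 0-based `(row, col)` pairs, row-major, with row 0
#' at the top; there is no wraparound, so edge and corner cells genuinely
#' have fewer neighbours (3 or 5 instead of 8) and the model has a small
#' edge effect.
#'
#' @param rows,cols Positive integer grid dimensions. Defaults give the
#'   standard 32 x 32 lattice of 1024 cells.
#' @return An object of class `grid_spec` with fields `rows` and `cols`.
#' @examples
#' g <- grid_spec()
#' moore_neighbors(g, c(0, 0))
#' @export
grid_spec <- function(rows = 32L, cols = 32L) {
  rows <- check_count(rows, "rows")
  cols <- check_count(cols, "cols")
  structure(list(rows = rows, cols = cols), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d (%d cells)\n", x$rows, x$cols,
              x$rows * x$cols))
  invisible(x)
}

check_count <- function(x, what) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer", what))
  }
  as.integer(x)
}

n_cells <- function(grid) grid$rows * grid$cols

# Coerce cell input (length-2 vector, two-column matrix, or data frame with
# row/col columns) to an integer matrix with columns row, col.
as_cell_matrix <- function(cells, arg = "cells") {
  if (is.null(cells)) {
    m <- matrix(integer(0), ncol = 2)
  } else if (is.data.frame(cells)) {
    if (!all(c("row", "col") %in% names(cells))) {
      abort(sprintf("`%s` must have `row` and `col` columns", arg))
    }
    m <- cbind(as.integer(cells$row), as.integer(cells$col))
  } else if (is.matrix(cells)) {
    if (ncol(cells) != 2) abort(sprintf("`%s` must have two columns", arg))
    m <- matrix(as.integer(cells), ncol = 2)
  } else if (is.numeric(cells) && length(cells) == 2) {
    m <- matrix(as.integer(cells), ncol = 2)
  } else {
    abort(sprintf(
      "`%s` must be a (row, col) pair, a two-column matrix, or a data frame",
      arg
    ))
  }
  colnames(m) <- c("row", "col")
  m
}

check_in_grid <- function(grid, m, arg = "cells") {
  bad <- m[, 1] < 0 | m[, 1] >= grid$rows | m[, 2] < 0 | m[, 2] >= grid$cols
  bad <- bad | is.na(m[, 1]) | is.na(m[, 2])
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "%s: cell (%s, %s) is outside the %d x %d grid",
      arg, m[i, 1], m[i, 2], grid$rows, grid$cols
    ))
  }
  invisible(m)
}

cell_index0 <- function(grid, m) m[, 1] * grid$cols + m[, 2]

index0_cells <- function(grid, idx) {
  tibble(row = idx %/% grid$cols, col = idx %% grid$cols)
}

#' Moore neighbourhood of a cell
#'
#' Returns all in-bounds cells at Chebyshev distance 1 from `cell`
#' (up to 8: the adjacent and diagonal cells), in row-major order of the
#' 3 x 3 block with the centre excluded.  Edges are hard: corner cells have
#' 3 neighbours, non-corner edge cells 5, interior cells 8.
#'
#' @param grid A [grid_spec()].
#' @param cell A 0-based `(row, col)` pair (or one-row data frame / matrix).
#' @return A tibble with columns `row`, `col`.
#' @export
moore_neighbors <- function(grid, cell) {
  m <- as_cell_matrix(cell, "cell")
  if (nrow(m) != 1) abort("`cell` must be a single (row, col) coordinate")
  check_in_grid(grid, m, "cell")
  off <- cbind(
    row = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    col = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  nb <- cbind(m[1, 1] + off[, 1], m[1, 2] + off[, 2])
  keep <- nb[, 1] >= 0 & nb[, 1] < grid$rows & nb[, 2] >= 0 & nb[, 2] < grid$cols
  tibble(row = nb[keep, 1], col = nb[keep, 2])
}

#' Create a barrier mask
#'
#' A barrier mask marks cells of the grid as impassable: barrier cells are
#' never occupied, never die, and never serve as parents, so a complete
#' barrier line stops all gene flow across it.  Masks are edited only
#' through [add_barrier_cells()] / [remove_barrier_cells()], which append to
#' an audit log carried on the object.
#'
#' @param grid A [grid_spec()].
#' @param cells Barrier coordinates (0-based `(row, col)`; data frame,
#'   two-column matrix, or `NULL` for an empty mask).
#' @return An object of class `barrier_mask`.
#' @examples
#' m <- barrier_mask(grid_spec(5, 5), data.frame(row = 0:4, col = 2))
#' connected_components(grid_spec(5, 5), m)
#' @export
barrier_mask <- function(grid, cells = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  m <- as_cell_matrix(cells)
  check_in_grid(grid, m)
  idx <- sort(unique(cell_index0(grid, m)))
  structure(
    list(grid = grid, cells = as_cell_df(grid, idx), log = list()),
    class = "barrier_mask"
  )
}

as_cell_df <- function(grid, idx0) as.data.frame(index0_cells(grid, idx0))

mask_index0 <- function(mask) {
  cell_index0(mask$grid, as_cell_matrix(mask$cells))
}

#' @export
print.barrier_mask <- function(x, ...) {
  cat(sprintf(
    "<barrier_mask> %d barrier cell(s) on a %d x %d grid, %d edit(s) logged\n",
    nrow(x$cells), x$grid$rows, x$grid$cols, length(x$log)
  ))
  invisible(x)
}

#' Edit a barrier mask
#'
#' `add_barrier_cells()` marks open cells as barriers; `remove_barrier_cells()`
#' reopens barrier cells.  Each edit is appended to the mask's audit log.
#' Adding a cell that is already a barrier (or removing one that is not) is
#' an error, so every logged edit corresponds to a real change.
#'
#' @param mask A [barrier_mask()].
#' @param cells Coordinates to add or remove.
#' @return The edited `barrier_mask`.
#' @export
add_barrier_cells <- function(mask, cells) {
  m <- as_cell_matrix(cells)
  check_in_grid(mask$grid, m)
  idx <- cell_index0(mask$grid, m)
  cur <- mask_index0(mask)
  if (any(idx %in% cur)) {
    abort("add_barrier_cells(): some cells are already barriers")
  }
  mask$cells <- as_cell_df(mask$grid, sort(unique(c(cur, idx))))
  mask$log <- c(mask$log, list(list(action = "add", cells = as_cell_df(mask$grid, idx))))
  mask
}

#' @rdname add_barrier_cells
#' @export
remove_barrier_cells <- function(mask, cells) {
  m <- as_cell_matrix(cells)
  check_in_grid(mask$grid, m)
  idx <- cell_index0(mask$grid, m)
  cur <- mask_index0(mask)
  if (!all(idx %in% cur)) {
    abort("remove_barrier_cells(): some cells are not barriers")
  }
  mask$cells <- as_cell_df(mask$grid, sort(setdiff(cur, idx)))
  mask$log <- c(mask$log, list(list(action = "remove", cells = as_cell_df(mask$grid, idx))))
  mask
}

#' Label Moore-connected components of the open cells
#'
#' Partitions the non-barrier cells into maximal sets connected through
#' Moore (8-cell) adjacency — the same adjacency the simulation uses for
#' parent choice, so two subpopulations belong to one component exactly when
#' alleles can flow between them.  A diagonal-only gap in a barrier
#' therefore connects (and leaks).  Component ids are 1-based and ordered by
#' each component's smallest row-major cell index, which makes labels stable
#' across calls.
#'
#' @param grid A [grid_spec()].
#' @param mask A [barrier_mask()] or `NULL` for no barriers.
#' @return A tibble with columns `component_id`, `row`, `col`, sorted by
#'   component then row-major position.  Barrier cells are absent.
#' @export
connected_components <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  barrier <- if (is.null(mask)) integer(0) else {
    stopifnot(identical(mask$grid, grid))
    mask_index0(mask)
  }
  open0 <- setdiff(seq_len(n_cells(grid)) - 1L, barrier)
  if (length(open0) == 0) {
    return(tibble(component_id = integer(0), row = integer(0), col = integer(0)))
  }
  is_open <- rep(FALSE, n_cells(grid))
  is_open[open0 + 1L] <- TRUE
  r <- open0 %/% grid$cols
  c <- open0 %% grid$cols
  # Undirected Moore edges via four forward offsets.
  offs <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  from <- integer(0); to <- integer(0)
  for (d in offs) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 0 & r2 < grid$rows & c2 >= 0 & c2 < grid$cols
    i2 <- r2[ok] * grid$cols + c2[ok]
    ok2 <- is_open[i2 + 1L]
    from <- c(from, open0[ok][ok2])
    to <- c(to, i2[ok2])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(open0))
  )
  memb <- igraph::components(g)$membership
  idx <- as.integer(names(memb))
  # Relabel so component 1 contains the smallest row-major open cell, etc.
  first <- tapply(idx, memb, min)
  relabel <- rank(first)
  comp <- as.integer(relabel[as.character(memb)])
  out <- tibble(component_id = comp, row = idx %/% grid$cols, col = idx %% grid$cols)
  arrange(out, .data$component_id, .data$row, .data$col)
}

#' Parse and render the text barrier-mask format
#'
#' The plain-text mask format is one line per grid row (top row first), one
#' character per cell: `#` for a barrier, `.` for an open cell.
#' `render_barrier_mask()` is the exact inverse of `parse_barrier_mask()`
#' (lines joined with `"\n"`, no trailing newline).
#'
#' @param text A single string (possibly containing newlines) or a character
#'   vector of lines.
#' @param grid Optional [grid_spec()] the mask must match; by default the
#'   grid is inferred from the text.
#' @return `parse_barrier_mask()` returns a [barrier_mask()];
#'   `render_barrier_mask()` returns a single string.
#' @examples
#' m <- parse_barrier_mask("#.\n.#")
#' m$cells
#' render_barrier_mask(m)
#' @export
parse_barrier_mask <- function(text, grid = NULL) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) == 0) abort("barrier mask text is empty")
  widths <- nchar(lines)
  if (any(widths != widths[1])) {
    i <- which(widths != widths[1])[1]
    abort(sprintf(
      "barrier mask line %d: expected %d characters, got %d",
      i, widths[1], widths[i]
    ))
  }
  chars <- strsplit(lines, "", fixed = TRUE)
  bad_line <- which(vapply(chars, function(ch) any(!ch %in% c("#", ".")), logical(1)))
  if (length(bad_line) > 0) {
    ch <- setdiff(chars[[bad_line[1]]], c("#", "."))[1]
    abort(sprintf("barrier mask line %d: unknown character '%s'", bad_line[1], ch))
  }
  inferred <- grid_spec(length(lines), widths[1])
  if (!is.null(grid)) {
    if (!identical(grid$rows, inferred$rows) || !identical(grid$cols, inferred$cols)) {
      abort(sprintf(
        "barrier mask is %d x %d but grid is %d x %d",
        inferred$rows, inferred$cols, grid$rows, grid$cols
      ))
    }
    inferred <- grid
  }
  mat <- do.call(rbind, chars)
  hit <- which(mat == "#", arr.ind = TRUE)
  barrier_mask(inferred, cbind(hit[, 1] - 1L, hit[, 2] - 1L))
}

#' @rdname parse_barrier_mask
#' @param mask A [barrier_mask()].
#' @export
render_barrier_mask <- function(mask) {
  mat <- matrix(".", nrow = mask$grid$rows, ncol = mask$grid$cols)
  if (nrow(mask$cells) > 0) {
    mat[cbind(mask$cells$row + 1L, mask$cells$col + 1L)] <- "#"
  }
  paste(apply(mat, 1, paste, collapse = ""), collapse = "\n")
}
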