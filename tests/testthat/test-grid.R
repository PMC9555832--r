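test_that("Moore neighbourhoods truncate at hard edges, in row-major order", {
  g <- grid_spec(32, 32)
  nb <- moore_neighbors(g, c(10, 10))
  expect_equal(nrow(nb), 8)
  expect_equal(nb$row, c(9, 9, 9, 10, 10, 11, 11, 11))
  expect_equal(nb$col, c(9, 10, 11, 9, 11, 9, 10, 11))

  corner <- moore_neighbors(g, c(0, 0))
  expect_equal(as.data.frame(corner), data.frame(row = c(0, 1, 1), col = c(1, 0, 1)))

  edge <- moore_neighbors(g, c(0, 5))
  expect_equal(nrow(edge), 5)

  expect_error(moore_neighbors(g, c(32, 0)), "outside")
  expect_error(moore_neighbors(g, c(0, -1)), "outside")
})

test_that("neighbour symmetry and counts hold across random cells", {
  set.seed(401)
  for (dims in list(c(3, 3), c(3, 7), c(5, 4), c(8, 8))) {
    g <- grid_spec(dims[1], dims[2])
    for (k in 1:15) {
      a <- c(sample(0:(dims[1] - 1), 1), sample(0:(dims[2] - 1), 1))
      nb <- moore_neighbors(g, a)
      expect_true(nrow(nb) %in% c(3, 5, 8))
      for (i in seq_len(nrow(nb))) {
        back <- moore_neighbors(g, c(nb$row[i], nb$col[i]))
        expect_true(any(back$row == a[1] & back$col == a[2]))
      }
      expect_false(any(nb$row == a[1] & nb$col == a[2]))
    }
  }
})

test_that("occupied neighbours exclude barrier and empty cells", {
  st <- distinct_allele_init(sim_config(rows = 5, cols = 5))
  expect_equal(nrow(occupied_neighbors(st, c(2, 2))), 8)

  # 3x3 block: barrier the 4 edge-midpoint neighbours of the centre; the
  # occupied neighbours left are exactly the 4 corners of the block.
  mids <- data.frame(row = c(1, 2, 2, 3), col = c(2, 1, 3, 2))
  st2 <- add_barrier(st, mids)
  got <- occupied_neighbors(st2, c(2, 2))
  expect_equal(
    as.data.frame(got),
    data.frame(row = c(1, 1, 3, 3), col = c(1, 3, 1, 3))
  )

  # fully walled-in cell has no candidate parents
  ring <- as.data.frame(moore_neighbors(grid_spec(5, 5), c(0, 0)))
  st3 <- add_barrier(st, ring)
  expect_equal(nrow(occupied_neighbors(st3, c(0, 0))), 0)
})

test_that("connected components partition open cells with stable labels", {
  g <- grid_spec(32, 32)
  cc <- connected_components(g)
  expect_equal(max(cc$component_id), 1)
  expect_equal(nrow(cc), 32 * 32)

  cross <- barrier_mask(g, cross_barrier_cells(g))
  cc4 <- connected_components(g, cross)
  expect_equal(max(cc4$component_id), 4)
  expect_equal(nrow(cc4), 32 * 32 - 63)
  # label 1 owns the smallest row-major cell; quadrant sizes as constructed
  expect_equal(cc4$row[1], 0)
  expect_equal(cc4$col[1], 0)
  expect_equal(as.vector(table(cc4$component_id)), c(225, 240, 240, 256))
  # every open cell appears exactly once
  expect_equal(anyDuplicated(cc4[, c("row", "col")]), 0)

  # corridor through a barrier column reconnects the halves
  g5 <- grid_spec(5, 5)
  wall <- barrier_mask(g5, data.frame(row = 0:4, col = 2))
  expect_equal(max(connected_components(g5, wall)$component_id), 2)
  gap <- remove_barrier_cells(wall, c(2, 2))
  expect_equal(max(connected_components(g5, gap)$component_id), 1)
})

test_that("removing a barrier cell never increases the component count", {
  set.seed(402)
  for (rep in 1:10) {
    g <- grid_spec(6, 6)
    n_bar <- sample(3:14, 1)
    idx <- sample(0:35, n_bar)
    mask <- barrier_mask(g, data.frame(row = idx %/% 6, col = idx %% 6))
    before <- max(connected_components(g, mask)$component_id)
    drop <- mask$cells[sample(nrow(mask$cells), 1), ]
    mask2 <- remove_barrier_cells(mask, drop)
    after <- max(connected_components(g, mask2)$component_id)
    expect_lte(after, before)
  }
})

test_that("text masks round-trip and report format errors by line", {
  m <- parse_barrier_mask("..\n..")
  expect_equal(nrow(m$cells), 0)
  expect_equal(m$grid$rows, 2)

  m2 <- parse_barrier_mask("#.\n.#")
  expect_equal(as.data.frame(m2$cells), data.frame(row = c(0, 1), col = c(0, 1)))

  set.seed(403)
  for (rep in 1:10) {
    rows <- sample(1:6, 1); cols <- sample(1:6, 1)
    txt <- paste(
      vapply(seq_len(rows),
             function(i) paste(sample(c("#", "."), cols, TRUE), collapse = ""),
             character(1)),
      collapse = "\n"
    )
    expect_identical(render_barrier_mask(parse_barrier_mask(txt)), txt)
  }

  expect_error(parse_barrier_mask("..\n..."), "line 2")
  expect_error(parse_barrier_mask(".x\n.."), "line 1.*'x'")
  expect_error(parse_barrier_mask("..\n..", grid_spec(3, 2)), "2 x 2.*3 x 2")
})

test_that("mask edits are strict and audit-logged", {
  m <- barrier_mask(grid_spec(4, 4), c(1, 1))
  m <- add_barrier_cells(m, c(2, 2))
  expect_error(add_barrier_cells(m, c(1, 1)), "already")
  expect_error(remove_barrier_cells(m, c(0, 0)), "not barriers")
  m <- remove_barrier_cells(m, c(1, 1))
  expect_equal(length(m$log), 2)
  expect_equal(as.data.frame(m$cells), data.frame(row = 2, col = 2))
})
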