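test_that("Hoppe urn: deterministic first draw, theta = 0 collapses to one allele", {
  set.seed(11)
  for (n in c(1, 5, 200)) {
    u <- hoppe_urn_draw(n, 0)
    expect_equal(u$n_alleles, 1)
    expect_true(all(u$alleles == 1))
  }
  u <- hoppe_urn_draw(500, 3)
  expect_equal(sort(unique(u$alleles)), seq_len(u$n_alleles))
  expect_equal(u$alleles[1], 1)
})

test_that("urn mean allele count tracks the Ewens closed form at small n", {
  set.seed(12)
  ks <- replicate(400, hoppe_urn_draw(100, 5)$n_alleles)
  ek <- ewens_expected_k(100, 5)
  expect_lt(abs(mean(ks) - ek), 4 * sd(ks) / sqrt(length(ks)))
})

test_that("urn init fills non-barrier cells row-major and records theta", {
  mask <- parse_barrier_mask("##...\n.....\n..#..")
  cfg <- sim_config(rows = 3, cols = 5, init_mu = 0.01, seed = 7)
  st <- hoppe_urn_init(cfg, mask)
  expect_equal(population_size(st), 12)
  expect_equal(st$init_params$N, 12)
  expect_equal(st$init_params$theta, 2 * 12 * 0.01)
  df <- as_tibble(st)
  expect_equal(df$state[df$row == 0 & df$col %in% 0:1], c("barrier", "barrier"))
  expect_true(all(is.na(df$allele[df$state == "barrier"])))
  expect_true(all(!is.na(df$allele[df$state == "occupied"])))
  expect_error(
    hoppe_urn_init(sim_config(rows = 1, cols = 2),
                   parse_barrier_mask("##")),
    "all cells are barriers"
  )
})

test_that("a monomorphic full grid is invariant under drift steps", {
  cfg <- sim_config(rows = 6, cols = 6, init_mu = 0, seed = 21)
  st <- hoppe_urn_init(cfg)
  st2 <- st
  for (i in 1:100) st2 <- step(st2, mu = 0)
  expect_identical(st2$allele, st$allele)
  expect_identical(st2$cell_state, st$cell_state)
  expect_equal(st2$step_count, 100)
  expect_equal(population_size(st2), 36)
})

test_that("single-event transition frequencies match the exact kernel law", {
  # 1x3 line, alleles (A, B, A): one event moves the state to
  # (A,A,A), (B,B,A) or (A,B,B) with probability 1/3 each.
  cfg <- sim_config(rows = 1, cols = 3, steps_per_generation = 1)
  n <- 6000
  out <- character(n)
  for (i in 1:n) {
    cfg$seed <- 5000L + i
    st <- manual_allele_init(cfg, c(1, 2, 1))
    st <- step(st, mu = 0)
    out[i] <- paste(st$allele, collapse = "")
  }
  freq <- table(out) / n
  expect_setequal(names(freq), c("111", "221", "122"))
  se <- sqrt(1 / 3 * 2 / 3 / n)
  for (s in names(freq)) expect_lt(abs(freq[[s]] - 1 / 3), 4 * se)
})

test_that("mutation creates globally unique allele ids; mu = 1 is all-novel", {
  cfg <- sim_config(rows = 4, cols = 4, seed = 31)
  st <- hoppe_urn_init(cfg)
  cutoff <- st$init_allele_cutoff
  before <- st$next_allele_id
  st2 <- st
  for (i in 1:50) st2 <- step(st2, mu = 1)
  expect_equal(st2$next_allele_id, before + 50)  # every event births a mutant
  new_ids <- setdiff(unique(st2$allele), unique(st$allele))
  expect_true(all(new_ids >= cutoff))
})

test_that("allele loss is monotone under mu = 0", {
  cfg <- sim_config(rows = 8, cols = 8, steps_per_generation = 100, seed = 33)
  st <- hoppe_urn_init(cfg)
  seen <- unique(st$allele[st$cell_state == 1L])
  prev <- length(seen)
  for (g in 1:30) {
    st <- run_generation(st, mu = 0)
    cur <- unique(st$allele[!is.na(st$allele)])
    expect_true(all(cur %in% seen))
    expect_lte(length(cur), prev)
    seen <- cur
    prev <- length(cur)
  }
})

test_that("force_mutation assigns fresh ids in list order", {
  cfg <- sim_config(rows = 4, cols = 4, init_mu = 0, seed = 41)
  st <- hoppe_urn_init(cfg)  # monomorphic
  expect_equal(n_alleles(st), 1)
  before <- st$next_allele_id

  st1 <- force_mutation(st, c(1, 1))
  expect_equal(n_alleles(st1), 2)

  cells <- data.frame(row = c(0, 2, 3), col = c(0, 2, 1))
  st3 <- force_mutation(st, cells)
  expect_equal(st3$next_allele_id, before + 3)
  got <- st3$allele[cells$row * 4 + cells$col + 1]
  expect_equal(got, before + 0:2)  # ids assigned in list order
  expect_equal(population_size(st3), 16)

  expect_identical(force_mutation(st, NULL)$allele, st$allele)
  stb <- add_barrier(st, c(1, 1))
  expect_error(force_mutation(stb, c(1, 1)), "not occupied.*barrier")
})

test_that("barrier edits account population exactly; removal does not resurrect", {
  st <- hoppe_urn_init(sim_config(seed = 51))
  expect_equal(population_size(st), 1024)
  st1 <- add_barrier(st, c(10, 10))
  expect_equal(population_size(st1), 1023)
  st2 <- remove_barrier(st1, c(10, 10))
  expect_equal(population_size(st2), 1023)
  expect_equal(as_tibble(st2)$state[10 * 32 + 10 + 1], "empty")
  expect_error(add_barrier(st1, c(10, 10)), "already a barrier")
  expect_error(remove_barrier(st2, c(10, 10)), "not a barrier")
})

test_that("empty cells are recolonized by the kernel and population recovers", {
  cfg <- sim_config(rows = 5, cols = 5, init_mu = 0, steps_per_generation = 200,
                    seed = 52)
  st <- hoppe_urn_init(cfg)
  st <- add_barrier(st, c(2, 2))
  st <- remove_barrier(st, c(2, 2))
  expect_equal(population_size(st), 24)
  sizes <- integer(10)
  for (g in 1:10) {
    st <- run_generation(st, mu = 0)
    sizes[g] <- population_size(st)
  }
  expect_true(all(diff(c(24, sizes)) >= 0))  # step never loses individuals
  expect_equal(sizes[10], 25)                # hole refilled
})

test_that("an individual walled in by barriers survives as no-op events", {
  st <- distinct_allele_init(sim_config(rows = 3, cols = 3))
  ring <- as.data.frame(moore_neighbors(grid_spec(3, 3), c(0, 0)))
  st <- add_barrier(st, ring)
  a0 <- st$allele[1]
  for (i in 1:200) st <- step(st, mu = 0)
  expect_equal(st$allele[1], a0)
  expect_equal(population_size(st), 6)
  expect_gt(st$noop_count, 0)
})

test_that("seeded runs replay bit-identically, batched or stepwise", {
  cfg <- sim_config(rows = 10, cols = 10, steps_per_generation = 150, seed = 61)
  a <- hoppe_urn_init(cfg)
  for (g in 1:5) a <- run_generation(a, mu = 0.01)

  b <- hoppe_urn_init(cfg)
  b <- run_generations(b, 5, mu = 0.01, record = FALSE)$state
  expect_identical(a$allele, b$allele)
  expect_identical(a$cell_state, b$cell_state)
  expect_identical(a$next_allele_id, b$next_allele_id)

  # recording on/off must not change the RNG stream
  f1 <- run_until_fixation(sim_config(rows = 6, cols = 6, seed = 62), mu = 0,
                           record = TRUE)
  f2 <- run_until_fixation(sim_config(rows = 6, cols = 6, seed = 62), mu = 0,
                           record = FALSE)
  expect_identical(f1$state$allele, f2$state$allele)
  expect_equal(f1$report$generations_to_fixation,
               f2$report$generations_to_fixation)
})
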