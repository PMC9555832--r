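test_that("allele spectrum gives exact counts and normalized frequencies", {
  cfg <- sim_config(rows = 2, cols = 2)
  st <- manual_allele_init(cfg, c(5, 5, 7, 9))
  sp <- allele_spectrum(st)
  expect_equal(sp$allele_id, c(5, 7, 9))
  expect_equal(sp$count, c(2, 1, 1))
  expect_equal(sp$frequency, c(0.5, 0.25, 0.25))
  expect_equal(nrow(sp), 3)

  # monomorphic full grid: one entry carrying the whole population
  stm <- hoppe_urn_init(sim_config(rows = 4, cols = 4, init_mu = 0, seed = 1))
  spm <- allele_spectrum(stm)
  expect_equal(nrow(spm), 1)
  expect_equal(spm$count, 16)

  # with barriers: per-component rows plus a pooled component 0
  stq <- hoppe_urn_init(sim_config(seed = 2))
  stq <- add_barrier(stq, cross_barrier_cells(grid_spec()))
  spq <- allele_spectrum(stq)
  expect_setequal(unique(spq$component_id), 0:4)
  sums <- tapply(spq$frequency, spq$component_id, sum)
  expect_equal(as.numeric(sums), rep(1, 5))
  counts <- tapply(spq$count, spq$component_id, sum)
  expect_equal(as.numeric(counts), c(961, 225, 240, 240, 256))
})

test_that("stale component labelling is rejected", {
  st <- hoppe_urn_init(sim_config(rows = 5, cols = 5, seed = 3))
  comps <- state_components(st)
  st2 <- add_barrier(st, c(2, 2))
  expect_error(allele_spectrum(st2, comps), "stale")
})

test_that("fixation detection per component, with empty components undefined", {
  cfg <- sim_config(rows = 4, cols = 4, init_mu = 0, seed = 4)
  st <- hoppe_urn_init(cfg)
  expect_true(is_fixed(st))
  st2 <- force_mutation(st, c(0, 0))
  expect_false(is_fixed(st2))

  # isolate one cell, then empty it: fixation there is undefined
  line <- data.frame(row = c(0, 1, 1), col = c(1, 0, 1))
  st3 <- add_barrier(st, line)
  comps <- state_components(st3)
  expect_equal(max(comps$component_id), 2)
  expect_true(is_fixed(st3, component = 1, components = comps))
  st4 <- add_barrier(st3, c(0, 0))
  st4 <- remove_barrier(st4, c(0, 0))
  expect_error(is_fixed(st4, component = 1), "undefined")
  expect_error(is_fixed(st3, component = 9), "no component")
})

test_that("fixation report flags fixed components and the fixed allele", {
  cfg <- sim_config(rows = 1, cols = 3)
  st <- manual_allele_init(cfg, c(4, 4, 9))
  st <- add_barrier(st, c(0, 1))  # isolates cells 0 and 2
  rep_ <- fixation_report(st)
  expect_equal(rep_$fixed, c(TRUE, TRUE))
  expect_equal(rep_$fixed_allele_id, c(4, 9))
  expect_true(attr(rep_, "global_fixed"))
})

test_that("run_until_fixation: monomorphic start fixes at generation 0", {
  fr <- run_until_fixation(sim_config(rows = 6, cols = 6, init_mu = 0, seed = 5),
                           mu = 0)
  expect_true(fr$global_fixed)
  expect_equal(fr$generations_to_fixation, 0)
  expect_equal(nrow(fr$trajectory), 1)
  expect_false(fr$cap_hit)
})

test_that("the generation cap is reported, not an error", {
  cfg <- sim_config(rows = 16, cols = 16, seed = 6, max_generations = 2)
  fr <- run_until_fixation(cfg, mu = 0, record = FALSE)
  expect_true(fr$cap_hit)
  expect_true(is.na(fr$generations_to_fixation))
})

test_that("replicate_fixation_times: single rep reproduces run_until_fixation", {
  cfg <- sim_config(rows = 6, cols = 6)
  one <- replicate_fixation_times(cfg, mu = 0, n_reps = 1, base_seed = 77)
  cfg$seed <- 77L
  ref <- run_until_fixation(cfg, mu = 0, record = FALSE)
  expect_equal(one$generations_to_fixation, ref$generations_to_fixation)
  expect_equal(one$fixed_allele_id, ref$report$fixed_allele_id)

  # monomorphic initialization: every replicate reports 0 generations
  cfg0 <- sim_config(rows = 5, cols = 5, init_mu = 0)
  reps <- replicate_fixation_times(cfg0, mu = 0, n_reps = 10, base_seed = 1)
  expect_true(all(reps$generations_to_fixation == 0))
})

test_that("smaller populations fix faster (Moran scaling)", {
  small <- replicate_fixation_times(sim_config(rows = 8, cols = 8), mu = 0,
                                    n_reps = 500, base_seed = 900)
  large <- replicate_fixation_times(sim_config(rows = 16, cols = 16), mu = 0,
                                    n_reps = 500, base_seed = 1900)
  expect_lt(median(small$generations_to_fixation),
            median(large$generations_to_fixation))
})
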