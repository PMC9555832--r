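test_that("experiment 1: unmodified drift ends with a single allele", {
  res <- activity1_defaults(seed = 101)
  final <- res$final_states$run
  expect_equal(n_alleles(final), 1)
  expect_true(all(res$fixation$fixed))

  counts <- res$trajectory |>
    dplyr::group_by(generation) |>
    dplyr::summarise(k = dplyr::n_distinct(allele_id), .groups = "drop") |>
    dplyr::arrange(generation)
  # generation-0 allele count equals the urn draw's K; loss is monotone
  st0 <- hoppe_urn_init(res$config)
  expect_equal(counts$k[1], n_alleles(st0))
  expect_true(all(diff(counts$k) <= 0))
  expect_equal(counts$k[nrow(counts)], 1)
})

test_that("experiment 2: quadrants fix in isolation, corridor merges two", {
  res <- activity2_absolute_barriers(seed = 102)
  ph1 <- res$fixation[res$fixation$phase == "phase1", ]
  expect_equal(nrow(ph1), 4)
  expect_true(all(ph1$fixed))
  expect_lte(dplyr::n_distinct(ph1$fixed_allele_id), 4)

  ph2 <- res$fixation[res$fixation$phase == "phase2", ]
  expect_equal(nrow(ph2), 3)  # corridor merged the two top quadrants
  expect_true(all(ph2$fixed))

  # merged component (id 1 after the corridor opens) fixed one of the two
  # top quadrants' phase-1 alleles; untouched quadrants kept theirs
  merged_allele <- ph2$fixed_allele_id[ph2$component_id == 1]
  expect_true(merged_allele %in% ph1$fixed_allele_id[ph1$component_id %in% c(1, 2)])
  expect_equal(
    sort(ph2$fixed_allele_id[ph2$component_id != 1]),
    sort(ph1$fixed_allele_id[ph1$component_id %in% c(3, 4)])
  )
  expect_equal(res$events$action, c("add_barrier", "remove_barrier"))
})

test_that("experiment 3: pre-opened corridor leaves three components", {
  res <- activity3_partial_barriers(seed = 103)
  run_traj <- res$trajectory[res$trajectory$phase == "run", ]
  g0 <- run_traj[run_traj$generation == 0 & run_traj$component_id > 0, ]
  expect_equal(dplyr::n_distinct(g0$component_id), 3)

  fx <- res$fixation
  expect_equal(sum(fx$connected), 1)
  # the merged component spans both top quadrants plus the corridor cells
  expect_equal(fx$n_cells[fx$connected], 225 + 240 + 3)
  expect_true(all(fx$fixed))

  # isolation: each isolated component fixed an allele it already carried at
  # generation 0 of the run phase
  for (k in fx$component_id[!fx$connected]) {
    init_alleles <- g0$allele_id[g0$component_id == k]
    expect_true(fx$fixed_allele_id[fx$component_id == k] %in% init_alleles)
  }
})

test_that("experiment 4: mutation rate sets the standing allele count", {
  res <- activity4_mutation_rates(seed = 104, mu_values = c(0, 1),
                                  n_generations = 15)
  counts <- res$trajectory |>
    dplyr::group_by(phase, generation) |>
    dplyr::summarise(k = dplyr::n_distinct(allele_id), .groups = "drop")
  k0 <- counts[counts$phase == "mu=0", ]
  expect_true(all(diff(k0$k[order(k0$generation)]) <= 0))
  k1 <- counts[counts$phase == "mu=1", ]
  # with every birth a novel allele, the count climbs towards population size
  expect_gt(max(k1$k), 900)
})

test_that("mean standing allele count is ordered in mu over replicates", {
  mus <- c(0, 0.001, 0.01)
  n_rep <- 100
  finals <- matrix(0, n_rep, length(mus))
  for (j in seq_along(mus)) {
    for (r in seq_len(n_rep)) {
      cfg <- sim_config(seed = 200000 + r)
      st <- hoppe_urn_init(cfg)
      st <- run_generations(st, 200, mu = mus[j], record = FALSE)$state
      finals[r, j] <- n_alleles(st)
    }
  }
  means <- colMeans(finals)
  expect_true(all(diff(means) > 0))
})

test_that("scenario results replay bit-identically from their event logs", {
  for (res in list(activity1_defaults(seed = 105),
                   activity2_absolute_barriers(seed = 106),
                   activity3_partial_barriers(seed = 107),
                   activity4_mutation_rates(seed = 108, n_generations = 30))) {
    rp <- replay_scenario(res)
    expect_identical(
      as.data.frame(res$trajectory), as.data.frame(rp$trajectory),
      info = res$scenario
    )
    for (lab in names(res$final_states)) {
      expect_identical(res$final_states[[lab]]$allele,
                       rp$final_states[[lab]]$allele, info = res$scenario)
    }
  }
})
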