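test_that("configuration invariants are enforced", {
  expect_error(sim_config("L", "M", 100,
                          sites = data.frame(column = c(5, 5), major = NA,
                                             minor = NA, minor_count = 1,
                                             sharing = "specific",
                                             plants = "1")),
               "distinct")
  expect_error(sim_config("L", "M", 100, n_clones = 10,
                          sites = data.frame(column = 5, major = NA,
                                             minor = NA, minor_count = 10,
                                             sharing = "specific",
                                             plants = "1")),
               "infeasible")
  expect_error(sim_config("L", "M", 100,
                          sites = data.frame(column = 5, major = NA,
                                             minor = NA, minor_count = 2,
                                             sharing = "specific",
                                             plants = "7")),
               "nonexistent")
  expect_error(sim_config("L", "M", 100,
                          sites = data.frame(column = 5, major = NA,
                                             minor = NA, minor_count = 2,
                                             sharing = "specific",
                                             plants = "1"),
                          indels = data.frame(start = 4, end = 6,
                                              plant = 1, carriers = 2)),
               "disjoint")
})

test_that("simulation is byte-deterministic in (config, seed)", {
  cfg <- random_material_config(3, with_indels = TRUE)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  sim1 <- simulate_material(cfg, seed = 11)
  sim2 <- simulate_material(cfg, seed = 11)
  write_clone_alignment(sim1$clone_sets, f1)
  write_clone_alignment(sim2$clone_sets, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes the output
  sim3 <- simulate_material(cfg, seed = 12)
  expect_false(identical(sim1$clone_sets, sim3$clone_sets))
  # and simulation does not disturb the caller's RNG stream
  set.seed(5); a <- runif(3)
  set.seed(5); invisible(simulate_material(cfg, seed = 11)); b <- runif(3)
  expect_identical(a, b)
})

test_that("plant substreams are independent of later plants", {
  cfg <- random_material_config(4)
  whole <- simulate_material(cfg, seed = 21)
  single <- simulate_clone_set(cfg, 2, seed = 21)
  expect_identical(single$clone_set, whole$clone_sets[[2]])
})

test_that("noise-free pipelines recover the planted truth end to end", {
  for (seed in 1:20) {
    cfg <- random_material_config(seed, with_indels = seed %% 3 == 0)
    sim <- simulate_material(cfg, seed = seed)
    ts <- truth_summary(sim$truth)
    expect_equal(ts$mode, "exact")
    sm <- cross_plant_summary(sim$clone_sets)
    expect_equal(sm$shared_by_3, unname(ts$categories["shared3"]))
    expect_equal(sm$shared_by_2, unname(ts$categories["shared2"]))
    expect_equal(sm$plant_specific, unname(ts$categories["specific"]))
    expect_equal(sm$total_polymorphic, unname(ts$categories["total"]))
    expect_equal(sm$common_callable, ts$common_callable)
    for (p in 1:3) {
      st <- call_all_sites(sim$clone_sets[[p]])
      expect_equal(segregating_sites(st), ts$per_plant$S[p])
      expect_equal(st$polymorphic_positions, sim$truth$planted_columns[[p]])
      nd <- nucleotide_diversity(sim$clone_sets[[p]])
      expect_equal(nd$pi, ts$per_plant$pi[p], tolerance = 1e-12)
      expect_equal(nd$L_used, ts$per_plant$L_used[p])
    }
  }
})

test_that("analytic pi from the truth matches its closed form", {
  cfg <- sim_config("L", "M", 1129,
                    sites = data.frame(column = 400, major = NA, minor = NA,
                                       minor_count = 3, sharing = "shared3",
                                       plants = NA))
  ts <- truth_summary(simulate_material(cfg, seed = 1)$truth)
  expect_equal(ts$per_plant$pi, rep((2 * 3 * 12 / (15 * 14)) / 1129, 3))

  cfg2 <- sim_config("L", "M", 646,
                     sites = data.frame(column = c(10, 20), major = NA,
                                        minor = NA, minor_count = 1,
                                        sharing = "shared3", plants = NA))
  ts2 <- truth_summary(simulate_material(cfg2, seed = 1)$truth)
  expect_equal(ts2$per_plant$pi[1], 2 * (2 * 1 * 14 / (15 * 14)) / 646)

  cfg3 <- sim_config("L", "M", 100)
  ts3 <- truth_summary(simulate_material(cfg3, seed = 1)$truth)
  expect_equal(ts3$per_plant$S, rep(0, 3))
  expect_equal(ts3$per_plant$pi, rep(0, 3))
})

test_that("error noise only adds polymorphic sites, in expectation", {
  cfg0 <- sim_config("L", "M", 400, n_plants = 1,
                     sites = plan_sites(400, 15, 2, 0, 0, n_plants = 1,
                                        seed = 9))
  cfg_e <- sim_config("L", "M", 400, n_plants = 1, sites = cfg0$sites,
                      error_rate = 0.002)
  S0 <- Se <- numeric(30)
  for (i in 1:30) {
    S0[i] <- segregating_sites(call_all_sites(
      simulate_clone_set(cfg0, 1, seed = 500 + i)$clone_set))
    Se[i] <- segregating_sites(call_all_sites(
      simulate_clone_set(cfg_e, 1, seed = 500 + i)$clone_set))
  }
  expect_true(all(S0 == 2))
  expect_true(all(Se >= 2))   # errors only add sites
  expect_gt(mean(Se), mean(S0))
})

test_that("realized errors are recorded faithfully in the truth", {
  cfg <- sim_config("L", "M", 500, n_plants = 1, n_clones = 10,
                    error_rate = 0.01)
  out <- simulate_clone_set(cfg, 1, seed = 33)
  err <- out$errors
  expect_gt(nrow(err), 0)
  m <- seq_matrix(out$clone_set)
  for (i in seq_len(nrow(err))) {
    expect_equal(unname(m[err$clone[i], err$column[i]]), err$to[i])
    expect_equal(out$reference[err$column[i]], err$from[i])
  }
})
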