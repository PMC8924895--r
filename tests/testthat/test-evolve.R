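# Evolutionary-programming optimizer: seeding, mutation, tournament,
# convergence, and the Lennard-Jones validation fixture.

test_that("water-substitution seeding produces one configuration per water", {
  w <- water_geometry()
  xyz <- do.call(rbind, lapply(0:3, function(k)
    sweep(w$xyz, 2, 3 * c(k %% 2, k %/% 2, 0.3 * k), "+")))
  wc <- cluster_config(rep(c("O", "H", "H"), 4), xyz)
  seeds <- seed_from_water_cluster(wc, "I")
  expect_length(seeds, 4)
  for (k in seq_along(seeds)) {
    expect_equal(n_atoms(seeds[[k]]), 10)     # 3*3 + 1
    expect_equal(seeds[[k]]$elements[seeds[[k]]$ion], "I")
    # ion sits exactly at the removed water's O position
    o_pos <- wc$xyz[identify_waters(wc)$o[k], ]
    expect_equal(seeds[[k]]$xyz[seeds[[k]]$ion, ], o_pos)
  }
  # re-adding the removed water reconstructs the original atom multiset
  ws <- identify_waters(wc)
  for (k in seq_along(seeds)) {
    rebuilt <- rbind(
      seeds[[k]]$xyz[-seeds[[k]]$ion, , drop = FALSE],
      wc$xyz[c(ws$o[k], ws$h1[k], ws$h2[k]), ])
    expect_equal(nrow(rebuilt), 12)
    o1 <- rebuilt[order(rebuilt[, 1], rebuilt[, 2], rebuilt[, 3]), ]
    o2 <- wc$xyz[order(wc$xyz[, 1], wc$xyz[, 2], wc$xyz[, 3]), ]
    expect_equal(o1, o2)
  }
  expect_error(seed_from_water_cluster(seeds[[1]], "I"), "already contains")
})

test_that("population initialization follows the (0, Delta) law", {
  genes <- c(0, 1, 2)
  set.seed(9)
  pop <- initialize_population(genes, ea_config(population_m = 50,
                                                delta_init = 0.5))
  expect_length(pop, 50)
  offs <- t(vapply(pop, function(i) i$chi - genes, numeric(3)))
  expect_true(all(offs >= 0 & offs <= 0.5))
  expect_true(all(vapply(pop, function(i) all(i$eta == 1), TRUE)))
  # Delta = 0: all individuals identical to the seed
  pop0 <- initialize_population(genes, ea_config(population_m = 10,
                                                 delta_init = 0))
  expect_true(all(vapply(pop0, function(i) identical(i$chi, genes), TRUE)))
  # same seed twice -> identical populations
  set.seed(9)
  pop2 <- initialize_population(genes, ea_config(population_m = 50,
                                                 delta_init = 0.5))
  expect_identical(pop, pop2)
})

test_that("mutation follows the self-adaptive law and its decay schedule", {
  cfg <- ea_config(delta0 = 0.15, deltaj = 0.85, eta_min = 1e-12)
  parent <- list(chi = rep(0, 4), eta = rep(2, 4), energy = NA_real_)
  # eta = 0 (degenerate override): child coordinates unchanged
  p0 <- list(chi = c(1, 2), eta = c(0, 0), energy = NA_real_)
  set.seed(1)
  expect_equal(mutate_individual(p0, 0, cfg)$chi, c(1, 2))
  # tau' = tau'' = 0: eta unchanged
  cfg0 <- ea_config(tau_prime = 0, tau_dprime = 0)
  set.seed(1)
  expect_equal(mutate_individual(parent, 0, cfg0)$eta, parent$eta)

  # Monte-Carlo: per-component step SD ~ eta * delta0 * deltaj^g within 3%
  set.seed(4)
  for (g in c(0, 3)) {
    steps <- replicate(30000,
                       mutate_individual(p0_ <- list(chi = 0, eta = 1.5,
                                                     energy = NA), g,
                                         cfg)$chi)
    expect_lt(abs(sd(steps) - 1.5 * 0.15 * 0.85^g) / (1.5 * 0.15 * 0.85^g),
              0.03)
  }
  # literal decay mode multiplies by (1 - deltaj) per generation
  cfg_lit <- ea_config(delta0 = 0.15, deltaj = 0.85, decay_mode = "literal")
  set.seed(4)
  s1 <- replicate(20000, mutate_individual(list(chi = 0, eta = 1,
                                                energy = NA), 1,
                                           cfg_lit)$chi)
  expect_lt(abs(sd(s1) - 0.15 * 0.15) / (0.15 * 0.15), 0.03)
})

test_that("tournament selection honors dominance and reduces to ranking", {
  cfg <- ea_config(population_m = 20, tournament_q = 10, seed = 1)
  set.seed(2)
  e <- rnorm(40)
  surv <- tournament_select(e, cfg)
  expect_length(surv, 20)
  expect_true(which.min(e) %in% surv)       # dominance of the best

  # q = 2M - 1 meets everyone: selection equals exact rank truncation
  cfg_full <- ea_config(population_m = 20, tournament_q = 39)
  set.seed(3)
  surv_full <- tournament_select(e, cfg_full)
  expect_setequal(surv_full, order(e)[1:20])

  # all-equal energies: documented tie-break gives exactly M survivors
  surv_tie <- tournament_select(rep(1, 40), cfg)
  expect_length(surv_tie, 20)

  expect_error(tournament_select(e[1:10], cfg), "pool size")
})

test_that("the EP loop is deterministic, elitist, and honors the threshold", {
  bowl <- function(cfg) sum(cfg$xyz^2) + 2
  seed1 <- cluster_config("O", matrix(c(2, -1, 1.5), 1))
  # non-decaying steps: the threshold rule itself halts the run
  cfg <- ea_config(population_m = 30, tournament_q = 5,
                   energy_threshold = 0.01, patience = 3,
                   delta0 = 1, deltaj = 1, eta_min = 1e-6,
                   max_generations = 300, seed = 4)
  r <- optimize_cluster(bowl, seed1, cfg, mode = "cartesian")
  expect_true(r$converged)
  expect_lt(r$generations_run, 300)         # stopped by the threshold rule
  expect_lt(r$best$energy - 2, 0.01)        # at the quadratic minimum
  expect_true(all(diff(r$best_energy_per_generation) <= 1e-12))
  # identical seeds give identical results
  r2 <- optimize_cluster(bowl, seed1, cfg, mode = "cartesian")
  expect_identical(r$best_energy_per_generation,
                   r2$best_energy_per_generation)
  expect_identical(r$best$chi, r2$best$chi)

  # non-finite potential values are evaluation errors
  expect_error(
    optimize_cluster(function(cfg) NaN, seed1,
                     ea_config(population_m = 5, tournament_q = 3,
                               max_generations = 2)),
    "non-finite")
})

test_that("Lennard-Jones energies follow the pair formula", {
  two <- cluster_config(c("O", "O"),
                        rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)))
  expect_equal(lennard_jones_energy(two, 1, 1), -1, tolerance = 1e-12)
  far <- cluster_config(c("O", "O"), rbind(c(0, 0, 0), c(500, 0, 0)))
  expect_lt(abs(lennard_jones_energy(far, 1, 1)), 1e-12)
  r0 <- 2^(1 / 6)
  tri <- cluster_config(rep("O", 3),
                        rbind(c(0, 0, 0), c(r0, 0, 0),
                              c(r0 / 2, r0 * sqrt(3) / 2, 0)))
  expect_equal(lennard_jones_energy(tri, 1, 1), -3, tolerance = 1e-12)
  expect_error(
    lennard_jones_energy(cluster_config(c("O", "O"),
                                        matrix(0, 2, 3))), "coincident")
  expect_error(lennard_jones_energy(cluster_config("O", matrix(0, 1, 3))),
               "at least 2")
})

test_that("the EA finds the LJ4 tetrahedron", {
  lj <- function(cfg) lennard_jones_energy(cfg, 1, 1)
  seeds <- lapply(1:3, function(k) sphere_seed(4, 600 + k, r0 = 1.1))
  r <- ep_global_search(lj, seeds,
                        ea_config(delta_init = 0.8, container_radius = 2,
                                  seed = 6),
                        explore_generations = 200, polish_top = 3,
                        restart_rounds = 0)
  expect_equal(r$best$energy, -6, tolerance = 1e-4)
  # all six pair distances at the pair minimum 2^(1/6)
  d <- as.vector(dist(r$best$config$xyz))
  expect_equal(d, rep(2^(1 / 6), 6), tolerance = 5e-3)
})

test_that("EA minimum on a dimer potential matches a dense grid search", {
  p <- truth_params()
  pot <- function(cfg) ion_water_energy(p, cfg)$total
  # dense grid oracle over the dimer coordinates
  grid <- build_spherical_grid(grid_spec(r_min = 2.4, r_max = 5,
                                         n_r = 27, n_theta = 19,
                                         n_phi = 7), "Cl")
  e_grid <- vapply(grid$configs, pot, 0.0)
  e_min_grid <- min(e_grid)

  seed_cfg <- dimer_config("Cl", 3.5, 90, 90)
  r <- optimize_cluster(pot, seed_cfg,
                        ea_config(population_m = 24, tournament_q = 6,
                                  delta_init = 0.4, delta0 = 1, deltaj = 1,
                                  eta_min = 0.02, patience = 1e6,
                                  max_generations = 80, seed = 3),
                        mode = "rigid")
  p2 <- optimize_cluster(pot, r$best$config,
                         ea_config(population_m = 24, tournament_q = 6,
                                   delta_init = 0, energy_threshold = 1e-7,
                                   patience = 25, max_generations = 150,
                                   eta_min = 1e-10, seed = 8),
                         mode = "rigid")
  expect_lt(p2$best$energy, e_min_grid + 0.05)
  # rigid mode keeps every monomer internally rigid
  ws <- identify_waters(p2$best$config)
  expect_equal(ws$r_oh1, 0.9572, tolerance = 1e-9)
  expect_equal(ws$angle_hoh, 104.52, tolerance = 1e-7)
})
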