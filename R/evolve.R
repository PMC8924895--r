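## Self-adaptive evolutionary-programming optimizer for locating
## minimum-energy cluster configurations on any supplied potential, with
## water-to-ion substitution seeding and a Lennard-Jones fixture potential.

#' Evolutionary-programming configuration
#'
#' Individuals are pairs (chi, eta) of a coordinate vector and a strategy
#' (step-size) vector.  Mutation follows
#' \code{chi'(j) = chi(j) + s_g * eta(j) * N_j(0,1)} and
#' \code{eta'(j) = eta(j) * exp(tau' N(0,1) + tau'' N_j(0,1))}, with the
#' generation-dependent global step scale \code{s_g = delta0 * deltaj^g}
#' (mode "factor"; mode "literal" reads "moves 85 percent less" literally as
#' \code{s_g = delta0 * (1 - deltaj)^g}).  Survivors are chosen by
#' q-opponent tournament over the joint parent-child pool.
#'
#' @param population_m population size M (default 100).
#' @param tournament_q tournament size (opponents per individual).
#' @param tau_prime,tau_dprime self-adaptation rates; \code{NULL} uses the
#'   standard choices \code{1/sqrt(2 n)} and \code{1/sqrt(2 sqrt(n))} for an
#'   n-dimensional coordinate vector.
#' @param delta_init displacement factor Delta: initial coordinates are the
#'   seed plus uniform(0, Delta) per-component offsets, Angstrom.
#' @param delta0 global mutation step factor (default 0.15).
#' @param deltaj per-generation step update factor (default 0.85).
#' @param decay_mode "factor" (step multiplied by deltaj each generation,
#'   the default reading) or "literal" (multiplied by 1 - deltaj).
#' @param energy_threshold convergence threshold on the best-energy change
#'   between consecutive generations, kcal/mol (default 0.01).
#' @param patience consecutive sub-threshold generations required before
#'   stopping (guards against premature stops; 1 reproduces the bare rule).
#' @param eta_min lower bound on strategy-parameter components, Angstrom.
#'   Self-adaptive EP is prone to premature step-size collapse (eta drifting
#'   to zero before the structure relaxes); a small floor keeps the search
#'   alive without affecting converged precision in the decayed-step modes.
#' @param container_radius spherical container radius, Angstrom: after
#'   mutation, any site farther than this from the cluster centroid is
#'   pulled radially back onto the sphere.  Prevents evaporation (an atom
#'   drifting beyond the attraction range and never returning), the usual
#'   failure mode of stochastic cluster searches; \code{Inf} disables it.
#' @param max_generations generation cap.
#' @param seed RNG seed.
#' @return an object of class \code{ea_config}.
#' @export
ea_config <- function(population_m = 100, tournament_q = 10,
                      tau_prime = NULL, tau_dprime = NULL,
                      delta_init = 1.0, delta0 = 0.15, deltaj = 0.85,
                      decay_mode = c("factor", "literal"),
                      energy_threshold = 0.01, patience = 3,
                      eta_min = 1e-3, container_radius = Inf,
                      max_generations = 200, seed = 1L) {
  decay_mode <- match.arg(decay_mode)
  if (population_m < 2) stop("population_m must be >= 2")
  if (tournament_q < 1 || tournament_q > 2 * population_m - 1)
    stop("tournament_q must be in [1, 2 M - 1]")
  if (deltaj <= 0 || deltaj > 1) stop("deltaj must be in (0, 1]")
  if (energy_threshold <= 0) stop("energy_threshold must be > 0")
  structure(list(population_m = as.integer(population_m),
                 tournament_q = as.integer(tournament_q),
                 tau_prime = tau_prime, tau_dprime = tau_dprime,
                 delta_init = delta_init, delta0 = delta0, deltaj = deltaj,
                 decay_mode = decay_mode,
                 energy_threshold = energy_threshold,
                 patience = as.integer(patience), eta_min = eta_min,
                 container_radius = container_radius,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed)),
            class = "ea_config")
}

#' Seed ion-water configurations by water substitution
#'
#' From a pure-water cluster, generates one starting configuration per
#' monomer by replacing that monomer's three atoms with the halide ion
#' placed at its oxygen position.
#'
#' @param water_cluster a \code{cluster_config} of waters (no ion).
#' @param ion halide symbol.
#' @return list of n \code{cluster_config} for an n-water input.
#' @export
seed_from_water_cluster <- function(water_cluster, ion) {
  if (!is.na(water_cluster$ion)) stop("cluster already contains an ion")
  ion <- match.arg(ion, c("F", "Cl", "Br", "I"))
  waters <- identify_waters(water_cluster)
  if (!nrow(waters)) stop("no water monomers found")
  lapply(seq_len(nrow(waters)), function(k) {
    drop <- c(waters$h1[k], waters$h2[k])
    el <- water_cluster$elements
    el[waters$o[k]] <- ion
    keep <- setdiff(seq_along(el), drop)
    cluster_config(el[keep], water_cluster$xyz[keep, , drop = FALSE],
                   label = sprintf("%s substituted at water %d",
                                   ion, k))
  })
}

## Gene encoding.  "cartesian": chi is the flattened coordinate vector
## (fully flexible).  "rigid": waters move as rigid bodies -- chi is the ion
## position (if present) followed, per water, by the monomer centroid and a
## rotation vector (Rodrigues axis-angle, radians) applied to the seed
## monomer geometry.
.rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.make_codec <- function(seed_config, mode) {
  # decode runs once per energy evaluation; skip constructor validation
  # (elements and ion tag are fixed by the seed)
  fast_config <- function(xyz)
    structure(list(elements = seed_config$elements, xyz = xyz,
                   ion = seed_config$ion, label = seed_config$label,
                   energy = NA_real_),
              class = "cluster_config")
  if (mode == "cartesian") {
    codec <- list(
      n = 3L * n_atoms(seed_config),
      encode = function(cfg) as.vector(t(cfg$xyz)),
      decode = function(chi) fast_config(matrix(chi, ncol = 3, byrow = TRUE)))
    codec$contain <- function(chi, r_c) {
      xyz <- matrix(chi, ncol = 3, byrow = TRUE)
      as.vector(t(.contain_points(xyz, r_c)))
    }
    codec$genes0 <- codec$encode(seed_config)
    codec
  } else {
    waters <- identify_waters(seed_config)
    n_w <- nrow(waters)
    has_ion <- !is.na(seed_config$ion)
    rel <- lapply(seq_len(n_w), function(k) {
      idx <- c(waters$o[k], waters$h1[k], waters$h2[k])
      ctr <- colMeans(seed_config$xyz[idx, , drop = FALSE])
      list(idx = idx, rel = sweep(seed_config$xyz[idx, , drop = FALSE],
                                  2, ctr))
    })
    n <- 3L * has_ion + 6L * n_w
    encode <- function(cfg) {
      chi <- numeric(0)
      if (has_ion) chi <- cfg$xyz[cfg$ion, ]
      for (k in seq_len(n_w))
        chi <- c(chi, colMeans(cfg$xyz[rel[[k]]$idx, , drop = FALSE]),
                 c(0, 0, 0))
      chi
    }
    decode <- function(chi) {
      xyz <- seed_config$xyz
      off <- 0L
      if (has_ion) { xyz[seed_config$ion, ] <- chi[1:3]; off <- 3L }
      for (k in seq_len(n_w)) {
        ctr <- chi[off + 1:3]; rot <- chi[off + 4:6]; off <- off + 6L
        xyz[rel[[k]]$idx, ] <- rel[[k]]$rel %*% t(.rodrigues(rot)) +
          matrix(ctr, 3, 3, byrow = TRUE)
      }
      fast_config(xyz)
    }
    codec <- list(n = n, encode = encode, decode = decode)
    codec$contain <- function(chi, r_c) {
      # ion position and monomer centroids are the contained sites;
      # rotation genes are untouched
    idx <- if (has_ion) c(1:3, 3 + as.vector(vapply(seq_len(n_w) - 1L,
        function(k) 6L * k + 1:3, integer(3))))
      else as.vector(vapply(seq_len(n_w) - 1L,
        function(k) 6L * k + 1:3, integer(3)))
      pts <- matrix(chi[idx], ncol = 3, byrow = TRUE)
      chi[idx] <- as.vector(t(.contain_points(pts, r_c)))
      chi
    }
    codec$genes0 <- encode(seed_config)
    codec
  }
}

.contain_points <- function(xyz, r_c) {
  ctr <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  out <- d > r_c
  if (any(out))
    xyz[out, ] <- ctr + sweep(xyz[out, , drop = FALSE], 2, ctr) * (r_c / d[out])
  xyz
}

#' Initialize an EP population
#'
#' M individuals, each with coordinates equal to the seed's plus independent
#' uniform(0, Delta) per-component offsets and all strategy parameters
#' eta = 1.  Draw order is fixed (per individual, all chi offsets), so runs
#' are reproducible under a seeded RNG.
#'
#' @param seed_genes numeric coordinate vector of the seed.
#' @param config an \code{\link{ea_config}}.
#' @return list of individuals, each a list \code{(chi, eta, energy = NA)}.
#' @export
initialize_population <- function(seed_genes, config) {
  lapply(seq_len(config$population_m), function(i) {
    list(chi = seed_genes +
           stats::runif(length(seed_genes), 0, config$delta_init),
         eta = rep(1, length(seed_genes)), energy = NA_real_)
  })
}

#' Mutate one individual
#'
#' Applies the self-adaptive EP mutation law with the generation-decayed
#' global step scale (see \code{\link{ea_config}}).  Draw order per call:
#' one shared N(0,1), then the per-component eta draws, then the
#' per-component chi draws.
#'
#' @param parent an individual \code{(chi, eta, energy)}.
#' @param generation generation index g (0 for the first mutation round).
#' @param config an \code{\link{ea_config}}.
#' @return the mutated child (energy unset).
#' @export
mutate_individual <- function(parent, generation, config) {
  n <- length(parent$chi)
  tau_p <- config$tau_prime %||% (1 / sqrt(2 * n))
  tau_pp <- config$tau_dprime %||% (1 / sqrt(2 * sqrt(n)))
  s_g <- config$delta0 *
    (if (config$decay_mode == "factor") config$deltaj
     else 1 - config$deltaj)^generation
  shared <- stats::rnorm(1)
  eta_draws <- stats::rnorm(n)
  chi_draws <- stats::rnorm(n)
  list(chi = parent$chi + parent$eta * s_g * chi_draws,
       eta = pmax(parent$eta * exp(tau_p * shared + tau_pp * eta_draws),
                  config$eta_min),
       energy = NA_real_)
}

#' Tournament selection
#'
#' Every individual of the joint 2M parent-child pool meets q randomly
#' chosen distinct opponents; the lower energy wins each encounter.  The M
#' individuals with the most wins survive, ties broken by lower energy
#' (which guarantees the pool's best individual always survives).
#'
#' @param energies energies of the 2M pool members, kcal/mol.
#' @param config an \code{\link{ea_config}}.
#' @return integer indices of the M survivors, ordered by decreasing wins
#'   then increasing energy.
#' @export
tournament_select <- function(energies, config) {
  n_pool <- length(energies)
  if (n_pool != 2 * config$population_m)
    stop("pool size must be 2 M = ", 2 * config$population_m)
  q <- config$tournament_q
  if (q > n_pool - 1) stop("tournament_q exceeds pool size - 1")
  wins <- integer(n_pool)
  for (i in seq_len(n_pool)) {
    opp <- sample(seq_len(n_pool)[-i], q)
    wins[i] <- sum(energies[i] < energies[opp])
  }
  order(-wins, energies)[seq_len(config$population_m)]
}

#' Optimize a cluster by evolutionary programming
#'
#' The full EP loop: mutate every parent, join parents and children,
#' tournament-select M survivors, repeat.  Convergence is declared when the
#' best energy changes by less than \code{energy_threshold} between
#' consecutive generations for \code{patience} generations in a row (or at
#' the generation cap).  Elitism through the joint pool makes the best
#' energy non-increasing.
#'
#' @param potential energy callback: \code{function(cluster_config)} in
#'   kcal/mol.  Non-finite values are errors.
#' @param seed_config starting \code{cluster_config}.
#' @param config an \code{\link{ea_config}}.
#' @param mode "cartesian" (every atom free) or "rigid" (water monomers move
#'   as rigid bodies; requires identifiable waters).
#' @param n_starts independent restarts (seeds \code{seed}, \code{seed+1},
#'   ...); the best run is returned with the energies of all starts in
#'   \code{start_energies}.
#' @return an object of class \code{ea_result}: list with \code{best}
#'   (\code{config}, \code{energy}, \code{chi}, \code{eta}),
#'   \code{best_energy_per_generation}, \code{generations_run},
#'   \code{converged} and \code{start_energies}.
#' @export
optimize_cluster <- function(potential, seed_config, config = ea_config(),
                             mode = c("cartesian", "rigid"), n_starts = 1) {
  mode <- match.arg(mode)
  codec <- .make_codec(seed_config, mode)
  runs <- lapply(seq_len(n_starts) - 1L, function(k) {
    .ea_run(potential, codec, config, config$seed + k)
  })
  best_k <- which.min(vapply(runs, function(r) r$best$energy, 0.0))
  res <- runs[[best_k]]
  res$start_energies <- vapply(runs, function(r) r$best$energy, 0.0)
  res
}

.ea_run <- function(potential, codec, config, seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  eval_chi <- function(chi) {
    e <- potential(codec$decode(chi))
    if (!is.finite(e))
      stop("evaluation error: potential returned a non-finite energy")
    e
  }
  pop <- initialize_population(codec$genes0, config)
  r_c <- config$container_radius
  if (is.finite(r_c) && !is.null(codec$contain))
    for (i in seq_along(pop)) pop[[i]]$chi <- codec$contain(pop[[i]]$chi, r_c)
  for (i in seq_along(pop)) pop[[i]]$energy <- eval_chi(pop[[i]]$chi)
  best_hist <- min(vapply(pop, `[[`, 0.0, "energy"))
  gen <- 0L; streak <- 0L; converged <- FALSE
  while (gen < config$max_generations) {
    gen <- gen + 1L
    children <- lapply(pop, mutate_individual, generation = gen - 1L,
                       config = config)
    if (is.finite(r_c) && !is.null(codec$contain))
      for (i in seq_along(children))
        children[[i]]$chi <- codec$contain(children[[i]]$chi, r_c)
    for (i in seq_along(children))
      children[[i]]$energy <- eval_chi(children[[i]]$chi)
    pool <- c(pop, children)
    energies <- vapply(pool, `[[`, 0.0, "energy")
    surv <- tournament_select(energies, config)
    # dominance safety: the pool's best individual always survives
    imin <- which.min(energies)
    if (!(imin %in% surv)) surv[length(surv)] <- imin
    pop <- pool[surv]
    best_g <- min(vapply(pop, `[[`, 0.0, "energy"))
    best_hist <- c(best_hist, best_g)
    if (abs(best_hist[gen + 1L] - best_hist[gen]) <
        config$energy_threshold) {
      streak <- streak + 1L
      if (streak >= config$patience) { converged <- TRUE; break }
    } else streak <- 0L
  }
  e_pop <- vapply(pop, `[[`, 0.0, "energy")
  bi <- pop[[which.min(e_pop)]]
  structure(
    list(best = list(config = codec$decode(bi$chi), energy = bi$energy,
                     chi = bi$chi, eta = bi$eta),
         best_energy_per_generation = best_hist[-1],
         generations_run = gen, converged = converged, seed = seed),
    class = "ea_result")
}

#' @export
print.ea_result <- function(x, ...) {
  cat(sprintf("ea_result: best energy %.6f kcal/mol after %d generation(s) (%s)\n",
              x$best$energy, x$generations_run,
              if (x$converged) "converged" else "generation cap reached"))
  invisible(x)
}

#' Two-phase evolutionary global search with restarts
#'
#' Composes the EP optimizer into an exploration + refinement protocol for
#' rough starting structures.  Phase 1 runs one EP search per supplied seed
#' configuration with a non-decaying step schedule and a step-size floor
#' (pure self-adaptive exploration).  Phase 2 takes the best few phase-1
#' results and applies slowly-decaying "annealing" cycles with a tight
#' convergence threshold, which polishes each candidate to the bottom of
#' its basin.  Optional restart rounds then re-run the explore + polish
#' pair with the incumbent best structure as the seed: the population
#' initialization's own (0, Delta) random offsets shake the compact
#' incumbent into neighbouring basins, which samples low-lying minima far
#' more effectively than fresh random geometries.  The incumbent is only
#' ever replaced by a better structure, so restarts are monotone.  All
#' phases are plain \code{\link{optimize_cluster}} runs; only the schedules
#' differ.
#'
#' @param potential energy callback, kcal/mol.
#' @param seed_configs list of starting \code{cluster_config}s (diverse
#'   seeds give the basin coverage of a multistart protocol).
#' @param config an \code{\link{ea_config}}; its \code{population_m},
#'   \code{tournament_q}, \code{seed} and \code{delta_init} are used for
#'   exploration, and \code{population_m}, \code{tournament_q} for
#'   refinement.
#' @param mode coordinate encoding, as in \code{\link{optimize_cluster}}.
#' @param explore_generations phase-1 generation budget per seed.
#' @param polish_top how many phase-1 candidates to refine.
#' @param polish_cycles annealing cycles per refined candidate.
#' @param final_cycles extra-fine annealing cycles applied to the single
#'   best polished candidate.
#' @param restart_rounds rounds of incumbent-seeded re-exploration.
#' @param restart_starts explorations per restart round.
#' @param restart_delta displacement factor Delta used when re-exploring
#'   from the incumbent, Angstrom.
#' @return the best \code{ea_result}, with \code{start_energies} (phase-1
#'   bests per seed), \code{polished_energies} and
#'   \code{round_energies} (incumbent energy after the initial round and
#'   each restart) attached.
#' @export
ep_global_search <- function(potential, seed_configs, config = ea_config(),
                             mode = c("cartesian", "rigid"),
                             explore_generations = 1000,
                             polish_top = 3, polish_cycles = 2,
                             final_cycles = 3,
                             restart_rounds = 2, restart_starts = 6,
                             restart_delta = 1.2) {
  mode <- match.arg(mode)

  explore_one <- function(seed_cfg, delta, rng_seed) {
    ecfg <- ea_config(
      population_m = config$population_m,
      tournament_q = config$tournament_q,
      delta_init = delta, delta0 = 1, deltaj = 1,
      energy_threshold = config$energy_threshold,
      patience = .Machine$integer.max, eta_min = 0.04,
      container_radius = config$container_radius,
      max_generations = explore_generations, seed = rng_seed)
    optimize_cluster(potential, seed_cfg, ecfg, mode)
  }
  polish_one <- function(res, rng_seed) {
    for (cyc in seq_len(polish_cycles)) {
      pcfg <- ea_config(
        population_m = config$population_m,
        tournament_q = config$tournament_q,
        delta_init = 0, delta0 = 0.05, deltaj = 0.97,
        energy_threshold = 1e-8, patience = 60, eta_min = 1e-12,
        container_radius = config$container_radius,
        max_generations = 500, seed = rng_seed + cyc)
      p <- optimize_cluster(potential, res$best$config, pcfg, mode)
      if (p$best$energy < res$best$energy) res <- p
    }
    res
  }
  run_round <- function(seeds, delta, base_seed) {
    explored <- lapply(seq_along(seeds), function(k)
      explore_one(seeds[[k]], delta, base_seed + k - 1L))
    se <- vapply(explored, function(r) r$best$energy, 0.0)
    top <- order(se)[seq_len(min(polish_top, length(explored)))]
    polished <- lapply(seq_along(top), function(j)
      polish_one(explored[[top[j]]], base_seed + 1000L * j))
    pe <- vapply(polished, function(r) r$best$energy, 0.0)
    list(best = polished[[which.min(pe)]], start_energies = se,
         polished_energies = pe)
  }

  r0 <- run_round(seed_configs, config$delta_init, config$seed)
  out <- r0$best
  round_energies <- out$best$energy
  for (round in seq_len(restart_rounds)) {
    seeds_r <- rep(list(out$best$config), restart_starts)
    rr <- run_round(seeds_r, restart_delta,
                    config$seed + 7777L * round)
    if (rr$best$best$energy < out$best$energy) out <- rr$best
    round_energies <- c(round_energies, out$best$energy)
  }
  # extra-fine annealing of the single best candidate
  for (cyc in seq_len(final_cycles)) {
    fcfg <- ea_config(
      population_m = config$population_m,
      tournament_q = config$tournament_q,
      delta_init = 0, delta0 = 0.01, deltaj = 0.985,
      energy_threshold = 1e-10, patience = 80, eta_min = 1e-12,
      container_radius = config$container_radius,
      max_generations = 700,
      seed = config$seed + 99991L + cyc)
    f <- optimize_cluster(potential, out$best$config, fcfg, mode)
    if (f$best$energy < out$best$energy) {
      f$generations_run <- out$generations_run + f$generations_run
      out <- f
    }
  }
  out$start_energies <- r0$start_energies
  out$polished_energies <- r0$polished_energies
  out$round_energies <- round_energies
  out
}

#' Lennard-Jones cluster energy
#'
#' \code{sum over pairs of 4 epsilon ((sigma/r)^12 - (sigma/r)^6)}; the
#' validation fixture potential for the optimizer.
#'
#' @param config a \code{cluster_config} (all atoms treated as identical
#'   particles).
#' @param epsilon,sigma well depth (kcal/mol) and size parameter (Angstrom).
#' @return energy, kcal/mol.
#' @export
lennard_jones_energy <- function(config, epsilon = 1, sigma = 1) {
  n <- n_atoms(config)
  if (n < 2) stop("need at least 2 particles")
  r2 <- stats::dist(config$xyz)^2
  if (any(r2 < 1e-18)) stop("degenerate geometry: coincident particles")
  sr6 <- sigma^6 / r2^3
  sum(4 * epsilon * (sr6 * sr6 - sr6))
}
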