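# Energy terms: Born-Mayer, Tang-Toennies, smeared electrostatics, induced
# dipoles, and the assembled ion-water / total / interaction energies.

test_that("Tang-Toennies damping matches the tail-series oracle", {
  # order 6 at delta*R = 1 against an independently coded complement series
  expect_equal(tang_toennies(6, 1, 1), tt_tail_oracle(6, 1),
               tolerance = 1e-10)
  for (x in c(0.3, 2, 5, 12))
    expect_equal(tang_toennies(6, 1, x), tt_tail_oracle(6, x),
                 tolerance = 1e-10)
  expect_identical(tang_toennies(6, 2.5, 0), 0)
  expect_equal(tang_toennies(6, 3, 1e3), 1)

  # in [0,1], increasing in R, higher order => smaller f at fixed deltaR
  R <- seq(0, 8, by = 0.05)
  f6 <- tang_toennies(6, 2, R)
  expect_true(all(f6 >= 0 & f6 <= 1))
  expect_true(all(diff(f6) >= 0))
  f8 <- tang_toennies(8, 2, R[-1])
  expect_true(all(f8 < tang_toennies(6, 2, R[-1])))

  expect_error(tang_toennies(-1, 1, 1), "order")
  expect_error(tang_toennies(6, 0, 1), "delta")
})

test_that("Born-Mayer and dispersion terms follow their closed forms", {
  w <- water_geometry()
  # ion straight above O: the single ion-O pair dominates geometry bookkeeping
  cfg <- dimer_config("Cl", 2.0, 0, 0)
  p <- ion_water_params("Cl", A_O = 1000, beta_O = 3, C6_O = 0,
                        A_H = 0, beta_H = 1, C6_H = 0, q_H = 0,
                        alpha_O = 0, alpha_H = 0, alpha_ion = 0)
  expect_equal(born_mayer_energy(p, cfg), 1000 * exp(-6), tolerance = 1e-12)
  cfg4 <- dimer_config("Cl", 4.0, 0, 0)
  expect_equal(born_mayer_energy(p, cfg4) / born_mayer_energy(p, cfg),
               exp(-6), tolerance = 1e-12)
  p0 <- bare_params()
  expect_identical(born_mayer_energy(p0, cfg), 0)
  expect_identical(dispersion_energy(p0, cfg), 0)

  # dispersion tends to -C6/R^6 (checked as a limit ratio at growing R)
  pd <- ion_water_params("Cl", A_O = 0, beta_O = 1, C6_O = 100,
                         A_H = 0, beta_H = 1, C6_H = 0, q_H = 0,
                         alpha_O = 0, alpha_H = 0, alpha_ion = 0,
                         delta_O = 3, tie_delta = FALSE)
  for (R in c(5, 10, 20)) {
    ratio <- dispersion_energy(pd, dimer_config("Cl", R, 0, 0)) /
      (-100 / R^6)
    expect_equal(ratio, tang_toennies(6, 3, R), tolerance = 1e-12)
  }
  expect_gt(dispersion_energy(pd, dimer_config("Cl", 20, 0, 0)) /
              (-100 / 20^6), 1 - 1e-6)
  expect_equal(dispersion_energy(pd, dimer_config("Cl", 10, 0, 0)),
               -100 / 10^6, tolerance = 1e-6)
})

test_that("permanent electrostatics recovers point Coulomb limits", {
  # two point charges: ion (-1) and a "water" with all charge on H is
  # awkward; instead use q_H with the second H and M-site far away --
  # simplest direct check: ion + single water with charges, smearing off
  p <- bare_params(q_H = 0.5)
  cfg <- dimer_config("Cl", 10, 0, 0)
  el <- permanent_electrostatics(p, cfg)
  # oracle: explicit site loop with point Coulomb
  s <- el$sites
  qi <- which(s$kind == "ion")
  e_hand <- sum(sapply(which(s$mono == 1), function(j) {
    R <- sqrt(sum((s$pos[qi, ] - s$pos[j, ])^2))
    KCAL_COULOMB * s$charge[qi] * s$charge[j] / R
  }))
  expect_equal(el$energy, e_hand, tolerance = 1e-12)

  # all charges zero (uncharged waters, no ion) -> zero energy and fields
  w <- water_geometry()
  two_w <- cluster_config(c(w$elements, w$elements),
                          rbind(w$xyz, sweep(w$xyz, 2, c(3, 0, 0), "+")))
  el0 <- permanent_electrostatics(bare_params(alpha_O = 1), two_w)
  expect_identical(el0$energy, 0)
  expect_true(all(el0$fields == 0))

  # field from a -1e point charge at 3 Angstrom: magnitude 1/9 e/A^2,
  # directed toward the charge (for a positive test site)
  pf <- bare_params(alpha_O = 1)
  ef <- permanent_electrostatics(pf, dimer_config("Cl", 3, 0, 0))
  io <- which(ef$sites$kind[ef$pol_index] == "O")
  expect_equal(sqrt(sum(ef$fields[io, ]^2)), 1 / 9, tolerance = 1e-12)
  # O sits at origin, ion on +z at 3: field on O points toward the anion
  expect_equal(ef$fields[io, ], c(0, 0, 1 / 9), tolerance = 1e-12)

  # smeared energies converge to the point limit as widths shrink
  for (wdt in c(0.2, 0.05, 0.01)) {
    ps <- ion_water_params("Cl", A_O = 0, beta_O = 1, C6_O = 0, A_H = 0,
                           beta_H = 1, C6_H = 0, q_H = 0.5,
                           width_H = wdt, width_M = wdt, width_O = wdt,
                           width_ion = wdt, alpha_O = 0, alpha_H = 0,
                           alpha_ion = 0)
    es <- permanent_electrostatics(ps, cfg)$energy
    if (wdt <= 0.05)
      expect_equal(es, e_hand, tolerance = 1e-6)
  }
})

test_that("induced dipoles match closed forms and the linear-solve oracle", {
  # single site alpha = 1 at 3 A from a -1e charge, no damping
  p <- bare_params(alpha_O = 1)
  cfg <- dimer_config("Cl", 3, 0, 0)
  st <- solve_induced_dipoles(p, cfg)
  expect_true(st$converged)
  expect_equal(induction_energy(st), -0.5 * KCAL_COULOMB / 81,
               tolerance = 1e-10)
  # mu = alpha E for the single site
  expect_equal(as.vector(st$dipoles), as.vector(st$fields),
               tolerance = 1e-10)
  # doubling alpha doubles U_ind
  p2 <- bare_params(alpha_O = 2)
  expect_equal(induction_energy(solve_induced_dipoles(p2, cfg)),
               2 * (-0.5 * KCAL_COULOMB / 81), tolerance = 1e-8)

  # zero permanent field (uncharged water, no ion) -> zero dipoles
  w <- water_geometry()
  two_w <- cluster_config(c(w$elements, w$elements),
                          rbind(w$xyz, sweep(w$xyz, 2, c(3, 0, 0), "+")))
  st0 <- solve_induced_dipoles(bare_params(alpha_O = 1), two_w)
  expect_true(all(abs(st0$dipoles) < 1e-14))
  expect_identical(induction_energy(st0), 0)

  # two coupled polarizable sites (O and ion, well separated) vs an
  # independent 6x6 linear-solve oracle
  pc <- bare_params(alpha_O = 1.1, alpha_ion = 2.0)
  cfgc <- dimer_config("Cl", 3.0, 35, 20)
  stc <- solve_induced_dipoles(pc, cfgc, method = "direct")
  s <- stc$pol_index
  sites <- permanent_electrostatics(pc, cfgc)$sites
  orc <- point_dipole_oracle(sites$pos[s, , drop = FALSE],
                             sites$alpha[s],
                             sites$pos[sites$kind == "ion", , drop = FALSE],
                             -1)
  expect_lt(max(abs(stc$dipoles - orc$dipoles)), 1e-10)
  expect_equal(induction_energy(stc), orc$u_ind, tolerance = 1e-10)
})

test_that("iterative and direct dipole solvers agree on random systems", {
  set.seed(202)
  worst <- 0
  for (rep in 1:100) {
    n_w <- sample(1:3, 1)
    # random well-separated waters + ion
    centers <- matrix(stats::runif(3 * n_w, -4, 4), n_w, 3)
    while (n_w > 1 && min(dist(centers)) < 2.6)
      centers <- matrix(stats::runif(3 * n_w, -4, 4), n_w, 3)
    w <- water_geometry()
    xyz <- do.call(rbind, lapply(seq_len(n_w), function(k) {
      Q <- random_rotation(1000 + rep * 10 + k)
      sweep(w$xyz %*% t(Q), 2, centers[k, ], "+")
    }))
    ion_pos <- stats::runif(3, 5, 7) * sample(c(-1, 1), 3, replace = TRUE)
    cfg <- cluster_config(c(rep(c("O", "H", "H"), n_w), "Cl"),
                          rbind(xyz, ion_pos))
    p <- truth_params()
    it <- solve_induced_dipoles(p, cfg, method = "iterative")
    dr <- solve_induced_dipoles(p, cfg, method = "direct")
    worst <- max(worst, max(abs(it$dipoles - dr$dipoles)))
    expect_lte(induction_energy(dr), 0)
  }
  expect_lt(worst, 1e-8)
})

test_that("polarization catastrophe and non-convergence are errors", {
  # two undamped polarizable sites brought too close: alpha/R^3 > 1/2
  p <- bare_params(alpha_O = 10, alpha_ion = 10)
  cfg <- dimer_config("Cl", 1.8, 0, 0)
  expect_error(solve_induced_dipoles(p, cfg, method = "direct"),
               "polarization catastrophe")
  # induction_energy refuses an unconverged state
  st <- solve_induced_dipoles(bare_params(alpha_O = 1),
                              dimer_config("Cl", 3, 0, 0))
  st$converged <- FALSE
  expect_error(induction_energy(st), "unconverged")
})

test_that("ion-water energy assembles its terms and is SE(3) invariant", {
  p <- truth_params()
  cfg <- dimer_config("Cl", 3.2, 120, 0)
  br <- ion_water_energy(p, cfg)
  expect_equal(br$total, br$rep + br$disp + br$elec + br$ind,
               tolerance = 1e-10)
  expect_equal(br$rep, born_mayer_energy(p, cfg), tolerance = 1e-12)
  expect_equal(br$disp, dispersion_energy(p, cfg), tolerance = 1e-12)

  # rigid rotation + translation and monomer relabeling leave it unchanged
  w <- water_geometry()
  two <- cluster_config(
    c(w$elements, w$elements, "Cl"),
    rbind(w$xyz, sweep(w$xyz, 2, c(3.1, 0.4, -0.2), "+"), c(-1, -2.8, 0.5)))
  e_ref <- ion_water_energy(p, two)$total
  Q <- random_rotation(77)
  rt <- cluster_config(two$elements,
                       sweep(two$xyz %*% t(Q), 2, c(10, -4, 6), "+"))
  expect_equal(ion_water_energy(p, rt)$total, e_ref, tolerance = 1e-9)
  perm <- cluster_config(two$elements[c(4:6, 1:3, 7)],
                         two$xyz[c(4:6, 1:3, 7), ])
  expect_equal(ion_water_energy(p, perm)$total, e_ref, tolerance = 1e-9)

  # distant ion: interaction small and entirely elec + ind
  far <- dimer_config("Cl", 100, 70, 30)
  brf <- ion_water_energy(p, far)
  expect_lt(abs(brf$total), 0.01)
  expect_lt(abs(brf$rep) + abs(brf$disp), 1e-8)
  expect_lt(abs(brf$total - (brf$elec + brf$ind)), 1e-8)
})

test_that("total and interaction energies obey their reductions", {
  p <- truth_params()
  wm <- simple_water_model()
  w <- water_geometry()

  # no ion: total reduces to the water model energy (+ water-only induction)
  two_w <- cluster_config(c(w$elements, w$elements),
                          rbind(w$xyz, sweep(w$xyz, 2, c(3, 0, 0), "+")))
  waters <- identify_waters(two_w)
  e_model <- wm$intra(two_w, waters) + wm$inter_noind(p, two_w, waters)
  e_tot <- total_energy(p, two_w, wm)
  st <- solve_induced_dipoles(p, two_w)
  expect_equal(e_tot, e_model + induction_energy(st), tolerance = 1e-9)

  # one water + ion: total = ion_water total + monomer energy (rigid: ~0)
  dim1 <- dimer_config("Cl", 3.1, 110, 40)
  expect_equal(total_energy(p, dim1, wm),
               ion_water_energy(p, dim1)$total, tolerance = 1e-9)
  expect_equal(interaction_energy(p, dim1, wm),
               ion_water_energy(p, dim1)$total, tolerance = 1e-9)

  # three-body nonadditivity: zero iff all polarizabilities vanish
  cfg3 <- cluster_config(
    c(w$elements, w$elements, "Cl"),
    rbind(w$xyz, sweep(w$xyz, 2, c(3.2, 0, 0), "+"), c(1.6, 2.9, 0)))
  nonadd <- function(params) {
    waters <- identify_waters(cfg3)
    sub <- function(keep) cluster_config(cfg3$elements[keep],
                                         cfg3$xyz[keep, , drop = FALSE])
    e_full <- total_energy(params, cfg3, wm)
    dims <- list(c(1:3, 7), c(4:6, 7), 1:6)
    e_2b <- sum(vapply(dims, function(k) total_energy(params, sub(k), wm),
                       0.0))
    # monomer energies are zero here (rigid reference waters, lone ion)
    e_full - e_2b
  }
  expect_gt(abs(nonadd(p)), 1e-3)
  p_noalpha <- ion_water_params("Cl", A_O = 8e4, beta_O = 3.4, C6_O = 1400,
                                A_H = 4e3, beta_H = 2.8, C6_H = 350,
                                alpha_O = 0, alpha_H = 0, alpha_ion = 0)
  expect_lt(abs(nonadd(p_noalpha)), 1e-10)

  # separability: charge-dipole tails decay away with distance
  expect_lt(abs(interaction_energy(p, dimer_config("Cl", 500, 90, 0), wm)),
            1e-4)
  expect_lt(abs(interaction_energy(p, dimer_config("Cl", 5000, 90, 0), wm)),
            1e-6)

  # term isolation: only A > 0 -> interaction equals Born-Mayer exactly
  p_rep <- bare_params()
  p_rep$pair$O$A <- 5e4; p_rep$pair$H$A <- 2e3
  cfg <- dimer_config("Cl", 3.0, 60, 90)
  expect_equal(interaction_energy(p_rep, cfg, wm),
               born_mayer_energy(p_rep, cfg), tolerance = 1e-12)

  # charge-only dimer: interaction equals the hand-summed Coulomb terms
  p_q <- bare_params(q_H = 0.4)
  elq <- permanent_electrostatics(p_q, cfg)
  expect_equal(interaction_energy(p_q, cfg, wm), elq$energy,
               tolerance = 1e-12)
})

test_that("parameter objects validate and serialize losslessly", {
  p <- truth_params()
  expect_equal(p$pair$O$delta, p$pair$O$beta)   # delta = beta rule
  expect_error(ion_water_params("Na", 1, 1, 1, 1, 1, 1))
  expect_error(ion_water_params("Cl", -1, 1, 1, 1, 1, 1), "pair term")
  expect_error(ion_water_params("Cl", 1, 0, 1, 1, 1, 1), "pair term")

  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q$pair, p$pair)
  expect_equal(q$alpha, p$alpha)
  expect_equal(q$widths, p$widths)
  expect_equal(q$q_H, p$q_H)
})
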