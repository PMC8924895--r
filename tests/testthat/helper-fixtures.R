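# Shared fixtures and independent oracles, all built in code.

KCAL_COULOMB <- 332.0637157

# ground-truth parameter set used by synthetic-data fixtures: magnitudes of
# realistic chloride-water short-range terms
truth_params <- function(...) {
  ion_water_params("Cl", A_O = 8e4, beta_O = 3.4, C6_O = 1400,
                   A_H = 4e3, beta_H = 2.8, C6_H = 350, ...)
}

start_params <- function(...) {
  ion_water_params("Cl", A_O = 3e4, beta_O = 3.0, C6_O = 800,
                   A_H = 2e3, beta_H = 2.4, C6_H = 200, ...)
}

# bare-charge parameters: everything off except what the caller turns on
bare_params <- function(ion = "Cl", q_H = 0, alpha_O = 0, alpha_H = 0,
                        alpha_ion = 0, ...) {
  ion_water_params(ion, A_O = 0, beta_O = 1, C6_O = 0,
                   A_H = 0, beta_H = 1, C6_H = 0,
                   q_H = q_H, width_H = 0, width_M = 0, width_O = 0,
                   width_ion = 0, alpha_O = alpha_O, alpha_H = alpha_H,
                   alpha_ion = alpha_ion, thole_dd = 0, ...)
}

# n-atom cluster with atoms uniform in a sphere of radius r0 (single-element
# particles for optimizer fixtures)
sphere_seed <- function(n, seed, r0 = 1.3, element = "O") {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  i <- 0
  while (i < n) {
    p <- stats::runif(3, -r0, r0)
    if (sum(p^2) <= r0^2) { i <- i + 1; pts[i, ] <- p }
  }
  cluster_config(rep(element, n), pts)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# --- independent oracles ----------------------------------------------------

# Tang-Toennies via the complementary (tail) series: f = e^-x sum_{k>n} x^k/k!
tt_tail_oracle <- function(order, x) {
  term <- exp(-x) * x^(order + 1) / factorial(order + 1)
  s <- 0
  k <- order + 1
  while (abs(term) > 1e-300 && k < 10000) {
    s <- s + term
    k <- k + 1
    term <- term * x / k
  }
  s
}

# direct 3p x 3p linear solve of coupled point dipoles (no damping),
# independently coded from the textbook tensor
point_dipole_oracle <- function(pos, alpha, charges_pos, charges_q) {
  p <- nrow(pos)
  E <- matrix(0, p, 3)
  for (i in seq_len(p)) for (j in seq_along(charges_q)) {
    r <- pos[i, ] - charges_pos[j, ]
    R <- sqrt(sum(r^2))
    if (R < 1e-9) next   # a site does not feel its own charge
    E[i, ] <- E[i, ] + charges_q[j] * r / R^3
  }
  A <- diag(rep(1 / alpha, each = 3))
  if (p > 1) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      r <- pos[i, ] - pos[j, ]
      R <- sqrt(sum(r^2))
      Tb <- (3 * tcrossprod(r / R) - diag(3)) / R^3
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      A[ri, rj] <- -Tb
      A[rj, ri] <- -Tb
    }
  }
  mu <- solve(A, as.vector(t(E)))
  list(dipoles = matrix(mu, p, 3, byrow = TRUE), fields = E,
       u_ind = -0.5 * KCAL_COULOMB * sum(mu * as.vector(t(E))))
}

# multistart Nelder-Mead local-optimization oracle for LJ clusters
lj_multistart_oracle <- function(n, n_starts = 60, seed = 99,
                                 epsilon = 1, sigma = 1) {
  f <- function(x) {
    xyz <- matrix(x, ncol = 3)
    r2 <- as.vector(stats::dist(xyz))^2
    if (any(r2 < 1e-12)) return(1e10)
    sr6 <- sigma^6 / r2^3
    sum(4 * epsilon * (sr6^2 - sr6))
  }
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    par <- stats::rnorm(3 * n, sd = 0.9)
    val <- Inf
    # chained simplex restarts: Nelder-Mead needs a fresh simplex to
    # converge fully in this many dimensions
    for (rs in 1:8) {
      o <- stats::optim(par, f, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
      done <- val - o$value < 1e-10
      val <- min(val, o$value)
      par <- o$par
      if (done) break
    }
    if (val < best) best <- val
  }
  best
}
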