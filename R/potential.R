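## Ion-water interaction energy: Born-Mayer repulsion, Tang-Toennies damped
## dispersion, smeared-charge permanent electrostatics and self-consistent
## many-body induced-dipole polarization.
##
## Unit conventions: coordinates Angstrom, charges e, polarizabilities
## Angstrom^3, energies kcal/mol.  Fields and dipole-dipole tensors are kept
## in e/Angstrom^2 and 1/Angstrom^3 (no Coulomb constant); the constant
## k = 332.0637157 kcal Angstrom/(mol e^2) multiplies energies only, so
## mu = alpha * E gives induced dipoles directly in e Angstrom.

#' Tang-Toennies damping function
#'
#' \code{f_n(R, delta) = 1 - exp(-delta R) * sum_{k=0..n} (delta R)^k / k!},
#' the incomplete-gamma switch that turns dispersion off at short range.
#' Monotonically increasing in R, bounded in [0, 1]; order 6 matches the
#' \code{R^-6} dispersion term.
#'
#' @param order series order n (non-negative integer).
#' @param delta damping steepness, 1/Angstrom (> 0).
#' @param R separation(s), Angstrom (>= 0); vectorized.
#' @return damping factor(s) in [0, 1].
#' @examples
#' tang_toennies(6, 3.0, 2.0)
#' @export
tang_toennies <- function(order, delta, R) {
  if (length(order) != 1 || order < 0 || order != round(order))
    stop("order must be a single non-negative integer")
  if (delta <= 0) stop("delta must be > 0")
  if (any(R < 0)) stop("R must be >= 0")
  x <- delta * R
  out <- numeric(length(x))
  # strongly damped region: evaluate the complementary (tail) series
  # f = e^-x sum_{k>n} x^k/k! directly, avoiding the cancellation of
  # 1 - (sum close to 1); elsewhere the forward complement is exact enough
  small <- x <= order + 1
  if (any(small)) {
    xs <- x[small]
    term <- exp(-xs) * xs^(order + 1) / factorial(order + 1)
    s <- term
    k <- order + 1
    while (any(abs(term) > 1e-18 * (s + 1e-300)) && k < order + 400) {
      k <- k + 1
      term <- term * xs / k
      s <- s + term
    }
    out[small] <- s
  }
  if (any(!small)) {
    xl <- x[!small]
    s <- exp(-xl)
    term <- s
    for (k in seq_len(order)) {
      term <- term * xl / k
      s <- s + term
    }
    out[!small] <- 1 - s
  }
  pmin(pmax(out, 0), 1)
}

.pair_distances <- function(config, waters = NULL) {
  if (is.na(config$ion)) stop("configuration has no ion")
  if (is.null(waters)) waters <- identify_waters(config)
  xi <- config$xyz[config$ion, ]
  d <- function(i) sqrt(sum((config$xyz[i, ] - xi)^2))
  list(R_O = vapply(waters$o, d, 0.0),
       R_H = vapply(c(waters$h1, waters$h2), d, 0.0))
}

#' Born-Mayer repulsion energy
#'
#' Sum of \code{A * exp(-beta * R)} over ion-O and ion-H pairs.
#'
#' @param params an \code{ion_water_params}.
#' @param config a \code{cluster_config} with an ion.
#' @param waters optional precomputed \code{\link{identify_waters}} table.
#' @return energy, kcal/mol.
#' @export
born_mayer_energy <- function(params, config, waters = NULL) {
  rr <- .pair_distances(config, waters)
  if (any(c(rr$R_O, rr$R_H) < 1e-9))
    stop("degenerate geometry: ion coincides with a water atom")
  sum(params$pair$O$A * exp(-params$pair$O$beta * rr$R_O)) +
    sum(params$pair$H$A * exp(-params$pair$H$beta * rr$R_H))
}

#' Damped dispersion energy
#'
#' \code{-sum C6 * f6(R, delta) / R^6} over ion-O and ion-H pairs
#' (attractive, hence negative); tends to \code{-C6/R^6} per pair at large
#' separation.
#'
#' @inheritParams born_mayer_energy
#' @return energy, kcal/mol (<= 0).
#' @export
dispersion_energy <- function(params, config, waters = NULL) {
  rr <- .pair_distances(config, waters)
  if (any(c(rr$R_O, rr$R_H) < 1e-9))
    stop("degenerate geometry: ion coincides with a water atom")
  pO <- params$pair$O; pH <- params$pair$H
  -sum(pO$C6 * tang_toennies(6, pO$delta, rr$R_O) / rr$R_O^6) -
    sum(pH$C6 * tang_toennies(6, pH$delta, rr$R_H) / rr$R_H^6)
}

## --- Thole smearing --------------------------------------------------------
## Charge smearing uses a Slater-type density exp(-r/a): the screened pair
## potential is phi = q/r * [1 - (1 + y/2) exp(-y)] and the screened field
## E = q/r^2 * [1 - (1 + y + y^2/2) exp(-y)], y = r/a_ij, both in [0, 1] x
## the point forms.  Dipole-dipole coupling uses the exponential-3 Thole
## screens lambda3 = 1 - exp(-x), lambda5 = 1 - (1 + x) exp(-x) with
## x = (r/A_ij)^3 and the canonical polarizability-derived damping length
## A_ij = (alpha_i alpha_j)^(1/6) / a^(1/3) (a = thole_dd; intramonomer
## pairs get A_ij scaled up by thole_intra_scale: increased damping).
## Charge-pair widths combine in quadrature,
## a_ij = sqrt((a_i^2 + a_j^2)/2); zero widths give point behaviour.

.pair_width <- function(a_i, a_j) {
  w <- sqrt((a_i^2 + a_j^2) / 2)
  ifelse(is.finite(w), w, 0)
}

.screen_qq <- function(R, a) {
  out <- rep(1, length(R))
  sm <- a > 1e-12
  if (any(sm)) {
    y <- R[sm] / a[sm]
    out[sm] <- 1 - (1 + y / 2) * exp(-y)
  }
  out
}

.screen_qfield <- function(R, a) {
  out <- rep(1, length(R))
  sm <- a > 1e-12
  if (any(sm)) {
    y <- R[sm] / a[sm]
    out[sm] <- 1 - (1 + y + y^2 / 2) * exp(-y)
  }
  out
}

.screen_dd <- function(R, a) {
  if (a <= 1e-12) return(c(l3 = 1, l5 = 1))
  x <- (R / a)^3
  c(l3 = 1 - exp(-x), l5 = 1 - (1 + x) * exp(-x))
}

## Permanent charge-charge energy over a site table; include selects pair
## classes by monomer id (0 = ion): "all" inter-monomer pairs, only
## ion-water pairs, or only water-water pairs.  No intramonomer terms.
.site_elec_energy <- function(sites,
                              include = c("all", "ion_water", "water_water")) {
  include <- match.arg(include)
  q <- sites$charge
  ch <- which(abs(q) > 0)
  e <- 0
  if (length(ch) >= 2) {
    for (ii in seq_len(length(ch) - 1)) for (jj in (ii + 1):length(ch)) {
      i <- ch[ii]; j <- ch[jj]
      if (sites$mono[i] == sites$mono[j]) next
      ion_pair <- sites$mono[i] == 0 || sites$mono[j] == 0
      if (include == "ion_water" && !ion_pair) next
      if (include == "water_water" && ion_pair) next
      rij <- sites$pos[j, ] - sites$pos[i, ]
      R <- sqrt(sum(rij^2))
      if (R < 1e-9) stop("degenerate geometry: coincident interacting sites")
      a <- .pair_width(sites$width[i], sites$width[j])
      e <- e + sites$k * q[i] * q[j] * .screen_qq(R, a) / R
    }
  }
  e
}

## Field (e/Angstrom^2) at each polarizable site from all permanent charges
## outside the site's own monomer.
.site_perm_fields <- function(sites) {
  pol <- which(sites$alpha > 0)
  ch <- which(abs(sites$charge) > 0)
  E <- matrix(0, length(pol), 3)
  for (pi in seq_along(pol)) {
    i <- pol[pi]
    for (j in ch) {
      if (sites$mono[i] == sites$mono[j]) next
      rij <- sites$pos[i, ] - sites$pos[j, ]   # from charge toward site
      R <- sqrt(sum(rij^2))
      if (R < 1e-9) stop("degenerate geometry: coincident interacting sites")
      a <- .pair_width(sites$width[i], sites$width[j])
      E[pi, ] <- E[pi, ] +
        sites$charge[j] * .screen_qfield(R, a) * rij / R^3
    }
  }
  list(pol_index = pol, fields = E)
}

## 3p x 3p Thole-damped dipole-dipole interaction matrix T such that the
## field at site i from dipole mu_j is T[i,j] %*% mu_j.  Intramonomer pairs
## use an enlarged width (increased intramolecular damping).
.dipole_tensor <- function(sites, pol) {
  p <- length(pol)
  TT <- matrix(0, 3 * p, 3 * p)
  if (p < 2) return(TT)
  for (ii in seq_len(p - 1)) for (jj in (ii + 1):p) {
    i <- pol[ii]; j <- pol[jj]
    rij <- sites$pos[i, ] - sites$pos[j, ]
    R <- sqrt(sum(rij^2))
    if (R < 1e-9) stop("degenerate geometry: coincident polarizable sites")
    a <- if (sites$thole_dd > 0)
      (sites$alpha[i] * sites$alpha[j])^(1 / 6) / sites$thole_dd^(1 / 3)
    else 0
    if (sites$mono[i] == sites$mono[j] && sites$mono[i] != 0)
      a <- a * sites$thole_intra_scale
    lam <- .screen_dd(R, a)
    rhat <- rij / R
    blk <- (3 * lam["l5"] * tcrossprod(rhat) - lam["l3"] * diag(3)) / R^3
    ri <- (3 * ii - 2):(3 * ii); rj <- (3 * jj - 2):(3 * jj)
    TT[ri, rj] <- blk
    TT[rj, ri] <- blk
  }
  TT
}

#' Permanent electrostatics: energy and fields
#'
#' Smeared-charge Coulomb energy between sites on different monomers (the
#' ion counts as its own monomer; no intramonomer terms), together with the
#' electrostatic field each polarizable site feels from all permanent
#' charges outside its own monomer.  Widths of zero give point-charge
#' behaviour.
#'
#' @inheritParams born_mayer_energy
#' @param config a \code{cluster_config} (ion optional).
#' @param include which charge-charge pairs enter the energy: all
#'   inter-monomer pairs, only ion-water pairs, or only water-water pairs.
#'   Fields are always computed from all external permanent charges.
#' @return list with \code{energy} (kcal/mol), \code{fields} (matrix, one
#'   row per polarizable site, e/Angstrom^2), \code{pol_index} (site-table
#'   rows the fields belong to) and \code{sites} (the site table).
#' @export
permanent_electrostatics <- function(params, config, waters = NULL,
                                     include = c("all", "ion_water",
                                                 "water_water")) {
  include <- match.arg(include)
  sites <- .build_sites(params, config, waters)
  f <- .site_perm_fields(sites)
  list(energy = .site_elec_energy(sites, include),
       fields = f$fields, pol_index = f$pol_index, sites = sites)
}

.elec_energy <- function(params, config, waters, include) {
  sites <- .build_sites(params, config, waters)
  list(energy = .site_elec_energy(sites, include), sites = sites)
}

#' Solve the self-consistent induced dipoles
#'
#' Finds the dipoles satisfying
#' \code{mu_i = alpha_i (E_perm,i + sum_j T_ij mu_j)} with Thole-damped
#' dipole-dipole tensors.  The default path is fixed-point iteration with a
#' direct linear solve as fallback (and as the "direct" method); the two
#' agree to the solver tolerance.  A non-positive-definite interaction
#' matrix (polarization catastrophe) is an error.
#'
#' @inheritParams permanent_electrostatics
#' @param fields optional precomputed permanent fields (from
#'   \code{\link{permanent_electrostatics}}); recomputed when \code{NULL}.
#' @param method "auto" (fixed point, direct fallback), "iterative" or
#'   "direct".
#' @param tol convergence tolerance on the max dipole-component change,
#'   e Angstrom.
#' @param max_iter fixed-point iteration cap.
#' @param mixing fixed-point damping factor in (0, 1].
#' @return an object of class \code{induced_dipoles}: list with
#'   \code{dipoles} (matrix, e Angstrom, one row per polarizable site),
#'   \code{fields}, \code{pol_index}, \code{residual}, \code{iterations},
#'   \code{converged} and \code{k} (Coulomb constant).
#' @export
solve_induced_dipoles <- function(params, config, waters = NULL,
                                  fields = NULL,
                                  method = c("auto", "iterative", "direct"),
                                  tol = 1e-10, max_iter = 200,
                                  mixing = 0.65) {
  method <- match.arg(method)
  sites <- .build_sites(params, config, waters)
  .solve_dipoles_sites(sites, fields, method, tol, max_iter, mixing)
}

.solve_dipoles_sites <- function(sites, fields = NULL,
                                 method = "auto", tol = 1e-10,
                                 max_iter = 200, mixing = 0.65) {
  if (is.null(fields)) {
    f <- .site_perm_fields(sites)
  } else {
    f <- fields
  }
  pol <- f$pol_index
  p <- length(pol)
  if (!p) stop("no polarizable site in the system")
  alpha <- sites$alpha[pol]
  Evec <- as.vector(t(f$fields))
  TT <- .dipole_tensor(sites, pol)
  ainv <- rep(1 / alpha, each = 3)
  D <- diag(ainv, 3 * p) - TT
  ch <- tryCatch(chol((D + t(D)) / 2), error = function(e) NULL)
  if (is.null(ch))
    stop("polarization catastrophe: dipole interaction matrix is not ",
         "positive definite")
  solve_direct <- function() backsolve(ch, forwardsolve(t(ch), Evec))
  mu <- NULL; iters <- 0L; resid <- 0; converged <- FALSE
  if (method %in% c("auto", "iterative")) {
    mu <- rep(alpha, each = 3) * Evec   # first-order start
    for (it in seq_len(max_iter)) {
      mu_new <- rep(alpha, each = 3) * (Evec + as.vector(TT %*% mu))
      mu_new <- mixing * mu_new + (1 - mixing) * mu
      resid <- max(abs(mu_new - mu))
      mu <- mu_new
      iters <- it
      if (resid <= tol) { converged <- TRUE; break }
    }
    if (!converged && method == "iterative")
      stop("induced-dipole iteration did not converge: residual ", resid,
           " e*Angstrom after ", max_iter, " iterations")
  }
  if (method == "direct" || (method == "auto" && !converged)) {
    mu <- solve_direct()
    resid <- max(abs(rep(alpha, each = 3) *
                       (Evec + as.vector(TT %*% mu)) - mu))
    converged <- TRUE
    if (method == "direct") iters <- 0L
  }
  structure(
    list(dipoles = matrix(mu, p, 3, byrow = TRUE),
         fields = f$fields, pol_index = pol,
         residual = resid, iterations = iters, converged = converged,
         k = sites$k),
    class = "induced_dipoles")
}

#' Many-body induction energy
#'
#' \code{U_ind = -1/2 k sum_i mu_i . E_perm,i}; non-positive for any
#' converged dipole state.
#'
#' @param state an \code{induced_dipoles} object from
#'   \code{\link{solve_induced_dipoles}}.
#' @return energy, kcal/mol (<= 0).
#' @export
induction_energy <- function(state) {
  if (!inherits(state, "induced_dipoles"))
    stop("state must come from solve_induced_dipoles()")
  if (!isTRUE(state$converged))
    stop("unconverged induced-dipole state (residual ", state$residual, ")")
  -0.5 * state$k * sum(state$dipoles * state$fields)
}

.induction_of <- function(sites, ...) {
  if (!any(sites$alpha > 0)) return(0)
  induction_energy(.solve_dipoles_sites(sites, ...))
}

.drop_ion_sites <- function(sites) {
  keep <- sites$mono != 0
  list(pos = sites$pos[keep, , drop = FALSE], charge = sites$charge[keep],
       width = sites$width[keep], alpha = sites$alpha[keep],
       mono = sites$mono[keep], kind = sites$kind[keep], k = sites$k,
       thole_dd = sites$thole_dd,
       thole_intra_scale = sites$thole_intra_scale)
}

#' Ion-water interaction energy breakdown
#'
#' Evaluates the ion-water intermolecular interaction as the sum of
#' Born-Mayer repulsion, Tang-Toennies damped dispersion, permanent
#' ion-water electrostatics, and the ion's many-body induction contribution
#' (full-cluster induction minus the induction of the water subsystem at the
#' same geometry, so that for an ion-water dimer it is simply the dimer's
#' induction energy).
#'
#' @inheritParams born_mayer_energy
#' @return an object of class \code{energy_breakdown}: list with
#'   \code{rep}, \code{disp}, \code{elec}, \code{ind} and \code{total}
#'   (kcal/mol), \code{total = rep + disp + elec + ind}.
#' @export
ion_water_energy <- function(params, config, waters = NULL) {
  if (is.na(config$ion)) stop("configuration has no ion")
  if (is.null(waters)) waters <- identify_waters(config)
  rep_e <- born_mayer_energy(params, config, waters)
  disp_e <- dispersion_energy(params, config, waters)
  sites <- .build_sites(params, config, waters)
  elec_e <- .site_elec_energy(sites, "ion_water")
  ind_e <- .induction_of(sites) - .induction_of(.drop_ion_sites(sites))
  structure(
    list(rep = rep_e, disp = disp_e, elec = elec_e, ind = ind_e,
         total = rep_e + disp_e + elec_e + ind_e),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("ion-water energy (kcal/mol): rep %+.6f  disp %+.6f  elec %+.6f  ind %+.6f\n  total %+.6f\n",
              x$rep, x$disp, x$elec, x$ind, x$total))
  invisible(x)
}

#' Total cluster energy
#'
#' Many-body total energy over a pluggable water model: water intramolecular
#' distortion, water-water non-induction intermolecular energy (both from
#' the water model), the ion-water short-range and permanent-electrostatic
#' terms, and the induction solved over the full site set (ion plus all
#' waters), so polarization is genuinely many-body rather than a sum of
#' dimer inductions.
#'
#' @inheritParams born_mayer_energy
#' @param config a \code{cluster_config}; the ion is optional (without it
#'   the result is the water model's energy plus water-only induction).
#' @param water_model a \code{water_model} object
#'   (default \code{\link{simple_water_model}()}).
#' @return energy, kcal/mol.
#' @export
total_energy <- function(params, config, water_model = simple_water_model(),
                         waters = NULL) {
  if (!inherits(water_model, "water_model"))
    stop("water_model must be a water_model object")
  if (is.null(waters)) waters <- identify_waters(config)
  sites <- .build_sites(params, config, waters)
  e <- water_model$intra(config, waters) +
    water_model$inter_noind(params, config, waters)
  has_pol <- any(sites$alpha > 0)
  if (!is.na(config$ion)) {
    e <- e + born_mayer_energy(params, config, waters) +
      dispersion_energy(params, config, waters) +
      .site_elec_energy(sites, "ion_water")
  }
  if (has_pol) e <- e + .induction_of(sites)
  e
}

#' Cluster interaction energy
#'
#' The supermolecular interaction energy
#' \code{dE = E(cluster) - E(waters at the same geometry) - E(ion)}; the
#' isolated-ion energy is zero in this classical model.
#'
#' @inheritParams total_energy
#' @return energy, kcal/mol.
#' @export
interaction_energy <- function(params, config,
                               water_model = simple_water_model(),
                               waters = NULL) {
  if (is.na(config$ion)) stop("configuration has no ion")
  if (is.null(waters)) waters <- identify_waters(config)
  keep <- setdiff(seq_along(config$elements), config$ion)
  cfg_w <- cluster_config(config$elements[keep],
                          config$xyz[keep, , drop = FALSE],
                          label = config$label)
  waters_w <- identify_waters(cfg_w)
  total_energy(params, config, water_model, waters) -
    total_energy(params, cfg_w, water_model, waters_w)
}
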