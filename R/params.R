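## Ion-water model parameters, interaction-site construction and the
## pluggable water-model interface.

# Reference halide dipole polarizabilities (Angstrom^3), CCSD(T)-quality
# literature values; overridable per parameter set.
.halide_alpha <- c(F = 2.467, Cl = 5.482, Br = 7.268, I = 10.275)

#' Ion-water interaction parameters
#'
#' The fit target of the framework: per-pair (ion-O, ion-H) Born-Mayer
#' repulsion amplitudes \code{A} and steepnesses \code{beta}, dispersion
#' coefficients \code{C6} with Tang-Toennies damping steepnesses
#' \code{delta}, plus the electrostatic-site template (charges, Thole
#' smearing widths, polarizabilities, M-site placement).
#'
#' When the \code{delta = beta} tie is active (the default, see
#' \code{tie_delta}), each pair's damping steepness is kept exactly equal to
#' its Born-Mayer steepness.
#'
#' @param ion halide symbol: "F", "Cl", "Br" or "I".
#' @param A_O,beta_O,C6_O,A_H,beta_H,C6_H Born-Mayer amplitudes (kcal/mol),
#'   steepnesses (1/Angstrom, stored positive, used as \code{exp(-beta*R)})
#'   and dispersion coefficients (kcal Angstrom^6/mol) for the ion-O and
#'   ion-H pairs.
#' @param delta_O,delta_H Tang-Toennies damping steepnesses (1/Angstrom);
#'   default equal to the corresponding \code{beta}.
#' @param tie_delta logical; if \code{TRUE} (default) \code{delta} is defined
#'   to equal \code{beta} and follows it through fits.
#' @param q_H hydrogen partial charge (e); the M-site carries \code{-2*q_H}.
#' @param m_site_fraction M-site position as a fraction of the O-to-(H
#'   midpoint) segment along the HOH bisector, in (0, 1].  The default 0.25
#'   places it about 0.147 Angstrom from O for the rigid reference monomer.
#' @param width_H,width_M,width_O,width_ion Thole charge-smearing widths
#'   (Angstrom); 0 disables smearing for that site kind.
#' @param alpha_O,alpha_H,alpha_ion isotropic dipole polarizabilities
#'   (Angstrom^3); \code{alpha_ion} defaults to a reference CCSD(T)-quality
#'   value for the chosen halide.
#' @param thole_dd dimensionless Thole dipole-dipole damping parameter a:
#'   the damping length for a polarizable pair is
#'   \code{(alpha_i alpha_j)^(1/6) / a^(1/3)} (smaller a = stronger
#'   damping).
#' @param thole_intra_scale multiplier (> 1) applied to the dipole-dipole
#'   damping length for intramonomer pairs (increased intramolecular
#'   damping).
#' @param coulomb_constant Coulomb constant, kcal Angstrom/(mol e^2).
#' @param model water-model tag carried in serialized files
#'   ("custom", "i-TTM2", "i-TTM3", "i-TTM4" or "i-MBpol").
#' @return an object of class \code{ion_water_params}.
#' @examples
#' p <- ion_water_params("Cl", A_O = 8e4, beta_O = 3.4, C6_O = 1400,
#'                       A_H = 4e3, beta_H = 2.8, C6_H = 350)
#' p$pair$O$delta == p$pair$O$beta   # delta = beta rule
#' @export
ion_water_params <- function(ion,
                             A_O, beta_O, C6_O,
                             A_H, beta_H, C6_H,
                             delta_O = beta_O, delta_H = beta_H,
                             tie_delta = TRUE,
                             q_H = 0.574, m_site_fraction = 0.25,
                             width_H = 0.3, width_M = 0.3,
                             width_O = 0.3, width_ion = 0.6,
                             alpha_O = 1.310, alpha_H = 0.294,
                             alpha_ion = NULL,
                             thole_dd = 0.572,
                             thole_intra_scale = 2.0,
                             coulomb_constant = 332.0637157,
                             model = "custom") {
  ion <- match.arg(ion, c("F", "Cl", "Br", "I"))
  if (is.null(alpha_ion)) alpha_ion <- unname(.halide_alpha[ion])
  pair <- list(
    O = list(A = A_O, beta = beta_O, C6 = C6_O, delta = delta_O),
    H = list(A = A_H, beta = beta_H, C6 = C6_H, delta = delta_H))
  for (s in names(pair)) {
    p <- pair[[s]]
    if (p$A < 0 || p$C6 < 0 || p$beta <= 0 || p$delta <= 0)
      stop("invalid ion-", s, " pair term: need A >= 0, C6 >= 0, beta > 0, ",
           "delta > 0")
    if (tie_delta) pair[[s]]$delta <- p$beta
  }
  if (m_site_fraction <= 0 || m_site_fraction > 1)
    stop("m_site_fraction must be in (0, 1]")
  if (any(c(width_H, width_M, width_O, width_ion) < 0))
    stop("smearing widths must be >= 0")
  if (any(c(alpha_O, alpha_H, alpha_ion) < 0))
    stop("polarizabilities must be >= 0")
  structure(
    list(ion = ion, model = model, pair = pair, tie_delta = tie_delta,
         q_H = q_H, q_ion = -1.0, m_site_fraction = m_site_fraction,
         widths = c(H = width_H, M = width_M, O = width_O, ion = width_ion),
         alpha = c(O = alpha_O, H = alpha_H, ion = alpha_ion),
         thole_dd = thole_dd,
         thole_intra_scale = thole_intra_scale,
         coulomb_constant = coulomb_constant),
    class = "ion_water_params")
}

#' @export
print.ion_water_params <- function(x, ...) {
  cat("ion_water_params for ", x$ion, "- (model: ", x$model, ")\n", sep = "")
  for (s in c("O", "H")) {
    p <- x$pair[[s]]
    cat(sprintf("  ion-%s: A = %.6g kcal/mol, beta = %.6g 1/A, C6 = %.6g kcal A^6/mol, delta = %.6g 1/A\n",
                s, p$A, p$beta, p$C6, p$delta))
  }
  cat(sprintf("  q_H = %.4g e, alpha(O,H,ion) = %.4g, %.4g, %.4g A^3\n",
              x$q_H, x$alpha["O"], x$alpha["H"], x$alpha["ion"]))
  invisible(x)
}

#' Write / read ion-water parameters as JSON
#'
#' Serialization is versioned with a \code{model} field naming the intended
#' water model ("i-TTM2", "i-TTM3", "i-TTM4", "i-MBpol" or "custom"), so
#' appendix-style parameter files supplied by the user can be loaded.
#'
#' @param params an \code{ion_water_params}.
#' @param path JSON file path.
#' @return \code{write_params}: invisibly, \code{path};
#'   \code{read_params}: an \code{ion_water_params}.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$widths <- as.list(x$widths)   # keep names through JSON
  x$alpha <- as.list(x$alpha)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("ion", "pair", "q_H", "m_site_fraction", "widths", "alpha")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file missing field(s): ", paste(miss, collapse = ", "))
  ion_water_params(
    ion = x$ion,
    A_O = x$pair$O$A, beta_O = x$pair$O$beta, C6_O = x$pair$O$C6,
    A_H = x$pair$H$A, beta_H = x$pair$H$beta, C6_H = x$pair$H$C6,
    delta_O = x$pair$O$delta, delta_H = x$pair$H$delta,
    tie_delta = isTRUE(x$tie_delta),
    q_H = x$q_H, m_site_fraction = x$m_site_fraction,
    width_H = x$widths[["H"]], width_M = x$widths[["M"]],
    width_O = x$widths[["O"]], width_ion = x$widths[["ion"]],
    alpha_O = x$alpha[["O"]], alpha_H = x$alpha[["H"]],
    alpha_ion = x$alpha[["ion"]],
    thole_dd = x$thole_dd %||% 0.572,
    thole_intra_scale = x$thole_intra_scale %||% 2.0,
    coulomb_constant = x$coulomb_constant %||% 332.0637157,
    model = x$model %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rigid reference water monomer geometry
#'
#' @param r_oh O-H bond length, Angstrom (default 0.9572).
#' @param angle_hoh H-O-H angle, degrees (default 104.52).
#' @return a 3-atom \code{cluster_config} (O, H, H) in the water-fixed
#'   frame: O at the origin, H atoms in the xz-plane, HOH bisector along -z.
#' @export
water_geometry <- function(r_oh = 0.9572, angle_hoh = 104.52) {
  half <- angle_hoh * pi / 360
  cluster_config(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(r_oh * sin(half), 0, -r_oh * cos(half)),
          c(-r_oh * sin(half), 0, -r_oh * cos(half))),
    label = "rigid reference water")
}

## Interaction-site table: one row per electrostatic/polarizable site.
## monomer 0 = ion; kinds: H (charge + alpha), O (alpha only),
## M (charge only), ion (charge + alpha).  Charges in e, widths/positions in
## Angstrom, alpha in Angstrom^3.
.build_sites <- function(params, config, waters = NULL) {
  if (is.null(waters)) waters <- identify_waters(config)
  n_w <- nrow(waters)
  pos <- matrix(0, 0, 3); charge <- numeric(0); width <- numeric(0)
  alpha <- numeric(0); mono <- integer(0); kind <- character(0)
  if (n_w > 0) {
    for (w in seq_len(n_w)) {
      o <- config$xyz[waters$o[w], ]
      h1 <- config$xyz[waters$h1[w], ]
      h2 <- config$xyz[waters$h2[w], ]
      msite <- o + params$m_site_fraction * ((h1 + h2) / 2 - o)
      pos <- rbind(pos, h1, h2, o, msite)
      charge <- c(charge, params$q_H, params$q_H, 0, -2 * params$q_H)
      width <- c(width, params$widths[c("H", "H", "O", "M")])
      alpha <- c(alpha, params$alpha[c("H", "H", "O")], 0)
      mono <- c(mono, rep(w, 4))
      kind <- c(kind, "H", "H", "O", "M")
    }
  }
  if (!is.na(config$ion)) {
    pos <- rbind(pos, config$xyz[config$ion, ])
    charge <- c(charge, params$q_ion)
    width <- c(width, params$widths[["ion"]])
    alpha <- c(alpha, params$alpha[["ion"]])
    mono <- c(mono, 0L)
    kind <- c(kind, "ion")
  }
  rownames(pos) <- NULL
  list(pos = pos, charge = unname(charge), width = unname(width),
       alpha = unname(alpha), mono = mono, kind = kind,
       k = params$coulomb_constant,
       thole_dd = params$thole_dd,
       thole_intra_scale = params$thole_intra_scale)
}

#' Simple reference water model
#'
#' A deliberately simple water model fulfilling the pluggable water-model
#' contract: fixed point charges (\code{q_H} on H, \code{-2 q_H} on the
#' M-site) shared with the ion-water parameter set, a harmonic intramolecular
#' distortion term, and an O-O Lennard-Jones intermolecular term on top of
#' the smeared water-water electrostatics.  Induction over the water sites is
#' handled by the framework, not by the model.
#'
#' @param lj_epsilon,lj_sigma O-O Lennard-Jones parameters (kcal/mol,
#'   Angstrom).
#' @param k_bond harmonic O-H stretch constant, kcal/mol/Angstrom^2.
#' @param k_angle harmonic HOH bend constant, kcal/mol/rad^2.
#' @param r_oh_ref,angle_ref reference monomer geometry (Angstrom, degrees).
#' @return an object of class \code{water_model}: list with \code{name},
#'   \code{intra(config, waters)} and
#'   \code{inter_noind(params, config, waters)} callbacks.  Site charges and
#'   polarizabilities come from the \code{ion_water_params} template, so the
#'   ion-water and water-water electrostatics are mutually consistent.
#' @export
simple_water_model <- function(lj_epsilon = 0.155, lj_sigma = 3.154,
                               k_bond = 1059.162, k_angle = 75.90,
                               r_oh_ref = 0.9572, angle_ref = 104.52) {
  intra <- function(config, waters) {
    if (!nrow(waters)) return(0)
    sum(0.5 * k_bond * (waters$r_oh1 - r_oh_ref)^2 +
        0.5 * k_bond * (waters$r_oh2 - r_oh_ref)^2 +
        0.5 * k_angle * ((waters$angle_hoh - angle_ref) * pi / 180)^2)
  }
  inter_noind <- function(params, config, waters) {
    n_w <- nrow(waters)
    if (n_w < 2) return(0)
    # water-water smeared charge-charge
    e <- .elec_energy(params, config, waters, include = "water_water")$energy
    # O-O Lennard-Jones
    for (i in seq_len(n_w - 1)) for (j in (i + 1):n_w) {
      r <- sqrt(sum((config$xyz[waters$o[i], ] -
                       config$xyz[waters$o[j], ])^2))
      sr6 <- (lj_sigma / r)^6
      e <- e + 4 * lj_epsilon * (sr6^2 - sr6)
    }
    e
  }
  structure(list(name = "simple-water", intra = intra,
                 inter_noind = inter_noind,
                 lj_epsilon = lj_epsilon, lj_sigma = lj_sigma),
            class = "water_model")
}
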