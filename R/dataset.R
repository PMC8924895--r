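## Training-set construction: spherical dimer grids, energy-based weights,
## synthetic reference data and TSV round-trip I/O.

#' Spherical grid specification
#'
#' Equidistant grid in the ion-water dimer coordinates: R (anion-oxygen
#' distance), theta (polar angle from +z) and phi (azimuthal angle from +x)
#' in the water-fixed frame of \code{\link{water_geometry}} (O at the
#' origin, C2v axis along z, H atoms in the xz-plane, bisector toward -z).
#' Exploiting the monomer's mirror symmetry, theta and phi are restricted to
#' [0, 180] degrees.
#'
#' @param r_min,r_max radial range, Angstrom.
#' @param n_r,n_theta,n_phi point counts per coordinate; the default
#'   10 x 10 x 5 gives a 500-point grid.
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(r_min = 2.0, r_max = 8.0,
                      n_r = 10, n_theta = 10, n_phi = 5) {
  if (r_min <= 0 || r_max < r_min) stop("need 0 < r_min <= r_max")
  if (any(c(n_r, n_theta, n_phi) < 1)) stop("counts must be >= 1")
  structure(list(r_min = r_min, r_max = r_max, n_r = as.integer(n_r),
                 n_theta = as.integer(n_theta), n_phi = as.integer(n_phi)),
            class = "grid_spec")
}

.seq_grid <- function(lo, hi, n) if (n == 1) lo else seq(lo, hi, length.out = n)

#' Build an ion-water dimer configuration from spherical coordinates
#'
#' @param ion halide symbol.
#' @param R,theta,phi ion position in the water-fixed frame: radial distance
#'   (Angstrom) and polar/azimuthal angles (degrees).
#' @param water a rigid water monomer in the frame of
#'   \code{\link{water_geometry}}.
#' @return a 4-atom \code{cluster_config} (O, H, H, ion).
#' @export
dimer_config <- function(ion, R, theta, phi, water = water_geometry()) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  ion_pos <- R * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  cluster_config(c(water$elements, ion), rbind(water$xyz, ion_pos),
                 label = sprintf("R=%.6g theta=%.6g phi=%.6g", R, theta, phi))
}

#' Recover the (R, theta, phi) coordinates of a dimer configuration
#'
#' Inverse of \code{\link{dimer_config}}: re-derives the water-fixed frame
#' from the monomer geometry (O origin, z opposite the HOH bisector, H atoms
#' in the xz-plane) and expresses the ion position in it.  Mirror-equivalent
#' positions (y < 0) are folded back into phi in [0, 180].
#'
#' @param config a one-water-plus-ion \code{cluster_config}.
#' @return named numeric vector \code{c(R, theta, phi)} (Angstrom, degrees).
#' @export
dimer_coords <- function(config) {
  if (is.na(config$ion)) stop("configuration has no ion")
  w <- identify_waters(config)
  if (nrow(w) != 1) stop("configuration must contain exactly one water")
  o <- config$xyz[w$o, ]; h1 <- config$xyz[w$h1, ]; h2 <- config$xyz[w$h2, ]
  bis <- (h1 + h2) / 2 - o
  ez <- -bis / sqrt(sum(bis^2))
  vx <- (h1 - o) - sum((h1 - o) * ez) * ez
  ex <- vx / sqrt(sum(vx^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  v <- config$xyz[config$ion, ] - o
  xyz <- c(sum(v * ex), sum(v * ey), sum(v * ez))
  R <- sqrt(sum(xyz^2))
  theta <- acos(max(-1, min(1, xyz[3] / R))) * 180 / pi
  phi <- atan2(abs(xyz[2]), xyz[1]) * 180 / pi
  if (R * sin(theta * pi / 180) < 1e-10) phi <- 0
  c(R = R, theta = theta, phi = phi)
}

#' Build a spherical training grid
#'
#' Generates the dimer training configurations on an equidistant
#' (R, theta, phi) grid; the 10 x 10 x 5 default yields 500 points.  R and
#' phi include their range endpoints; theta takes interior equidistant
#' values, since the polar axis itself is phi-degenerate.  Reference
#' energies and weights are left unset.
#'
#' @param spec a \code{\link{grid_spec}}.
#' @param ion halide symbol.
#' @param water rigid monomer geometry (water-fixed frame).
#' @param overlap_min smallest allowed ion-to-atom distance, Angstrom;
#'   closer grid points raise a degenerate-geometry error listing them.
#' @return an object of class \code{training_set} with \code{points}
#'   (data frame: R, theta, phi, e_ref, weight), \code{configs} (list of
#'   \code{cluster_config}), \code{e_min}, \code{d_e} (both NA until
#'   reference energies and weights are attached), \code{frame} and
#'   \code{provenance}.
#' @export
build_spherical_grid <- function(spec, ion, water = water_geometry(),
                                 overlap_min = 0.7) {
  stopifnot(inherits(spec, "grid_spec"))
  ion <- match.arg(ion, c("F", "Cl", "Br", "I"))
  rs <- .seq_grid(spec$r_min, spec$r_max, spec$n_r)
  # theta uses interior equidistant points: the poles (0, 180) are
  # phi-degenerate (all phi give the same geometry)
  ths <- seq(0, 180, length.out = spec$n_theta + 2)[seq_len(spec$n_theta) + 1]
  phs <- .seq_grid(0, 180, spec$n_phi)
  pts <- expand.grid(phi = phs, theta = ths, R = rs,
                     KEEP.OUT.ATTRS = FALSE)[, c("R", "theta", "phi")]
  configs <- vector("list", nrow(pts))
  bad <- integer(0)
  for (i in seq_len(nrow(pts))) {
    cfg <- dimer_config(ion, pts$R[i], pts$theta[i], pts$phi[i], water)
    dmin <- min(sqrt(rowSums(
      (cfg$xyz[-cfg$ion, , drop = FALSE] -
         matrix(cfg$xyz[cfg$ion, ], nrow(cfg$xyz) - 1, 3, byrow = TRUE))^2)))
    if (dmin < overlap_min) bad <- c(bad, i)
    configs[[i]] <- cfg
  }
  if (length(bad))
    stop("degenerate geometry: ion overlaps water atoms (< ", overlap_min,
         " Angstrom) at grid point(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  structure(
    list(points = data.frame(pts, e_ref = NA_real_, weight = NA_real_),
         configs = configs, e_min = NA_real_, d_e = NA_real_,
         frame = list(ion = ion,
                      water_elements = water$elements,
                      water_xyz = water$xyz),
         provenance = sprintf("spherical grid %dx%dx%d, R in [%g, %g] A",
                              spec$n_r, spec$n_theta, spec$n_phi,
                              spec$r_min, spec$r_max)),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("training_set: ", nrow(x$points), " points (",
      sum(!is.na(x$points$e_ref)), " with reference energies)\n", sep = "")
  if (!is.na(x$e_min))
    cat(sprintf("  e_min = %.4f kcal/mol, d_e = %.4f kcal/mol\n",
                x$e_min, x$d_e))
  cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Energy-based training weights
#'
#' \code{w(E) = (1 / (E - E_min + D_E))^2}: maximal at the training-set
#' minimum energy and strictly decreasing with E, so near-minimum
#' configurations dominate the weighted fit.  \code{D_E} sets the range of
#' favourably weighted energies above the minimum.
#'
#' @param set a \code{training_set} with reference energies attached.
#' @param d_e energy range \code{D_E}, kcal/mol (> 0); defaults to the
#'   set's stored value.
#' @return numeric vector of weights, one per point.
#' @export
energy_weights <- function(set, d_e = set$d_e) {
  e <- set$points$e_ref
  if (any(is.na(e))) stop("reference energies not set")
  if (is.na(d_e) || d_e <= 0) stop("d_e must be > 0")
  e_min <- if (is.na(set$e_min)) min(e) else set$e_min
  if (any(e < e_min - 1e-12))
    stop("inconsistent set: reference energy below e_min")
  (1 / (e - e_min + d_e))^2
}

#' Attach reference energies and weights to a training set
#'
#' @param set a \code{training_set}.
#' @param e_ref reference energies, kcal/mol (one per point).
#' @param d_e weight range \code{D_E}, kcal/mol.
#' @param weights optional explicit weights; default
#'   \code{\link{energy_weights}}.
#' @return the updated \code{training_set}.
#' @export
set_reference_energies <- function(set, e_ref, d_e = 2.0, weights = NULL) {
  if (length(e_ref) != nrow(set$points))
    stop("need one reference energy per point")
  set$points$e_ref <- as.numeric(e_ref)
  set$e_min <- min(e_ref)
  set$d_e <- d_e
  set$points$weight <- if (is.null(weights)) energy_weights(set) else weights
  set
}

#' Synthetic reference data from a known potential
#'
#' Evaluates a ground-truth ion-water model on every grid configuration and
#' adds Gaussian noise, producing a training set with a known answer for
#' fit-recovery testing.  Deterministic for a given seed.
#'
#' @param true_params the ground-truth \code{ion_water_params}.
#' @param grid a \code{training_set} (typically from
#'   \code{\link{build_spherical_grid}}).
#' @param noise_sd Gaussian noise standard deviation, kcal/mol (>= 0).
#' @param seed RNG seed.
#' @param d_e weight range passed to \code{\link{energy_weights}}.
#' @return the \code{training_set} with \code{e_ref}, \code{e_min},
#'   \code{d_e} and weights filled in and provenance recording the
#'   generator settings.
#' @export
make_synthetic_reference <- function(true_params, grid, noise_sd = 0,
                                     seed = 1, d_e = 2.0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  e <- vapply(grid$configs,
              function(cfg) ion_water_energy(true_params, cfg)$total, 0.0)
  if (noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    e <- e + stats::rnorm(length(e), 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  grid <- set_reference_energies(grid, e, d_e = d_e)
  grid$provenance <- sprintf(
    "%s | synthetic reference: ion=%s params[A_O=%.6g beta_O=%.6g C6_O=%.6g A_H=%.6g beta_H=%.6g C6_H=%.6g] noise_sd=%g seed=%d",
    grid$provenance, true_params$ion,
    true_params$pair$O$A, true_params$pair$O$beta, true_params$pair$O$C6,
    true_params$pair$H$A, true_params$pair$H$beta, true_params$pair$H$C6,
    noise_sd, seed)
  grid
}

#' Write / read a training set
#'
#' The points go to a TSV with header columns \code{R}, \code{theta},
#' \code{phi}, \code{e_ref}, \code{weight}; the frame convention,
#' \code{e_min}, \code{d_e} and provenance go to a JSON sidecar at
#' \code{<path>.json}.  The round trip is lossless (configurations are
#' rebuilt from the coordinates and stored frame).
#'
#' @param set a \code{training_set}.
#' @param path TSV path.
#' @return \code{write_training_set}: invisibly, \code{path};
#'   \code{read_training_set}: a \code{training_set}.
#' @export
write_training_set <- function(set, path) {
  pts <- set$points
  fmt <- function(v) sprintf("%.17g", v)
  tab <- data.frame(R = fmt(pts$R), theta = fmt(pts$theta),
                    phi = fmt(pts$phi), e_ref = fmt(pts$e_ref),
                    weight = fmt(pts$weight))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(e_min = set$e_min, d_e = set$d_e, frame = set$frame,
         provenance = set$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e)))
  need <- c("R", "theta", "phi", "e_ref", "weight")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) & !is.na(tab[[cn]]) & tab[[cn]] != "NA")
    if (length(bad))
      stop("format error: non-numeric '", cn, "' at row ", bad[1])
    tab[[cn]] <- v
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  frame <- meta$frame
  water <- if (!is.null(frame))
    cluster_config(frame$water_elements, matrix(unlist(frame$water_xyz),
                                                ncol = 3))
  else water_geometry()
  ion <- frame$ion %||% "Cl"
  configs <- lapply(seq_len(nrow(tab)), function(i)
    dimer_config(ion, tab$R[i], tab$theta[i], tab$phi[i], water))
  structure(
    list(points = tab[, need], configs = configs,
         e_min = meta$e_min %||% min(tab$e_ref),
         d_e = meta$d_e %||% NA_real_,
         frame = list(ion = ion, water_elements = water$elements,
                      water_xyz = water$xyz),
         provenance = meta$provenance %||% paste("read from", path)),
    class = "training_set")
}

#' Subset a training set
#' @param set a \code{training_set}.
#' @param idx integer or logical index over points.
#' @return the subset \code{training_set} (e_min/weights untouched).
#' @export
subset_training_set <- function(set, idx) {
  set$points <- set$points[idx, , drop = FALSE]
  rownames(set$points) <- NULL
  set$configs <- set$configs[idx]
  set
}
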