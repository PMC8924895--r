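## Geometry: cluster containers, XYZ I/O, water-monomer detection and the
## structural analyses (surface-plane distances, ion-displacement scans).

# IUPAC 2021 standard atomic weights for the elements this package handles.
.atomic_masses <- c(
  H = 1.008, O = 15.999,
  F = 18.998403163, Cl = 35.45, Br = 79.904, I = 126.90447
)

.halides <- c("F", "Cl", "Br", "I")

#' Cluster configuration
#'
#' An ordered set of atoms (element symbols plus Cartesian coordinates in
#' Angstrom) with at most one tagged halide ion.  This is the geometry object
#' on which every energy in the package is evaluated.
#'
#' @param elements character vector of element symbols (H, O, F, Cl, Br, I).
#' @param xyz numeric matrix, one row per atom, columns x, y, z in Angstrom.
#' @param ion index of the ion atom, or \code{NULL}/\code{NA} to auto-detect
#'   the unique halide atom (if any).
#' @param label free-text label carried through I/O and reports.
#' @param energy optional energy tag in kcal/mol (e.g. parsed from an XYZ
#'   comment line).
#' @return an object of class \code{cluster_config}: a list with components
#'   \code{elements}, \code{xyz}, \code{ion} (atom index or \code{NA}),
#'   \code{label} and \code{energy}.
#' @examples
#' w <- water_geometry()
#' cfg <- cluster_config(c("Cl", w$elements), rbind(c(0, 0, 3), w$xyz))
#' cfg$ion   # 1, auto-detected
#' @export
cluster_config <- function(elements, xyz, ion = NULL, label = "",
                           energy = NA_real_) {
  elements <- as.character(elements)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (nrow(xyz) != length(elements))
    stop("number of coordinate rows (", nrow(xyz),
         ") does not match number of elements (", length(elements), ")")
  bad <- setdiff(unique(elements), names(.atomic_masses))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates")
  hal <- which(elements %in% .halides)
  if (length(hal) > 1)
    stop("at most one halide ion allowed, found ", length(hal))
  if (is.null(ion) || (length(ion) == 1 && is.na(ion))) {
    ion <- if (length(hal) == 1) hal else NA_integer_
  } else {
    ion <- as.integer(ion)
    if (ion < 1 || ion > length(elements))
      stop("ion index out of range")
  }
  structure(
    list(elements = elements, xyz = xyz, ion = ion,
         label = as.character(label), energy = as.numeric(energy)),
    class = "cluster_config")
}

#' @export
print.cluster_config <- function(x, ...) {
  n <- length(x$elements)
  ion <- if (is.na(x$ion)) "none" else
    paste0(x$elements[x$ion], " (atom ", x$ion, ")")
  cat("cluster_config: ", n, " atoms, ion: ", ion, "\n", sep = "")
  if (nzchar(x$label)) cat("  label: ", x$label, "\n", sep = "")
  if (!is.na(x$energy)) cat("  energy tag: ", x$energy, " kcal/mol\n", sep = "")
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config a \code{cluster_config}.
#' @return integer atom count.
#' @export
n_atoms <- function(config) length(config$elements)

#' Read a cluster from an XYZ file
#'
#' Parses the plain two-header-line XYZ dialect: an atom-count line, a free
#' comment line (scanned for an optional \code{E=<value>} energy tag,
#' kcal/mol), then one \code{element x y z} record per atom.  A unique halide
#' atom, if present, is tagged as the ion.
#'
#' @param path path to an XYZ file.
#' @param frame which frame to read from a multi-frame file (default 1).
#' @return a \code{cluster_config}.
#' @seealso \code{\link{write_xyz}}, \code{\link{read_xyz_frames}}
#' @export
read_xyz <- function(path, frame = 1L) {
  frames <- read_xyz_frames(path)
  if (frame < 1 || frame > length(frames))
    stop("requested frame ", frame, " but file has ", length(frames))
  frames[[frame]]
}

#' Read all frames of a (multi-frame) XYZ file
#' @param path path to an XYZ file.
#' @return list of \code{cluster_config}, one per frame.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed atom-count line at line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("count line at line ", i, " declares ", n,
           " atoms but file ends after ",
           length(lines) - i - 1L, " records")
    comment <- lines[i + 1L]
    rec <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rec), "\\s+")
    el <- character(n); xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      tk <- toks[[k]]
      if (length(tk) < 4)
        stop("malformed atom record at line ", i + 1L + k, ": '", rec[k], "'")
      el[k] <- tk[1]
      co <- suppressWarnings(as.numeric(tk[2:4]))
      if (any(is.na(co)))
        stop("coordinate parse failure at line ", i + 1L + k,
             ": '", rec[k], "'")
      xyz[k, ] <- co
    }
    if (!all(el %in% names(.atomic_masses)))
      stop("unknown element at line ",
           i + 1L + which(!(el %in% names(.atomic_masses)))[1])
    energy <- NA_real_
    m <- regmatches(comment,
                    regexpr("E=\\s*[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                            comment))
    if (length(m) == 1 && nzchar(m))
      energy <- as.numeric(sub("E=\\s*", "", m))
    frames[[length(frames) + 1L]] <-
      cluster_config(el, xyz, label = trimws(comment), energy = energy)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no XYZ frames found in ", path)
  frames
}

#' Write one or more clusters to an XYZ file
#'
#' @param config a \code{cluster_config} or a list of them (multi-frame).
#' @param path output path.
#' @param digits coordinate precision (default 10, round-trips to well below
#'   1e-6 Angstrom).
#' @return invisibly, \code{path}.
#' @export
write_xyz <- function(config, path, digits = 10) {
  if (inherits(config, "cluster_config")) config <- list(config)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in config) {
    comment <- cf$label
    if (!is.na(cf$energy) && !grepl("E=", comment))
      comment <- trimws(paste(comment, sprintf("E=%.10g", cf$energy)))
    writeLines(as.character(length(cf$elements)), con)
    writeLines(comment, con)
    fmt <- sprintf("%%-2s %%%d.%df %%%d.%df %%%d.%df",
                   digits + 6, digits, digits + 6, digits,
                   digits + 6, digits)
    writeLines(sprintf(fmt, cf$elements, cf$xyz[, 1], cf$xyz[, 2],
                       cf$xyz[, 3]),
               con)
  }
  invisible(path)
}

#' Identify water monomers
#'
#' Assigns every hydrogen to its nearest oxygen within the O-H bonding
#' cutoff and requires the result to be a perfect matching: each oxygen ends
#' up with exactly two hydrogens and each hydrogen belongs to exactly one
#' oxygen.  Ambiguous assignments (an H essentially equidistant from two O)
#' and malformed monomers raise errors.
#'
#' @param config a \code{cluster_config} whose non-ion atoms are O and H only.
#' @param oh_cutoff O-H bonding cutoff in Angstrom.  The default 1.3 covers
#'   distorted monomers while excluding hydrogen bonds (~1.7 Angstrom and up).
#' @param tie_tol two O at H-distances within this of each other count as
#'   ambiguous (Angstrom).
#' @return data frame with one row per water: columns \code{o}, \code{h1},
#'   \code{h2} (atom indices), \code{r_oh1}, \code{r_oh2} (Angstrom) and
#'   \code{angle_hoh} (degrees).
#' @export
identify_waters <- function(config, oh_cutoff = 1.3, tie_tol = 1e-6) {
  idx <- seq_along(config$elements)
  if (!is.na(config$ion)) idx <- idx[idx != config$ion]
  el <- config$elements[idx]
  if (!all(el %in% c("O", "H")))
    stop("non-ion atoms must be O and H only; found: ",
         paste(setdiff(el, c("O", "H")), collapse = ", "))
  o_idx <- idx[el == "O"]
  h_idx <- idx[el == "H"]
  if (length(h_idx) != 2 * length(o_idx))
    stop("topology error: ", length(o_idx), " O and ", length(h_idx),
         " H atoms cannot form complete waters")
  if (!length(o_idx))
    return(data.frame(o = integer(), h1 = integer(), h2 = integer(),
                      r_oh1 = numeric(), r_oh2 = numeric(),
                      angle_hoh = numeric()))
  assign_o <- integer(length(h_idx))
  for (k in seq_along(h_idx)) {
    d <- sqrt(colSums((t(config$xyz[o_idx, , drop = FALSE]) -
                         config$xyz[h_idx[k], ])^2))
    within <- which(d <= oh_cutoff)
    if (!length(within))
      stop("topology error: H atom ", h_idx[k],
           " has no O within cutoff ", oh_cutoff, " Angstrom")
    ord <- order(d)
    if (length(within) > 1 && d[ord[2]] - d[ord[1]] < tie_tol)
      stop("topology error: H atom ", h_idx[k],
           " is ambiguously shared between O atoms ",
           o_idx[ord[1]], " and ", o_idx[ord[2]])
    assign_o[k] <- o_idx[ord[1]]
  }
  out <- lapply(o_idx, function(o) {
    hs <- h_idx[assign_o == o]
    if (length(hs) != 2)
      stop("topology error: O atom ", o, " has ", length(hs),
           " bonded H (need exactly 2)")
    v1 <- config$xyz[hs[1], ] - config$xyz[o, ]
    v2 <- config$xyz[hs[2], ] - config$xyz[o, ]
    r1 <- sqrt(sum(v1^2)); r2 <- sqrt(sum(v2^2))
    ang <- acos(max(-1, min(1, sum(v1 * v2) / (r1 * r2)))) * 180 / pi
    data.frame(o = o, h1 = hs[1], h2 = hs[2],
               r_oh1 = r1, r_oh2 = r2, angle_hoh = ang)
  })
  do.call(rbind, out)
}

#' Center of mass
#'
#' Mass-weighted mean position using IUPAC standard atomic weights.
#'
#' @param config a \code{cluster_config}.
#' @param include_ion include the ion's mass (default \code{TRUE}); with
#'   \code{FALSE} only the water atoms contribute.
#' @return numeric length-3 vector, Angstrom.
#' @export
center_of_mass <- function(config, include_ion = TRUE) {
  idx <- seq_along(config$elements)
  if (!include_ion && !is.na(config$ion)) idx <- idx[idx != config$ion]
  if (!length(idx)) stop("empty configuration")
  m <- .atomic_masses[config$elements[idx]]
  colSums(config$xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Surface-plane analysis of an ion-water cluster
#'
#' Defines the plane through the cluster center of mass perpendicular to the
#' line joining the center of mass and the ion, and reports the signed
#' distance of every oxygen atom and of the ion from that plane.  Positive
#' distances point toward the ion; an ion sitting outside the water envelope
#' (on the cluster surface) therefore has \code{r} larger than every oxygen.
#'
#' @param config a \code{cluster_config} with an ion.
#' @param include_ion whether the center of mass includes the ion's mass
#'   (default \code{TRUE}).
#' @return an object of class \code{plane_analysis}: list with
#'   \code{plane_point} (the COM), \code{plane_normal} (unit vector toward
#'   the ion) and \code{r_values}, a data frame with columns
#'   \code{site_type} ("O" or "ion"), \code{atom_index} and \code{r}
#'   (signed distance, Angstrom).
#' @export
surface_plane_analysis <- function(config, include_ion = TRUE) {
  if (is.na(config$ion)) stop("configuration has no ion")
  com <- center_of_mass(config, include_ion = include_ion)
  v <- config$xyz[config$ion, ] - com
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9)
    stop("degenerate geometry: ion coincides with the center of mass")
  normal <- v / nv
  o_idx <- which(config$elements == "O")
  sites <- data.frame(
    site_type = c(rep("O", length(o_idx)), "ion"),
    atom_index = c(o_idx, config$ion),
    r = vapply(c(o_idx, config$ion),
               function(i) sum((config$xyz[i, ] - com) * normal), 0.0))
  structure(list(plane_point = com, plane_normal = normal, r_values = sites),
            class = "plane_analysis")
}

#' @export
print.plane_analysis <- function(x, ...) {
  r_o <- x$r_values$r[x$r_values$site_type == "O"]
  r_i <- x$r_values$r[x$r_values$site_type == "ion"]
  cat("plane_analysis: ", length(r_o), " O sites\n", sep = "")
  cat(sprintf("  r(ion) = %.3f A, max r(O) = %.3f A (%s)\n", r_i, max(r_o),
              if (r_i > max(r_o)) "ion outside water envelope"
              else "ion inside water envelope"))
  invisible(x)
}

#' Export a plane analysis as TSV
#' @param x a \code{plane_analysis}.
#' @param path output path; columns \code{site_type}, \code{atom_index},
#'   \code{r} (Angstrom, 1-based atom indices).
#' @return invisibly, \code{path}.
#' @export
write_plane_analysis <- function(x, path) {
  utils::write.table(x$r_values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ion displacement scan
#'
#' Generates configurations in which the ion is moved along the line joining
#' the water-cluster center of mass and the ion position in the input
#' (minimum-energy) structure, with all water atoms held fixed.  Step
#' \code{s} places the ion at \code{COM + s * (ion - COM)}: \code{s = 0} is
#' the center of mass, \code{s = 1} the original position, \code{s > 1}
#' extrapolates outward into the dissociative region.
#'
#' @param config a \code{cluster_config} with an ion.
#' @param steps numeric vector of scan steps; the default schedule is dense
#'   near the minimum.
#' @param include_ion_com whether the reference center of mass includes the
#'   ion (default \code{FALSE}: the COM of the fixed water frame, so the scan
#'   path does not depend on the moving ion).
#' @return list of \code{cluster_config}, one per step, labelled with the
#'   step value.
#' @export
ion_scan_path <- function(config,
                          steps = c(0, 0.2, 0.4, 0.6, 0.8, 0.9, 1.0,
                                    1.1, 1.25, 1.5),
                          include_ion_com = FALSE) {
  if (is.na(config$ion)) stop("configuration has no ion")
  if (!length(steps)) stop("empty steps list")
  com <- center_of_mass(config, include_ion = include_ion_com)
  dir <- config$xyz[config$ion, ] - com
  lapply(steps, function(s) {
    xyz <- config$xyz
    xyz[config$ion, ] <- com + s * dir
    cluster_config(config$elements, xyz, ion = config$ion,
                   label = sprintf("%s scan_step=%g", config$label, s))
  })
}
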