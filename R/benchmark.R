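## Benchmark protocol: ingest per-structure interaction energies from
## external methods, compute percentage deviations and scan-averaged errors
## against a reference method, and assemble comparison reports.

#' Method energy table
#'
#' Per-structure interaction energies for one named method (a model
#' potential or ingested quantum-chemistry values).
#'
#' @param method_name method label, e.g. "i-TTM4" or "DF-MP2".
#' @param entries data frame with columns \code{structure_id} (unique) and
#'   \code{energy} (kcal/mol, finite); extra columns (e.g. \code{group} for
#'   the halide) are carried as metadata.
#' @param metadata optional free-form list (basis set, dispersion tags...).
#' @return an object of class \code{method_energy_table}.
#' @export
method_energy_table <- function(method_name, entries, metadata = list()) {
  if (!all(c("structure_id", "energy") %in% names(entries)))
    stop("entries need columns structure_id and energy")
  entries$structure_id <- as.character(entries$structure_id)
  entries$energy <- as.numeric(entries$energy)
  dup <- entries$structure_id[duplicated(entries$structure_id)]
  if (length(dup))
    stop("duplicate structure_id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(entries$energy)))
    stop("non-finite energies in method table '", method_name, "'")
  rownames(entries) <- NULL
  structure(list(method_name = method_name, entries = entries,
                 metadata = metadata),
            class = "method_energy_table")
}

#' @export
print.method_energy_table <- function(x, ...) {
  cat("method_energy_table '", x$method_name, "': ", nrow(x$entries),
      " structures\n", sep = "")
  invisible(x)
}

#' Read / write method energies as TSV
#'
#' Expected columns: \code{structure_id}, \code{energy_kcal_mol}, plus any
#' optional metadata columns (kept).
#'
#' @param path TSV path.
#' @param method_name method label; default the file name without extension.
#' @return \code{read_method_energies}: a \code{method_energy_table};
#'   \code{write_method_energies}: invisibly, \code{path}.
#' @export
read_method_energies <- function(path, method_name = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("structure_id", "energy_kcal_mol") %in% names(tab)))
    stop("format error: need columns structure_id and energy_kcal_mol")
  v <- suppressWarnings(as.numeric(tab$energy_kcal_mol))
  bad <- which(is.na(v))
  if (length(bad))
    stop("format error: non-numeric energy at row ", bad[1])
  tab$energy <- v
  tab$energy_kcal_mol <- NULL
  if (is.null(method_name))
    method_name <- sub("\\.[^.]*$", "", basename(path))
  method_energy_table(method_name, tab)
}

#' @rdname read_method_energies
#' @param table a \code{method_energy_table}.
#' @export
write_method_energies <- function(table, path) {
  out <- table$entries
  names(out)[names(out) == "energy"] <- "energy_kcal_mol"
  out$energy_kcal_mol <- sprintf("%.17g", out$energy_kcal_mol)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Percentage deviation from a reference method
#'
#' \code{delta = 100 (E_model - E_ref) / |E_ref|} per structure present in
#' both tables.  Structures with a zero reference energy are reported with
#' \code{NA} and a warning, not dropped silently; disjoint tables give an
#' empty result with a warning.
#'
#' @param model,reference \code{method_energy_table}s.
#' @return data frame with columns \code{structure_id}, \code{e_model},
#'   \code{e_ref} and \code{delta_percent}, plus any \code{group} column
#'   shared by the reference table.
#' @export
percent_delta <- function(model, reference) {
  shared <- intersect(model$entries$structure_id,
                      reference$entries$structure_id)
  if (!length(shared)) {
    warning("no shared structures between '", model$method_name,
            "' and '", reference$method_name, "'")
    return(data.frame(structure_id = character(), e_model = numeric(),
                      e_ref = numeric(), delta_percent = numeric()))
  }
  em <- model$entries$energy[match(shared, model$entries$structure_id)]
  er <- reference$entries$energy[match(shared,
                                       reference$entries$structure_id)]
  delta <- ifelse(er == 0, NA_real_, 100 * (em - er) / abs(er))
  if (any(er == 0))
    warning("zero reference energy for: ",
            paste(shared[er == 0], collapse = ", "))
  out <- data.frame(structure_id = shared, e_model = em, e_ref = er,
                    delta_percent = delta)
  if ("group" %in% names(reference$entries))
    out$group <- reference$entries$group[match(shared,
                                               reference$entries$structure_id)]
  out
}

#' Mean absolute error along a scan
#'
#' Mean over scan points of \code{|E_model - E_ref|}; the summary statistic
#' for ion-displacement scans.
#'
#' @param model_energies,reference_energies numeric vectors over the same
#'   scan points.  If both are named, names must match as sets and are used
#'   to align the points.
#' @return mean absolute error, kcal/mol.
#' @export
scan_error_summary <- function(model_energies, reference_energies) {
  if (!is.null(names(model_energies)) &&
      !is.null(names(reference_energies))) {
    if (!setequal(names(model_energies), names(reference_energies)))
      stop("mismatched scan-point sets")
    reference_energies <-
      reference_energies[names(model_energies)]
  } else if (length(model_energies) != length(reference_energies)) {
    stop("mismatched scan-point sets")
  }
  mean(abs(model_energies - reference_energies))
}

#' Model-potential energy table
#'
#' Evaluates the cluster interaction energy of a parameter set on each
#' supplied structure, producing a \code{method_energy_table} comparable
#' with ingested quantum-chemistry tables.  Structure ids are taken from the
#' configuration labels (or \code{structure_<i>} when empty).
#'
#' @param params an \code{ion_water_params}.
#' @param structures list of \code{cluster_config}.
#' @param water_model a \code{water_model}.
#' @param method_name table label (default the params' model tag).
#' @return a \code{method_energy_table}.
#' @export
model_energy_table <- function(params, structures,
                               water_model = simple_water_model(),
                               method_name = NULL) {
  if (is.null(method_name))
    method_name <- paste0("i-TTM(", params$ion, ")")
  ids <- vapply(seq_along(structures), function(i) {
    lb <- structures[[i]]$label
    if (nzchar(lb)) lb else sprintf("structure_%d", i)
  }, "")
  e <- vapply(structures,
              function(cfg) interaction_energy(params, cfg, water_model),
              0.0)
  method_energy_table(method_name,
                      data.frame(structure_id = ids, energy = e))
}

#' Comparison report across methods
#'
#' Assembles the benchmark protocol outputs: per-structure percentage
#' deviations of every method from the reference, per-group (e.g. per
#' halide) maximum and mean absolute deviations, correlation summaries
#' (slope, intercept, RMSD of model vs reference energies), optional scan
#' mean-absolute-error summaries, and max-normalized average errors (every
#' method divided by the worst, so bars lie in [0, 1] with at least one
#' method at 1).
#'
#' @param tables list of \code{method_energy_table}s, including the
#'   reference.
#' @param reference name of the reference method.
#' @param scans optional named list: \code{scans[[method]]} is a named
#'   numeric vector of scan-point energies; must contain the reference
#'   method.
#' @return an object of class \code{comparison_report}: list with
#'   \code{reference_method}, \code{per_structure} (long data frame),
#'   \code{per_group} (or NULL), \code{correlation}, \code{scan_mae}
#'   (or NULL) and \code{normalized_error}.
#' @export
comparison_report <- function(tables, reference, scans = NULL) {
  names(tables) <- vapply(tables, `[[`, "", "method_name")
  if (!reference %in% names(tables))
    stop("reference method '", reference, "' not among the tables")
  ref <- tables[[reference]]
  models <- tables[names(tables) != reference]
  per_structure <- do.call(rbind, lapply(models, function(m) {
    d <- percent_delta(m, ref)
    if (nrow(d)) cbind(method = m$method_name, d) else NULL
  }))
  rownames(per_structure) <- NULL
  per_group <- NULL
  if (!is.null(per_structure) && "group" %in% names(per_structure)) {
    per_group <- do.call(rbind, lapply(
      split(per_structure, per_structure[c("method", "group")]),
      function(d) data.frame(method = d$method[1], group = d$group[1],
                             mean_abs_delta = mean(abs(d$delta_percent),
                                                   na.rm = TRUE),
                             max_abs_delta = max(abs(d$delta_percent),
                                                 na.rm = TRUE))))
    rownames(per_group) <- NULL
  }
  correlation <- do.call(rbind, lapply(models, function(m) {
    d <- percent_delta(m, ref)
    if (nrow(d) < 2)
      return(data.frame(method = m$method_name, slope = NA_real_,
                        intercept = NA_real_, rmsd = NA_real_))
    fit <- stats::lm(e_model ~ e_ref, data = d)
    data.frame(method = m$method_name,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               rmsd = sqrt(mean((d$e_model - d$e_ref)^2)))
  }))
  rownames(correlation) <- NULL
  scan_mae <- NULL
  if (!is.null(scans)) {
    if (!reference %in% names(scans))
      stop("scans must include the reference method '", reference, "'")
    other <- setdiff(names(scans), reference)
    scan_mae <- data.frame(
      method = other,
      mae = vapply(other, function(m)
        scan_error_summary(scans[[m]], scans[[reference]]), 0.0))
    rownames(scan_mae) <- NULL
  }
  mean_err <- vapply(models, function(m) {
    d <- percent_delta(m, ref)
    mean(abs(d$delta_percent), na.rm = TRUE)
  }, 0.0)
  normalized_error <- data.frame(
    method = names(models),
    mean_abs_delta = unname(mean_err),
    normalized = if (max(mean_err) > 0) unname(mean_err / max(mean_err))
                 else rep(0, length(mean_err)))
  rownames(normalized_error) <- NULL
  structure(list(reference_method = reference,
                 per_structure = per_structure, per_group = per_group,
                 correlation = correlation, scan_mae = scan_mae,
                 normalized_error = normalized_error),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report vs ", x$reference_method, "\n", sep = "")
  print(x$normalized_error)
  invisible(x)
}

#' Write a comparison report as TSV files
#'
#' Deterministic (byte-identical for identical inputs): writes
#' \code{per_structure.tsv}, \code{correlation.tsv},
#' \code{normalized_error.tsv} and, when present, \code{per_group.tsv} and
#' \code{scan_mae.tsv} under \code{dir}.
#'
#' @param report a \code{comparison_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, paste0(name, ".tsv"))
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$per_structure, "per_structure")
  wr(report$per_group, "per_group")
  wr(report$correlation, "correlation")
  wr(report$scan_mae, "scan_mae")
  wr(report$normalized_error, "normalized_error")
  invisible(paths)
}
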