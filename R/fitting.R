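## Two-stage parameterization with active-learning reweighting: weighted
## chi-squared, SVD solution of the linear (A, C6) parameters, Nelder-Mead
## simplex optimization of the nonlinear (beta) parameters, and the
## iterative error-driven weight-update loop.

#' Fit configuration
#'
#' Knobs of the active-learning fitting loop: convergence tolerances, the
#' error-fraction threshold selecting which points get boosted, and the
#' geometric "gradual descent" boost schedule
#' \code{boost_t = weight_boost_initial * weight_boost_decay^t}.
#'
#' @param max_al_iterations cap on reweighting iterations.
#' @param max_simplex_steps simplex iteration budget per reweighting
#'   iteration.
#' @param mean_error_tol convergence when the mean absolute pointwise error
#'   drops below this, kcal/mol.
#' @param pointwise_error_tol convergence when the maximum absolute
#'   pointwise error drops below this, kcal/mol.
#' @param error_fraction_threshold points whose absolute error exceeds this
#'   fraction of the maximum error get their weights boosted; values above 1
#'   disable boosting (single weighted fit).
#' @param weight_boost_initial,weight_boost_decay boost schedule parameters
#'   (> 0 and in (0, 1]); flagged weights are multiplied by
#'   \code{1 + boost_t}.
#' @param sv_rel_tol relative singular-value truncation threshold of the
#'   linear solve.
#' @param seed RNG seed recorded with results.
#' @return an object of class \code{fit_config}.
#' @export
fit_config <- function(max_al_iterations = 30, max_simplex_steps = 200,
                       mean_error_tol = 0.05, pointwise_error_tol = 0.5,
                       error_fraction_threshold = 0.5,
                       weight_boost_initial = 1.0,
                       weight_boost_decay = 0.7,
                       sv_rel_tol = 1e-10, seed = 1L) {
  if (any(c(mean_error_tol, pointwise_error_tol) <= 0))
    stop("tolerances must be > 0")
  if (error_fraction_threshold <= 0)
    stop("error_fraction_threshold must be > 0")
  if (weight_boost_initial <= 0 || weight_boost_decay <= 0 ||
      weight_boost_decay > 1)
    stop("need weight_boost_initial > 0 and weight_boost_decay in (0, 1]")
  structure(list(max_al_iterations = as.integer(max_al_iterations),
                 max_simplex_steps = as.integer(max_simplex_steps),
                 mean_error_tol = mean_error_tol,
                 pointwise_error_tol = pointwise_error_tol,
                 error_fraction_threshold = error_fraction_threshold,
                 weight_boost_initial = weight_boost_initial,
                 weight_boost_decay = weight_boost_decay,
                 sv_rel_tol = sv_rel_tol, seed = as.integer(seed)),
            class = "fit_config")
}

## Per-point geometry features and the parameter-independent energy part
## (permanent electrostatics + induction), fixed while A, beta, C6 move.
.fit_features <- function(params, set) {
  n <- nrow(set$points)
  R_O <- numeric(n); R_H1 <- numeric(n); R_H2 <- numeric(n)
  fixed <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- set$configs[[i]]
    w <- identify_waters(cfg)
    xi <- cfg$xyz[cfg$ion, ]
    R_O[i] <- sqrt(sum((cfg$xyz[w$o, ] - xi)^2))
    R_H1[i] <- sqrt(sum((cfg$xyz[w$h1, ] - xi)^2))
    R_H2[i] <- sqrt(sum((cfg$xyz[w$h2, ] - xi)^2))
    sites <- .build_sites(params, cfg, w)
    fixed[i] <- .site_elec_energy(sites, "ion_water") +
      .induction_of(sites) - .induction_of(.drop_ion_sites(sites))
  }
  list(R_O = R_O, R_H1 = R_H1, R_H2 = R_H2, fixed = fixed)
}

## Model dimer energies from features for a pair-term list.
.feature_energy <- function(pair, ft) {
  pO <- pair$O; pH <- pair$H
  pO$A * exp(-pO$beta * ft$R_O) +
    pH$A * (exp(-pH$beta * ft$R_H1) + exp(-pH$beta * ft$R_H2)) -
    pO$C6 * tang_toennies(6, pO$delta, ft$R_O) / ft$R_O^6 -
    pH$C6 * (tang_toennies(6, pH$delta, ft$R_H1) / ft$R_H1^6 +
               tang_toennies(6, pH$delta, ft$R_H2) / ft$R_H2^6) +
    ft$fixed
}

.set_pair <- function(params, A_O, beta_O, C6_O, A_H, beta_H, C6_H) {
  params$pair$O <- list(A = A_O, beta = beta_O, C6 = C6_O,
                        delta = if (params$tie_delta) beta_O
                                else params$pair$O$delta)
  params$pair$H <- list(A = A_H, beta = beta_H, C6 = C6_H,
                        delta = if (params$tie_delta) beta_H
                                else params$pair$H$delta)
  params
}

#' Weighted chi-squared of a parameter set
#'
#' The weighted sum of squared residuals
#' \code{sum_N w_N (V_model(N) - E_ref(N))^2} over the training set.
#'
#' @param params an \code{ion_water_params}.
#' @param set a \code{training_set} with energies and weights attached.
#' @param features optional precomputed per-point features (internal
#'   speed-up for the fitting loop).
#' @return non-negative scalar; zero iff every weighted residual vanishes.
#' @export
chi_squared <- function(params, set, features = NULL) {
  w <- set$points$weight
  if (any(is.na(w))) stop("training-set weights not set")
  if (is.null(features)) features <- .fit_features(params, set)
  v <- .feature_energy(params$pair, features)
  sum(w * (v - set$points$e_ref)^2)
}

#' Weighted linear least squares via truncated SVD
#'
#' Solves \code{min_c sum_i w_i (y_i - X_i . c)^2} through the singular
#' value decomposition of the weighted design matrix, truncating singular
#' values below \code{sv_rel_tol} times the largest (minimum-norm solution
#' for rank-deficient designs).
#'
#' @param X design matrix (rows = observations, columns = linear-in-
#'   parameter basis terms).
#' @param y response vector.
#' @param weights non-negative weights.
#' @param sv_rel_tol relative singular-value truncation threshold.
#' @return list with \code{coef}, \code{rank} and \code{singular_values}.
#' @export
fit_linear_terms <- function(X, y, weights = rep(1, length(y)),
                             sv_rel_tol = 1e-10) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X))
    stop("need at least as many points (", nrow(X),
         ") as coefficients (", ncol(X), ")")
  sw <- sqrt(weights)
  sv <- svd(X * sw)
  keep <- sv$d >= sv_rel_tol * sv$d[1]
  if (!any(keep)) stop("fit error: design matrix is numerically zero")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * crossprod(sv$u, y * sw))
  list(coef = as.vector(coef), rank = sum(keep), singular_values = sv$d)
}

#' Nelder-Mead simplex minimization
#'
#' Standard Nelder-Mead descent (via \code{stats::optim}) with a single
#' restart from the best vertex on stagnation; the returned objective value
#' never exceeds the initial one.
#'
#' @param objective function of a numeric parameter vector.
#' @param init initial parameter vector (objective must be finite there).
#' @param max_steps total iteration budget.
#' @param restart whether to restart once from the incumbent.
#' @return list with \code{par}, \code{value} and \code{evaluations}.
#' @export
simplex_fit <- function(objective, init, max_steps = 500, restart = TRUE) {
  f0 <- objective(init)
  if (!is.finite(f0))
    stop("fit error: objective not finite at the initial parameters (",
         paste(signif(init, 6), collapse = ", "), ")")
  guarded <- function(p) {
    v <- objective(p)
    if (is.na(v)) stop("fit error: objective returned NA at (",
                       paste(signif(p, 6), collapse = ", "), ")")
    if (!is.finite(v)) return(1e30)
    v
  }
  evals <- 0L
  run <- function(p0, steps) {
    o <- stats::optim(p0, guarded, method = "Nelder-Mead",
                      control = list(maxit = steps))
    evals <<- evals + o$counts[["function"]]
    o
  }
  half <- if (restart) max(1L, max_steps %/% 2L) else max_steps
  o1 <- run(init, half)
  best <- o1
  if (restart && half < max_steps) {
    o2 <- run(o1$par, max_steps - half)
    if (o2$value <= best$value) best <- o2
  }
  if (best$value > f0) best <- list(par = init, value = f0)
  list(par = best$par, value = best$value, evaluations = evals)
}

## One weighted fit at fixed weights: simplex over log(beta_O, beta_H) with
## the linear parameters (A's, and the C6's unless frozen) solved by SVD at
## every simplex step (variable projection).
.weighted_fit <- function(set, init, config, features,
                          freeze_c6 = FALSE, max_steps) {
  w <- set$points$weight
  y0 <- set$points$e_ref - features$fixed
  c6O <- init$pair$O$C6; c6H <- init$pair$H$C6
  solve_at <- function(beta) {
    bO <- beta[1]; bH <- beta[2]
    basis_A <- cbind(exp(-bO * features$R_O),
                     exp(-bH * features$R_H1) + exp(-bH * features$R_H2))
    if (freeze_c6) {
      y <- y0 +
        c6O * tang_toennies(6, bO, features$R_O) / features$R_O^6 +
        c6H * (tang_toennies(6, bH, features$R_H1) / features$R_H1^6 +
                 tang_toennies(6, bH, features$R_H2) / features$R_H2^6)
      ls <- fit_linear_terms(basis_A, y, w, config$sv_rel_tol)
      co <- c(ls$coef, c6O, c6H)
      resid <- y - as.vector(basis_A %*% ls$coef)
    } else {
      basis <- cbind(basis_A,
                     -tang_toennies(6, bO, features$R_O) / features$R_O^6,
                     -(tang_toennies(6, bH, features$R_H1) / features$R_H1^6 +
                         tang_toennies(6, bH, features$R_H2) / features$R_H2^6))
      ls <- fit_linear_terms(basis, y0, w, config$sv_rel_tol)
      co <- ls$coef
      resid <- y0 - as.vector(basis %*% ls$coef)
    }
    list(coef = co, chi2 = sum(w * resid^2))
  }
  obj <- function(lb) solve_at(exp(lb))$chi2
  sf <- simplex_fit(obj, log(c(init$pair$O$beta, init$pair$H$beta)),
                    max_steps = max_steps)
  beta <- exp(sf$par)
  sol <- solve_at(beta)
  params <- .set_pair(init, A_O = sol$coef[1], beta_O = beta[1],
                      C6_O = sol$coef[3], A_H = sol$coef[2],
                      beta_H = beta[2], C6_H = sol$coef[4])
  list(params = params, chi2 = sol$chi2, evaluations = sf$evaluations)
}

.point_errors <- function(params, set, features)
  .feature_energy(params$pair, features) - set$points$e_ref

#' Active-learning weighted fit
#'
#' The error-driven reweighting loop: repeat \{minimize chi-squared by
#' simplex + SVD; evaluate per-point absolute errors; if no convergence
#' criterion holds, boost the weights of points whose error exceeds
#' \code{error_fraction_threshold} times the maximum error by the factor
#' \code{1 + boost_t}, with the geometrically decaying schedule
#' \code{boost_t = weight_boost_initial * weight_boost_decay^t}\} until a
#' tolerance or the iteration cap is reached.  Weights are renormalized to
#' mean 1 after each boost; an iterate that fails to improve the RMS error
#' is rejected and the loop halts.
#'
#' @param set a \code{training_set} with initial weights (e.g.
#'   \code{\link{energy_weights}} or uniform).
#' @param init initial \code{ion_water_params}.
#' @param config a \code{\link{fit_config}}.
#' @param freeze_c6 hold both C6 coefficients fixed at their initial values
#'   (stage 2 of the two-stage protocol).
#' @return an object of class \code{fit_result}: list with \code{params},
#'   \code{chi2}, \code{rms_error}, \code{max_error}, \code{mean_error},
#'   \code{weight_history} (one weight vector per iteration run),
#'   \code{converged}, \code{criterion_met}, \code{iterations},
#'   \code{evaluations} and a per-iteration \code{diagnostics} data frame.
#' @export
active_learning_fit <- function(set, init, config = fit_config(),
                                freeze_c6 = FALSE) {
  if (any(is.na(set$points$weight))) stop("initial weights not set")
  features <- .fit_features(init, set)
  weight_history <- list()
  diag_rows <- list()
  best <- NULL; best_rms <- Inf
  converged <- FALSE; criterion <- "max_iterations"
  evals <- 0L
  t <- 0L
  repeat {
    weight_history[[t + 1L]] <- set$points$weight
    ft <- .weighted_fit(set, if (is.null(best)) init else best$params,
                        config, features, freeze_c6,
                        config$max_simplex_steps)
    evals <- evals + ft$evaluations
    err <- .point_errors(ft$params, set, features)
    rms <- sqrt(mean(err^2)); mx <- max(abs(err)); mn <- mean(abs(err))
    n_boost <- 0L
    accepted <- rms <= best_rms + 1e-12
    if (accepted) { best <- ft; best_rms <- rms }
    diag_rows[[t + 1L]] <- data.frame(iteration = t, chi2 = ft$chi2,
                                      rms = rms, max_error = mx,
                                      mean_error = mn,
                                      n_boosted = NA_integer_,
                                      accepted = accepted)
    t <- t + 1L
    if (mn <= config$mean_error_tol) {
      converged <- TRUE; criterion <- "mean_error"; break
    }
    if (mx <= config$pointwise_error_tol) {
      converged <- TRUE; criterion <- "pointwise_error"; break
    }
    if (!accepted) { criterion <- "no_improvement"; break }
    if (t >= config$max_al_iterations) break
    flagged <- abs(err) > config$error_fraction_threshold * mx
    n_boost <- sum(flagged)
    diag_rows[[t]]$n_boosted <- n_boost
    if (n_boost == length(err))
      warning("all points flagged for boosting; proceeding")
    if (n_boost > 0) {
      boost <- config$weight_boost_initial *
        config$weight_boost_decay^(t - 1L)
      wts <- set$points$weight
      wts[flagged] <- wts[flagged] * (1 + boost)
      set$points$weight <- wts / mean(wts)
    }
  }
  errb <- .point_errors(best$params, set, features)
  structure(
    list(params = best$params, chi2 = best$chi2,
         rms_error = sqrt(mean(errb^2)), max_error = max(abs(errb)),
         mean_error = mean(abs(errb)),
         weight_history = weight_history, converged = converged,
         criterion_met = criterion, iterations = t, evaluations = evals,
         diagnostics = do.call(rbind, diag_rows)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %d iteration(s), %s (criterion: %s)\n",
              x$iterations,
              if (x$converged) "converged" else "not converged",
              x$criterion_met))
  cat(sprintf("  chi2 = %.6g, rms = %.4g, max|err| = %.4g kcal/mol\n",
              x$chi2, x$rms_error, x$max_error))
  invisible(x)
}

#' Single-pass weighted fit (comparison baseline)
#'
#' One weighted simplex + SVD fit at fixed weights, given the same total
#' simplex budget as a full active-learning run
#' (\code{max_al_iterations * max_simplex_steps}); the baseline against
#' which the reweighting loop is compared.
#'
#' @inheritParams active_learning_fit
#' @return a \code{fit_result} (single iteration, weights untouched).
#' @export
single_pass_fit <- function(set, init, config = fit_config(),
                            freeze_c6 = FALSE) {
  cfg1 <- config
  cfg1$max_al_iterations <- config$max_al_iterations   # same loop count
  cfg1$error_fraction_threshold <- Inf                 # boosts never fire
  active_learning_fit(set, init, cfg1, freeze_c6)
}

#' Two-stage parameterization
#'
#' Stage 1 imposes the correct asymptotic behaviour: the C6 dispersion
#' coefficients are fit linearly on the long-range subset, where repulsion
#' is negligible and damping is close to 1.  Stage 2 freezes those C6
#' values and runs the active-learning loop for the Born-Mayer A and beta
#' parameters on the full set, with each damping steepness delta tied to its
#' beta.
#'
#' An optional joint refinement pass (default one) then re-runs the
#' active-learning fit with the C6 coefficients released, warm-started from
#' the stage-2 parameters.  The long-range stage anchors the asymptotics
#' and supplies consistent starting values, but dispersion carries little
#' statistical weight at large R, so a C6 estimate from long-range points
#' alone is noise-limited; the joint pass restores the efficiency of
#' estimating all linear terms from the full set.  Set
#' \code{refine_cycles = 0} for the strict two-stage protocol with C6
#' frozen at the stage-1 values.
#'
#' @param set_longrange long-range \code{training_set} (large-R points
#'   only).
#' @param set_full full \code{training_set}.
#' @param init initial \code{ion_water_params}.
#' @param config a \code{\link{fit_config}}.
#' @param refine_cycles number of joint refinement passes after stage 2.
#' @return a \code{fit_result} with an extra \code{stage1} component
#'   (stage-1 C6 values and the singular values of the long-range solve).
#' @export
two_stage_fit <- function(set_longrange, set_full, init,
                          config = fit_config(), refine_cycles = 1) {
  if (!nrow(set_longrange$points))
    stop("long-range training set is empty")
  features_lr <- .fit_features(init, set_longrange)
  y <- set_longrange$points$e_ref - features_lr$fixed
  w <- set_longrange$points$weight
  if (any(is.na(w))) w <- rep(1, length(y))
  X <- cbind(-1 / features_lr$R_O^6,
             -(1 / features_lr$R_H1^6 + 1 / features_lr$R_H2^6))
  ls <- fit_linear_terms(X, y, w, config$sv_rel_tol)
  c6 <- ls$coef
  current <- .set_pair(init,
                       A_O = init$pair$O$A, beta_O = init$pair$O$beta,
                       C6_O = c6[1],
                       A_H = init$pair$H$A, beta_H = init$pair$H$beta,
                       C6_H = c6[2])
  res <- active_learning_fit(set_full, current, config, freeze_c6 = TRUE)
  for (cycle in seq_len(refine_cycles))
    res <- active_learning_fit(set_full, res$params, config,
                               freeze_c6 = FALSE)
  res$stage1 <- list(C6_O = c6[1], C6_H = c6[2],
                     singular_values = ls$singular_values)
  res
}
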