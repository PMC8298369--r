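# Multi-experiment nonlinear least squares for the kinetic constants.
#
# The objective is the sum of squared differences between observed and
# predicted *normalized* PCT and H2O2 concentrations (each series divided
# by its initial value), concatenated over all runs, minimized by
# Levenberg-Marquardt over log-transformed free parameters.  The rate laws
# depend on k4 and k5 only through their ratio, so at least one of the two
# should be held fixed for a well-posed problem; the package default fixes
# k4.

#' Model context for fitting
#'
#' Bundles everything the residual function needs besides the parameters.
#'
#' @param runs Named list of [experiment_run()]s covering every run id in
#'   the dataset.
#' @param geometry A [reactor_geometry()].
#' @param lvrpa_table An `lvrpa_table` (needed when any run is irradiated).
#' @return A list of class `model_context`.
#' @export
model_context <- function(runs, geometry = default_geometry(),
                          lvrpa_table = NULL) {
  if (is.null(names(runs)))
    names(runs) <- vapply(runs, `[[`, character(1), "run_id")
  structure(list(runs = runs, geometry = geometry,
                 lvrpa_table = lvrpa_table), class = "model_context")
}

#' Residual vector of normalized concentrations
#'
#' For each PCT and H2O2 observation, `(y_obs - y_model) / y0` with `y0`
#' the run's initial concentration of that species, concatenated in a
#' deterministic (run, species, time) order; iron and TOC series are
#' excluded from fitting.
#'
#' @param params A [kinetic_params()].
#' @param dataset Tidy measurement data frame (`run_id`, `species`,
#'   `time_min`, `conc_mg_L`).
#' @param context A [model_context()].
#' @param weights Optional named per-species weights on the normalized
#'   residuals (e.g. inverse measurement sd); default unweighted.
#' @return Numeric residual vector with a `key` attribute (data frame of
#'   run/species/time per entry).
#' @export
fit_residuals <- function(params, dataset, context, weights = NULL) {
  dat <- dataset[dataset$species %in% c("PCT", "H2O2"), , drop = FALSE]
  if (!is.null(dat$model_backed)) dat <- dat[dat$model_backed, , drop = FALSE]
  missing_runs <- setdiff(unique(dat$run_id), names(context$runs))
  if (length(missing_runs))
    stop("no run definition for: ", paste(missing_runs, collapse = ", "))
  run_ids <- names(context$runs)[names(context$runs) %in% unique(dat$run_id)]
  res <- lapply(run_ids, function(id) {
    run <- context$runs[[id]]
    d <- dat[dat$run_id == id, , drop = FALSE]
    d <- d[order(match(d$species, c("PCT", "H2O2")), d$time_min), ,
           drop = FALSE]
    sim <- simulate_run(run, params, context$geometry, context$lvrpa_table,
                        t_eval = sort(unique(d$time_min)))
    y0 <- c(PCT = run$c_pct_0, H2O2 = run$c_h2o2_0)
    if (any(y0 <= 0)) stop("normalization needs positive initial ",
                           "concentrations in run ", id)
    model <- ifelse(d$species == "PCT",
                    sim$c_pct_mg_L[match(d$time_min, sim$time_min)],
                    sim$c_h2o2_mg_L[match(d$time_min, sim$time_min)])
    w <- if (is.null(weights)) 1 else weights[d$species]
    list(r = w * (d$conc_mg_L - model) / y0[d$species],
         key = d[, c("run_id", "species", "time_min")])
  })
  out <- unlist(lapply(res, `[[`, "r"), use.names = FALSE)
  attr(out, "key") <- do.call(rbind, lapply(res, `[[`, "key"))
  out
}

#' Root mean square error of a normalized series, in percent
#'
#' `100 * sqrt(sum((y - y*)^2) / n)` between observed and predicted
#' normalized concentrations.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return RMSE in percent.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1L) stop("need at least one observation")
  100 * sqrt(mean((observed - predicted)^2))
}

#' Fit the kinetic constants to a multi-experiment dataset
#'
#' Levenberg-Marquardt minimization (via [minpack.lm::nls.lm]) of the
#' normalized-concentration residuals over the log-transformed free subset
#' of (k1, k3, k4, k5); `phi_bar` is always held at its configured value.
#' Log-parameterization enforces positivity without a constrained solver.
#'
#' @inheritParams fit_residuals
#' @param initial_guess A [kinetic_params()] start point.
#' @param fixed Character vector of parameters to hold fixed (default
#'   `"k4"`).  Freeing both `k4` and `k5` leaves only their ratio
#'   identified and triggers a warning.
#' @param control Passed to [minpack.lm::nls.lm.control].  The default
#'   tightens the step/objective tolerances to 1e-10 and enlarges the
#'   forward-difference scale (`epsfcn = 1e-8`, i.e. relative steps of
#'   about 1e-4): the Jacobian in the weakly identified k1 direction must
#'   be probed above the ODE solver's 1e-8 relative tolerance, or the
#'   finite differences measure integrator noise instead of sensitivity.
#' @return A list of class `fit_result`: `params`, `fixed_mask`,
#'   `residual_norm` (sum of squared residuals at the optimum),
#'   `rmse_by_species` (percent, on normalized concentrations), `n_obs`,
#'   `converged`, `non_identifiable`, `n_iter`, `message`.
#' @export
fit_kinetics <- function(dataset, context, initial_guess = kinetic_params(),
                         fixed = "k4", weights = NULL,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, gtol = 0,
                           epsfcn = 1e-8, maxiter = 500)) {
  all_k <- c("k1", "k3", "k4", "k5")
  if (!all(fixed %in% all_k)) stop("fixed must be a subset of k1, k3, k4, k5")
  free <- setdiff(all_k, fixed)
  if (!length(free)) stop("no free parameters to fit")
  if (all(c("k4", "k5") %in% free))
    warning("k4 and k5 are both free but only their ratio is identifiable; ",
            "fix one of them")

  as_params <- function(theta) {
    p <- unclass(initial_guess)
    p[free] <- exp(theta)
    do.call(kinetic_params, p)
  }
  n_res <- length(fit_residuals(initial_guess, dataset, context, weights))
  fn <- function(theta) {
    # a solver failure at an extreme trial point is treated as a large
    # residual so the optimizer backs off rather than aborting the fit
    tryCatch(
      as.numeric(fit_residuals(as_params(theta), dataset, context, weights)),
      error = function(e) rep(1e3, n_res))
  }
  theta0 <- log(unlist(unclass(initial_guess)[free]))
  opt <- minpack.lm::nls.lm(par = theta0, fn = fn, control = control)
  params_hat <- as_params(opt$par)
  r_hat <- fit_residuals(params_hat, dataset, context, weights)
  ssr <- sum(r_hat^2)

  # Sensitivity probe: a flat objective (e.g. a dataset with no catalyst)
  # carries no information about the parameters; flag rather than return a
  # silent pseudo-fit.
  probe <- vapply(seq_along(free), function(j) {
    th <- opt$par; th[j] <- th[j] + log(1.5)
    sum(fn(th)^2)
  }, numeric(1))
  non_identifiable <- all(abs(probe - ssr) <= 1e-14 * max(1, ssr))

  key <- attr(r_hat, "key")
  rmse_sp <- vapply(c(PCT = "PCT", H2O2 = "H2O2"), function(sp) {
    i <- key$species == sp
    if (!any(i)) return(NA_real_)
    100 * sqrt(mean(r_hat[i]^2))
  }, numeric(1))

  structure(list(
    params = params_hat,
    fixed_mask = fixed,
    residual_norm = ssr,
    rmse_by_species = rmse_sp,
    n_obs = nrow(key),
    converged = opt$info %in% 1:4 && !non_identifiable,
    non_identifiable = non_identifiable,
    n_iter = opt$niter,
    message = opt$message
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Kinetic fit (", x$n_obs, " observations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  if (x$non_identifiable) cat("  flat objective: parameters not identifiable\n")
  p <- x$params
  cat(sprintf("  k1 = %.4g  k3 = %.4g  k4 = %.4g  k5 = %.4g  (fixed: %s)\n",
              p$k1, p$k3, p$k4, p$k5, paste(x$fixed_mask, collapse = ", ")))
  cat(sprintf("  SSR = %.4g; RMSE%% PCT = %.3g, H2O2 = %.3g; %d iterations\n",
              x$residual_norm, x$rmse_by_species[["PCT"]],
              x$rmse_by_species[["H2O2"]], x$n_iter))
  invisible(x)
}
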