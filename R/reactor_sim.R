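# Well-stirred batch-recycle reactor mass balances.
#
#   dC/dt = R^T(C) + (V_irr / V_T) * phi_bar * <LVRPA>(C_Fe3) * tau(C),
#   C(0) = C0,
#
# integrated in mol L^-1 and seconds with a stiff solver; the boundary API
# speaks mg L^-1 and minutes (the units of the experimental design).  For
# dark runs the radiation term is identically zero.  Ferric photolysis and
# the Fenton step make the iron cycle fast relative to the 120-min horizon,
# hence the stiff integrator.

#' Definition of one experimental run
#'
#' @param run_id Identifier (e.g. "E1").
#' @param c_pct_0,c_h2o2_0,c_fe2_0 Initial concentrations, mg L^-1.
#' @param irradiated Logical: lamp on?
#' @param duration Run duration, min.
#' @param c_fe3_0 Initial ferric concentration, mg L^-1.  Defaults to 0:
#'   the catalyst is dosed as ferrous sulfate, so all iron starts ferrous.
#' @return An object of class `experiment_run`.
#' @export
experiment_run <- function(run_id, c_pct_0, c_h2o2_0, c_fe2_0,
                           irradiated = FALSE, duration = 120,
                           c_fe3_0 = 0) {
  if (any(c(c_pct_0, c_h2o2_0, c_fe2_0, c_fe3_0) < 0))
    stop("initial concentrations must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  structure(list(run_id = run_id, c_pct_0 = c_pct_0, c_h2o2_0 = c_h2o2_0,
                 c_fe2_0 = c_fe2_0, c_fe3_0 = c_fe3_0,
                 irradiated = isTRUE(irradiated), duration = duration),
            class = "experiment_run")
}

# Right-hand side in mol L^-1 and seconds.  lvrpa_fun maps ferric molarity
# to the volume-averaged LVRPA in Einstein L^-1 s^-1 (NULL for dark runs).
reactor_rhs <- function(t, y, parms) {
  state <- list(c_pct = max(y[1], 0), c_h2o2 = max(y[2], 0),
                c_fe2 = max(y[3], 0), c_fe3 = max(y[4], 0))
  lv <- if (is.null(parms$lvrpa_fun)) 0 else parms$lvrpa_fun(state$c_fe3)
  r <- total_rates(state, parms$params, lv, parms$v_ratio, smooth_eps = 1e-10)
  list(unname(r))
}

#' Simulate one reactor run
#'
#' Integrates the reactor balances with `deSolve::lsoda` (relative
#' tolerance 1e-8, absolute tolerance 1e-12 M) and returns the trajectory
#' at the requested output times.  The volume-averaged LVRPA is read from a
#' monotone interpolant of `lvrpa_table` at the instantaneous ferric
#' concentration; it is identically zero for dark runs.  Output
#' concentrations are clipped at zero (solver noise floor 1e-12 M).
#'
#' @param run An [experiment_run()].
#' @param params A [kinetic_params()].
#' @param geometry A [reactor_geometry()] (supplies V_irr / V_T).
#' @param lvrpa_table An `lvrpa_table` from [build_lvrpa_table()]; may be
#'   `NULL` for dark runs.
#' @param t_eval Output times, min, within `[0, duration]`.  Defaults to a
#'   1-min grid.
#' @return A `simulation_result`: a data frame with columns `time_min`,
#'   molar concentrations (`c_pct`, `c_h2o2`, `c_fe2`, `c_fe3`), their
#'   mg L^-1 counterparts (`*_mg_L`) and `lvrpa` (Einstein cm^-3 s^-1, 0
#'   when dark), with the run id as an attribute.
#' @export
simulate_run <- function(run, params, geometry = default_geometry(),
                         lvrpa_table = NULL, t_eval = NULL) {
  if (is.null(t_eval)) t_eval <- seq(0, run$duration, by = 1)
  if (any(t_eval < 0 | t_eval > run$duration))
    stop("t_eval must lie within [0, duration]")
  t_eval <- sort(unique(t_eval))

  y0 <- c(mg_per_L_to_molar(run$c_pct_0, "PCT"),
          mg_per_L_to_molar(run$c_h2o2_0, "H2O2"),
          mg_per_L_to_molar(run$c_fe2_0, "Fe2"),
          mg_per_L_to_molar(run$c_fe3_0, "Fe3"))
  lvrpa_fun <- if (run$irradiated) {
    if (is.null(lvrpa_table)) stop("irradiated run needs an lvrpa_table")
    lvrpa_interpolator(lvrpa_table)
  } else NULL

  times_s <- unique(c(0, t_eval * 60))
  parms <- list(params = params, v_ratio = geometry$v_irr / geometry$v_total,
                lvrpa_fun = lvrpa_fun)
  solve_with <- function(method) {
    sol <- NULL
    # capture the Fortran solver's console diagnostics; failures are
    # reported through the fallback/error path below
    utils::capture.output(sol <- withCallingHandlers(
      try(method(y = y0, times = times_s, func = reactor_rhs, parms = parms,
                 rtol = 1e-8, atol = 1e-12, maxsteps = 100000),
          silent = TRUE),
      warning = function(w) invokeRestart("muffleWarning")),
      type = "output")
    sol
  }
  sol <- solve_with(deSolve::lsoda)
  if (inherits(sol, "try-error") || nrow(sol) < length(times_s))
    sol <- solve_with(deSolve::vode)   # BDF fallback for harsh parameters
  if (inherits(sol, "try-error") || nrow(sol) < length(times_s)) {
    last_t <- if (inherits(sol, "try-error")) NA_real_ else
      max(sol[, 1]) / 60
    stop(sprintf("solver failure in run %s (last accepted time %.3f min)",
                 run$run_id, last_t))
  }
  sol <- sol[match(t_eval * 60, sol[, 1]), , drop = FALSE]
  conc <- pmax(sol[, 2:5, drop = FALSE], 0)        # clip solver noise floor
  out <- data.frame(
    time_min = t_eval,
    c_pct = conc[, 1], c_h2o2 = conc[, 2],
    c_fe2 = conc[, 3], c_fe3 = conc[, 4])
  out$c_pct_mg_L <- molar_to_mg_per_L(out$c_pct, "PCT")
  out$c_h2o2_mg_L <- molar_to_mg_per_L(out$c_h2o2, "H2O2")
  out$c_fe2_mg_L <- molar_to_mg_per_L(out$c_fe2, "Fe2")
  out$c_fe3_mg_L <- molar_to_mg_per_L(out$c_fe3, "Fe3")
  out$lvrpa <- if (is.null(lvrpa_fun)) 0 else lvrpa_fun(out$c_fe3) / 1000
  attr(out, "run_id") <- run$run_id
  class(out) <- c("simulation_result", class(out))
  out
}

#' Fixed-step RK4 reference integrator
#'
#' A classical 4th-order Runge-Kutta integration of the mass balances at a
#' fixed step, with the rate laws written out directly from the mechanism
#' (independent of [total_rates()] and of the stiff solver), used as a
#' cross-check of [simulate_run()] on short horizons.  Slow by
#' construction; not for production use.
#'
#' @inheritParams simulate_run
#' @param t_end Horizon, min.
#' @param dt Step size, s.
#' @return Named molar concentration vector at `t_end`.
#' @export
simulate_run_rk4 <- function(run, params, geometry = default_geometry(),
                             lvrpa_table = NULL, t_end = 10, dt = 1e-3) {
  y <- c(mg_per_L_to_molar(run$c_pct_0, "PCT"),
         mg_per_L_to_molar(run$c_h2o2_0, "H2O2"),
         mg_per_L_to_molar(run$c_fe2_0, "Fe2"),
         mg_per_L_to_molar(run$c_fe3_0, "Fe3"))
  lvrpa_fun <- if (run$irradiated) lvrpa_interpolator(lvrpa_table) else NULL
  v_ratio <- geometry$v_irr / geometry$v_total
  k1c <- params$k1; k3c <- params$k3; k4c <- params$k4; k5c <- params$k5
  phi <- params$phi_bar
  f <- function(y) {
    cp <- max(y[1], 0); ch <- max(y[2], 0)
    cf2 <- max(y[3], 0); cf3 <- max(y[4], 0)
    a <- k5c * cp; b <- k4c * ch; s <- a + b
    inv_d <- if (s > 0) a / s else 0     # 1/delta
    inv_r <- if (s > 0) b / s else 0     # 1/rho
    fen <- k1c * cf2 * ch
    g <- k3c * cf3 * ch
    photo <- if (is.null(lvrpa_fun)) 0 else
      v_ratio * phi * lvrpa_fun(cf3)
    c(-fen * inv_d - photo * inv_d,
      -fen * (1 + inv_r) - g - photo * inv_r,
      -fen + g + photo,
      fen - g - photo)
  }
  n_steps <- round(t_end * 60 / dt)
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  names(y) <- c("c_pct", "c_h2o2", "c_fe2", "c_fe3")
  pmax(y, 0)
}
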