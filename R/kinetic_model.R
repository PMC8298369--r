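# Reduced Fenton / photo-Fenton rate laws.
#
# Mechanism (HO* under the steady-state approximation, SSA):
#   1. Fe2+ + H2O2 -> Fe3+ + HO- + HO*          k1   (Fenton)
#   2. Fe(OH)2+ + hv -> Fe2+ + HO*              Phi  (photolysis, quantum yield)
#   3. Fe3+ + H2O2 -> Fe2+ + H+ + HO2*          k3   (Fenton-like, rate gamma)
#   4. H2O2 + HO* -> HO2* + H2O                 k4
#   5. PCT + HO* -> intermediates               k5
#
# The SSA collapses the radical balance into two partition factors:
# 1/delta is the fraction of HO* attacking PCT, 1/rho the fraction
# attacking H2O2, and 1/delta + 1/rho = 1 identically.  The photochemical
# term enters each species through the stoichiometric vector
# tau = (-1/delta, -1/rho, +1, -1).

#' Kinetic parameter set
#'
#' @param k1 Fenton rate constant, M^-1 s^-1.
#' @param k3 Fenton-like (ferric + peroxide) rate constant, M^-1 s^-1.
#' @param k4 HO* + H2O2 rate constant, M^-1 s^-1.
#' @param k5 HO* + PCT rate constant, M^-1 s^-1.
#' @param phi_bar Wavelength-averaged primary quantum yield of ferric
#'   photolysis, mol Einstein^-1.  A configuration constant of the package
#'   (default 0.21), used consistently for data generation and fitting.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1 = 147.29, k3 = 3.16, k4 = 7.00e7,
                           k5 = 3.58e9, phi_bar = 0.21) {
  p <- list(k1 = k1, k3 = k3, k4 = k4, k5 = k5, phi_bar = phi_bar)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                           is.na(v) || v <= 0, logical(1))]
  if (length(bad)) stop("kinetic parameters must be positive scalars: ",
                        paste(bad, collapse = ", "))
  structure(p, class = "kinetic_params")
}

#' Concentration state
#'
#' Molar concentrations of the four modelled species at one time point.
#'
#' @param c_pct,c_h2o2,c_fe2,c_fe3 Concentrations, mol L^-1 (>= 0).
#' @return An object of class `conc_state`.
#' @export
conc_state <- function(c_pct, c_h2o2, c_fe2, c_fe3) {
  s <- c(c_pct = c_pct, c_h2o2 = c_h2o2, c_fe2 = c_fe2, c_fe3 = c_fe3)
  if (any(s < 0)) stop("concentrations must be non-negative")
  structure(as.list(s), class = "conc_state")
}

# HO* partition fractions (1/delta, 1/rho).  Written in the sum form
# k5 C_PCT / (k5 C_PCT + k4 C_H2O2) so the degenerate limits are the
# continuous ones; when both sinks vanish there is no radical sink and
# both fractions are defined as 0 (no consumption).
#
# smooth_eps > 0 (mol/L) multiplies each fraction by c/(c + eps), turning
# the jump of the fractions at zero concentration into a Lipschitz ramp.
# The ODE layer uses eps = 1e-10 M: the bias is
# O(eps/c), i.e. below solver tolerance at any measurable concentration,
# while removing right-hand-side chattering when a species is exhausted.
partition_fractions <- function(state, params, smooth_eps = 0) {
  a <- params$k5 * state$c_pct
  b <- params$k4 * state$c_h2o2
  if (a + b <= 0) return(c(inv_delta = 0, inv_rho = 0))
  f <- c(inv_delta = a / (a + b), inv_rho = b / (a + b))
  if (smooth_eps > 0)
    f <- f * c(state$c_pct / (state$c_pct + smooth_eps),
               state$c_h2o2 / (state$c_h2o2 + smooth_eps))
  f
}

#' HO* partition factor toward PCT
#'
#' `delta = 1 + (k4/k5) C_H2O2 / C_PCT`; `1/delta` is the fraction of
#' hydroxyl radicals attacking PCT.
#'
#' @param state A [conc_state()] with `c_pct > 0`.
#' @param params A [kinetic_params()].
#' @return Dimensionless factor >= 1.
#' @export
delta <- function(state, params) {
  if (state$c_pct <= 0) stop("delta undefined at c_pct = 0")
  1 + (params$k4 / params$k5) * state$c_h2o2 / state$c_pct
}

#' HO* partition factor toward H2O2
#'
#' `rho = 1 + (k5/k4) C_PCT / C_H2O2`; `1/rho` is the fraction of hydroxyl
#' radicals attacking H2O2.  For any strictly positive state,
#' `1/delta + 1/rho = 1`.
#'
#' @param state A [conc_state()] with `c_h2o2 > 0`.
#' @param params A [kinetic_params()].
#' @return Dimensionless factor >= 1.
#' @export
rho <- function(state, params) {
  if (state$c_h2o2 <= 0) stop("rho undefined at c_h2o2 = 0")
  1 + (params$k5 / params$k4) * state$c_pct / state$c_h2o2
}

#' Fenton-like (dark iron-recycling) rate
#'
#' `gamma = k3 C_Fe3 C_H2O2`, the slow reduction of ferric iron by H2O2.
#'
#' @inheritParams delta
#' @return Rate in mol L^-1 s^-1.
#' @export
gamma_rate <- function(state, params) {
  params$k3 * state$c_fe3 * state$c_h2o2
}

#' Thermal (dark) reaction rate vector
#'
#' With the Fenton flux `F = k1 C_Fe2 C_H2O2` and the Fenton-like rate
#' `gamma`:
#'   r_PCT  = -F / delta
#'   r_H2O2 = -F (1 + 1/rho) - gamma
#'   r_Fe2  = -F + gamma
#'   r_Fe3  = +F - gamma
#' Iron is conserved by construction (r_Fe2 + r_Fe3 = 0).
#'
#' @inheritParams delta
#' @return Named numeric rate vector (`r_pct`, `r_h2o2`, `r_fe2`, `r_fe3`),
#'   mol L^-1 s^-1.
#' @param smooth_eps Optional regularization scale, mol L^-1: each
#'   partition fraction is damped by `c / (c + smooth_eps)` so the rate
#'   vector is Lipschitz across species exhaustion.  0 (default) gives the
#'   exact rate laws; the ODE layer passes 1e-10 M, two decades above its absolute tolerance.
#' @export
thermal_rates <- function(state, params, smooth_eps = 0) {
  pf <- partition_fractions(state, params, smooth_eps)
  f <- params$k1 * state$c_fe2 * state$c_h2o2
  g <- gamma_rate(state, params)
  c(r_pct = -f * pf[["inv_delta"]],
    r_h2o2 = -f * (1 + pf[["inv_rho"]]) - g,
    r_fe2 = -f + g,
    r_fe3 = f - g)
}

#' Total (thermal + photochemical) reaction rate vector
#'
#' Adds the radiation-activated channel,
#' `v_ratio * phi_bar * <LVRPA> * tau`, with stoichiometric vector
#' `tau = (-1/delta, -1/rho, +1, -1)`: the photolysis of Fe(OH)2+
#' regenerates Fe2+ and yields one extra HO*, which partitions over PCT and
#' H2O2 exactly like the thermal radicals.
#'
#' @inheritParams delta
#' @param lvrpa_vol_avg Volume-averaged LVRPA, Einstein L^-1 s^-1 (>= 0).
#' @param v_ratio Irradiated-to-total volume ratio V_irr / V_T in (0, 1].
#' @inheritParams thermal_rates
#' @return Named numeric rate vector, mol L^-1 s^-1.
#' @export
total_rates <- function(state, params, lvrpa_vol_avg, v_ratio,
                        smooth_eps = 0) {
  if (lvrpa_vol_avg < 0) stop("LVRPA must be non-negative")
  if (v_ratio <= 0 || v_ratio > 1) stop("v_ratio must lie in (0, 1]")
  r <- thermal_rates(state, params, smooth_eps)
  pf <- partition_fractions(state, params, smooth_eps)
  photo <- v_ratio * params$phi_bar * lvrpa_vol_avg
  r + photo * c(-pf[["inv_delta"]], -pf[["inv_rho"]], 1, -1)
}
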