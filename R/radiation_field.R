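# LSSE radiation field: local and volume-averaged LVRPA.
#
# The lamp is modelled as a line source with spherical, isotropic emission
# (LSSE).  At a point (r, z) of the annulus (z measured along the lamp axis
# from the lamp's bottom end), the monochromatic LVRPA is
#
#   e_lambda^a(r, z) = kappa_lambda * P_lambda,s / (2 pi L_L) *
#                      Int_{theta2}^{theta1} exp(-kappa_T,lambda (r - r_int) / cos theta) d theta
#
# with limiting angles theta1 = atan(r / (L_L - z)) >= 0 and
# theta2 = atan(-r / z) <= 0.  The theta integral runs from theta2 to
# theta1 (the orientation giving a positive integral).  Summing over the
# useful wavelengths (300-420 nm) and averaging over the irradiated annulus
# gives the driving force of the photochemical step.
#
# Units: kappa in cm^-1 (napierian), P_lambda,s in Einstein min^-1 nm^-1
# (converted to s^-1 internally), LVRPA in Einstein cm^-3 s^-1.

#' Limiting angles of the LSSE integral
#'
#' @param r Radial position, cm (> 0).
#' @param z Axial position measured from the lamp's bottom end, cm, in
#'   `[0, lamp_length]`.
#' @param lamp_length Useful lamp length, cm.
#' @return `c(theta1, theta2)` in radians, `theta1 >= 0 >= theta2`; the
#'   degenerate ends z = 0 and z = lamp_length give -pi/2 and +pi/2 as
#'   limits.
#' @export
limiting_angles <- function(r, z, lamp_length) {
  if (r <= 0) stop("r must be strictly positive")
  if (z < 0 || z > lamp_length) stop("z must lie within the lamp length")
  theta1 <- atan2(r, lamp_length - z)   # atan(r/(L_L - z)), = pi/2 at z = L_L
  theta2 <- -atan2(r, z)                # atan(-r/z), = -pi/2 at z = 0
  c(theta1 = theta1, theta2 = theta2)
}

#' Total volumetric absorption coefficient of the medium
#'
#' At pH 2.8 the ferric hydroxo complex Fe(OH)2+ is the dominant ferric
#' species and the only significant absorber above 300 nm; its
#' concentration is taken equal to the total ferric concentration.
#'
#' @param c_fe3 Ferric concentration, mol L^-1.
#' @param lambda Wavelength(s), nm, within the table coverage.
#' @param table An [absorptivity_table()].
#' @return kappa_T in cm^-1 (napierian), linearly interpolated in lambda.
#' @export
total_absorption_coeff <- function(c_fe3, lambda, table) {
  if (any(c_fe3 < 0)) stop("c_fe3 must be non-negative")
  rng <- range(table$wavelengths)
  if (any(lambda < rng[1] | lambda > rng[2]))
    stop("wavelength outside absorptivity table coverage")
  alpha <- stats::approx(table$wavelengths, table$molar_absorptivity,
                         xout = lambda)$y
  alpha * c_fe3
}

#' Local monochromatic LVRPA (LSSE model)
#'
#' Spectral LVRPA density at a point of the annulus, by adaptive quadrature
#' of the LSSE integral (relative tolerance 1e-8).
#'
#' @param r Radial position, cm, within `[r_int, r_ext]`.
#' @param z Axial position along the lamp, cm.
#' @param lambda Wavelength, nm (used to read the lamp spectral power).
#' @param kappa Volumetric absorption coefficient of the absorbing reacting
#'   species at `lambda`, cm^-1.
#' @param kappa_T Total volumetric absorption coefficient of the medium at
#'   `lambda`, cm^-1.
#' @param geometry A [reactor_geometry()].
#' @param spectrum A [lamp_spectrum()].
#' @return Spectral LVRPA, Einstein cm^-3 s^-1 nm^-1.
#' @export
lvrpa_local <- function(r, z, lambda, kappa, kappa_T, geometry, spectrum) {
  if (r < geometry$r_int || r > geometry$r_ext)
    stop("r outside the annulus")
  if (kappa < 0 || kappa_T < 0) stop("absorption coefficients must be >= 0")
  if (kappa == 0) return(0)
  p_s <- stats::approx(spectrum$wavelengths, spectrum$spectral_photon_power,
                       xout = lambda)$y / 60   # Einstein s^-1 nm^-1
  th <- limiting_angles(r, z, geometry$lamp_length)
  d <- r - geometry$r_int
  I <- stats::integrate(function(theta) exp(-kappa_T * d / cos(theta)),
                        lower = th["theta2"], upper = th["theta1"],
                        rel.tol = 1e-8)$value
  kappa * p_s / (2 * pi * geometry$lamp_length) * I
}

# Composite Simpson weights for n (odd) points spanning [0, 1].
simpson_weights <- function(n) {
  if (n < 3L || n %% 2L == 0L) stop("Simpson rule needs an odd n >= 3")
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w / (3 * (n - 1))
}

# Trapezoid weights for an arbitrary ascending grid.
trapez_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(0)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2; w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Volume-averaged polychromatic LVRPA
#'
#' Averages the wavelength-summed LVRPA over the irradiated annulus,
#'
#'   (2 pi / V_irr) Int_0^h Int_{r_int}^{r_ext} sum_lambda e_lambda^a r dr dz,
#'
#' on a tensor product of composite-Simpson grids in r, z and theta with a
#' trapezoid sum over the lamp's wavelength grid.
#'
#' @inheritParams lvrpa_local
#' @param c_fe3 Ferric concentration, mol L^-1.
#' @param table An [absorptivity_table()].
#' @param nr,nz,ntheta Odd Simpson node counts (defaults 33, 33, 65).
#' @param check Richardson check: if `TRUE`, recompute with all node counts
#'   doubled and error if the result moves by 0.5% or more.
#' @return Volume-averaged LVRPA, Einstein cm^-3 s^-1.
#' @export
lvrpa_volume_average <- function(c_fe3, geometry, spectrum, table,
                                 nr = 33L, nz = 33L, ntheta = 65L,
                                 check = FALSE) {
  if (c_fe3 < 0) stop("c_fe3 must be non-negative")
  if (c_fe3 == 0) return(0)
  val <- lvrpa_vavg_grid(c_fe3, geometry, spectrum, table, nr, nz, ntheta)
  if (check) {
    val2 <- lvrpa_vavg_grid(c_fe3, geometry, spectrum, table,
                            2L * nr + 1L, 2L * nz + 1L, 2L * ntheta + 1L)
    if (abs(val2 - val) > 0.005 * abs(val2))
      stop("volume-average quadrature not converged at requested grid")
    val <- val2
  }
  val
}

lvrpa_vavg_grid <- function(c_fe3, geometry, spectrum, table, nr, nz, ntheta) {
  g <- geometry
  r <- seq(g$r_int, g$r_ext, length.out = nr)
  za <- seq(0, g$h_irr, length.out = nz)            # height within annulus
  zl <- g$lamp_offset + za                          # lamp axial coordinate
  wr <- simpson_weights(nr) * (g$r_ext - g$r_int)
  wz <- simpson_weights(nz) * g$h_irr
  u <- seq(0, 1, length.out = ntheta)
  wu <- simpson_weights(ntheta)

  theta1 <- outer(r, g$lamp_length - zl, function(ri, dz) atan2(ri, dz))
  theta2 <- -outer(r, zl, function(ri, zi) atan2(ri, zi))
  span <- theta1 - theta2                           # nr x nz, > 0

  # theta nodes: dim (nr, nz, ntheta); optical path factor d/cos(theta)
  theta <- array(0, dim = c(nr, nz, ntheta))
  for (k in seq_len(ntheta)) theta[, , k] <- theta2 + span * u[k]
  d <- r - g$r_int
  path <- array(d, dim = c(nr, nz, ntheta)) / cos(theta)

  wl <- spectrum$wavelengths
  p_s <- spectrum$spectral_photon_power / 60       # Einstein s^-1 nm^-1
  wlam <- trapez_weights(wl)
  kappa <- total_absorption_coeff(c_fe3, wl, table)  # cm^-1, per lambda

  S <- matrix(0, nr, nz)                           # sum_lambda e_lambda^a
  for (l in seq_along(wl)) {
    if (kappa[l] == 0 || p_s[l] == 0) next
    ex <- exp(-kappa[l] * path)
    I <- span * apply(sweep(ex, 3, wu, `*`), c(1, 2), sum)
    S <- S + wlam[l] * kappa[l] * p_s[l] / (2 * pi * g$lamp_length) * I
  }
  v_irr_cm3 <- g$v_irr * 1000
  (2 * pi / v_irr_cm3) * sum((wr * r) * S %*% wz)
}

#' Tabulate the volume-averaged LVRPA on a ferric-concentration grid
#'
#' @param grid_mg_L Ascending ferric concentrations starting at 0, mg L^-1.
#' @inheritParams lvrpa_volume_average
#' @param ... Passed to [lvrpa_volume_average()] (grid sizes, `check`).
#' @return An object of class `lvrpa_table` with fields `fe3_mg_L`,
#'   `fe3_molar` and `lvrpa` (Einstein cm^-3 s^-1).  The tabulated curve is
#'   checked to be strictly increasing and concave (self-shielding).
#' @export
build_lvrpa_table <- function(grid_mg_L, geometry, spectrum, table, ...) {
  if (any(diff(grid_mg_L) <= 0)) stop("grid must be strictly ascending")
  if (grid_mg_L[1] != 0) stop("grid must start at 0")
  fe3_molar <- mg_per_L_to_molar(grid_mg_L, "Fe3")
  lv <- vapply(fe3_molar, lvrpa_volume_average, numeric(1),
               geometry = geometry, spectrum = spectrum, table = table, ...)
  if (length(lv) > 1L && any(diff(lv) <= 0))
    stop("tabulated LVRPA is not strictly increasing")
  if (length(lv) > 2L && any(diff(lv, differences = 2) > 1e-12 * max(lv)))
    stop("tabulated LVRPA is not concave")
  structure(list(fe3_mg_L = grid_mg_L, fe3_molar = fe3_molar, lvrpa = lv),
            class = "lvrpa_table")
}

#' Interpolator of the volume-averaged LVRPA for the ODE layer
#'
#' Monotone piecewise-cubic (Hyman-filtered) interpolation of the tabulated
#' volume average versus ferric molarity; beyond the last node the curve is
#' extended linearly with the terminal slope, and negative arguments clamp
#' to zero.  Note the unit change: the table stores Einstein cm^-3 s^-1,
#' the returned function yields Einstein L^-1 s^-1 (x 1000), the basis the
#' reactor balances use.
#'
#' @param table An `lvrpa_table`.
#' @return `function(c_fe3_molar) -> Einstein L^-1 s^-1`, vectorized.
#' @export
lvrpa_interpolator <- function(table) {
  x <- table$fe3_molar
  y <- table$lvrpa * 1000                          # Einstein L^-1 s^-1
  n <- length(x)
  if (n == 1L) return(function(c) rep(y[1], length(c)))
  f <- stats::splinefun(x, y, method = if (n >= 3L) "hyman" else "monoH.FC")
  xmax <- x[n]
  slope_end <- f(xmax, deriv = 1)
  function(c_fe3) {
    c_fe3 <- pmax(c_fe3, 0)
    ifelse(c_fe3 > xmax, y[n] + slope_end * (c_fe3 - xmax), f(c_fe3))
  }
}

#' @export
print.lvrpa_table <- function(x, ...) {
  cat("Volume-averaged LVRPA table (Einstein cm^-3 s^-1)\n")
  print(data.frame(fe3_mg_L = x$fe3_mg_L, lvrpa = signif(x$lvrpa, 4)))
  invisible(x)
}
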