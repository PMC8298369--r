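# LSSE radiation field: limiting angles, local LVRPA, volume averaging.

test_that("limiting angles are symmetric at midpoint and degenerate at the ends", {
  th <- limiting_angles(5, 29.49, 58.98)
  expect_equal(unname(th["theta1"]), atan(5 / 29.49), tolerance = 1e-10)
  expect_equal(unname(th["theta1"]), 0.1679, tolerance = 1e-3)
  expect_equal(unname(th["theta2"]), -unname(th["theta1"]))
  expect_equal(unname(limiting_angles(5, 0, 58.98)["theta2"]), -pi / 2)
  expect_equal(unname(limiting_angles(5, 58.98, 58.98)["theta1"]), pi / 2)
  expect_error(limiting_angles(0, 1, 58.98), "positive")
  expect_error(limiting_angles(5, 60, 58.98), "within")
})

test_that("absorption coefficient is linear in concentration and exact at grid nodes", {
  tab <- fix_absorptivity()
  expect_identical(total_absorption_coeff(0, c(310, 395), tab), c(0, 0))
  wl <- tab$wavelengths[7]
  c1 <- 1e-4
  expect_equal(total_absorption_coeff(c1, wl, tab),
               tab$molar_absorptivity[7] * c1)   # node lookup is exact
  expect_equal(total_absorption_coeff(2 * c1, 333, tab),
               2 * total_absorption_coeff(c1, 333, tab))
  expect_error(total_absorption_coeff(c1, 500, tab), "coverage")
})

test_that("local LVRPA matches the optically thin closed form and a brute-force quadrature", {
  g <- fix_geometry()
  sp <- fix_spectrum()
  r <- 5; z <- 25; lam <- 360
  th <- limiting_angles(r, z, g$lamp_length)
  p_s <- approx(sp$wavelengths, sp$spectral_photon_power, lam)$y / 60

  expect_identical(lvrpa_local(r, z, lam, 0, 0, g, sp), 0)

  # kappa_T = 0: integral reduces to the angular span
  kap <- 0.02
  thin <- kap * p_s * (th["theta1"] - th["theta2"]) /
    (2 * pi * g$lamp_length)
  expect_equal(lvrpa_local(r, z, lam, kap, 0, g, sp), unname(thin),
               tolerance = 1e-10)

  # midpoint-rule oracle at 1e6 theta steps, attenuating medium
  kap_T <- 0.15
  n <- 1e6
  theta <- seq(th["theta2"], th["theta1"], length.out = n + 1)
  mid <- (theta[-1] + theta[-(n + 1)]) / 2
  I <- sum(exp(-kap_T * (r - g$r_int) / cos(mid))) * diff(theta[1:2])
  oracle <- kap * p_s / (2 * pi * g$lamp_length) * I
  expect_equal(lvrpa_local(r, z, lam, kap, kap_T, g, sp), unname(oracle),
               tolerance = 1e-6)

  expect_error(lvrpa_local(10, z, lam, kap, kap_T, g, sp), "annulus")
})

test_that("volume-averaged LVRPA vanishes without absorber and is monotone concave", {
  tab <- fix_lvrpa_table()
  expect_identical(tab$lvrpa[1], 0)
  expect_true(all(diff(tab$lvrpa) > 0))
  expect_true(all(diff(tab$lvrpa, differences = 2) <= 0))
  # self-shielding: absorbed photons per unit absorber strictly decreasing
  eff <- tab$lvrpa[-1] / tab$fe3_mg_L[-1]
  expect_true(all(diff(eff) < 0))
})

test_that("volume average obeys the optically thin closed form and the energy bound", {
  g <- fix_geometry()
  sp <- fix_spectrum()
  ab <- fix_absorptivity()

  # energy bound: absorbed power in the annulus never exceeds lamp output
  tab <- fix_lvrpa_table()
  emitted <- sp$total_photon_power / 60              # Einstein s^-1
  expect_true(all(tab$lvrpa * g$v_irr * 1000 <= emitted))

  # optically thin: kappa_T * (r_ext - r_int) ~ 5e-5, so the exponential
  # can be replaced by 1; independent closed-form oracle on a fine grid
  c_thin <- 1e-8
  kap_max <- max(total_absorption_coeff(c_thin, ab$wavelengths, ab))
  expect_lt(kap_max * (g$r_ext - g$r_int), 1e-3)
  nr <- 201; nz <- 201
  r <- seq(g$r_int, g$r_ext, length.out = nr)
  za <- seq(0, g$h_irr, length.out = nz) + g$lamp_offset
  span <- outer(r, za, function(ri, zi)
    atan2(ri, g$lamp_length - zi) + atan2(ri, zi))
  wr <- rep(1, nr); wr[c(1, nr)] <- 0.5
  wz <- rep(1, nz); wz[c(1, nz)] <- 0.5
  hr <- (g$r_ext - g$r_int) / (nr - 1); hz <- g$h_irr / (nz - 1)
  span_int <- sum((wr * r) * span %*% wz) * hr * hz
  wl <- sp$wavelengths
  wlam <- diff(wl)
  wlam <- c(wlam[1] / 2, (wlam[-1] + wlam[-length(wlam)]) / 2,
            wlam[length(wlam)] / 2)
  kappa <- total_absorption_coeff(c_thin, wl, ab)
  p_s <- sp$spectral_photon_power / 60
  closed <- sum(wlam * kappa * p_s) / (2 * pi * g$lamp_length) *
    (2 * pi / (g$v_irr * 1000)) * span_int
  expect_equal(lvrpa_volume_average(c_thin, g, sp, ab), closed,
               tolerance = 1e-4)
})

test_that("volume-average quadrature is converged: doubling the grid moves it < 0.5%", {
  g <- fix_geometry(); sp <- fix_spectrum(); ab <- fix_absorptivity()
  c10 <- mg_per_L_to_molar(10, "Fe3")
  v1 <- lvrpa_volume_average(c10, g, sp, ab)
  v2 <- lvrpa_volume_average(c10, g, sp, ab, nr = 67L, nz = 67L,
                             ntheta = 131L)
  expect_lt(abs(v2 - v1) / v2, 0.005)
  # and the built-in Richardson check passes
  expect_no_error(lvrpa_volume_average(c10, g, sp, ab, check = TRUE))
})

test_that("LVRPA table construction validates its inputs and interpolates exactly at nodes", {
  g <- fix_geometry(); sp <- fix_spectrum(); ab <- fix_absorptivity()
  expect_error(build_lvrpa_table(c(0, 5, 2.5), g, sp, ab), "ascending")
  expect_error(build_lvrpa_table(c(2.5, 5), g, sp, ab), "start at 0")
  tab0 <- build_lvrpa_table(0, g, sp, ab)
  expect_identical(tab0$lvrpa, 0)
  expect_identical(lvrpa_interpolator(tab0)(c(0, 1e-4)), c(0, 0))

  tab <- fix_lvrpa_table()
  f <- lvrpa_interpolator(tab)
  expect_equal(f(tab$fe3_molar), tab$lvrpa * 1000, tolerance = 1e-12)
  # extrapolation beyond the grid continues with the terminal slope
  xm <- tab$fe3_molar[5]
  slope <- (f(xm) - f(xm - 1e-9)) / 1e-9
  expect_equal(f(xm + 1e-5), f(xm) + slope * 1e-5, tolerance = 1e-4)
  # negative arguments clamp to zero concentration
  expect_identical(f(-1e-6), f(0))
})

test_that("spectrum and absorptivity CSV round trips preserve the tables", {
  sp <- fix_spectrum()
  f <- withr_local_tempfile()
  write.csv(data.frame(wavelength_nm = sp$wavelengths,
                       photon_power_einstein_per_min_per_nm =
                         sp$spectral_photon_power), f, row.names = FALSE)
  sp2 <- read_spectrum_csv(f)
  expect_equal(sp2$total_photon_power, 3.36e-4, tolerance = 1e-6)
  expect_equal(sp2$wavelengths, sp$wavelengths)

  ab <- fix_absorptivity()
  f2 <- withr_local_tempfile()
  write.csv(data.frame(wavelength_nm = ab$wavelengths,
                       molar_absorptivity_per_M_per_cm =
                         ab$molar_absorptivity), f2, row.names = FALSE)
  expect_equal(read_absorptivity_csv(f2)$molar_absorptivity,
               ab$molar_absorptivity)
  # decadic input is converted to the napierian basis
  expect_equal(read_absorptivity_csv(f2, decadic = TRUE)$molar_absorptivity,
               ab$molar_absorptivity * log(10))
  expect_error(read_spectrum_csv(f2), "columns")
})
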