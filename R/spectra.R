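# Lamp emission spectrum and ferric-complex absorptivity tables.
#
# Both are two-column tables on the photochemically useful window
# 300-420 nm.  The molar absorptivity table must be on the naperian
# (base-e) volumetric basis; decadic literature values are converted with
# `decadic = TRUE`.

#' Lamp spectral photon emission
#'
#' @param wavelengths Ascending wavelength grid, nm, covering 300--420 nm.
#' @param spectral_photon_power Spectral photon emission P_lambda,s at each
#'   grid point, Einstein min^-1 nm^-1 (all non-negative).
#' @return An object of class `lamp_spectrum` with the trapezoid-integrated
#'   `total_photon_power` (Einstein min^-1).
#' @export
lamp_spectrum <- function(wavelengths, spectral_photon_power) {
  if (length(wavelengths) != length(spectral_photon_power))
    stop("grid/value length mismatch")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be ascending")
  if (any(spectral_photon_power < 0)) stop("spectral power must be >= 0")
  total <- trapz(wavelengths, spectral_photon_power)
  structure(list(wavelengths = wavelengths,
                 spectral_photon_power = spectral_photon_power,
                 total_photon_power = total),
            class = "lamp_spectrum")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Synthetic actinic-BL-like lamp spectrum
#'
#' A smooth unimodal photon-emission curve on 300--420 nm (Gaussian shape
#' centred at 365 nm, the emission maximum of actinic blacklight phosphors),
#' normalized so the total photon power equals the actinometric value of
#' the pilot lamp, E = 3.36e-4 Einstein min^-1.  Synthetic: shipped so every
#' radiation-field computation is self-contained; it is not the
#' manufacturer's measured spectrum.
#'
#' @param total_photon_power Total photon power, Einstein min^-1.
#' @param n Number of grid points.
#' @return A `lamp_spectrum`.
#' @export
synthetic_lamp_spectrum <- function(total_photon_power = 3.36e-4, n = 25L) {
  wl <- seq(300, 420, length.out = n)
  shape <- exp(-0.5 * ((wl - 365) / 22)^2)
  lamp_spectrum(wl, shape * total_photon_power / trapz(wl, shape))
}

#' Molar absorptivity table for the ferric hydroxo complex
#'
#' Fe(OH)2+ is the dominant ferric species at pH 2.8 and the principal
#' radiation absorber of the system; H2O2 and Fe2+ absorption is neglected
#' above 300 nm.
#'
#' @param wavelengths Ascending grid, nm, covering 300--420 nm.
#' @param molar_absorptivity Molar (napierian) absorptivity, M^-1 cm^-1.
#' @param decadic If `TRUE` the supplied values are decadic (base-10)
#'   absorptivities and are multiplied by ln(10).
#' @return An object of class `absorptivity_table`.
#' @export
absorptivity_table <- function(wavelengths, molar_absorptivity,
                               decadic = FALSE) {
  if (length(wavelengths) != length(molar_absorptivity))
    stop("grid/value length mismatch")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be ascending")
  if (any(molar_absorptivity < 0)) stop("absorptivity must be >= 0")
  if (decadic) molar_absorptivity <- molar_absorptivity * log(10)
  structure(list(wavelengths = wavelengths,
                 molar_absorptivity = molar_absorptivity),
            class = "absorptivity_table")
}

#' Synthetic Fe(OH)2+ absorptivity table
#'
#' A smooth decreasing absorptivity curve on 300--420 nm with the magnitude
#' of literature ferric hydroxo-complex spectra (hundreds of M^-1 cm^-1 near
#' 300 nm, decaying towards the visible).  Synthetic: a self-contained
#' stand-in for the literature table, adequate for every structural and
#' property check; quantitative reproduction of measured volume-averaged
#' absorption values requires the actual literature spectrum as CSV.
#'
#' @param n Number of grid points.
#' @return An `absorptivity_table` (napierian basis).
#' @export
synthetic_absorptivity_table <- function(n = 25L) {
  wl <- seq(300, 420, length.out = n)
  alpha <- 1400 * exp(-(wl - 300) / 28)
  absorptivity_table(wl, alpha)
}

#' Read a lamp spectrum CSV
#'
#' @param path CSV with header columns `wavelength_nm`,
#'   `photon_power_einstein_per_min_per_nm`.
#' @return A `lamp_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("wavelength_nm", "photon_power_einstein_per_min_per_nm")
  if (!all(need %in% names(x)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "))
  lamp_spectrum(x$wavelength_nm, x$photon_power_einstein_per_min_per_nm)
}

#' Read an absorptivity CSV
#'
#' @param path CSV with header columns `wavelength_nm`,
#'   `molar_absorptivity_per_M_per_cm` (napierian basis).
#' @param decadic Set `TRUE` if the file stores decadic values.
#' @return An `absorptivity_table`.
#' @export
read_absorptivity_csv <- function(path, decadic = FALSE) {
  x <- utils::read.csv(path)
  need <- c("wavelength_nm", "molar_absorptivity_per_M_per_cm")
  if (!all(need %in% names(x)))
    stop("absorptivity CSV must have columns: ", paste(need, collapse = ", "))
  absorptivity_table(x$wavelength_nm, x$molar_absorptivity_per_M_per_cm,
                     decadic = decadic)
}
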