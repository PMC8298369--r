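# Stoichiometry, unit conversions and scalar process metrics.
#
# The mineralization stoichiometry of paracetamol (PCT) by hydrogen peroxide,
#   C8H9NO2 + 21 H2O2 -> 8 CO2 + 25 H2O + H+ + NO3-,
# frames the whole experimental design: the oxidant dose, the molar ratio R
# and the TOC equivalent of a PCT solution all derive from it.

#' Built-in species table
#'
#' Molar masses (IUPAC 2021 standard atomic weights) and carbon counts for
#' the species of the paracetamol Fenton / photo-Fenton system.  Users may
#' extend or override rows via [read_species_csv()].
#'
#' @format A data frame with columns `name`, `molar_mass` (g mol^-1) and
#'   `carbon_atoms` (integer).
#' @export
species_table <- function() {
  data.frame(
    name = c("PCT", "H2O2", "Fe2", "Fe3", "FeTOT", "C"),
    molar_mass = c(151.16, 34.01, 55.85, 55.85, 55.85, 12.011),
    carbon_atoms = c(8L, 0L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Read a user species table
#'
#' @param path CSV with columns `name`, `molar_mass_g_mol`, `carbon_atoms`.
#'   Rows replace or extend the built-in table.
#' @return A species data frame as in [species_table()].
#' @export
read_species_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "molar_mass_g_mol", "carbon_atoms")
  if (!all(need %in% names(x)))
    stop("species CSV must have columns: ", paste(need, collapse = ", "))
  if (any(x$molar_mass_g_mol <= 0)) stop("molar_mass_g_mol must be > 0")
  user <- data.frame(name = x$name, molar_mass = x$molar_mass_g_mol,
                     carbon_atoms = as.integer(x$carbon_atoms),
                     stringsAsFactors = FALSE)
  base <- species_table()
  rbind(user, base[!base$name %in% user$name, ])
}

species_info <- function(name, table = species_table()) {
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown species: ", name)
  table[i, ]
}

#' Convert a mass concentration to molarity
#'
#' @param conc Concentration in mg L^-1 (non-negative).
#' @param species Species name (row of [species_table()]) or a one-row
#'   species data frame.
#' @return Concentration in mol L^-1.
#' @examples
#' mg_per_L_to_molar(40, "PCT")   # 2.646e-4 M
#' @export
mg_per_L_to_molar <- function(conc, species) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (is.character(species)) species <- species_info(species)
  conc / (1000 * species$molar_mass)
}

#' Convert a molarity to mass concentration (mg L^-1)
#' @inheritParams mg_per_L_to_molar
#' @param conc_molar Concentration in mol L^-1.
#' @export
molar_to_mg_per_L <- function(conc_molar, species) {
  if (is.character(species)) species <- species_info(species)
  conc_molar * 1000 * species$molar_mass
}

#' Stoichiometric hydrogen peroxide dose for total mineralization
#'
#' 21 mol of H2O2 per mol of PCT, from the mineralization stoichiometry.
#'
#' @param c_pct Initial PCT concentration, mg L^-1.
#' @return H2O2 dose in mg L^-1 (189 mg L^-1 for 40 mg L^-1 PCT).
#' @export
stoichiometric_h2o2_dose <- function(c_pct) {
  if (any(c_pct < 0)) stop("concentration must be non-negative")
  m_pct <- species_info("PCT")$molar_mass
  m_h2o2 <- species_info("H2O2")$molar_mass
  21 * (c_pct / m_pct) * m_h2o2
}

#' Initial molar ratio R = H2O2 : PCT
#'
#' @param c_h2o2,c_pct Initial concentrations in mg L^-1; `c_pct` must be
#'   strictly positive.
#' @return Dimensionless molar ratio (10.5, 21 or 42 in the canonical design).
#' @export
molar_ratio_R <- function(c_h2o2, c_pct) {
  if (any(c_pct <= 0)) stop("c_pct must be strictly positive")
  if (any(c_h2o2 < 0)) stop("c_h2o2 must be non-negative")
  mg_per_L_to_molar(c_h2o2, "H2O2") / mg_per_L_to_molar(c_pct, "PCT")
}

#' Total organic carbon equivalent of a PCT solution
#'
#' Eight carbon atoms per PCT molecule; 40 mg L^-1 PCT carries about
#' 25.4 mg C L^-1.
#'
#' @param c_pct PCT concentration, mg L^-1.
#' @return TOC in mg C L^-1.
#' @export
toc_equivalent <- function(c_pct) {
  if (any(c_pct < 0)) stop("concentration must be non-negative")
  c_pct * 8 * species_info("C")$molar_mass / species_info("PCT")$molar_mass
}

#' Specific consumption of the oxidizing agent
#'
#' Milligrams of H2O2 consumed per milligram of TOC mineralized over the
#' reaction window; a process-efficiency metric (lower is more efficient).
#'
#' @param h2o2_t0,h2o2_tf H2O2 at start / end, mg L^-1.
#' @param toc_t0,toc_tf TOC at start / end, mg L^-1; requires
#'   `toc_t0 > toc_tf` (some mineralization occurred).
#' @return mg H2O2 per mg TOC.
#' @export
specific_oxidant_consumption <- function(h2o2_t0, h2o2_tf, toc_t0, toc_tf) {
  if (any(toc_t0 <= toc_tf))
    stop("no mineralization: toc_t0 must exceed toc_tf")
  (h2o2_t0 - h2o2_tf) / (toc_t0 - toc_tf)
}

#' Time to fall below a detection threshold
#'
#' First time at which a sampled concentration trajectory drops below a
#' threshold (e.g. the 0.15 mg L^-1 HPLC detection limit for PCT).  By
#' default the crossing is located by linear interpolation between the
#' bracketing samples; `interpolate = FALSE` returns the first sampling
#' instant at which the value is below the threshold.
#'
#' @param times Sampling times in min, strictly increasing.
#' @param values Concentrations at `times`, mg L^-1.
#' @param threshold Detection threshold, mg L^-1.
#' @param interpolate Interpolate between samples (default) or report the
#'   first sample below.
#' @return Time in min, or `NA_real_` if the trajectory never goes below.
#' @export
removal_time <- function(times, values, threshold, interpolate = TRUE) {
  if (length(times) == 0L) stop("empty trajectory")
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  below <- values < threshold
  if (!any(below)) return(NA_real_)
  i <- which(below)[1L]
  if (i == 1L) return(times[1L])
  if (!interpolate) return(times[i])
  # linear crossing between sample i-1 (>= threshold) and i (< threshold)
  t0 <- times[i - 1L]; t1 <- times[i]
  y0 <- values[i - 1L]; y1 <- values[i]
  t0 + (y0 - threshold) * (t1 - t0) / (y0 - y1)
}
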