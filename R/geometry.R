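# Reactor geometry for the annular photoreactor.

#' Annular photoreactor geometry
#'
#' Constructs and validates the geometry of the irradiated annulus around
#' the axial lamp.  Lengths in cm, volumes in L.  The irradiated annulus is
#' assumed centred axially on the lamp unless `lamp_offset` is given.
#'
#' @param r_int Inner radius of the annular liquid (outer radius of the
#'   inner cylinder), cm.
#' @param r_ext Outer radius of the annular liquid (inner radius of the
#'   outer cylinder), cm.
#' @param h_irr Irradiated annular height, cm.
#' @param lamp_length Useful lamp length L_L, cm.
#' @param lamp_offset Axial position of the bottom of the irradiated
#'   section, measured from the lamp's bottom end, cm.  Default centres the
#'   annulus on the lamp.
#' @param v_irr Irradiated volume, L.
#' @param v_total Total liquid volume of the recirculation system, L.
#' @return An object of class `reactor_geometry`.
#' @export
reactor_geometry <- function(r_int, r_ext, h_irr, lamp_length,
                             lamp_offset = (lamp_length - h_irr) / 2,
                             v_irr, v_total) {
  if (!(r_int > 0 && r_int < r_ext)) stop("need 0 < r_int < r_ext")
  if (h_irr > lamp_length) stop("h_irr must not exceed lamp_length")
  if (lamp_offset < 0 || lamp_offset + h_irr > lamp_length)
    stop("irradiated section must lie within the lamp length")
  v_annulus <- pi * (r_ext^2 - r_int^2) * h_irr / 1000  # L
  if (abs(v_annulus - v_irr) / v_irr > 0.01)
    stop(sprintf("annular volume %.4f L disagrees with v_irr %.4f L by > 1%%",
                 v_annulus, v_irr))
  if (v_irr >= v_total) stop("v_irr must be smaller than v_total")
  structure(list(r_int = r_int, r_ext = r_ext, h_irr = h_irr,
                 lamp_length = lamp_length, lamp_offset = lamp_offset,
                 v_irr = v_irr, v_total = v_total),
            class = "reactor_geometry")
}

#' Default pilot-plant geometry
#'
#' The 15-L batch-recycle system: a 6-L annular glass photoreactor
#' (irradiated annulus r 3.5--7.0 cm, height 13 cm, irradiated volume
#' 1.5 L) around a 58.98-cm actinic lamp, plus a 9-L reservoir tank.
#'
#' @return A `reactor_geometry`.
#' @export
default_geometry <- function() {
  reactor_geometry(r_int = 3.5, r_ext = 7.0, h_irr = 13,
                   lamp_length = 58.98, v_irr = 1.5, v_total = 15)
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat("Annular photoreactor geometry\n")
  cat(sprintf("  annulus: r %.2f-%.2f cm, height %.2f cm (V_irr %.2f L)\n",
              x$r_int, x$r_ext, x$h_irr, x$v_irr))
  cat(sprintf("  lamp: length %.2f cm, annulus offset %.2f cm\n",
              x$lamp_length, x$lamp_offset))
  cat(sprintf("  total volume: %.1f L (V_irr/V_T = %.3f)\n",
              x$v_total, x$v_irr / x$v_total))
  invisible(x)
}
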