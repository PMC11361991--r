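#' Mechanical parameters of the coupled respiratory model
#'
#' Lumped resistances and compliances of the two-compartment chest wall
#' (rib cage and abdomen, separated by the diaphragm), the lung, and the
#' pleural coupling, plus the body cross-sectional area used to convert
#' displaced abdominal volume into diaphragm displacement. Defaults are the
#' reference simulation values of the model (all strictly positive):
#' resistances in cmH2O/(L·s), compliances in L/cmH2O, area in m^2.
#'
#' @param r_rc,r_ab,r_l Resistances of rib cage, abdomen and lung,
#'   cmH2O/(L·s).
#' @param c_rc,c_ab,c_l,c_pl Compliances of rib cage, abdomen, lung and
#'   pleural cavity, L/cmH2O.
#' @param a_di Body cross-sectional area, m^2; approximately weight (kg)
#'   divided by height (m).
#'
#' @return An object of class `mech_params`: a named list of the eight
#'   parameters.
#' @examples
#' p <- mech_params()
#' p$c_ab * 3  # steady-state abdominal volume (L) under 3 cmH2O
#' @export
mech_params <- function(r_rc = 1, r_ab = 1, r_l = 2,
                        c_rc = 0.2, c_ab = 0.4, c_l = 0.2, c_pl = 0.25,
                        a_di = 0.08) {
  p <- list(r_rc = r_rc, r_ab = r_ab, r_l = r_l,
            c_rc = c_rc, c_ab = c_ab, c_l = c_l, c_pl = c_pl,
            a_di = a_di)
  for (nm in names(p)) check_positive_scalar(p[[nm]], nm)
  structure(p, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params>\n")
  cat(sprintf("  R_rc=%g R_ab=%g R_l=%g cmH2O/(L.s)\n", x$r_rc, x$r_ab, x$r_l))
  cat(sprintf("  C_rc=%g C_ab=%g C_l=%g C_pl=%g L/cmH2O\n",
              x$c_rc, x$c_ab, x$c_l, x$c_pl))
  cat(sprintf("  A_di=%g m^2\n", x$a_di))
  invisible(x)
}

is_mech_params <- function(x) inherits(x, "mech_params")

as_mech_params <- function(x) {
  if (is_mech_params(x)) return(x)
  do.call(mech_params, as.list(x))
}
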