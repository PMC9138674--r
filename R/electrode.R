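#' Electrode and well geometry for an ECIS array
#'
#' Describes one well of an 8-well ECIS array: the sensing-electrode geometry
#' and the cell-free electrode-electrolyte interface. The interface is modelled
#' as a constant-phase element (CPE) in series with a solution/constriction
#' resistance, the standard equivalent circuit for a gold microelectrode in
#' culture medium. The specific (area-normalized) CPE impedance is
#' \eqn{Z_n(\omega) = A (j\omega)^{-n}} with magnitude `cpe_magnitude` = A
#' (ohm cm^2 s^-n) and exponent `cpe_exponent` = n in (0, 1].
#'
#' The shipped presets are tuned so the cell-free whole-well resistance at
#' 40 kHz is 2000 ohm for the single-electrode array (8W1E) and 300 ohm for
#' the ten-electrode array (8W10E), the values used to size the electric-fence
#' current (1 mA and 6 mA, both giving about 2 V across a cell-free well).
#'
#' @param array_type `"8W1E"` (one 250-um electrode per well) or `"8W10E"`
#'   (ten electrodes in parallel).
#' @param electrode_radius_um Sensing-electrode radius in micrometres.
#' @param n_electrodes Number of electrodes per well (1 or 10). Defaults from
#'   `array_type`.
#' @param well_area_cm2 Well bottom area in cm^2 (geometry metadata only).
#' @param cpe_magnitude CPE coefficient A in ohm cm^2 s^-n; `NULL` solves A so
#'   the whole-well 40 kHz resistance equals `r40k_target_ohm`.
#' @param cpe_exponent CPE exponent n in (0, 1]; n = 1 is a pure capacitor.
#' @param r_solution_ohm Series solution/constriction (plus lead) resistance in
#'   ohm. Defaults per array type.
#' @param medium_resistivity_ohm_cm Culture-medium resistivity rho (ohm cm).
#' @param r40k_target_ohm Cell-free whole-well resistance at 40 kHz used to
#'   solve `cpe_magnitude` when it is not given.
#'
#' @return An object of class `ecis_electrode`: a list with the fields above
#'   plus `area_cm2` (total sensing area).
#' @examples
#' el <- electrode_spec("8W1E")
#' Re(well_impedance(40000, el))  # ~2000 ohm
#' @export
electrode_spec <- function(array_type = c("8W1E", "8W10E"),
                           electrode_radius_um = 125,
                           n_electrodes = NULL,
                           well_area_cm2 = 0.8,
                           cpe_magnitude = NULL,
                           cpe_exponent = 0.9,
                           r_solution_ohm = NULL,
                           medium_resistivity_ohm_cm = 54,
                           r40k_target_ohm = NULL) {
  array_type <- match.arg(array_type)
  if (is.null(n_electrodes)) {
    n_electrodes <- if (array_type == "8W1E") 1L else 10L
  }
  if (!n_electrodes %in% c(1L, 10L)) {
    stop("`n_electrodes` must be 1 (8W1E) or 10 (8W10E)", call. = FALSE)
  }
  if (electrode_radius_um <= 0) stop("`electrode_radius_um` must be > 0", call. = FALSE)
  if (cpe_exponent <= 0 || cpe_exponent > 1) {
    stop("`cpe_exponent` must lie in (0, 1]", call. = FALSE)
  }
  if (medium_resistivity_ohm_cm <= 0) {
    stop("`medium_resistivity_ohm_cm` must be > 0", call. = FALSE)
  }
  area_single <- pi * (electrode_radius_um * 1e-4)^2   # cm^2
  area_total <- n_electrodes * area_single
  if (is.null(r_solution_ohm)) {
    r_solution_ohm <- if (array_type == "8W1E") 1800 else 280
  }
  if (is.null(r40k_target_ohm)) {
    r40k_target_ohm <- if (array_type == "8W1E") 2000 else 300
  }
  if (is.null(cpe_magnitude)) {
    # Solve A so that Re(Z_well) at 40 kHz hits the target:
    # Re(A (j w)^-n)/area + r_s = target
    w <- 2 * pi * 40000
    r_if <- r40k_target_ohm - r_solution_ohm
    if (r_if <= 0) stop("`r40k_target_ohm` must exceed `r_solution_ohm`", call. = FALSE)
    cpe_magnitude <- r_if * area_total * w^cpe_exponent / cos(cpe_exponent * pi / 2)
  }
  if (cpe_magnitude <= 0) stop("`cpe_magnitude` must be > 0", call. = FALSE)
  structure(
    list(
      array_type = array_type,
      electrode_radius_um = electrode_radius_um,
      n_electrodes = as.integer(n_electrodes),
      well_area_cm2 = well_area_cm2,
      area_cm2 = area_total,
      cpe_magnitude = cpe_magnitude,
      cpe_exponent = cpe_exponent,
      r_solution_ohm = r_solution_ohm,
      medium_resistivity_ohm_cm = medium_resistivity_ohm_cm
    ),
    class = "ecis_electrode"
  )
}

#' @export
print.ecis_electrode <- function(x, ...) {
  cat("<ecis_electrode> ", x$array_type,
      ": ", x$n_electrodes, " x r=", x$electrode_radius_um, " um",
      ", area ", signif(x$area_cm2, 4), " cm^2",
      ", CPE A=", signif(x$cpe_magnitude, 5), " n=", x$cpe_exponent,
      ", Rsol=", signif(x$r_solution_ohm, 5), " ohm\n", sep = "")
  invisible(x)
}

#' Morphological parameters of a cell-covered electrode
#'
#' The three parameters the cell-electrode model resolves from a frequency
#' scan: junctional resistance between adjacent cells `rb_ohm_cm2` (Rb,
#' ohm cm^2), average cell-substrate separation `h_nm` (h, nm) and specific
#' membrane capacitance `cm_uf_cm2` (Cm, uF/cm^2), together with the cell
#' radius `rc_um` (rc, um) and medium resistivity rho needed to relate h to
#' the model's constraint parameter \eqn{\alpha = r_c \sqrt{\rho / h}}
#' (ohm^1/2 cm). Give either `h_nm` or `alpha`; the other is derived.
#'
#' @param rb_ohm_cm2 Junctional resistance Rb (ohm cm^2), >= 0.
#' @param h_nm Cell-substrate separation h (nm), > 0 (or `NULL` if `alpha`
#'   given; `h_nm = 0`/`alpha = 0` jointly encode the no-constraint limit).
#' @param cm_uf_cm2 Membrane capacitance Cm (uF/cm^2), > 0.
#' @param rc_um Cell radius (um), > 0.
#' @param rho_ohm_cm Medium resistivity (ohm cm), > 0.
#' @param alpha Constraint parameter alpha (ohm^1/2 cm); alternative to `h_nm`.
#'
#' @return An object of class `ecis_cells` with fields `rb_ohm_cm2`, `alpha`,
#'   `h_nm`, `cm_uf_cm2`, `rc_um`, `rho_ohm_cm`.
#' @examples
#' cells <- cell_params(rb_ohm_cm2 = 1.7267, h_nm = 49.1535,
#'                      cm_uf_cm2 = 1, rc_um = 11.72)
#' cells$alpha
#' @export
cell_params <- function(rb_ohm_cm2, h_nm = NULL, cm_uf_cm2 = 1,
                        rc_um = 11.72, rho_ohm_cm = 54, alpha = NULL) {
  if (rb_ohm_cm2 < 0) stop("`rb_ohm_cm2` must be >= 0", call. = FALSE)
  if (cm_uf_cm2 <= 0) stop("`cm_uf_cm2` must be > 0", call. = FALSE)
  if (rc_um <= 0 || rho_ohm_cm <= 0) stop("`rc_um` and `rho_ohm_cm` must be > 0", call. = FALSE)
  if (is.null(h_nm) && is.null(alpha)) stop("give `h_nm` or `alpha`", call. = FALSE)
  if (!is.null(h_nm) && !is.null(alpha)) stop("give only one of `h_nm`, `alpha`", call. = FALSE)
  if (is.null(alpha)) {
    if (h_nm < 0) stop("`h_nm` must be >= 0", call. = FALSE)
    alpha <- if (h_nm == 0) Inf else h_to_alpha(h_nm, rho_ohm_cm, rc_um)
    if (h_nm == 0) alpha <- 0  # h = 0 used as the degenerate no-cell limit marker
  } else {
    if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
    h_nm <- if (alpha == 0) 0 else alpha_to_h(alpha, rho_ohm_cm, rc_um)
  }
  structure(
    list(rb_ohm_cm2 = rb_ohm_cm2, alpha = alpha, h_nm = h_nm,
         cm_uf_cm2 = cm_uf_cm2, rc_um = rc_um, rho_ohm_cm = rho_ohm_cm),
    class = "ecis_cells"
  )
}

#' @export
print.ecis_cells <- function(x, ...) {
  cat("<ecis_cells> Rb=", signif(x$rb_ohm_cm2, 5), " ohm cm^2",
      ", h=", signif(x$h_nm, 5), " nm (alpha=", signif(x$alpha, 5), ")",
      ", Cm=", signif(x$cm_uf_cm2, 5), " uF/cm^2",
      ", rc=", x$rc_um, " um\n", sep = "")
  invisible(x)
}

#' Convert between cell-substrate separation h and constraint parameter alpha
#'
#' The disc-cell model's constraint parameter is
#' \eqn{\alpha = r_c \sqrt{\rho / h}}, equivalently \eqn{h = \rho r_c^2 /
#' \alpha^2}: current flowing radially in the thin film of medium between the
#' ventral membrane and the substrate sees a resistance set by the film height
#' h, the medium resistivity rho and the cell radius rc.
#'
#' @param alpha Constraint parameter (ohm^1/2 cm), > 0.
#' @param h_nm Separation (nm), > 0.
#' @param rho_ohm_cm Medium resistivity (ohm cm), > 0.
#' @param rc_um Cell radius (um), > 0.
#' @return `alpha_to_h()` returns h in nm; `h_to_alpha()` returns alpha in
#'   ohm^1/2 cm. The pair is an exact inverse round trip.
#' @examples
#' a <- h_to_alpha(49.1535, 54, 11.72)
#' alpha_to_h(a, 54, 11.72)  # 49.1535
#' @export
alpha_to_h <- function(alpha, rho_ohm_cm = 54, rc_um = 11.72) {
  stopifnot(all(alpha > 0), rho_ohm_cm > 0, rc_um > 0)
  rc_cm <- rc_um * 1e-4
  h_cm <- rho_ohm_cm * rc_cm^2 / alpha^2
  h_cm * 1e7   # cm -> nm
}

#' @rdname alpha_to_h
#' @export
h_to_alpha <- function(h_nm, rho_ohm_cm = 54, rc_um = 11.72) {
  stopifnot(all(h_nm > 0), rho_ohm_cm > 0, rc_um > 0)
  rc_cm <- rc_um * 1e-4
  rc_cm * sqrt(rho_ohm_cm / (h_nm * 1e-7))
}
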