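# Closed-form physico-chemical calculators used alongside the impedance
# readouts: zeta potential, alamarBlue reduction / relative adhesion,
# electric-fence voltage, cell radius from spread area.

EPSILON0_F_PER_M <- 8.8541878128e-12

#' Zeta potential from a streaming-potential slope
#'
#' Helmholtz-Smoluchowski relation
#' \eqn{\zeta = \frac{\eta \lambda}{\varepsilon_0 \varepsilon_r}
#' \frac{\Delta E}{\Delta P}}: the streaming-potential slope dE/dP measured
#' across the sample channel, scaled by electrolyte viscosity and
#' conductivity over permittivity. SI units in, millivolts out; linear in
#' the slope. Electrolyte defaults are for 10 mM NaCl at 25 C (the
#' instrument's electrolyte constants are rarely reported; override as
#' needed).
#'
#' @param dE_dP Streaming-potential slope (V/Pa); may be a vector.
#' @param eta_pa_s Electrolyte dynamic viscosity (Pa s), > 0.
#' @param lambda_s_m Electrolyte conductivity (S/m), > 0.
#' @param eps_r Relative permittivity (dimensionless), > 0.
#' @return Zeta potential in mV (same sign as `dE_dP`).
#' @examples
#' zeta_potential(2e-7)
#' @export
zeta_potential <- function(dE_dP, eta_pa_s = 8.9e-4, lambda_s_m = 0.1265,
                           eps_r = 78.5) {
  if (eta_pa_s <= 0 || lambda_s_m <= 0 || eps_r <= 0) {
    stop("`eta_pa_s`, `lambda_s_m` and `eps_r` must all be > 0", call. = FALSE)
  }
  zeta_v <- (eta_pa_s * lambda_s_m / (EPSILON0_F_PER_M * eps_r)) * dE_dP
  zeta_v * 1e3
}

#' Percent reduction of alamarBlue reagent
#'
#' \eqn{100 (E - N) / (P - N)} from the 570/590 nm fluorescence of the
#' experimental well (E), the negative control (reagent + medium, no cells,
#' N) and the positive control (fully reduced reagent, P). Inputs recycle in
#' the usual vectorized way.
#'
#' @param experimental_rfu,negative_rfu,positive_rfu Fluorescence readings
#'   (RFU).
#' @return Percent reduction (0 at the negative control, 100 at the
#'   positive).
#' @examples
#' alamar_reduction(55, 10, 110)
#' @export
alamar_reduction <- function(experimental_rfu, negative_rfu, positive_rfu) {
  if (any(positive_rfu == negative_rfu)) {
    stop("positive and negative control RFU must differ", call. = FALSE)
  }
  100 * (experimental_rfu - negative_rfu) / (positive_rfu - negative_rfu)
}

#' Initial adhesion relative to a control substrate
#'
#' Divides each substrate's alamarBlue reduction (or any adhesion proxy) by
#' the control's value, so the control maps to exactly 1.
#'
#' @param reductions Named numeric vector of per-substrate values, or a data
#'   frame with columns `substrate` and `reduction_pct`.
#' @param control Name of the control substrate (must be present, value > 0).
#' @return Tibble with columns `substrate`, `reduction_pct`,
#'   `relative_adhesion`.
#' @examples
#' relative_adhesion(c(collagen = 59.705, control = 50.0), "control")
#' @export
relative_adhesion <- function(reductions, control = "control") {
  if (is.data.frame(reductions)) {
    v <- reductions$reduction_pct
    names(v) <- reductions$substrate
    reductions <- v
  }
  if (is.null(names(reductions)) || !control %in% names(reductions)) {
    stop("control substrate '", control, "' not found among the inputs",
         call. = FALSE)
  }
  ref <- reductions[[control]]
  if (ref <= 0) stop("control value must be > 0", call. = FALSE)
  tibble::tibble(
    substrate = names(reductions),
    reduction_pct = unname(reductions),
    relative_adhesion = unname(reductions) / ref
  )
}

#' Electric-fence pulse schedule for an array type
#'
#' The fencing protocol: trains of 3 successive sinusoidal pulses every
#' 5 min at a 40 kHz carrier, 200 ms on / 200 ms off, at 1 mA (8W1E) or 6 mA
#' (8W10E) - currents sized so a cell-free well (about 2000 and 300 ohm at
#' 40 kHz) sees roughly 2 V.
#'
#' @param array_type `"8W1E"` or `"8W10E"`.
#' @param fence_off_h Time (h, from inoculation) at which the fence is
#'   switched off.
#' @return A list of class `ecis_fence` with the schedule fields.
#' @export
fence_schedule <- function(array_type = c("8W1E", "8W10E"), fence_off_h = 10) {
  array_type <- match.arg(array_type)
  if (fence_off_h < 0) stop("`fence_off_h` must be >= 0", call. = FALSE)
  structure(
    list(
      array_type = array_type,
      current_ma = if (array_type == "8W1E") 1 else 6,
      carrier_hz = 40000,
      pulses_per_interval = 3L,
      interval_min = 5,
      pulse_on_ms = 200,
      pulse_off_ms = 200,
      fence_off_h = fence_off_h
    ),
    class = "ecis_fence"
  )
}

#' Voltage across a cell-free well under the fence current
#'
#' Ohm's law with the milliamp fence current: V = I R. The protocol check:
#' 2000 ohm x 1 mA = 2.0 V and 300 ohm x 6 mA = 1.8 V, both "approximately
#' 2 V", the level that excludes cell attachment without harming the
#' coating.
#'
#' @param well_resistance_ohm Cell-free well resistance at the carrier
#'   frequency (ohm), > 0.
#' @param current_ma Fence current (mA), or an `ecis_fence` schedule.
#' @return Voltage in volts.
#' @examples
#' ef_voltage(2000, 1)
#' ef_voltage(300, fence_schedule("8W10E"))
#' @export
ef_voltage <- function(well_resistance_ohm, current_ma) {
  if (inherits(current_ma, "ecis_fence")) current_ma <- current_ma$current_ma
  if (any(well_resistance_ohm <= 0)) {
    stop("`well_resistance_ohm` must be > 0", call. = FALSE)
  }
  well_resistance_ohm * current_ma * 1e-3
}

#' Cell radius from spread area
#'
#' \eqn{r_c = \sqrt{A_c / \pi}}: the equivalent circular radius of the
#' optically measured spread cell area.
#'
#' @param area_um2 Cell area (um^2), >= 0.
#' @return Radius in um.
#' @examples
#' radius_from_area(pi * 13.39^2)
#' @export
radius_from_area <- function(area_um2) {
  if (any(area_um2 < 0)) stop("`area_um2` must be >= 0", call. = FALSE)
  sqrt(area_um2 / pi)
}
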