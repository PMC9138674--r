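# Forward impedance model of ECIS electrodes.
#
# Conventions: specific impedances are area-normalized (ohm cm^2); whole-well
# impedances are in ohm. Series-equivalent readout channels follow the
# instrument: R = Re(Z), C = -1/(w Im(Z)).

#' Bracket term (z/2) I0(z) / I1(z) of the disc-cell model
#'
#' Modified-Bessel ratio appearing in the cell-covered electrode impedance,
#' evaluated for complex argument. Uses the power-series ratio for
#' moderate |z|, a Lentz continued fraction beyond, and the large-argument
#' asymptotic ratio for very large |z|, so the term is finite and accurate
#' from z = 0 (value 1) up to |z| ~ 1e3 and beyond without overflow.
#'
#' @param z Complex vector (the model evaluates it at gamma rc).
#' @return Complex vector of the same length; value 1 at z = 0.
#' @keywords internal
#' @export
bessel_bracket <- function(z) {
  vapply(z, bessel_bracket1, complex(1))
}

bessel_bracket1 <- function(z) {
  az <- Mod(z)
  if (az == 0) return(1 + 0i)
  if (az <= 12) {
    # (z/2) I0/I1 = sum q^k/(k!)^2 / sum q^k/(k!(k+1)!), q = z^2/4
    q <- z * z / 4
    num_t <- den_t <- 1 + 0i
    num <- den <- 1 + 0i
    for (k in 1:400) {
      num_t <- num_t * q / (k * k)
      den_t <- den_t * q / (k * (k + 1))
      num <- num + num_t
      den <- den + den_t
      if (Mod(num_t) < 1e-18 * Mod(num) && Mod(den_t) < 1e-18 * Mod(den)) break
    }
    return(num / den)
  }
  if (az <= 1e4) {
    # I0/I1 = 2/z + 1/(4/z + 1/(6/z + ...)) from the three-term recurrence;
    # modified Lentz evaluation.
    tiny <- 1e-30
    f <- 2 / z
    if (Mod(f) == 0) f <- tiny
    C <- f
    D <- 0 + 0i
    for (k in 2:500) {
      b <- 2 * k / z
      D <- b + D
      if (Mod(D) == 0) D <- tiny
      C <- b + 1 / C
      if (Mod(C) == 0) C <- tiny
      D <- 1 / D
      delta <- C * D
      f <- f * delta
      if (Mod(delta - 1) < 1e-16) break
    }
    return(z * f / 2)
  }
  # asymptotic I_nu(z) ~ e^z/sqrt(2 pi z) * (1 - (4nu^2-1)/(8z) + ...)
  zi <- 1 / z
  num <- 1 + zi * (1 / 8 + zi * (9 / 128 + zi * 75 / 1024))
  den <- 1 - zi * (3 / 8 + zi * (15 / 128 + zi * 105 / 1024))
  z * num / (2 * den)
}

#' Specific impedance of the cell-free electrode
#'
#' Constant-phase-element interface: \eqn{Z_n(\omega) = A (j\omega)^{-n}}
#' (ohm cm^2) with A = `cpe_magnitude` and n = `cpe_exponent` from the
#' electrode spec. With n = 1 this is a pure interfacial capacitance
#' \eqn{1/(j\omega C)} with specific capacitance C = 1/A.
#'
#' @param freq_hz Frequency vector (Hz), > 0.
#' @param electrode An [electrode_spec()].
#' @return Complex specific impedance (ohm cm^2), one value per frequency.
#' @examples
#' cell_free_impedance(4000, electrode_spec("8W1E"))
#' @export
cell_free_impedance <- function(freq_hz, electrode) {
  stopifnot(inherits(electrode, "ecis_electrode"))
  if (any(freq_hz <= 0)) stop("`freq_hz` must be > 0", call. = FALSE)
  w <- 2 * pi * freq_hz
  n <- electrode$cpe_exponent
  electrode$cpe_magnitude * w^(-n) * exp(complex(imaginary = -n * pi / 2))
}

membrane_impedance <- function(freq_hz, cm_uf_cm2) {
  # apical + basal membranes in series, purely capacitive: Zm = 2/(j w Cm)
  w <- 2 * pi * freq_hz
  2 / complex(imaginary = w * cm_uf_cm2 * 1e-6)
}

#' Specific impedance of the cell-covered electrode
#'
#' Disc-cell solution for a confluent layer of radius-`rc` cells over the
#' electrode. Current reaching the electrode under a cell either couples
#' capacitively through the two membranes or flows radially in the thin
#' cell-substrate film and out through the intercellular junctions, giving
#' \deqn{\frac{1}{Z_c} = \frac{1}{Z_n}\left[\frac{Z_n}{Z_n+Z_m} +
#'   \frac{Z_m/(Z_n+Z_m)}{\frac{\gamma r_c}{2}\frac{I_0(\gamma r_c)}
#'   {I_1(\gamma r_c)} + R_b\left(\frac{1}{Z_n}+\frac{1}{Z_m}\right)}\right]}
#' with \eqn{\gamma r_c = \alpha\sqrt{1/Z_n + 1/Z_m}},
#' \eqn{Z_m = 2/(j\omega C_m)} and \eqn{I_0, I_1} modified Bessel functions
#' of complex argument. At Rb = 0 and alpha = 0 the bracket collapses to 1
#' and the cell-free impedance is recovered.
#'
#' @inheritParams cell_free_impedance
#' @param cells A [cell_params()].
#' @return Complex specific impedance (ohm cm^2), one value per frequency.
#' @examples
#' el <- electrode_spec("8W1E")
#' cells <- cell_params(rb_ohm_cm2 = 1.7267, h_nm = 49.1535,
#'                      cm_uf_cm2 = 1, rc_um = 11.72)
#' cell_covered_impedance(4000, el, cells)
#' @export
cell_covered_impedance <- function(freq_hz, electrode, cells) {
  stopifnot(inherits(electrode, "ecis_electrode"), inherits(cells, "ecis_cells"))
  if (any(freq_hz <= 0)) stop("`freq_hz` must be > 0", call. = FALSE)
  zn <- cell_free_impedance(freq_hz, electrode)
  zm <- membrane_impedance(freq_hz, cells$cm_uf_cm2)
  ysum <- 1 / zn + 1 / zm
  grc <- cells$alpha * sqrt(ysum)
  bracket <- zn / (zn + zm) +
    (zm / (zn + zm)) / (bessel_bracket(grc) + cells$rb_ohm_cm2 * ysum)
  zn / bracket
}

#' Whole-well impedance at partial cell coverage
#'
#' Mixes the cell-free and cell-covered specific admittances in proportion to
#' the covered area fraction (electrically a parallel circuit of the two
#' regions), scales by the total sensing area and adds the series solution
#' resistance:
#' \eqn{Z_{well} = 1/\{A_{tot}[(1-c)/Z_n + c/Z_c]\} + R_{sol}}.
#'
#' @inheritParams cell_covered_impedance
#' @param cells A [cell_params()], or `NULL` for a cell-free well.
#' @param coverage Covered area fraction in \[0, 1\].
#' @return Complex whole-well impedance (ohm), one value per frequency.
#' @examples
#' el <- electrode_spec("8W1E")
#' Re(well_impedance(40000, el))   # about 2000 ohm cell-free
#' @export
well_impedance <- function(freq_hz, electrode, cells = NULL, coverage = 1) {
  stopifnot(inherits(electrode, "ecis_electrode"))
  if (coverage < 0 || coverage > 1) stop("`coverage` must be in [0, 1]", call. = FALSE)
  zn <- cell_free_impedance(freq_hz, electrode)
  if (is.null(cells) || coverage == 0) {
    zspec <- zn
  } else {
    zc <- cell_covered_impedance(freq_hz, electrode, cells)
    zspec <- if (coverage == 1) zc else 1 / ((1 - coverage) / zn + coverage / zc)
  }
  zspec / electrode$area_cm2 + electrode$r_solution_ohm
}

#' Series-equivalent resistance and capacitance channels
#'
#' Converts complex impedance to the two channels the instrument reports:
#' series resistance R = Re(Z) (ohm) and series capacitance
#' C = -1/(w Im(Z)), returned in nF.
#'
#' @param z Complex impedance (ohm).
#' @param freq_hz Frequency (Hz) at which `z` was measured.
#' @return A tibble with columns `resistance_ohm` and `capacitance_nf`.
#' @export
impedance_channels <- function(z, freq_hz) {
  w <- 2 * pi * freq_hz
  tibble::tibble(
    resistance_ohm = Re(z),
    capacitance_nf = -1e9 / (w * Im(z))
  )
}

#' Default 25-point frequency grid of the scan mode
#'
#' Log-spaced from 31.25 Hz to 100 kHz inclusive.
#' @param n Number of frequencies.
#' @return Numeric vector of frequencies (Hz), strictly increasing.
#' @export
scan_frequencies <- function(n = 25) {
  exp(seq(log(31.25), log(1e5), length.out = n))
}
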