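---
title: "Models and methods behind ecisfence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecisfence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecisfence)
```

# The measurement and the quantities

Electric cell-substrate impedance sensing (ECIS) grows cells on small gold
electrodes (250 µm diameter, one per well in 8W1E arrays or ten in 8W10E) and
measures the complex impedance of each well with a weak AC current. The
electric-fence (EF) protocol keeps one electrode cell-free with repeated
high-current pulse trains (3 sinusoidal pulses per 5 min, 200 ms on/off,
40 kHz carrier, 1 mA for 8W1E and 6 mA for 8W10E) while the surrounding
monolayer grows to confluence; when the fence is switched off, cells migrate
inward over the intact coating and the well resistance rises. The package
implements the quantitative readouts of this protocol:

* **Attachment kinetics** from the 64 kHz series-capacitance channel:
  capacitance falls approximately linearly with electrode coverage at high
  frequency, so the slope of its decline, `Sc = |-dC/dt|`, measures the
  spreading rate, taken between fixed thresholds (3 and 1.5 on the nF channel
  for 8W1E, 30 and 10 for 8W10E) to avoid the settling and plateau phases.
* **Migration kinetics** from the 4 kHz resistance channel after fence-off:
  the regression slope `Sr = |dR/dt|` of the rise between the cell-free
  baseline and the confluent plateau, and the halfway recovery time `T50`.
* **Morphology** from 25-point frequency scans (31.25 Hz–100 kHz): the
  cell-electrode model resolves junctional resistance `Rb` (Ω·cm²),
  cell-substrate separation `h` (nm) and membrane capacitance `Cm` (µF/cm²).
* **Micromotion** from rapid time collection (RTC, 2048 points at 1 s,
  4 kHz): the Var32 fluctuation statistic.
* **Closed forms**: Helmholtz–Smoluchowski zeta potential, alamarBlue percent
  reduction and relative adhesion, the EF voltage check `V = I·R`, and the
  equivalent cell radius `rc = sqrt(Ac/pi)`.

# The cell-electrode impedance model

The cell-free electrode–electrolyte interface is a constant-phase element in
series with a solution/constriction resistance: the specific impedance is
`Zn(w) = A (jw)^(-n)` (Ω·cm²), with `n = 0.9` by default and `A` solved in
closed form so that the whole-well 40 kHz resistance equals the protocol's
sizing values (2000 Ω for 8W1E with `Rsol = 1800` Ω; 300 Ω for 8W10E, which
shares the specific interface over ten times the area with `Rsol = 280` Ω).
A useful side-check of these defaults: the implied cell-free 64 kHz series
capacitance of an 8W1E well is ~3 nF, which is also the cell-free level the
attachment generator uses.

A confluent layer of disc-shaped cells of radius `rc` over the electrode
adds two current paths: capacitive coupling through the apical and basal
membranes, `Zm = 2/(jw Cm)`, and radial flow through the thin film of medium
(height `h`, resistivity `rho`) under the cells and out through the
intercellular junctions (`Rb`). The resulting specific impedance is

$$\frac{1}{Z_c} = \frac{1}{Z_n}\left[\frac{Z_n}{Z_n+Z_m} +
 \frac{Z_m/(Z_n+Z_m)}{\frac{\gamma r_c}{2}\frac{I_0(\gamma r_c)}{I_1(\gamma r_c)}
 + R_b\left(\frac{1}{Z_n}+\frac{1}{Z_m}\right)}\right],
 \qquad \gamma r_c = \alpha\sqrt{\tfrac{1}{Z_n}+\tfrac{1}{Z_m}},$$

with `alpha = rc sqrt(rho/h)` and `I0`, `I1` modified Bessel functions of
complex argument. At `Rb = alpha = 0` the bracket collapses to 1 and the
cell-free spectrum is recovered exactly. The membranes are treated as purely
capacitive (no membrane conductance): `Rb`, `h` and `Cm` are precisely the
three parameters the study protocol reports, and adding a conductance would
not be identifiable from a 25-point scan.

**Numerics.** The bracket term `(z/2) I0(z)/I1(z)` is evaluated by the
power-series ratio for `|z| <= 12`, by a Lentz continued fraction (from the
three-term recurrence `I0/I1 = 2/z + 1/(4/z + ...)`) up to `|z| = 1e4`, and
by the large-argument asymptotic ratio beyond, so it is finite and accurate
over the whole model range without Bessel overflow. Model arguments have
phase in (0°, 45°], where all three branches agree with direct series
evaluation to better than 1e-9.

**Partial coverage** mixes the cell-free and cell-covered specific
admittances in proportion to the covered area fraction (a parallel circuit
of the two regions) before adding `Rsol`.

# The inverse fit

`fit_cell_params()` works in two stages, both minimizing the complex
least-squares objective `sum[(dlog|Z|)^2 + (dphase)^2]` (equal weights; the
log-magnitude/phase pairing makes the objective scale-free across the
five-decade frequency range):

1. the cell-free scan calibrates `(A, n, Rsol)` from deterministic
   Nelder–Mead starts over a small grid of CPE exponents;
2. the covered scan then determines `(Rb, alpha, Cm)` by bounded L-BFGS-B on
   log-parameters, multi-started from a seeded Latin-hypercube spread inside
   the bounds (defaults: Rb in [1e-3, 100] Ω·cm², h in [1, 2000] nm, Cm in
   [0.1, 20] µF/cm²), with a Nelder–Mead polish; ties resolve to the lowest
   residual, then the lowest start index. `h` is reported through
   `alpha_to_h()`.

The fit is deterministic given its seed. The per-parameter relative spread
across near-optimal starts is reported as a stability proxy, not a standard
error. Noiseless synthetic scans are recovered to machine precision across
the physiological box; at 1% magnitude noise the median error of each
parameter stays under a few percent.

One identity worth knowing: the model family is *closed* under a global
impedance gain `c` via `(Rb, alpha, Cm) -> (c Rb, sqrt(c) alpha, Cm/c)`. A
gain error in the instrument therefore does not degrade the fit residual at
all — it silently rescales the morphology parameters. Absolute impedance
calibration matters, and the test suite pins this equivariance law.

# Kinetics estimators

Baselines and plateaus are estimated as the means of the first and last
`k = 5` samples (the protocol itself does not specify an estimator; a short
mean is robust and simple). Threshold and midpoint crossings are located by
linear interpolation between bracketing samples, since sampling intervals of
several minutes would otherwise bias T50 by up to half an interval.
Consequence worth knowing: a substrate whose settling lag is shorter than
the `k`-sample window (collagen: ~4 min lag at 3-min sampling) gets a
slightly depressed baseline and hence a T50 a few percent late; the
per-substrate orderings are unaffected. The migration T50 is measured from
the fence-off time carried by the trace.

An unsaturated migration trace (still rising in its final samples, judged by
comparing the last two `k`-sample blocks against 5% of the excursion) yields
a warning and a provisional slope over the available window.

**Stage segmentation.** The adhesion time course divides into initial
adhesion, spreading, remodeling and steady state, distinguishable by their
slopes. `segment_stages()` finds the exactly optimal partition of the trace
into four segments, each with its own least-squares line, by the classical
changepoint dynamic programme over sample indices (O(n²) with prefix sums)
— provably the same optimum as exhaustive enumeration of changepoint
triples, which the tests verify. The continuity-constrained alternative
(a linear spline) does not admit an exact DP because continuity couples the
segments; the independent-lines model was chosen so that global optimality
is guaranteed. Stage boundary *times* are then reported as the intersection
of consecutive fitted lines, clamped to the gap between adjoining samples,
which recovers kinks that fall between samples exactly on noiseless
piecewise-linear input.

# Var32

The 2048-point RTC series is split into 64 consecutive groups of 32 points;
each group is divided by its own mean; the population variance (divisor 32)
of each normalized group is computed and the 64 variances are averaged.
Reading the protocol's "divided by the average value" as the *per-group*
mean is the standard micromotion convention and makes the statistic
invariant to the overall resistance level and insensitive to slow drift
across groups; the whole-series reading is available via
`normalize = "series"`. "Variance (the square of standard deviation)" does
not disambiguate the divisor; the population divisor is used, and the
alternative differs by the fixed factor 32/31. Computation is two-pass —
the one-pass `E[x²]−E[x]²` form loses ~8 digits at the protocol's ~1e-7
variances and would fail the brute-force cross-check.

# The synthetic-signal generator

No raw instrument data are deposited for this protocol family, so the
generator emulates the study's signals at desk scale; the shipped profiles
*are* the study conditions, set once from the printed per-substrate values:

* **Attachment** (`simulate_attachment()`): flat at the 3.2 nF cell-free
  level for a settling lag, then linear decline at exactly the printed
  spreading rate (collagen 6.9381, control 1.1917, PLL 0.7438, PDL
  0.2116 nF/h), then flat at the confluent level. The lag is solved from the
  printed attachment T50; confluent levels are 1.0 nF, except PLL (1.1) and
  PDL (1.45), reflecting the poly-lysines' poorer spreading — values chosen
  once so every printed T50 is attainable with the printed slope and a
  non-negative lag. The printed thresholds ("3/1.5 µF" for 8W1E beside
  slopes in nF/h) are applied as the same numbers on the nF scale: a 250-µm
  electrode's 64 kHz series capacitance is a few nF, and 3→1.5 nF at
  6.94 nF/h takes 0.22 h, exactly the printed collagen attachment T50 —
  the only reading under which thresholds, slopes and T50s cohere.
* **Migration** (`simulate_migration()`): baseline while the fence is on;
  after fence-off the 250-µm disc closes by a uniform inward radial front,
  `c(t) = 1-(1-min(1, vt/r_e))²`, the simplest geometry consistent with
  inward migration. The front speed is solved from the printed migration T50
  (`v = (1-sqrt(1/2)) r_e/T50`; collagen ≈ 36 µm/h, a realistic keratinocyte
  speed), and in the default fast mode the resistance excursion is solved
  linearly from the printed Sr through the same discrete regression
  functional the extractor uses. Model mode instead reads resistance off the
  forward model under admittance mixing — physically faithful, and visibly
  *convex* in coverage, so its resistance midpoint falls after the coverage
  midpoint (measured: 1.21 h vs 1.01 h for collagen defaults). Monotone
  readout maps do not preserve midpoints; this readout bias is a real
  property of resistance-based wound-healing quantification, and is why the
  fast mode, calibrated directly in the readout domain, is the default.
* **Micromotion** (`simulate_micromotion()`): `R = R0 exp(x)` with `x` a
  stationary discrete Ornstein–Uhlenbeck process (30 s mean-reversion,
  1 s sampling). Correlated small fluctuations are required: the printed
  Var32 magnitudes (3.5–4.0e-7) with white noise would imply an unphysically
  small amplitude of instrument-only character. The stationary sd is solved
  in closed form from the target Var32 via the exact finite-sample
  expectation of the per-segment variance of an AR(1) (factor
  `kappa(phi, 32)`), so the calibration is analytic, never fitted. The PLL
  level (3.45e-7) is a package choice: the study prints control, collagen
  and PDL only, with PLL described as at or below control.
* **Scans** (`simulate_scan()`): forward model on the 25-point grid with
  multiplicative magnitude noise and additive phase jitter. The simulated
  covered wells use the printed per-substrate `h` (49.2/60.7/31.9/51.4 nm),
  the printed `Rb = 1.7267` Ω·cm² for all substrates (the study found no
  substrate dependence), printed radii where given (collagen 11.72 µm, PDL
  13.39 µm; 11 µm otherwise) and an assumed `Cm = 1` µF/cm² — the study
  never prints fitted Cm.
* **Stage traces** (`simulate_adhesion_stages()`): piecewise-linear four-
  phase capacitance with the printed collagen stage durations (0.19, 1.68,
  4.74 h) and 2/78/20% excursion drops per phase; other substrates' stage
  times are package choices preserving the printed ordering (collagen
  fastest, PDL slowest).

Every stream is reproducible bit-for-bit given its seed; multiplicative
Gaussian noise (default 0.5%) reflects signal-proportional instrument noise.

**What the generator does not emulate:** proliferation, single-cell
heterogeneity, fence-pulse electrochemistry, drifts and temperature
artifacts, or coupling between the capacitance and resistance channels of
one well. Passing tests on generated data therefore demonstrate that the
estimators recover known ground truth under realistic noise and sampling —
not that the biological conclusions of any particular experiment are
reproduced.

# Physico-chemical closed forms

The Helmholtz–Smoluchowski relation is applied in the only dimensionally
consistent grouping producing volts,
`zeta = (eta*lambda/(eps0*eps_r)) * dE/dP`, returned in mV; electrolyte
defaults (8.9e-4 Pa·s, 0.1265 S/m, eps_r 78.5) describe 10 mM NaCl at 25 °C
and are explicit arguments because instrument software constants are rarely
reported. The alamarBlue reduction is the usual two-control normalization,
invariant to a common detector gain and offset; relative adhesion divides by
the control's value so the control is exactly 1. The fence schedule is
stored and emitted, but pulse electrochemistry is not modelled — only the
`V = I·R` sizing check is computed (2000 Ω × 1 mA = 2.0 V;
300 Ω × 6 mA = 1.8 V).

# Problem sizes and determinism

Defaults are sized for desk-scale work: attachment traces sample every
3 min for 12 h (241 points), migration every 5 min through closure plus a
2 h plateau tail, RTC series are the protocol's 2048 points, scan fits use
4–8 multi-starts, and the pipeline's replicate counts (3–5 wells per
substrate) match the study's N. Every random stream — generator noise,
multi-start spreads, OU innovations — descends deterministically from a
single user-supplied seed.

# Known limitations

* The independent-lines segmentation may leave infinitesimal jumps between
  fitted stage lines on noisy data; boundary times remain well defined via
  the line-intersection rule.
* Var32 of a single RTC series scatters ~11% (relative sd) under the
  correlated fluctuation model; population comparisons need replicate
  series, as in the study (N > 10).
* The scan fit assumes a confluent covered electrode (coverage 1); partial
  coverage during a scan biases `Rb` downward.
* Attachment T50 inherits a small positive bias for substrates whose
  settling lag is shorter than the baseline window (see Kinetics above).
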