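# Attachment and migration kinetics: regression slopes, T50.
#
# Traces are tidy tibbles with a time column (hours) and a value column
# (capacitance in nF or resistance in ohm); all functions are data-frame
# first and return one-row tibbles so per-well results stack with purrr/dplyr.

check_trace <- function(time_h, value) {
  if (length(time_h) < 3) stop("trace needs at least 3 samples", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (anyNA(time_h) || anyNA(value)) stop("trace contains NA", call. = FALSE)
  invisible(NULL)
}

# first time the trace crosses `level` in the given direction, by linear
# interpolation between the bracketing samples
cross_time <- function(time_h, value, level, direction = c("down", "up")) {
  direction <- match.arg(direction)
  s <- if (direction == "down") -1 else 1
  v <- s * (value - level)
  idx <- which(v[-1] >= 0 & v[-length(v)] < 0)
  if (v[1] >= 0) return(time_h[1])
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  frac <- (0 - v[i]) / (v[i + 1] - v[i])
  time_h[i] + frac * (time_h[i + 1] - time_h[i])
}

ols_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ssy <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  list(slope = unname(cf[2]),
       intercept = unname(cf[1]),
       r_squared = if (ssy > 0) 1 - sse / ssy else 1)
}

#' Attachment/spreading rate from a capacitance trace
#'
#' The spreading rate Sc = |-dC/dt| is the absolute slope of the ordinary
#' least-squares line through all samples whose capacitance lies between the
#' two thresholds, a window that excludes both the settling phase at the
#' cell-free level and the plateau after confluence. Threshold crossing times
#' are located by linear interpolation. Default thresholds are 3 and 1.5 for
#' the single-electrode array and 30 and 10 for the ten-electrode array
#' (nF channel).
#'
#' @param data Trace data frame.
#' @param upper,lower Capacitance thresholds bounding the regression window
#'   (same unit as the value column; `upper > lower`).
#' @param time,value Tidy-eval columns holding time (h) and capacitance;
#'   default `time_h`, `value`.
#' @return One-row tibble: `slope` (Sc, unit of value per hour), `r_squared`,
#'   `t_upper_h`/`t_lower_h` (interpolated crossing times), `n_points`,
#'   `upper`, `lower`.
#' @examples
#' tr <- tibble::tibble(time_h = seq(0, 5, 0.1), value = 3.2 - 0.5 * time_h)
#' capacitance_slope(tr)
#' @export
capacitance_slope <- function(data, upper = 3, lower = 1.5,
                              time = time_h, value = value) {
  t <- dplyr::pull(data, {{ time }})
  v <- dplyr::pull(data, {{ value }})
  check_trace(t, v)
  if (upper <= lower) stop("`upper` must exceed `lower`", call. = FALSE)
  if (max(v) < upper) {
    stop("incomplete trace: capacitance never reaches the upper threshold ",
         upper, call. = FALSE)
  }
  if (min(v) > lower) {
    stop("incomplete trace: capacitance never falls below the lower threshold ",
         lower, call. = FALSE)
  }
  t_up <- cross_time(t, v, upper, "down")
  t_lo <- cross_time(t, v, lower, "down")
  keep <- v >= lower & v <= upper
  if (sum(keep) < 2) stop("fewer than 2 samples inside the threshold window", call. = FALSE)
  fit <- ols_fit(t[keep], v[keep])
  tibble::tibble(
    slope = abs(fit$slope),
    r_squared = fit$r_squared,
    t_upper_h = t_up,
    t_lower_h = t_lo,
    n_points = sum(keep),
    upper = upper,
    lower = lower
  )
}

# baseline / plateau levels as means of the first / last k samples
trace_levels <- function(v, k = 5) {
  n <- length(v)
  k <- min(k, floor(n / 2))
  list(baseline = mean(v[seq_len(k)]), plateau = mean(v[seq(n - k + 1, n)]), k = k)
}

#' Migration rate from a fence-release resistance trace
#'
#' The migration rate Sr = |dR/dt| is the absolute OLS slope of the
#' resistance rise between the cell-free baseline and the confluent plateau.
#' Baseline and plateau are estimated as the means of the first and last `k`
#' samples; the regression window keeps samples whose resistance lies between
#' `baseline_frac` and `plateau_frac` of the baseline-to-plateau excursion,
#' avoiding the flat fence-on segment and the saturating tail.
#'
#' @param data Trace data frame.
#' @param baseline_frac,plateau_frac Fractions of the excursion bounding the
#'   regression window.
#' @param k Number of edge samples averaged for the baseline and plateau.
#' @param time,value Tidy-eval columns (default `time_h`, `value`).
#' @return One-row tibble: `slope` (Sr, ohm/h), `r_squared`, `baseline`,
#'   `plateau`, `n_points`, `saturated` (FALSE, with a warning, when the
#'   trace is still rising at its end and the plateau estimate is provisional).
#' @examples
#' tr <- tibble::tibble(time_h = seq(0, 6, 0.1),
#'                      value = 2000 + 2000 * pmin(time_h, 4))
#' resistance_slope(tr)
#' @export
resistance_slope <- function(data, baseline_frac = 0.1, plateau_frac = 0.9,
                             k = 5, time = time_h, value = value) {
  t <- dplyr::pull(data, {{ time }})
  v <- dplyr::pull(data, {{ value }})
  check_trace(t, v)
  if (!(baseline_frac < plateau_frac) || baseline_frac < 0 || plateau_frac > 1) {
    stop("need 0 <= baseline_frac < plateau_frac <= 1", call. = FALSE)
  }
  lv <- trace_levels(v, k)
  if (lv$plateau <= lv$baseline) {
    stop("trace shows no resistance rise (plateau <= baseline)", call. = FALSE)
  }
  # unsaturated if the trace is still rising into its final samples: the
  # last-k mean sits well above the preceding-k mean (noise-robust block
  # comparison rather than a tail regression)
  n <- length(v)
  excursion <- lv$plateau - lv$baseline
  prev_i <- seq(max(1, n - 2 * lv$k + 1), n - lv$k)
  tail_rise <- lv$plateau - mean(v[prev_i])
  lo <- lv$baseline + baseline_frac * excursion
  hi <- lv$baseline + plateau_frac * excursion
  keep <- v >= lo & v <= hi
  if (sum(keep) < 2) stop("fewer than 2 samples inside the regression window", call. = FALSE)
  fit <- ols_fit(t[keep], v[keep])
  saturated <- tail_rise < 0.05 * excursion
  if (!saturated) {
    warning("unsaturated trace: plateau not reached; slope computed over ",
            "the available window", call. = FALSE)
  }
  tibble::tibble(
    slope = abs(fit$slope),
    r_squared = fit$r_squared,
    baseline = lv$baseline,
    plateau = lv$plateau,
    n_points = sum(keep),
    saturated = saturated
  )
}

#' Halfway recovery time T50 of a kinetic trace
#'
#' First time the trace crosses the midpoint between its baseline and plateau
#' levels (means of the first and last `k` samples), linearly interpolated
#' between the bracketing samples. Resistance traces cross upward,
#' capacitance traces downward; the direction is inferred from the sign of
#' plateau - baseline. The returned T50 is relative to `t0` (default: the
#' trace's `fence_off_h` attribute if present, else the first sample time),
#' so fence-release traces measure recovery from fence-off.
#'
#' @param data Trace data frame.
#' @param k Edge samples averaged for baseline/plateau.
#' @param t0 Time origin (h); `NULL` uses `attr(data, "fence_off_h")` or the
#'   first sample time.
#' @param time,value Tidy-eval columns (default `time_h`, `value`).
#' @return One-row tibble: `t50_h`, `baseline`, `plateau`, `midpoint`.
#' @examples
#' tr <- tibble::tibble(time_h = seq(0, 6, 0.05),
#'                      value = 2000 + 8000 * stats::plogis((time_h - 1.5) / 0.3))
#' trace_t50(tr)
#' @export
trace_t50 <- function(data, k = 5, t0 = NULL, time = time_h, value = value) {
  t <- dplyr::pull(data, {{ time }})
  v <- dplyr::pull(data, {{ value }})
  check_trace(t, v)
  if (is.null(t0)) {
    t0 <- attr(data, "fence_off_h")
    if (is.null(t0)) t0 <- t[1]
  }
  lv <- trace_levels(v, k)
  if (lv$plateau == lv$baseline) {
    stop("baseline equals plateau; T50 undefined", call. = FALSE)
  }
  mid <- (lv$baseline + lv$plateau) / 2
  dir <- if (lv$plateau > lv$baseline) "up" else "down"
  tc <- cross_time(t, v, mid, dir)
  if (is.na(tc)) stop("trace never crosses the baseline-plateau midpoint", call. = FALSE)
  tibble::tibble(t50_h = tc - t0, baseline = lv$baseline,
                 plateau = lv$plateau, midpoint = mid)
}
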