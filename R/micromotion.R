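# Micromotion fluctuation analysis of rapid-time-collection (RTC) series.

#' Mean-normalize a micromotion series
#'
#' Divides every point by the whole-series mean, giving a dimensionless
#' series with mean exactly 1; scaling the input by any positive constant
#' leaves the output unchanged.
#'
#' @param x Numeric vector of resistance samples (all of one series).
#' @return Numeric vector, same length, mean 1.
#' @examples
#' normalize_trace(c(2, 4))
#' @export
normalize_trace <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("series mean must be positive", call. = FALSE)
  x / m
}

#' Var32 micromotion statistic
#'
#' The fluctuation statistic of the rapid-time-collection protocol: a series
#' of 2048 one-second resistance samples at 4 kHz is split into 64
#' consecutive groups of 32 points, each group is divided by its own mean,
#' the population variance (divisor = group length) of each normalized group
#' is computed, and the variances are averaged. Per-group normalization makes
#' the statistic invariant to scaling the whole series and insensitive to
#' slow drift across groups; the alternative reading that normalizes by the
#' whole-series mean is available via `normalize = "series"` (the two differ
#' when the series drifts). Sample-variance users note: the population
#' divisor differs from n-1 by a fixed factor L/(L-1) = 32/31.
#'
#' @param x Numeric vector of resistance samples (ohm), all positive, or a
#'   data frame with a `resistance_ohm` column.
#' @param segment_length Points per group (default 32).
#' @param normalize `"segment"` (default: each group by its own mean) or
#'   `"series"` (whole series by its overall mean first).
#' @return One-row tibble: `var32`, `n_segments`, `segment_length`,
#'   `n_points_used`. A trailing remainder that does not fill a group is
#'   dropped with a warning.
#' @examples
#' set.seed(1)
#' var32(1000 * (1 + 0.01 * rnorm(2048)))
#' @export
var32 <- function(x, segment_length = 32, normalize = c("segment", "series")) {
  normalize <- match.arg(normalize)
  if (is.data.frame(x)) {
    if (!"resistance_ohm" %in% names(x)) {
      stop("data frame input needs a `resistance_ohm` column", call. = FALSE)
    }
    x <- x$resistance_ohm
  }
  n <- length(x)
  if (segment_length < 2) stop("`segment_length` must be >= 2", call. = FALSE)
  if (n < segment_length) {
    stop("series shorter than one segment (", n, " < ", segment_length, ")",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all values must be positive and finite (normalization undefined)",
         call. = FALSE)
  }
  n_seg <- n %/% segment_length
  used <- n_seg * segment_length
  if (used < n) {
    warning("dropping trailing remainder of ", n - used, " points", call. = FALSE)
    x <- x[seq_len(used)]
  }
  if (normalize == "series") x <- normalize_trace(x)
  seg <- matrix(x, nrow = segment_length)
  if (normalize == "segment") {
    seg <- sweep(seg, 2, colMeans(seg), `/`)
  }
  # two-pass population variance per group (one-pass E[x^2]-E[x]^2 cancels
  # catastrophically at the protocol's tiny relative fluctuations)
  vars <- colMeans(sweep(seg, 2, colMeans(seg), `-`)^2)
  tibble::tibble(
    var32 = mean(vars),
    n_segments = n_seg,
    segment_length = as.integer(segment_length),
    n_points_used = as.integer(used)
  )
}
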