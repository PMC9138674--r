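# Adhesion-stage segmentation: optimal piecewise-linear partition of a
# capacitance time course into initial adhesion | spreading | remodeling |
# steady state, by dynamic programming over changepoint positions.

STAGE_NAMES <- c("initial_adhesion", "spreading", "remodeling", "steady_state")

# per-range OLS residual sums of squares from prefix sums, O(1) per query
segment_cost_fns <- function(t, y) {
  ct <- cumsum(t); cy <- cumsum(y)
  ctt <- cumsum(t * t); cty <- cumsum(t * y); cyy <- cumsum(y * y)
  pre <- function(c, i) if (i == 0) 0 else c[i]
  function(i, j) {
    m <- j - i + 1
    st <- ct[j] - pre(ct, i - 1); sy <- cy[j] - pre(cy, i - 1)
    stt <- ctt[j] - pre(ctt, i - 1); sty <- cty[j] - pre(cty, i - 1)
    syy <- cyy[j] - pre(cyy, i - 1)
    sxx <- stt - st * st / m
    sxy <- sty - st * sy / m
    sse <- (syy - sy * sy / m) - sxy * sxy / sxx
    max(sse, 0)   # clip tiny negative rounding
  }
}

#' Segment a kinetic trace into adhesion stages
#'
#' Partitions a trace into `n_stages` consecutive segments, each fitted by
#' its own least-squares line, choosing the changepoints that minimize the
#' total squared error by exact dynamic programming over sample indices (the
#' classical optimal-partition recursion, provably equal to exhaustive
#' enumeration of changepoint tuples). Stage boundaries are reported as the
#' intersection times of consecutive fitted lines, clamped to the gap between
#' the adjoining samples, so a kink that falls between samples is still
#' located exactly on noiseless piecewise-linear input. With the default four
#' stages the segments are labelled initial adhesion, spreading, remodeling
#' and steady state.
#'
#' @param data Trace data frame.
#' @param n_stages Number of segments (default 4).
#' @param min_len Minimum samples per segment (>= 2, so each line is
#'   determined).
#' @param time,value Tidy-eval columns (default `time_h`, `value`).
#' @return An object of class `ecis_stages`: list with `stages` (per-stage
#'   tibble: stage, start/end index and time, duration_h, slope, intercept,
#'   sse), `breakpoints_h` (n_stages - 1 boundary times), `durations_h`
#'   (first n_stages - 1 stage durations, i.e. the reported adhesion-phase
#'   times), `sse_total`, and the data. `tidy()` returns the stage tibble.
#' @examples
#' t <- seq(0, 9, 0.05)
#' y <- stats::approx(c(0, 0.2, 1.9, 6.6, 9), c(3.2, 3.15, 1.5, 1.02, 1.0),
#'                    xout = t)$y
#' seg <- segment_stages(tibble::tibble(time_h = t, value = y))
#' seg$durations_h
#' @export
segment_stages <- function(data, n_stages = 4, min_len = 2,
                           time = time_h, value = value) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  check_trace(t, y)
  n <- length(t)
  if (min_len < 2) stop("`min_len` must be >= 2", call. = FALSE)
  if (n < n_stages * min_len) {
    stop("trace too short: need at least ", n_stages * min_len,
         " samples for ", n_stages, " stages", call. = FALSE)
  }
  cost <- segment_cost_fns(t, y)

  # dp[k, j]: minimal SSE of splitting samples 1..j into k segments
  dp <- matrix(Inf, n_stages, n)
  from <- matrix(NA_integer_, n_stages, n)
  for (j in min_len:n) dp[1, j] <- cost(1, j)
  if (n_stages > 1) {
    for (k in 2:n_stages) {
      for (j in (k * min_len):n) {
        # segment k runs i..j; previous k-1 segments fill 1..i-1
        i_cand <- ((k - 1) * min_len + 1):(j - min_len + 1)
        tot <- vapply(i_cand, function(i) dp[k - 1, i - 1] + cost(i, j), numeric(1))
        b <- which.min(tot)
        dp[k, j] <- tot[b]
        from[k, j] <- i_cand[b]
      }
    }
  }

  # backtrack segment start indices
  starts <- integer(n_stages)
  j <- n
  for (k in n_stages:1) {
    starts[k] <- if (k == 1) 1L else from[k, j]
    j <- starts[k] - 1L
  }
  ends <- c(starts[-1] - 1L, n)

  fits <- purrr::map(seq_len(n_stages), function(k) {
    idx <- starts[k]:ends[k]
    ols_fit(t[idx], y[idx])
  })

  # boundary between stage k and k+1: intersection of the two fitted lines,
  # clamped to [t(end of k), t(start of k+1)]
  breakpoints <- vapply(seq_len(n_stages - 1), function(k) {
    a1 <- fits[[k]]$intercept; b1 <- fits[[k]]$slope
    a2 <- fits[[k + 1]]$intercept; b2 <- fits[[k + 1]]$slope
    lo <- t[ends[k]]; hi <- t[starts[k + 1]]
    bp <- if (abs(b1 - b2) < 1e-12 * (abs(b1) + abs(b2) + 1e-300)) {
      (lo + hi) / 2
    } else {
      (a2 - a1) / (b1 - b2)
    }
    min(max(bp, lo), hi)
  }, numeric(1))

  edges <- c(t[1], breakpoints, t[n])
  stages <- tibble::tibble(
    stage = if (n_stages == 4) STAGE_NAMES else paste0("stage_", seq_len(n_stages)),
    start_idx = starts,
    end_idx = ends,
    start_h = edges[-length(edges)],
    end_h = edges[-1],
    duration_h = diff(edges),
    slope = purrr::map_dbl(fits, "slope"),
    intercept = purrr::map_dbl(fits, "intercept"),
    sse = purrr::map_dbl(seq_len(n_stages), function(k) cost(starts[k], ends[k]))
  )

  structure(
    list(
      stages = stages,
      breakpoints_h = breakpoints,
      durations_h = stages$duration_h[seq_len(n_stages - 1)],
      sse_total = dp[n_stages, n],
      data = tibble::tibble(time_h = t, value = y)
    ),
    class = "ecis_stages"
  )
}

#' @export
print.ecis_stages <- function(x, ...) {
  cat("<ecis_stages> ", nrow(x$stages), " stages, total SSE ",
      signif(x$sse_total, 5), "\n", sep = "")
  print(x$stages[, c("stage", "start_h", "end_h", "duration_h", "slope")])
  invisible(x)
}

#' @rdname segment_stages
#' @param x An `ecis_stages` object.
#' @param ... Unused.
#' @method tidy ecis_stages
#' @export
tidy.ecis_stages <- function(x, ...) x$stages
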