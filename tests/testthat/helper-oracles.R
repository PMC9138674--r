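# Independent oracles used by the tests. These deliberately reimplement the
# quantities under test by a different route (direct series summation,
# two-pass closed forms, double loops, exhaustive enumeration) so that each
# check compares two independent computations.

# (z/2) I0(z)/I1(z) by direct truncated power-series evaluation of I0 and I1.
# `nterms = NULL` sums adaptively to machine convergence.
oracle_bessel_bracket <- function(z, nterms = NULL) {
  vapply(z, function(z) {
    q <- z * z / 4
    i0 <- 1 + 0i; i1s <- 1 + 0i   # I1 = (z/2) * i1s
    t0 <- t1 <- 1 + 0i
    kmax <- if (is.null(nterms)) 500L else nterms
    for (k in seq_len(kmax)) {
      t0 <- t0 * q / (k * k)
      t1 <- t1 * q / (k * (k + 1))
      i0 <- i0 + t0
      i1s <- i1s + t1
      if (is.null(nterms) && Mod(t0) < 1e-20 * Mod(i0) &&
          Mod(t1) < 1e-20 * Mod(i1s)) break
    }
    i0 / i1s   # (z/2) I0 / ((z/2) i1s) = i0/i1s
  }, complex(1))
}

# two-pass closed-form least-squares slope/intercept
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = b, intercept = my - b * mx)
}

# brute-force Var32: explicit double loop over segments and points,
# per-segment mean normalization, population variance
oracle_var32 <- function(x, L = 32) {
  n_seg <- length(x) %/% L
  total <- 0
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * L + 1):(s * L)]
    seg <- seg / mean(seg)
    m <- mean(seg)
    v <- 0
    for (p in seg) v <- v + (p - m)^2
    total <- total + v / L
  }
  total / n_seg
}

# exhaustive optimal 4-segment partition: enumerate all changepoint triples
# (segment start indices), fit each segment by closed-form OLS, return the
# minimal total SSE
oracle_best_sse_4seg <- function(t, y, min_len = 2) {
  n <- length(t)
  sse_rng <- function(i, j) {
    xs <- t[i:j]; ys <- y[i:j]
    f <- oracle_ols(xs, ys)
    sum((ys - f$intercept - f$slope * xs)^2)
  }
  best <- Inf
  for (i2 in (min_len + 1):(n - 3 * min_len + 1)) {
    for (i3 in (i2 + min_len):(n - 2 * min_len + 1)) {
      for (i4 in (i3 + min_len):(n - min_len + 1)) {
        s <- sse_rng(1, i2 - 1) + sse_rng(i2, i3 - 1) +
          sse_rng(i3, i4 - 1) + sse_rng(i4, n)
        if (s < best) best <- s
      }
    }
  }
  best
}

# default single-electrode array and the reference cell parameters used
# across fixtures (Rb and h as printed for the control monolayer; Cm assumed)
ref_electrode <- function() electrode_spec("8W1E")
ref_cells <- function() {
  cell_params(rb_ohm_cm2 = 1.7267, h_nm = 49.1535, cm_uf_cm2 = 1,
              rc_um = 11.72)
}
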