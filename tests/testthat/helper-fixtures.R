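# Shared fixtures and independent oracles used across the suite.

t0 <- function() as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

# planar track from x/y matrices (marks itself as projected)
mk_planar_track <- function(x, y, dt = 100, id = "t1", species = "SIM") {
  tr <- track(data.frame(time = t0() + (seq_along(x) - 1) * dt, x = x, y = y),
              id = id, species = species)
  tr$crs_note <- "planar (test fixture)"
  tr
}

mk_random_track <- function(n = 20, seed = 1, step_sd = 80, dt_range = c(60, 240)) {
  set.seed(seed)
  dts <- round(runif(n - 1, dt_range[1], dt_range[2]))
  tr <- track(data.frame(time = t0() + cumsum(c(0, dts)),
                         x = cumsum(c(0, rnorm(n - 1, 0, step_sd))),
                         y = cumsum(c(0, rnorm(n - 1, 0, step_sd)))),
              id = "rnd", species = "SIM")
  tr$crs_note <- "planar (test fixture)"
  tr
}

# Dense-resampling FPT oracle: resample the path at 1-s resolution and scan
# for the first sample outside the circle in each direction.
oracle_fpt <- function(tr, radii) {
  fx <- tr$fixes
  tt <- as.numeric(fx$time)
  ts <- seq(tt[1], tt[length(tt)], by = 1)
  xs <- approx(tt, fx$x, ts)$y
  ys <- approx(tt, fx$y, ts)$y
  n <- nrow(fx)
  out <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    d <- sqrt((xs - fx$x[i])^2 + (ys - fx$y[i])^2)
    i0 <- match(tt[i], ts)
    for (k in seq_along(radii)) {
      fw <- which(d[i0:length(d)] > radii[k])
      bw <- which(d[i0:1] > radii[k])
      if (length(fw) && length(bw))
        out[i, k] <- (fw[1] - 1) + (bw[1] - 1)
    }
  }
  out
}

# Exhaustive-enumeration segmentation oracle (earliest-breakpoint ties).
oracle_segmentation <- function(x, K, Lmin) {
  n <- length(x)
  sse <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf; bb <- NULL
  rec <- function(start, k, acc, J) {
    if (k == 1) {
      if (n - start + 1 >= Lmin) {
        j <- J + sse(x[start:n])
        if (j < best - 1e-12) { best <<- j; bb <<- c(acc, n) }
      }
      return(invisible())
    }
    for (e in (start + Lmin - 1):(n - (k - 1) * Lmin))
      rec(e + 1, k - 1, c(acc, e), J + sse(x[start:e]))
  }
  rec(1, K, integer(0), 0)
  list(breaks = bb, J = best)
}

# Asymptotic two-sample KS p-value, written independently of ks.test.
oracle_ks_p <- function(D, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  x <- sqrt(ne) * D
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))))
}

# Two-sample KS D from first principles (ECDF sup-gap at all jump points).
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}
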