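#' A sample of foraging-patch areas
#'
#' Container for one group's patch areas; the statistical layer works on
#' natural-log areas, since patch areas are typically lognormally
#' distributed.
#'
#' @param areas positive areas in m^2.
#' @param group group (species) label.
#' @return object of class `area_sample` with `areas`, `log_areas`,
#'   `group`.
#' @export
area_sample <- function(areas, group = NA_character_) {
  areas <- as.numeric(areas)
  if (!length(areas)) stop("empty area sample", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("areas must be positive and finite", call. = FALSE)
  structure(list(areas = areas, log_areas = log(areas),
                 group = as.character(group)),
            class = "area_sample")
}

#' @export
print.area_sample <- function(x, ...) {
  cat(sprintf("<area_sample> %s: n = %d, mean log area = %.3f (sd %.3f)\n",
              x$group, length(x$areas), mean(x$log_areas),
              stats::sd(x$log_areas)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of patch-area distributions
#'
#' Compares the log-area distributions of two groups with the two-sample
#' KS statistic `D = sup |ECDF_a - ECDF_b|` and the asymptotic two-sided
#' p-value. `D` is invariant under any common strictly monotone transform,
#' so the log transform does not affect it; it is applied for consistency
#' with the rest of the statistical layer.
#'
#' @param a,b [area_sample()] objects (or numeric vectors of log areas).
#' @return object of class `ks_result`: list with `D`, `p`, `n1`, `n2`,
#'   `groups`.
#' @export
ks_compare <- function(a, b) {
  la <- if (inherits(a, "area_sample")) a$log_areas else as.numeric(a)
  lb <- if (inherits(b, "area_sample")) b$log_areas else as.numeric(b)
  if (length(la) < 2 || length(lb) < 2)
    stop("need at least 2 observations per sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(la, lb, exact = FALSE))
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 n1 = length(la), n2 = length(lb),
                 groups = c(if (inherits(a, "area_sample")) a$group else NA,
                            if (inherits(b, "area_sample")) b$group else NA)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> %s vs %s: D = %.4f, p = %.4g (n = %d, %d)\n",
              x$groups[1], x$groups[2], x$D, x$p, x$n1, x$n2))
  invisible(x)
}

#' Count modes of a Gaussian kernel density estimate
#'
#' Number of strict local maxima of the Gaussian KDE with bandwidth `h`,
#' evaluated on a 512-point regular grid spanning
#' `[min(x) - 3h, max(x) + 3h]`; flat plateaus count as one mode. For the
#' Gaussian kernel the mode count is nonincreasing in `h`, which is what
#' makes the critical bandwidth well defined.
#'
#' @param x numeric sample (n >= 2).
#' @param h kernel bandwidth (standard deviation), > 0.
#' @param n_grid evaluation grid size.
#' @return integer mode count.
#' @export
count_modes <- function(x, h, n_grid = 512) {
  stopifnot(h > 0, length(x) >= 2)
  d <- stats::density(x, bw = h, kernel = "gaussian", n = n_grid,
                      from = min(x) - 3 * h, to = max(x) + 3 * h)
  y <- d$y
  ## the FFT evaluation leaves absolute noise ~1e-17 in deep density tails,
  ## which would register as spurious micro-modes; floor it
  y[y < max(y) * 1e-8] <- 0
  ## collapse plateaus, then count sign changes + to -
  r <- rle(y)$values
  if (length(r) == 1L) return(1L)
  s <- sign(diff(r))
  sum(s[-length(s)] > 0 & s[-1] < 0) + as.integer(s[1] < 0) +
    as.integer(s[length(s)] > 0)
}

#' Critical bandwidth for at most k modes
#'
#' The smallest bandwidth `h` at which the Gaussian KDE of `x` has at most
#' `k` modes, found by bisection (relative tolerance `tol`) on a bracketing
#' interval grown from the sample range. Monotonicity of the mode count in
#' `h` (Gaussian kernel) guarantees the bisection is valid.
#' `h_crit(k)` is strictly decreasing in `k` until the floor where the
#' sample's distinct values cannot produce more modes.
#'
#' @param x numeric sample.
#' @param k mode count bound (>= 1).
#' @param tol relative bisection tolerance.
#' @return critical bandwidth (same units as `x`).
#' @export
critical_bandwidth <- function(x, k = 1, tol = 1e-4) {
  stopifnot(k >= 1, length(x) >= 2)
  if (stats::sd(x) == 0)
    stop("all sample values identical: critical bandwidth undefined",
         call. = FALSE)
  hi <- diff(range(x))
  while (count_modes(x, hi) > k) hi <- hi * 2
  lo <- hi / 1024
  while (count_modes(x, lo) <= k) {
    hi <- lo
    lo <- lo / 32
    if (lo < 1e-12 * diff(range(x))) return(hi)  # floor: never exceeds k
  }
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (count_modes(x, mid) <= k) hi <- mid else lo <- mid
  }
  hi
}

#' Silverman's smoothed-bootstrap test for at most k modes
#'
#' Tests H0 "the density of `x` has at most `k` modes" by the critical
#' bandwidth `h_crit(k)`: smoothed bootstrap samples are drawn as
#' `y_i = xbar + (x_{J_i} - xbar + h_crit * e_i) / sqrt(1 + h_crit^2/s^2)`
#' (with `J_i` resampled indices, `e_i` standard normal and `s^2` the
#' sample variance; the rescaling keeps the bootstrap variance equal to
#' `s^2`), and the p-value is the add-one-corrected fraction of replicates
#' whose KDE at `h_crit` has more than `k` modes. The complementary
#' `m = 1 - p` is reported as multimodality support: large `m` supports
#' more than `k` modes, with the conventional decision cut-off `m >= 0.95`.
#' The test is known to be conservative.
#'
#' @param x numeric sample (n >= 5) or an [area_sample()] (log areas used).
#' @param k mode bound under H0.
#' @param B bootstrap replicates (default 999; fewer than 99 is unstable
#'   and warned about).
#' @param seed integer seed for the bootstrap (required for
#'   reproducibility).
#' @return list of class `silverman_test` with `k`, `h_crit`, `p`, `m`,
#'   `B`, `seed`, `n`.
#' @export
silverman_test <- function(x, k = 1, B = 999, seed = 1) {
  if (inherits(x, "area_sample")) x <- x$log_areas
  n <- length(x)
  stopifnot(n >= 5)
  if (B < 99) warning("B < 99 gives unstable p-values", call. = FALSE)
  h <- critical_bandwidth(x, k)
  xbar <- mean(x)
  s2 <- stats::var(x)
  scale <- sqrt(1 + h^2 / s2)
  exceed <- 0L
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (b in seq_len(B)) {
    J <- sample.int(n, n, replace = TRUE)
    y <- xbar + (x[J] - xbar + h * stats::rnorm(n)) / scale
    if (count_modes(y, h) > k) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (B + 1)
  structure(list(k = k, h_crit = h, p = p, m = 1 - p, B = B, seed = seed,
                 n = n), class = "silverman_test")
}

#' @export
print.silverman_test <- function(x, ...) {
  cat(sprintf("<silverman_test> H0: <= %d mode%s; h_crit = %.4g, p = %.3f, multimodality support m = %.3f%s\n",
              x$k, if (x$k == 1) "" else "s", x$h_crit, x$p, x$m,
              if (x$m >= 0.95) "  [>= 0.95: multimodal]" else ""))
  invisible(x)
}

#' Scan mode counts with Silverman's test
#'
#' Runs [silverman_test()] for `k = 1 .. k_max` (conventionally 30) and
#' reports, per `k`, the critical bandwidth, p-value, multimodality support
#' `m = 1 - p`, and whether `m` reaches the `cutoff`. The summary names the
#' `k` with maximal support and whether any `k` passes the cut-off.
#'
#' @param x numeric sample or [area_sample()].
#' @param k_max largest mode count scanned.
#' @param B bootstrap replicates per k.
#' @param seed integer seed; k-specific streams are derived from it.
#' @param cutoff decision threshold on `m` (default 0.95).
#' @return object of class `modality_scan`: data.frame `table`
#'   (k, h_crit, p, m, decision) plus `best_k`, `best_m`, `any_multimodal`,
#'   `B`, `seed`, `cutoff`, `group`.
#' @export
modality_scan <- function(x, k_max = 30, B = 999, seed = 1, cutoff = 0.95) {
  group <- if (inherits(x, "area_sample")) x$group else NA_character_
  if (inherits(x, "area_sample")) x <- x$log_areas
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    st <- silverman_test(x, k = k, B = B, seed = seed + k)
    rows[[k]] <- data.frame(k = k, h_crit = st$h_crit, p = st$p, m = st$m,
                            decision = st$m >= cutoff)
  }
  tab <- do.call(rbind, rows)
  best <- which.max(tab$m)
  structure(list(table = tab, best_k = tab$k[best], best_m = tab$m[best],
                 any_multimodal = any(tab$decision), B = B, seed = seed,
                 cutoff = cutoff, group = group),
            class = "modality_scan")
}

#' @export
print.modality_scan <- function(x, ...) {
  cat(sprintf("<modality_scan>%s k = 1..%d, B = %d\n",
              if (is.na(x$group)) "" else paste0(" ", x$group, ":"),
              nrow(x$table), x$B))
  cat(sprintf("  max multimodality support m = %.3f at k = %d mode%s; %s\n",
              x$best_m, x$best_k, if (x$best_k == 1) "" else "s",
              if (x$any_multimodal)
                sprintf("multimodality supported (m >= %.2f)", x$cutoff)
              else
                sprintf("no k reaches the %.2f cut-off", x$cutoff)))
  invisible(x)
}

#' Export a modality scan as CSV
#'
#' @param scan a `modality_scan`.
#' @param path output file.
#' @export
modality_to_csv <- function(scan, path) {
  utils::write.csv(scan$table, path, row.names = FALSE)
  invisible(path)
}

#' Smoothed density-histogram data for plotting
#'
#' Bin counts plus a plug-in-bandwidth smoothed density of log areas, the
#' data behind the standard two-group comparison figure.
#'
#' @param x an [area_sample()].
#' @param bins histogram bin count.
#' @return list with `breaks`, `counts`, `density_x`, `density_y`.
#' @export
density_histogram <- function(x, bins = 30) {
  stopifnot(inherits(x, "area_sample"))
  hh <- graphics::hist(x$log_areas, breaks = bins, plot = FALSE)
  dd <- stats::density(x$log_areas)
  list(breaks = hh$breaks, counts = hh$counts,
       density_x = dd$x, density_y = dd$y)
}

## save/restore .Random.seed so seeded internals don't clobber the caller's
## RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
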