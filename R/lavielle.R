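## Within-segment contrast for x[i..j], precomputed from cumulative sums.
## model "mean":    sum of squared deviations from the segment mean
## model "meanvar": len * log(max(sse/len, eps))  (Gaussian mean+variance)
.segment_cost_fun <- function(x, model = c("mean", "meanvar")) {
  model <- match.arg(model)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  eps <- 1e-12 * max(stats::var(x), 1e-300)
  function(i, j) {                       # vectorised over i (same j)
    len <- j - i + 1
    sse <- pmax(cs2[j + 1] - cs2[i] - (cs[j + 1] - cs[i])^2 / len, 0)
    if (model == "mean") sse else len * log(pmax(sse / len, eps))
  }
}

#' Optimal segmentation of a series into K contiguous segments
#'
#' Exact minimiser, by dynamic programming, of the within-segment contrast
#' summed over `K` contiguous segments each of length at least `Lmin`.
#' Under the default `model = "mean"` the contrast of a segment is its sum
#' of squared deviations from the segment mean, so segments are homogeneous
#' in level; `"meanvar"` also lets the variance change between segments.
#' Ties are broken toward the earliest breakpoints.
#'
#' @param x numeric series.
#' @param K number of segments (`K * Lmin <= length(x)`).
#' @param Lmin minimum segment length in samples.
#' @param model contrast model, `"mean"` (default) or `"meanvar"`.
#' @return list with `breaks` (last index of each of the K segments; the
#'   final entry is `length(x)`) and `J` (the minimal contrast).
#' @export
optimal_segmentation <- function(x, K, Lmin = 2, model = c("mean", "meanvar")) {
  model <- match.arg(model)
  n <- length(x)
  stopifnot(K >= 1, Lmin >= 1)
  if (K * Lmin > n)
    stop(sprintf("infeasible: K*Lmin = %d > n = %d", K * Lmin, n),
         call. = FALSE)
  cost <- .segment_cost_fun(x, model)
  ## Jmat[k, j]: minimal contrast of splitting x[1..j] into k segments
  Jmat <- matrix(Inf, K, n)
  back <- matrix(NA_integer_, K, n)
  js <- Lmin:n
  Jmat[1, js] <- cost(rep(1L, length(js)), js)
  if (K >= 2) for (k in 2:K) {
    for (j in (k * Lmin):n) {
      ## last segment is (l+1)..j with l ranging over feasible cut points
      l <- ((k - 1) * Lmin):(j - Lmin)
      cand <- Jmat[k - 1, l] + cost(l + 1L, j)
      best <- which.min(cand)            # first minimum = earliest cut
      Jmat[k, j] <- cand[best]
      back[k, j] <- l[best]
    }
  }
  breaks <- integer(K); breaks[K] <- n
  if (K >= 2) for (k in K:2) breaks[k - 1] <- back[k, breaks[k]]
  list(breaks = breaks, J = Jmat[K, n])
}

#' Contrast curve J(K) for K = 1..Kmax
#'
#' @inheritParams optimal_segmentation
#' @param Kmax largest number of segments to evaluate.
#' @return list with `J` (numeric Kmax vector) and `breaks` (list of
#'   breakpoint vectors per K).
#' @export
contrast_curve <- function(x, Kmax, Lmin = 2, model = c("mean", "meanvar")) {
  model <- match.arg(model)
  fits <- lapply(seq_len(Kmax), function(K)
    optimal_segmentation(x, K, Lmin, model))
  list(J = vapply(fits, `[[`, numeric(1), "J"),
       breaks = lapply(fits, `[[`, "breaks"))
}

#' Choose the number of segments by the second-derivative rule
#'
#' The contrast `J(K)` is standardised to
#' `Jt(K) = (J(Kmax) - J(K)) / (J(Kmax) - J(1)) * (Kmax - 1) + 1`
#' and its discrete second derivative
#' `D(K) = Jt(K-1) - 2 Jt(K) + Jt(K+1)` is computed for `2 <= K <= Kmax-1`.
#' `K_opt` is the largest `K` with `D(K) > S`; when no `K` qualifies (or the
#' contrast is flat, as for a constant series) `K_opt = 1`. The conventional
#' threshold is `S = 0.75`; with series shorter than 500 samples the rule is
#' sensitive to `S`, so a warning is emitted in [segment_path()] in that
#' case.
#'
#' @param J contrast values for K = 1..Kmax.
#' @param S curvature threshold (> 0).
#' @return list with `K_opt`, `D` (second-derivative series, NA at the
#'   ends), and `J_std` (standardised contrast).
#' @export
choose_Kopt <- function(J, S = 0.75) {
  Kmax <- length(J)
  if (Kmax < 3) stop("need J for Kmax >= 3", call. = FALSE)
  denom <- J[1] - J[Kmax]
  if (denom <= 0) {
    message("flat contrast curve; K_opt = 1 by convention")
    return(list(K_opt = 1L, D = rep(NA_real_, Kmax),
                J_std = rep(NA_real_, Kmax)))
  }
  Jt <- (J[Kmax] - J) / (J[Kmax] - J[1]) * (Kmax - 1) + 1
  D <- rep(NA_real_, Kmax)
  ks <- 2:(Kmax - 1)
  D[ks] <- Jt[ks - 1] - 2 * Jt[ks] + Jt[ks + 1]
  qual <- which(D > S)
  list(K_opt = if (length(qual)) max(qual) else 1L, D = D, J_std = Jt)
}

#' Segment a track's FPT series into homogeneous movement bouts
#'
#' Runs the penalized-contrast segmentation on the first-passage-time series
#' evaluated at the population scale `r_pop`, choosing the number of bouts
#' by the second-derivative rule ([choose_Kopt()]). Fixes whose FPT is
#' undefined at `r_pop` are imputed from the nearest defined fix in time
#' (flagged in the result) so that breakpoint indices stay aligned with
#' fixes.
#'
#' @param tr the projected [track] the profile came from.
#' @param prof the track's `fpt_profile`.
#' @param scale a `population_scale` (or a single radius in metres).
#' @param Lmin minimum bout length in fixes; with a 2-h fix interval,
#'   `Lmin = 12` makes the minimum bout 24 h.
#' @param Kmax maximum number of bouts; default
#'   `min(floor(n / (2*Lmin)), 40)`, a deterministic stand-in for per-track
#'   visual assessment, 3-4x plausible bout counts.
#' @param S curvature threshold for [choose_Kopt()].
#' @param model contrast model (see [optimal_segmentation()]).
#' @param log_fpt segment `log(FPT)` instead of raw FPT (default raw).
#' @return object of class `lavielle_seg`: list with `id`, `r_pop`,
#'   `series`, `imputed` (logical per fix), `K_opt`, `breaks`, `J`, `D`,
#'   and `segments` (data.frame: segment, start/end fix, start/end time,
#'   n_fixes, mean_fpt).
#' @export
segment_path <- function(tr, prof, scale, Lmin = 12, Kmax = NULL, S = 0.75,
                         model = c("mean", "meanvar"), log_fpt = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(prof, "fpt_profile"))
  r_pop <- if (inherits(scale, "population_scale")) scale$r_pop else
    as.numeric(scale)
  ri <- which.min(abs(prof$radii - r_pop))
  series <- prof$fpt[, ri]
  n <- length(series)
  imputed <- is.na(series)
  if (all(imputed))
    stop("FPT undefined at r_pop for every fix", call. = FALSE)
  if (any(imputed)) {
    def <- which(!imputed)
    ## nearest defined neighbour in index (time) distance; earlier on ties
    for (i in which(imputed)) {
      fi <- findInterval(i, def)
      lo <- if (fi >= 1L) def[fi] else NA_integer_
      hi <- if (fi < length(def)) def[fi + 1L] else NA_integer_
      pick <- if (is.na(lo)) hi else if (is.na(hi)) lo else
        if (abs(i - lo) <= abs(hi - i)) lo else hi
      series[i] <- series[pick]
    }
  }
  if (log_fpt) series <- log(series)
  if (n < 500)
    warning("series shorter than 500 fixes: K_opt is sensitive to S",
            call. = FALSE)
  if (is.null(Kmax)) Kmax <- min(floor(n / (2 * Lmin)), 40L)
  if (n < 2 * Lmin || Kmax < 3) {
    message(sprintf("track %s: series too short for segmentation; single segment",
                    prof$id))
    breaks <- n
    res <- list(K_opt = 1L, J = NA_real_, D = NA_real_)
  } else {
    cc <- contrast_curve(series, Kmax, Lmin, model)
    ch <- choose_Kopt(cc$J, S)
    breaks <- cc$breaks[[ch$K_opt]]
    res <- list(K_opt = ch$K_opt, J = cc$J, D = ch$D)
  }
  starts <- c(1L, utils::head(breaks, -1L) + 1L)
  segs <- data.frame(
    segment = seq_along(breaks), start_fix = starts, end_fix = breaks,
    start_time = prof$time[starts], end_time = prof$time[breaks],
    n_fixes = breaks - starts + 1L,
    mean_fpt = vapply(seq_along(breaks), function(k)
      mean(series[starts[k]:breaks[k]]), numeric(1)))
  structure(list(id = prof$id, r_pop = prof$radii[ri], series = series,
                 imputed = imputed, K_opt = res$K_opt, breaks = breaks,
                 J = res$J, D = res$D, Lmin = Lmin, S = S,
                 segments = segs),
            class = "lavielle_seg")
}

#' @export
print.lavielle_seg <- function(x, ...) {
  cat(sprintf("<lavielle_seg> %s: %d fixes at r = %g m -> K_opt = %d bout%s\n",
              x$id, length(x$series), x$r_pop, x$K_opt,
              if (x$K_opt == 1) "" else "s"))
  if (any(x$imputed))
    cat(sprintf("  %d fix(es) imputed (FPT undefined at r_pop)\n",
                sum(x$imputed)))
  invisible(x)
}

#' Export segments as CSV
#'
#' @param seg a `lavielle_seg`.
#' @param path output file.
#' @export
segments_to_csv <- function(seg, path) {
  df <- seg$segments
  df$start_time <- format(df$start_time, "%Y-%m-%dT%H:%M:%SZ")
  df$end_time <- format(df$end_time, "%Y-%m-%dT%H:%M:%SZ")
  df <- cbind(id = seg$id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
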