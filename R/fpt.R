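#' Radius grid for first-passage-time analysis
#'
#' Arithmetic grid of circle radii, `r_min, r_min + step, ...` up to the
#' largest value not exceeding `r_max`. The default grid (100 m to 10,000 m
#' in 80-m steps, realised radii 100, 180, ..., 9,940) spans the scales
#' relevant for wide-ranging waterbirds.
#'
#' @param r_min,r_max grid limits in metres (`r_min > 0`).
#' @param step grid increment in metres.
#' @return numeric vector of radii with attributes `r_min`, `r_max`, `step`.
#' @export
radius_grid <- function(r_min = 100, r_max = 10000, step = 80) {
  stopifnot(r_min > 0, step > 0, r_max >= r_min)
  r <- seq(r_min, r_max, by = step)
  structure(r, r_min = r_min, r_max = r_max, step = step)
}

## First crossing of the circle |p - centre| = r walked from the fix
## outward along one side of the path.
##
## pts: (m+1) x 2 matrix of path points starting at the fix; tt: their times
## as offsets from the fix (nonnegative, increasing along the walk).
## Returns, for each radius, the time offset of the first crossing, or NA if
## the path ends first. Relies on |p(t) - c|^2 being convex on each linear
## step, so the running maximum of vertex distances locates the first
## crossing segment exactly.
.first_crossing <- function(pts, tt, radii) {
  m <- nrow(pts) - 1L
  out <- rep(NA_real_, length(radii))
  if (m < 1L) return(out)
  d <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  dmax <- cummax(d)
  ## first vertex index (2-based) whose running max exceeds r
  ix <- findInterval(radii, dmax, left.open = TRUE) + 1L
  ok <- ix <= m + 1L & radii < dmax[m + 1L]
  if (!any(ok)) return(out)
  i2 <- ix[ok]                     # crossing lies in segment (i2-1, i2)
  a <- pts[i2 - 1L, , drop = FALSE]
  b <- pts[i2, , drop = FALSE]
  vx <- b[, 1] - a[, 1]; vy <- b[, 2] - a[, 2]
  A <- vx^2 + vy^2
  B <- 2 * (a[, 1] * vx + a[, 2] * vy)
  C <- a[, 1]^2 + a[, 2]^2 - radii[ok]^2
  disc <- pmax(B^2 - 4 * A * C, 0)
  tseg <- ifelse(A > 0, (-B + sqrt(disc)) / (2 * A), 0) # outgoing root
  tseg <- pmin(pmax(tseg, 0), 1)
  out[ok] <- tt[i2 - 1L] + tseg * (tt[i2] - tt[i2 - 1L])
  out
}

#' First-passage time along a track
#'
#' For each fix and each radius `r`, the first-passage time is the duration
#' between the last time the path (linearly interpolated between fixes)
#' entered the circle of radius `r` centred on that fix before passing
#' through it, and the first time it left the circle afterwards. High FPT
#' marks locations where movement is concentrated (area-restricted search);
#' the radius at which the variance of log FPT peaks estimates the spatial
#' scale of that clustering.
#'
#' FPT is undefined (NA) at a fix/radius where the path reaches either end
#' of the track without crossing the circle; undefined entries are excluded
#' from all downstream statistics (per-radius exclusion).
#'
#' @param tr a projected [track].
#' @param radii a [radius_grid()] (any increasing positive numeric works).
#' @return an object of class `fpt_profile`: list with `id`, `radii`,
#'   `fpt` (n_fix x n_radii matrix, seconds), `time` (fix timestamps),
#'   and after [var_log_fpt()] also `var_log` and `r_max_individual`.
#' @export
compute_fpt <- function(tr, radii = radius_grid()) {
  stopifnot(inherits(tr, "track"))
  if (!is_projected(tr)) stop("project the track first", call. = FALSE)
  p <- cbind(tr$fixes$x, tr$fixes$y)
  tt <- as.numeric(tr$fixes$time)
  n <- nrow(p)
  r <- as.numeric(radii)
  fpt <- matrix(NA_real_, n, length(r))
  rmax <- max(r)
  for (i in seq_len(n)) {
    ## forward walk
    fw <- if (i < n) {
      idx <- i:n
      pts <- sweep(p[idx, , drop = FALSE], 2, p[i, ])
      .first_crossing(pts, tt[idx] - tt[i], r)
    } else rep(NA_real_, length(r))
    ## backward walk (time offsets positive into the past)
    bw <- if (i > 1) {
      idx <- i:1
      pts <- sweep(p[idx, , drop = FALSE], 2, p[i, ])
      .first_crossing(pts, tt[i] - tt[idx], r)
    } else rep(NA_real_, length(r))
    fpt[i, ] <- fw + bw
  }
  structure(list(id = track_id(tr), species = tr$species, radii = r,
                 fpt = fpt, time = tr$fixes$time),
            class = "fpt_profile")
}

#' Variance of log first-passage time
#'
#' Fills the scale-diagnostic curve of an `fpt_profile`: at each radius, the
#' sample variance of the natural log of the defined FPT values across
#' fixes. Radii with fewer than two defined values get `NA`.
#' `r_max_individual` is the radius at which the curve is maximal (ties
#' broken toward the smaller radius).
#'
#' @param prof an `fpt_profile` from [compute_fpt()].
#' @return the profile with `var_log` and `r_max_individual` filled.
#' @export
var_log_fpt <- function(prof) {
  stopifnot(inherits(prof, "fpt_profile"))
  v <- apply(prof$fpt, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) NA_real_ else stats::var(log(col))
  })
  prof$var_log <- v
  prof$r_max_individual <- if (all(is.na(v))) NA_real_ else
    prof$radii[which.max(v)]   # which.max: first (smallest radius) on ties
  prof
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat(sprintf("<fpt_profile> %s: %d fixes x %d radii [%g..%g m]\n",
              x$id, nrow(x$fpt), length(x$radii), min(x$radii), max(x$radii)))
  cat(sprintf("  defined FPT: %.1f%% of entries\n",
              100 * mean(!is.na(x$fpt))))
  if (!is.null(x$r_max_individual))
    cat(sprintf("  var-log-FPT peak at r = %g m\n", x$r_max_individual))
  invisible(x)
}

#' Population-level analysis scale from several FPT profiles
#'
#' Averages the variance-of-log-FPT curves of several individuals radius by
#' radius (individuals undefined at a radius are omitted from that radius's
#' mean) and takes the radius of the peak of the mean curve as the common
#' population-level scale `r_pop` for all subsequent analysis. FPT grows
#' with circle size, so a common radius is needed to standardise the
#' segmentation stage across individuals.
#'
#' @param profiles list of `fpt_profile` objects sharing one radius grid,
#'   each already passed through [var_log_fpt()].
#' @param species optional tag stored on the result.
#' @return object of class `population_scale`: list with `radii`,
#'   `var_fpt_mean`, `r_pop`, `n_individuals`, `species`.
#' @export
population_peak <- function(profiles, species = NA_character_) {
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  r0 <- profiles[[1]]$radii
  for (p in profiles) {
    stopifnot(inherits(p, "fpt_profile"))
    if (length(p$radii) != length(r0) || any(p$radii != r0))
      stop("profiles must share one radius grid", call. = FALSE)
    if (is.null(p$var_log))
      stop("run var_log_fpt() on each profile first", call. = FALSE)
  }
  vmat <- do.call(rbind, lapply(profiles, `[[`, "var_log"))
  vmean <- colMeans(vmat, na.rm = TRUE)
  vmean[!is.finite(vmean)] <- NA_real_
  if (all(is.na(vmean))) stop("no radius has a defined mean variance",
                              call. = FALSE)
  structure(list(radii = r0, var_fpt_mean = vmean,
                 r_pop = r0[which.max(vmean)],
                 n_individuals = length(profiles), species = species),
            class = "population_scale")
}

#' @export
print.population_scale <- function(x, ...) {
  cat(sprintf("<population_scale>%s r_pop = %g m (peak of mean var-log-FPT over %d individual%s)\n",
              if (is.na(x$species)) "" else paste0(" ", x$species, ":"),
              x$r_pop, x$n_individuals,
              if (x$n_individuals == 1) "" else "s"))
  invisible(x)
}

#' Export an FPT matrix or variance curve as CSV
#'
#' @param prof an `fpt_profile`.
#' @param path output file.
#' @param what `"fpt"` (fix x radius matrix) or `"var"` (variance curve).
#' @export
fpt_to_csv <- function(prof, path, what = c("fpt", "var")) {
  what <- match.arg(what)
  if (what == "fpt") {
    df <- as.data.frame(prof$fpt)
    names(df) <- sprintf("r%g", prof$radii)
    df <- cbind(time = format(prof$time, "%Y-%m-%dT%H:%M:%SZ"), df)
  } else {
    df <- data.frame(radius_m = prof$radii, var_log_fpt = prof$var_log)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
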