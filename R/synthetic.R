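#' Configuration for the two-mode forager simulator
#'
#' Defines a composite correlated random walk with two behavioural modes:
#' *intensive* (area-restricted search inside a circular resource patch:
#' short steps, strong turning) and *extensive* (commuting between patches:
#' long, directed steps). Patch centres are placed on a jittered ring of
#' radius `patch_spacing`, which guarantees the spacing invariant
#' `patch_spacing > 2 * patch_radius`.
#'
#' Defaults emulate a GPS-tracked waterbird: 2-h fixes, 500-m foraging
#' patches spaced 6 km apart, c. 2-day residences (24 fixes), 60-m median
#' intensive steps and 1,500-m median commuting steps.
#'
#' @param n_patches number of patches (>= 1).
#' @param patch_radius patch radius, metres.
#' @param patch_spacing ring radius for patch centres, metres
#'   (> 2 * patch_radius).
#' @param fix_interval time between fixes, seconds.
#' @param step_intensive,step_extensive median step length (m) per mode
#'   (step lengths are lognormal with `sdlog`).
#' @param turn_sd_intensive,turn_sd_extensive wrapped-normal turning-angle
#'   standard deviation (radians) per mode.
#' @param residence_fixes mean number of fixes spent in a patch per visit
#'   (geometric residence).
#' @param n_fixes total fixes to emit.
#' @param sdlog lognormal sdlog of step lengths.
#' @param seed integer seed.
#' @return list of class `forager_config`.
#' @export
forager_config <- function(n_patches = 5, patch_radius = 500,
                           patch_spacing = 6000, fix_interval = 7200,
                           step_intensive = 60, step_extensive = 1500,
                           turn_sd_intensive = 2.5, turn_sd_extensive = 0.3,
                           residence_fixes = 24, n_fixes = 600,
                           sdlog = 0.3, seed = 1) {
  stopifnot(n_patches >= 1, patch_radius > 0,
            patch_spacing > 2 * patch_radius,
            fix_interval > 0, step_intensive > 0, step_extensive > 0,
            residence_fixes >= 1, n_fixes >= 2, sdlog > 0)
  structure(as.list(environment()), class = "forager_config")
}

#' Simulate a two-mode foraging track
#'
#' Composite correlated random walk per [forager_config()]: within a patch
#' the walker takes short, strongly turning steps (headings updated by
#' wrapped-normal increments) and is reflected back toward the patch centre
#' at the boundary; after a geometrically distributed residence it commutes
#' to a uniformly chosen other patch with long, directed steps until it
#' enters the target patch. One fix is emitted per step at `fix_interval`.
#' Lon/lat coordinates are synthesised by inverse-projecting the planar
#' walk around a nominal centre so the track exercises the projection
#' path; planar coordinates are exact.
#'
#' @param cfg a [forager_config()].
#' @param id individual identifier.
#' @param species species tag.
#' @param origin POSIXct start time.
#' @return list with `track` (a projected [track]) and `truth` (list:
#'   `mode` -- "intensive"/"extensive" per fix, `patch` -- patch index or
#'   NA per fix, `centers` -- n_patches x 2 matrix, `patch_radius`,
#'   `switches` -- fix indices at which the mode changes).
#' @export
simulate_forager <- function(cfg, id = "sim1", species = "SIM",
                             origin = as.POSIXct("2020-01-01", tz = "UTC")) {
  stopifnot(inherits(cfg, "forager_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  ## patch centres on a jittered ring
  ang <- 2 * pi * (seq_len(cfg$n_patches) - 1) / cfg$n_patches +
    stats::runif(cfg$n_patches, -0.15, 0.15) * 2 * pi / cfg$n_patches
  rad <- cfg$patch_spacing * (1 + stats::runif(cfg$n_patches, -0.05, 0.05))
  centers <- if (cfg$n_patches == 1) matrix(0, 1, 2) else
    cbind(rad * cos(ang), rad * sin(ang))

  n <- cfg$n_fixes
  x <- numeric(n); y <- numeric(n)
  mode <- character(n); patch <- rep(NA_integer_, n)
  cur <- 1L
  pos <- centers[cur, ] + stats::runif(2, -0.3, 0.3) * cfg$patch_radius
  heading <- stats::runif(1, -pi, pi)
  state <- "intensive"
  remaining <- 1L + stats::rgeom(1, 1 / cfg$residence_fixes)
  target <- NA_integer_
  x[1] <- pos[1]; y[1] <- pos[2]; mode[1] <- state; patch[1] <- cur

  draw_step <- function(scale) stats::rlnorm(1, log(scale), cfg$sdlog)

  for (i in 2:n) {
    if (state == "intensive") {
      heading <- heading + stats::rnorm(1, 0, cfg$turn_sd_intensive)
      len <- draw_step(cfg$step_intensive)
      prop <- pos + len * c(cos(heading), sin(heading))
      if (sqrt(sum((prop - centers[cur, ])^2)) > cfg$patch_radius) {
        ## reflect: head back toward the centre with some scatter
        heading <- atan2(centers[cur, 2] - pos[2],
                         centers[cur, 1] - pos[1]) +
          stats::rnorm(1, 0, 0.5)
        prop <- pos + len * c(cos(heading), sin(heading))
        off <- prop - centers[cur, ]
        d <- sqrt(sum(off^2))
        if (d > cfg$patch_radius)   # hard clamp to the patch boundary
          prop <- centers[cur, ] + off * (cfg$patch_radius / d) * 0.999
      }
      pos <- prop
      remaining <- remaining - 1L
      mode[i] <- "intensive"; patch[i] <- cur
      if (remaining <= 0L && cfg$n_patches > 1L) {
        state <- "extensive"
        target <- sample(setdiff(seq_len(cfg$n_patches), cur), 1)
        heading <- atan2(centers[target, 2] - pos[2],
                         centers[target, 1] - pos[1])
      }
    } else {
      bearing <- atan2(centers[target, 2] - pos[2],
                       centers[target, 1] - pos[1])
      heading <- bearing + stats::rnorm(1, 0, cfg$turn_sd_extensive)
      len <- draw_step(cfg$step_extensive)
      dist_left <- sqrt(sum((centers[target, ] - pos)^2))
      len <- min(len, dist_left)   # do not overshoot the target patch
      pos <- pos + len * c(cos(heading), sin(heading))
      mode[i] <- "extensive"
      if (sqrt(sum((pos - centers[target, ])^2)) <= cfg$patch_radius) {
        cur <- target
        state <- "intensive"
        remaining <- 1L + stats::rgeom(1, 1 / cfg$residence_fixes)
        heading <- stats::runif(1, -pi, pi)
      }
    }
    x[i] <- pos[1]; y[i] <- pos[2]
  }

  tt <- origin + (seq_len(n) - 1) * cfg$fix_interval
  ## synthesise geographic coordinates around a nominal southern-African
  ## centre so the ingest/projection path can be exercised end to end
  ll <- aeqd_inverse(x, y, lon0 = 25, lat0 = -28)
  fx <- data.frame(time = tt, lon = ll[, "lon"], lat = ll[, "lat"],
                   x = x, y = y)
  tr <- track(fx, id = id, species = species,
              crs_note = "aeqd centre lon=25.00000000 lat=-28.00000000 (simulated)")
  switches <- which(mode[-1] != mode[-n]) + 1L
  list(track = tr,
       truth = list(mode = mode, patch = patch, centers = centers,
                    patch_radius = cfg$patch_radius, switches = switches))
}

#' Draw a lognormal (or lognormal-mixture) patch-area sample
#'
#' Generates synthetic patch areas for the statistical layer: a single
#' lognormal component, or a two-component mixture for constructing
#' multimodal test cases.
#'
#' @param n sample size.
#' @param log_mean,log_sd mean and sd of log area (first component).
#' @param mix_weight weight of the first component (1 = single component).
#' @param log_mean2,log_sd2 second-component parameters (required when
#'   `mix_weight < 1`).
#' @param group group label for the resulting [area_sample()].
#' @param seed integer seed.
#' @return an [area_sample()].
#' @export
sample_patch_areas <- function(n, log_mean, log_sd, mix_weight = 1,
                               log_mean2 = NULL, log_sd2 = NULL,
                               group = "synthetic", seed = 1) {
  stopifnot(n >= 1, log_sd > 0)
  if (mix_weight < 0 || mix_weight > 1)
    stop("mix_weight must be in [0, 1]", call. = FALSE)
  if (mix_weight < 1 && (is.null(log_mean2) || is.null(log_sd2)))
    stop("mixture requested but second component not specified",
         call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (mix_weight == 1) {
    la <- stats::rnorm(n, log_mean, log_sd)
  } else {
    comp1 <- stats::runif(n) < mix_weight
    la <- ifelse(comp1, stats::rnorm(n, log_mean, log_sd),
                 stats::rnorm(n, log_mean2, log_sd2))
  }
  area_sample(exp(la), group = group)
}

#' Write a simulated track (and its ground truth) as delimited text
#'
#' Emits the same CSV format [load_tracks()] reads, plus an optional
#' sidecar CSV with the per-fix behavioural mode and patch index.
#'
#' @param sim result of [simulate_forager()].
#' @param path CSV path for the track.
#' @param truth_path optional CSV path for the ground truth.
#' @export
write_sim_csv <- function(sim, path, truth_path = NULL) {
  fx <- sim$track$fixes
  df <- data.frame(id = track_id(sim$track),
                   species = sim$track$species,
                   time = format(fx$time, "%Y-%m-%dT%H:%M:%SZ"),
                   lon = fx$lon, lat = fx$lat)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path))
    utils::write.csv(data.frame(fix = seq_along(sim$truth$mode),
                                mode = sim$truth$mode,
                                patch = sim$truth$patch),
                     truth_path, row.names = FALSE)
  invisible(path)
}
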