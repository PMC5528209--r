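#' Per-species analysis settings
#'
#' Bundles the settings that differ between study species: the nominal fix
#' interval, the minimum bout length `Lmin` (in fixes), the FPT radius
#' grid, the biased-random-bridge smoothing parameters, and the isopleth
#' level. `Lmin` and the fix interval are linked by the equal-duration
#' policy: the minimum bout duration `Lmin * fix_interval` should be the
#' same for all species being compared (24 h in the waterfowl defaults),
#' so that bouts are comparable units despite different tag duty cycles.
#'
#' @param fix_interval nominal time between fixes, seconds.
#' @param Lmin minimum bout length, fixes.
#' @param radii FPT radius grid, see [radius_grid()].
#' @param brb smoothing parameters, see [brb_params()]; defaults derive
#'   `Tmax = 3 * fix_interval` and `tau = fix_interval / 10`.
#' @param isopleth UD isopleth level.
#' @param Kmax optional cap on segment count (default: per-track rule in
#'   [segment_path()]).
#' @return list of class `species_settings`.
#' @export
species_settings <- function(fix_interval, Lmin,
                             radii = radius_grid(),
                             brb = brb_params(Tmax = 3 * fix_interval,
                                              tau = fix_interval / 10),
                             isopleth = 0.95, Kmax = NULL) {
  stopifnot(fix_interval > 0, Lmin >= 2)
  structure(list(fix_interval = fix_interval, Lmin = Lmin, radii = radii,
                 brb = brb, isopleth = isopleth, Kmax = Kmax),
            class = "species_settings")
}

#' Default settings for the two study duck species
#'
#' Egyptian Goose (`EG`): 2-h fixes, `Lmin = 12`; Red-billed Teal (`RBT`):
#' 4-h fixes, `Lmin = 6`. Both give a minimum bout duration of 24 h.
#'
#' @return named list of [species_settings()].
#' @export
default_species_settings <- function() {
  list(EG = species_settings(fix_interval = 7200, Lmin = 12),
       RBT = species_settings(fix_interval = 14400, Lmin = 6))
}

#' Minimum bout duration implied by species settings
#'
#' @param settings named list of [species_settings()].
#' @return named numeric vector of `Lmin * fix_interval` in hours.
#' @export
min_bout_hours <- function(settings) {
  vapply(settings, function(s) s$Lmin * s$fix_interval / 3600, numeric(1))
}

#' Framework-wide configuration
#'
#' @param species named list of [species_settings()], one per group.
#' @param split_gap maximum tolerated sampling gap, seconds (tracks are
#'   split on larger gaps).
#' @param k_max largest mode count scanned by [modality_scan()].
#' @param B bootstrap replicates for Silverman's test.
#' @param alpha KS detection level.
#' @param S Lavielle curvature threshold.
#' @param cutoff multimodality decision threshold.
#' @param run_modality,run_sensitivity switch the statistical stages on or
#'   off.
#' @param sens_increment,sens_max_delta sensitivity shift grid.
#' @return list of class `framework_config`.
#' @export
framework_config <- function(species = default_species_settings(),
                             split_gap = 7 * 86400, k_max = 30, B = 999,
                             alpha = 0.05, S = 0.75, cutoff = 0.95,
                             run_modality = TRUE, run_sensitivity = FALSE,
                             sens_increment = 0.01, sens_max_delta = 2) {
  bh <- min_bout_hours(species)
  if (length(unique(round(bh, 6))) > 1)
    warning(sprintf("unequal minimum bout durations across species (%s h)",
                    paste(round(bh, 2), collapse = ", ")), call. = FALSE)
  structure(list(species = species, split_gap = split_gap, k_max = k_max,
                 B = B, alpha = alpha, S = S, cutoff = cutoff,
                 run_modality = run_modality,
                 run_sensitivity = run_sensitivity,
                 sens_increment = sens_increment,
                 sens_max_delta = sens_max_delta),
            class = "framework_config")
}

#' Read a framework configuration from a YAML file
#'
#' Expected layout: a `shared` block (split_gap_days, k_max, B, alpha, S,
#' cutoff) and a `species` block with one entry per group giving
#' `fix_interval`, `Lmin`, optional `r_min`/`r_max`/`r_step`,
#' `hmin`/`cell_size`/`Tmax`/`tau`, `isopleth`.
#'
#' @param path YAML file.
#' @return a [framework_config()].
#' @export
read_framework_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- lapply(y$species, function(s) {
    radii <- radius_grid(r_min = s$r_min %||% 100,
                         r_max = s$r_max %||% 10000,
                         step = s$r_step %||% 80)
    brb <- brb_params(hmin = s$hmin %||% 100,
                      Tmax = s$Tmax %||% (3 * s$fix_interval),
                      tau = s$tau %||% (s$fix_interval / 10),
                      cell_size = s$cell_size %||% 50)
    species_settings(fix_interval = s$fix_interval, Lmin = s$Lmin,
                     radii = radii, brb = brb,
                     isopleth = s$isopleth %||% 0.95)
  })
  sh <- y$shared %||% list()
  framework_config(species = sp,
                   split_gap = (sh$split_gap_days %||% 7) * 86400,
                   k_max = sh$k_max %||% 30, B = sh$B %||% 999,
                   alpha = sh$alpha %||% 0.05, S = sh$S %||% 0.75,
                   cutoff = sh$cutoff %||% 0.95,
                   run_modality = sh$run_modality %||% TRUE,
                   run_sensitivity = sh$run_sensitivity %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full foraging-scale framework
#'
#' End-to-end analysis: per species, tracks are split on sampling gaps,
#' projected, analysed with FPT over the species' radius grid, the
#' population var-log-FPT peak fixes `r_pop`, each track's FPT series at
#' `r_pop` is segmented into bouts, each bout's fixes yield a
#' biased-random-bridge UD whose 95%-isopleth components are the foraging
#' patches; patch areas are pooled per species. Species pairs are then
#' compared with the two-sample KS test on log areas, each species'
#' area distribution is scanned for multimodality, and (optionally) the
#' shift-sensitivity analysis is run.
#'
#' @param tracks list of [track] objects; each track's `species` tag must
#'   match a name of `config$species`.
#' @param config a [framework_config()].
#' @param seed integer seed driving every stochastic stage (Silverman
#'   bootstraps); recorded in the manifest.
#' @return object of class `forage_scales`: per-species results
#'   (`$species[[g]]`: `tracks`, `profiles`, `scale`, `segmentations`,
#'   `patch_sets`, `areas`), `$ks` (list of pairwise `ks_result`),
#'   `$modality` (per-species `modality_scan`), `$sensitivity`
#'   (per-species list with `ks` and `bimodality` results, if run),
#'   `$config`, `$manifest`.
#' @export
forage_scales <- function(tracks, config = framework_config(), seed = 1) {
  stopifnot(inherits(config, "framework_config"))
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  groups <- vapply(tracks, function(t) t$species, character(1))
  unknown <- setdiff(unique(groups), names(config$species))
  if (length(unknown))
    stop("no settings for species: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  per_species <- list()
  for (g in intersect(names(config$species), unique(groups))) {
    st <- config$species[[g]]
    trs <- tracks[groups == g]
    ## split -> project
    pieces <- unlist(lapply(trs, split_on_gaps, max_gap = config$split_gap),
                     recursive = FALSE)
    pieces <- lapply(pieces, function(tr)
      if (is_projected(tr)) tr else project_planar(tr))
    ## FPT and population scale
    profiles <- lapply(pieces, function(tr)
      var_log_fpt(compute_fpt(tr, st$radii)))
    scale <- population_peak(profiles, species = g)
    ## segmentation and patches
    segmentations <- list()
    patch_sets <- list()
    for (i in seq_along(pieces)) {
      seg <- segment_path(pieces[[i]], profiles[[i]], scale,
                          Lmin = st$Lmin, Kmax = st$Kmax, S = config$S)
      segmentations[[i]] <- seg
      for (k in seq_len(nrow(seg$segments))) {
        rows <- seg$segments$start_fix[k]:seg$segments$end_fix[k]
        fx <- pieces[[i]]$fixes[rows, , drop = FALSE]
        if (nrow(fx) < 2) next
        ud <- build_ud(fx, st$brb)
        patch_sets[[length(patch_sets) + 1L]] <-
          extract_patches(ud, isopleth = st$isopleth,
                          id = track_id(pieces[[i]]), segment = k)
      }
    }
    per_species[[g]] <- list(
      tracks = pieces, profiles = profiles, scale = scale,
      segmentations = segmentations, patch_sets = patch_sets,
      areas = pool_patches(patch_sets, group = g))
  }

  gs <- names(per_species)
  ks <- list()
  if (length(gs) >= 2)
    for (i in seq_len(length(gs) - 1)) for (j in (i + 1):length(gs))
      ks[[paste(gs[i], gs[j], sep = "_vs_")]] <-
        ks_compare(per_species[[gs[i]]]$areas, per_species[[gs[j]]]$areas)

  modality <- NULL
  if (config$run_modality)
    modality <- lapply(per_species, function(ps)
      modality_scan(ps$areas, k_max = config$k_max, B = config$B,
                    seed = seed, cutoff = config$cutoff))

  sensitivity <- NULL
  if (config$run_sensitivity)
    sensitivity <- lapply(per_species, function(ps) list(
      ks = ks_shift_threshold(ps$areas, increment = config$sens_increment,
                              max_delta = config$sens_max_delta,
                              alpha = config$alpha),
      bimodality = pooled_bimodality_threshold(
        ps$areas, increment = config$sens_increment,
        max_delta = config$sens_max_delta, B = config$B, seed = seed,
        cutoff = config$cutoff)))

  manifest <- list(
    package = "foragescales",
    version = as.character(utils::packageVersion("foragescales")),
    seed = seed,
    n_tracks = length(tracks),
    species = lapply(per_species, function(ps) list(
      n_track_pieces = length(ps$tracks),
      r_pop = ps$scale$r_pop,
      n_patches = length(ps$areas$areas))),
    config = list(split_gap = config$split_gap, k_max = config$k_max,
                  B = config$B, alpha = config$alpha, S = config$S,
                  cutoff = config$cutoff))

  structure(list(species = per_species, ks = ks, modality = modality,
                 sensitivity = sensitivity, config = config,
                 manifest = manifest),
            class = "forage_scales")
}

#' @export
print.forage_scales <- function(x, ...) {
  cat("<forage_scales> foraging-scale comparison\n")
  for (g in names(x$species)) {
    ps <- x$species[[g]]
    cat(sprintf("  %s: %d track piece(s), r_pop = %g m, %d patches (median %.3f km^2)\n",
                g, length(ps$tracks), ps$scale$r_pop,
                length(ps$areas$areas),
                stats::median(ps$areas$areas) / 1e6))
  }
  for (nm in names(x$ks)) {
    k <- x$ks[[nm]]
    cat(sprintf("  KS %s: D = %.4f, p = %.4g\n", nm, k$D, k$p))
  }
  if (!is.null(x$modality))
    for (g in names(x$modality)) {
      m <- x$modality[[g]]
      cat(sprintf("  modality %s: max support m = %.3f at k = %d (%s)\n",
                  g, m$best_m, m$best_k,
                  if (m$any_multimodal) "multimodal" else "no cut-off reached"))
    }
  invisible(x)
}

#' @export
summary.forage_scales <- function(object, ...) {
  out <- list(
    tracks = do.call(rbind, lapply(object$species, function(ps)
      summarize_tracks(ps$tracks))),
    scales = data.frame(
      species = names(object$species),
      r_pop = vapply(object$species, function(ps) ps$scale$r_pop,
                     numeric(1)),
      n_patches = vapply(object$species,
                         function(ps) length(ps$areas$areas), numeric(1)),
      mean_log_area = vapply(object$species,
                             function(ps) mean(ps$areas$log_areas),
                             numeric(1))),
    ks = object$ks)
  class(out) <- "summary.forage_scales"
  out
}

#' @export
print.summary.forage_scales <- function(x, ...) {
  cat("Track summaries:\n")
  print(x$tracks, row.names = FALSE)
  cat("\nSpecies scales and patches:\n")
  print(x$scales, row.names = FALSE)
  for (nm in names(x$ks))
    cat(sprintf("\nKS %s: D = %.4f, p = %.4g\n", nm, x$ks[[nm]]$D,
                x$ks[[nm]]$p))
  invisible(x)
}

#' Plot a forage_scales result
#'
#' Two base-graphics panels: the per-species mean variance-of-log-FPT
#' curves with their peaks (the population scales), and the smoothed
#' density histograms of log patch areas per species.
#'
#' @param x a `forage_scales` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.forage_scales <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(max(2L, length(x$species)), "Dark 2")
  ## panel 1: var-log-FPT
  ylim <- range(unlist(lapply(x$species, function(ps)
    ps$scale$var_fpt_mean)), na.rm = TRUE)
  first <- TRUE
  for (i in seq_along(x$species)) {
    ps <- x$species[[i]]
    if (first) {
      graphics::plot(ps$scale$radii, ps$scale$var_fpt_mean, type = "l",
                     col = cols[i], ylim = ylim, xlab = "radius (m)",
                     ylab = "mean var(log FPT)",
                     main = "Scale diagnostic", ...)
      first <- FALSE
    } else graphics::lines(ps$scale$radii, ps$scale$var_fpt_mean,
                           col = cols[i])
    graphics::abline(v = ps$scale$r_pop, col = cols[i], lty = 3)
  }
  graphics::legend("topright", legend = names(x$species),
                   col = cols[seq_along(x$species)], lty = 1, bty = "n")
  ## panel 2: log-area densities
  dens <- lapply(x$species, function(ps) stats::density(ps$areas$log_areas))
  graphics::plot(NA, xlim = range(unlist(lapply(dens, `[[`, "x"))),
                 ylim = c(0, max(unlist(lapply(dens, `[[`, "y")))),
                 xlab = "log patch area (m^2)", ylab = "density",
                 main = "Patch areas")
  for (i in seq_along(dens))
    graphics::lines(dens[[i]], col = cols[i])
  invisible(x)
}

#' Write all framework artifacts to a directory
#'
#' Writes, deterministically (reruns with the same input and seed are
#' byte-identical): `track_summary.csv`, per-species `var_fpt_<sp>.csv`,
#' `segments.csv`, `patches.csv`, `ks.json`, `modality_<sp>.csv`,
#' `sensitivity_<sp>_<kind>.csv` and `manifest.json`.
#'
#' @param x a `forage_scales` result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "forage_scales"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary(x)$tracks, file.path(dir, "track_summary.csv"),
                   row.names = FALSE)
  segs <- list(); pats <- list()
  for (g in names(x$species)) {
    ps <- x$species[[g]]
    utils::write.csv(data.frame(radius_m = ps$scale$radii,
                                var_fpt_mean = ps$scale$var_fpt_mean),
                     file.path(dir, sprintf("var_fpt_%s.csv", g)),
                     row.names = FALSE)
    for (sg in ps$segmentations) {
      df <- sg$segments
      df$start_time <- format(df$start_time, "%Y-%m-%dT%H:%M:%SZ")
      df$end_time <- format(df$end_time, "%Y-%m-%dT%H:%M:%SZ")
      segs[[length(segs) + 1L]] <- cbind(species = g, id = sg$id, df)
    }
    for (pset in ps$patch_sets) {
      df <- pset$patches
      df$area_km2 <- df$area_m2 / 1e6
      pats[[length(pats) + 1L]] <- cbind(species = g, df)
    }
  }
  if (length(segs))
    utils::write.csv(do.call(rbind, segs), file.path(dir, "segments.csv"),
                     row.names = FALSE)
  if (length(pats))
    utils::write.csv(do.call(rbind, pats), file.path(dir, "patches.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    lapply(x$ks, function(k) list(D = k$D, p = k$p, n1 = k$n1, n2 = k$n2)),
    file.path(dir, "ks.json"), auto_unbox = TRUE, digits = 12)
  if (!is.null(x$modality))
    for (g in names(x$modality))
      modality_to_csv(x$modality[[g]],
                      file.path(dir, sprintf("modality_%s.csv", g)))
  if (!is.null(x$sensitivity))
    for (g in names(x$sensitivity)) {
      sensitivity_to_csv(x$sensitivity[[g]]$ks,
                         file.path(dir, sprintf("sensitivity_%s_ks.csv", g)))
      sensitivity_to_csv(x$sensitivity[[g]]$bimodality,
                         file.path(dir,
                                   sprintf("sensitivity_%s_bimodality.csv", g)))
    }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 12)
  invisible(dir)
}
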