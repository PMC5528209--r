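#' Biased-random-bridge smoothing parameters
#'
#' Parameters of the movement-based kernel density estimator. `hmin` is the
#' minimum smoothing bandwidth (metres), applied at step endpoints; it
#' should exceed the GPS location error by a comfortable margin (default
#' 100 m for c. 10-20 m accuracy). `Tmax` is the longest step duration
#' still treated as continuous movement; longer steps are treated as track
#' interruptions and skipped (default 3x the nominal fix interval).
#' `tau` is the time step at which each movement step is interpolated
#' (default fix interval / 10), and `cell_size` the UD raster resolution.
#'
#' @param hmin minimum bandwidth, metres.
#' @param D diffusion coefficient, m^2/s, or `NA` to estimate per segment
#'   with [estimate_diffusion()].
#' @param Tmax maximum step duration, seconds.
#' @param tau interpolation time step, seconds.
#' @param cell_size raster cell size, metres.
#' @return list of class `brb_params`.
#' @export
brb_params <- function(hmin = 100, D = NA_real_, Tmax = 3 * 7200,
                       tau = 720, cell_size = 50) {
  stopifnot(hmin > 0, Tmax > 0, tau > 0, cell_size > 0,
            is.na(D) || D >= 0)
  structure(list(hmin = hmin, D = D, Tmax = Tmax, tau = tau,
                 cell_size = cell_size), class = "brb_params")
}

#' Estimate a diffusion coefficient from step data
#'
#' Plug-in diffusion coefficient for the biased-random-bridge kernel,
#' estimated as `median(d_i^2 / (4 T_i)) / ln 2` over steps no longer than
#' `Tmax` (step length `d_i`, duration `T_i`). The median makes the
#' estimate robust to the occasional commuting step inside a bout; the
#' `1/ln 2` factor rescales the median to the mean of the chi-square(2)
#' step-length-squared law so the estimator is consistent under planar
#' Brownian motion.
#'
#' @param fixes data.frame with `time`, `x`, `y` (a segment's fixes).
#' @param Tmax maximum step duration (seconds) to include.
#' @return D in m^2/s.
#' @export
estimate_diffusion <- function(fixes, Tmax = Inf) {
  stopifnot(nrow(fixes) >= 2)
  d2 <- diff(fixes$x)^2 + diff(fixes$y)^2
  Tt <- diff(as.numeric(fixes$time))
  ok <- Tt <= Tmax & Tt > 0
  if (!any(ok)) stop("no steps with duration <= Tmax", call. = FALSE)
  stats::median(d2[ok] / (4 * Tt[ok])) / log(2)
}

#' Movement-based kernel utilization distribution of a segment
#'
#' Builds the biased-random-bridge UD: each movement step (duration
#' `T <= Tmax`) is interpolated at time step `tau` along the straight line
#' between its endpoints, and each interpolated point at relative position
#' `p` contributes an isotropic Gaussian kernel with variance
#' `h^2(p) = hmin^2 + 4 p (1-p) D T` -- minimal at the observed endpoints
#' and maximal mid-step, where the animal's true position is least
#' constrained. Each step's total weight is proportional to its duration,
#' so the UD estimates time spent per unit area. The raster is normalised
#' to total mass 1.
#'
#' @param fixes data.frame with `time`, `x`, `y` (projected metres).
#' @param params a [brb_params()]; if `params$D` is `NA` it is estimated
#'   from the fixes via [estimate_diffusion()].
#' @return object of class `ud_grid`: list with `x`, `y` (cell-centre
#'   coordinates), `z` (n_x x n_y matrix of cell probability masses summing
#'   to 1), `cell_size`, `params`, `D`.
#' @export
build_ud <- function(fixes, params = brb_params()) {
  stopifnot(inherits(params, "brb_params"), nrow(fixes) >= 2)
  if (is.null(fixes$x) || is.null(fixes$y))
    stop("fixes must carry projected x/y coordinates", call. = FALSE)
  tt <- as.numeric(fixes$time)
  Tt <- diff(tt)
  use <- which(Tt <= params$Tmax & Tt >= 0)
  if (!length(use)) stop("all steps exceed Tmax", call. = FALSE)
  D <- if (is.na(params$D)) estimate_diffusion(fixes, params$Tmax) else params$D

  ## interpolated kernel centres: midpoints of tau-sized sub-intervals
  cx <- list(); cy <- list(); ch <- list(); cw <- list()
  for (k in seq_along(use)) {
    i <- use[k]
    Ti <- max(Tt[i], 1e-9)
    m <- max(1L, as.integer(round(Ti / params$tau)))
    p <- (seq_len(m) - 0.5) / m
    cx[[k]] <- fixes$x[i] + p * (fixes$x[i + 1] - fixes$x[i])
    cy[[k]] <- fixes$y[i] + p * (fixes$y[i + 1] - fixes$y[i])
    ch[[k]] <- sqrt(params$hmin^2 + 4 * p * (1 - p) * D * Ti)
    cw[[k]] <- rep(Ti / m, m)
  }
  cx <- unlist(cx); cy <- unlist(cy); ch <- unlist(ch); cw <- unlist(cw)

  cs <- params$cell_size
  pad <- 3.5 * max(ch) + cs
  x0 <- floor((min(cx) - pad) / cs) * cs
  y0 <- floor((min(cy) - pad) / cs) * cs
  nx <- ceiling((max(cx) + pad - x0) / cs) + 1L
  ny <- ceiling((max(cy) + pad - y0) / cs) + 1L
  gx <- x0 + (seq_len(nx) - 0.5) * cs
  gy <- y0 + (seq_len(ny) - 0.5) * cs
  z <- matrix(0, nx, ny)
  ## separable Gaussian accumulation on a local window per kernel
  for (k in seq_along(cx)) {
    h <- ch[k]; r <- 3.5 * h
    ix <- max(1L, ceiling((cx[k] - r - x0) / cs)):min(nx, floor((cx[k] + r - x0) / cs) + 1L)
    iy <- max(1L, ceiling((cy[k] - r - y0) / cs)):min(ny, floor((cy[k] + r - y0) / cs) + 1L)
    z[ix, iy] <- z[ix, iy] +
      cw[k] * tcrossprod(stats::dnorm(gx[ix], cx[k], h),
                         stats::dnorm(gy[iy], cy[k], h))
  }
  z <- z / sum(z)
  structure(list(x = gx, y = gy, z = z, cell_size = cs,
                 origin = c(x0, y0), params = params, D = D),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid> %d x %d cells of %g m (D = %.3g m^2/s), total mass %.6f\n",
              length(x$x), length(x$y), x$cell_size, x$D, sum(x$z)))
  invisible(x)
}

## 8-connected component labelling of a logical matrix, union-find over
## the TRUE cells only (raster scan order: up the column, previous column).
.label8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  sel <- which(mask)                   # sorted: column-major scan order
  if (!length(sel)) return(lab)
  parent <- seq_along(sel)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (s in seq_along(sel)) {
    lin <- sel[s]
    i <- ((lin - 1L) %% nx) + 1L
    j <- ((lin - 1L) %/% nx) + 1L
    nb <- integer(0)
    if (i > 1L && mask[lin - 1L]) nb <- lab[lin - 1L]
    if (j > 1L) {
      base <- lin - nx
      if (mask[base]) nb <- c(nb, lab[base])
      if (i > 1L && mask[base - 1L]) nb <- c(nb, lab[base - 1L])
      if (i < nx && mask[base + 1L]) nb <- c(nb, lab[base + 1L])
    }
    if (!length(nb)) {
      lab[lin] <- s
    } else {
      roots <- unique(vapply(nb, find, integer(1)))
      keep <- min(c(roots, s))
      lab[lin] <- keep
      parent[s] <- keep
      for (r in roots) parent[r] <- keep
    }
  }
  root <- vapply(seq_along(sel), find, integer(1))
  lab[sel] <- match(root, sort(unique(root)))
  lab
}

#' Extract foraging patches from a utilization distribution
#'
#' Selects the smallest set of highest-density cells whose cumulative mass
#' reaches the isopleth level (ties in density broken by row-major cell
#' index), partitions the selected cells into 8-connected components, and
#' returns each component as one patch. Patch area is cell count times cell
#' area; these cell-based areas are the framework's sampling units.
#'
#' @param ud a `ud_grid` from [build_ud()].
#' @param isopleth cumulative-mass level in (0, 1); default 0.95, the
#'   conventional home-range level.
#' @param id,segment optional provenance tags stored with each patch.
#' @return object of class `patch_set`: list with `patches` (data.frame:
#'   patch, area_m2, mass, n_cells, id, segment), `cells` (list of cell
#'   index matrices per patch), `ud_dim`, `cell_size`, `origin`,
#'   `isopleth`, `selected_mass`, `max_cell_mass`.
#' @export
extract_patches <- function(ud, isopleth = 0.95, id = NA_character_,
                            segment = NA_integer_) {
  stopifnot(inherits(ud, "ud_grid"))
  if (!(isopleth > 0 && isopleth < 1))
    stop("isopleth must be in (0, 1)", call. = FALSE)
  zv <- as.vector(ud$z)
  ord <- order(-zv, seq_along(zv))     # density desc, row-major on ties
  cum <- cumsum(zv[ord])
  ncel <- which(cum >= isopleth)[1]
  if (is.na(ncel)) ncel <- length(ord)
  sel <- ord[seq_len(ncel)]
  mask <- matrix(FALSE, nrow(ud$z), ncol(ud$z))
  mask[sel] <- TRUE
  lab <- .label8(mask)
  cellarea <- ud$cell_size^2
  nx <- nrow(ud$z)
  bylab <- split(sel, lab[sel])
  bylab <- bylab[order(as.integer(names(bylab)))]
  cells <- lapply(bylab, function(lin)
    cbind(row = ((lin - 1L) %% nx) + 1L, col = ((lin - 1L) %/% nx) + 1L))
  names(cells) <- NULL
  patches <- data.frame(
    patch = seq_along(bylab),
    area_m2 = vapply(bylab, length, integer(1)) * cellarea,
    mass = vapply(bylab, function(lin) sum(zv[lin]), numeric(1)),
    n_cells = vapply(bylab, length, integer(1)),
    id = id, segment = segment, row.names = NULL)
  structure(list(patches = patches, cells = cells,
                 ud_dim = dim(ud$z), cell_size = ud$cell_size,
                 origin = ud$origin, isopleth = isopleth,
                 selected_mass = cum[ncel], max_cell_mass = max(zv)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patch%s at the %.0f%% isopleth, total area %.3f km^2\n",
              nrow(x$patches), if (nrow(x$patches) == 1) "" else "es",
              100 * x$isopleth, sum(x$patches$area_m2) / 1e6))
  invisible(x)
}

#' Pool patch sets into one area sample
#'
#' @param patch_sets list of `patch_set` objects from one group/species.
#' @param group group label.
#' @return an [area_sample()].
#' @export
pool_patches <- function(patch_sets, group = NA_character_) {
  areas <- unlist(lapply(patch_sets, function(p) p$patches$area_m2))
  area_sample(areas, group = group)
}

#' Write a UD raster as an ESRI ASCII grid
#'
#' @param ud a `ud_grid`.
#' @param path output file.
#' @export
ud_to_asc <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(ud$x)),
               sprintf("nrows %d", length(ud$y)),
               sprintf("xllcorner %.3f", ud$origin[1]),
               sprintf("yllcorner %.3f", ud$origin[2]),
               sprintf("cellsize %.3f", ud$cell_size),
               "NODATA_value -9999"), con)
  ## ASCII grids are written north to south
  for (j in rev(seq_along(ud$y)))
    writeLines(paste(formatC(ud$z[, j], format = "e", digits = 6),
                     collapse = " "), con)
  invisible(path)
}

#' Export patches as GeoJSON polygons
#'
#' Each patch is exported as a MultiPolygon of row-run rectangles (the
#' union of its grid cells, merged along grid rows); coordinates are
#' inverse-projected to lon/lat through the supplied projection centre.
#' Geometry export is cosmetic -- areas are measured on the grid.
#'
#' @param ps a `patch_set`.
#' @param path output file.
#' @param center named vector `c(lon0=, lat0=)` of the track projection
#'   centre (see [project_planar()]), or `NULL` to emit planar metres.
#' @export
patches_to_geojson <- function(ps, path, center = NULL) {
  cs <- ps$cell_size
  x0 <- ps$origin[1]; y0 <- ps$origin[2]
  feats <- lapply(seq_along(ps$cells), function(k) {
    idx <- ps$cells[[k]]
    polys <- list()
    for (j in sort(unique(idx[, 2]))) {
      xs <- sort(idx[idx[, 2] == j, 1])
      runs <- split(xs, cumsum(c(1, diff(xs) != 1)))
      for (run in runs) {
        xa <- x0 + (min(run) - 1) * cs; xb <- x0 + max(run) * cs
        ya <- y0 + (j - 1) * cs; yb <- y0 + j * cs
        ring <- rbind(c(xa, ya), c(xb, ya), c(xb, yb), c(xa, yb), c(xa, ya))
        if (!is.null(center))
          ring <- aeqd_inverse(ring[, 1], ring[, 2],
                               center[["lon0"]], center[["lat0"]])
        polys[[length(polys) + 1L]] <-
          list(lapply(seq_len(nrow(ring)), function(i) unname(ring[i, ])))
      }
    }
    list(type = "Feature",
         properties = list(patch = k,
                           area_m2 = ps$patches$area_m2[k],
                           id = ps$patches$id[k],
                           segment = ps$patches$segment[k]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
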