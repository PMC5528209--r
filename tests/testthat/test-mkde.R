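test_that("diffusion estimate is exact for identical steps and robust to rest", {
  fx <- data.frame(time = t0() + (0:3) * 100, x = c(0, 50, 100, 150), y = 0)
  expect_equal(estimate_diffusion(fx), 50^2 / (4 * 100) / log(2))
  fx0 <- data.frame(time = t0() + (0:5) * 100, x = rep(1, 6), y = rep(2, 6))
  expect_equal(estimate_diffusion(fx0), 0)
  expect_error(estimate_diffusion(fx, Tmax = 10), "no steps")
})

test_that("diffusion estimate recovers Brownian motion within 25%", {
  for (s in 1:3) {
    set.seed(s)
    D0 <- 5; Tt <- 60; n <- 500
    fx <- data.frame(time = t0() + (0:n) * Tt,
                     x = cumsum(c(0, rnorm(n, 0, sqrt(2 * D0 * Tt)))),
                     y = cumsum(c(0, rnorm(n, 0, sqrt(2 * D0 * Tt)))))
    expect_lt(abs(estimate_diffusion(fx) / D0 - 1), 0.25)
  }
})

test_that("the UD is a normalised density and D = 0 collapses to hmin kernels", {
  fx <- data.frame(time = t0() + c(0, 600), x = c(0, 500), y = c(0, 0))
  ud <- build_ud(fx, brb_params(hmin = 80, D = 0, Tmax = 1e9, tau = 60,
                                cell_size = 20))
  expect_s3_class(ud, "ud_grid")
  expect_equal(sum(ud$z), 1, tolerance = 1e-9)
  expect_true(all(ud$z >= 0))

  ## a stationary "step" is a single bivariate Gaussian with sd hmin
  sigma <- 200
  fx2 <- data.frame(time = t0() + c(0, 600), x = c(0, 0), y = c(0, 0))
  ud2 <- build_ud(fx2, brb_params(hmin = sigma, D = 0, Tmax = 1e9, tau = 600,
                                  cell_size = sigma / 10))
  want <- tcrossprod(dnorm(ud2$x, 0, sigma), dnorm(ud2$y, 0, sigma))
  want <- want / sum(want)
  expect_lt(max(abs(ud2$z - want)), 5e-6)   # kernel window truncation
})

test_that("Tmax screens steps and an all-gap segment errors", {
  fx <- data.frame(time = t0() + c(0, 1e6), x = c(0, 1), y = c(0, 1))
  expect_error(build_ud(fx, brb_params(Tmax = 100)), "exceed Tmax")
})

test_that("two stationary bouts give two patches with duration-share masses", {
  tt <- t0() + c(0, 3600, 13600, 13600 + 7200)
  fx <- data.frame(time = tt, x = c(0, 0, 8000, 8000), y = rep(0, 4))
  ud <- build_ud(fx, brb_params(hmin = 250, D = 0, Tmax = 7300, tau = 360,
                                cell_size = 50))
  ## transit step (10,000 s) exceeds Tmax and is skipped
  left_mass <- sum(ud$z[ud$x < 4000, ])
  expect_equal(left_mass, 3600 / 10800, tolerance = 1e-6)
  ps <- extract_patches(ud, 0.95)
  expect_equal(nrow(ps$patches), 2)
  expect_equal(sort(ps$patches$mass), sort(c(0.95 / 3, 2 * 0.95 / 3)),
               tolerance = 0.05)
})

test_that("95% isopleth of a Gaussian UD matches the chi-square closed form", {
  sigma <- 300
  fx <- data.frame(time = t0() + c(0, 600), x = c(0, 0), y = c(0, 0))
  ud <- build_ud(fx, brb_params(hmin = sigma, D = 0, Tmax = 1e9, tau = 600,
                                cell_size = sigma / 10))
  ps <- extract_patches(ud, 0.95)
  expect_equal(nrow(ps$patches), 1)
  expect_equal(ps$patches$area_m2, pi * 5.991 * sigma^2, tolerance = 0.05)
})

test_that("isopleth mass is conserved within one cell of the target", {
  sim <- simulate_forager(forager_config(seed = 3, n_fixes = 120))
  fx <- sim$track$fixes[1:60, ]
  ud <- build_ud(fx, brb_params(hmin = 100, Tmax = 3 * 7200, tau = 720,
                                cell_size = 50))
  expect_equal(sum(ud$z), 1, tolerance = 1e-9)
  ps <- extract_patches(ud, 0.95)
  expect_gte(ps$selected_mass, 0.95)
  expect_lte(ps$selected_mass, 0.95 + ps$max_cell_mass)
  expect_equal(sum(ps$patches$mass), ps$selected_mass, tolerance = 1e-9)
})

test_that("patch areas shrink as the isopleth decreases", {
  sim <- simulate_forager(forager_config(seed = 5, n_fixes = 120))
  ud <- build_ud(sim$track$fixes[1:60, ],
                 brb_params(hmin = 100, Tmax = 3 * 7200, tau = 720,
                            cell_size = 50))
  areas <- vapply(c(0.5, 0.8, 0.95, 0.99),
                  function(lv) sum(extract_patches(ud, lv)$patches$area_m2),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_error(extract_patches(ud, 1.5), "isopleth")
})

test_that("patch areas are grid-convergent and rigid-motion invariant", {
  sigma <- 300
  fx <- data.frame(time = t0() + c(0, 600), x = c(0, 0), y = c(0, 0))
  a1 <- sum(extract_patches(build_ud(fx, brb_params(hmin = sigma, D = 0,
      Tmax = 1e9, tau = 600, cell_size = sigma / 10)))$patches$area_m2)
  a2 <- sum(extract_patches(build_ud(fx, brb_params(hmin = sigma, D = 0,
      Tmax = 1e9, tau = 600, cell_size = sigma / 20)))$patches$area_m2)
  expect_lt(abs(a2 / a1 - 1), 0.05)

  sim <- simulate_forager(forager_config(seed = 6, n_fixes = 100))
  fx2 <- sim$track$fixes[1:50, c("time", "x", "y")]
  prm <- brb_params(hmin = 100, Tmax = 3 * 7200, tau = 720, cell_size = 50)
  base <- extract_patches(build_ud(fx2, prm))
  th <- 0.4
  fx3 <- data.frame(time = fx2$time,
                    x = 333 + cos(th) * fx2$x - sin(th) * fx2$y,
                    y = -77 + sin(th) * fx2$x + cos(th) * fx2$y)
  moved <- extract_patches(build_ud(fx3, prm))
  ring <- 2 * sum(base$patches$n_cells) * prm$cell_size  # one-cell ring bound
  expect_lt(abs(sum(moved$patches$area_m2) - sum(base$patches$area_m2)),
            ring * prm$cell_size)
})

test_that("an isopleth close to 1 selects every component of the support", {
  tt <- t0() + c(0, 3600, 13600, 17200)
  fx <- data.frame(time = tt, x = c(0, 0, 8000, 8000), y = rep(0, 4))
  ud <- build_ud(fx, brb_params(hmin = 250, D = 0, Tmax = 3700, tau = 360,
                                cell_size = 50))
  ps <- extract_patches(ud, 1 - 1e-9)
  expect_equal(nrow(ps$patches), 2)   # one patch per support lobe
  expect_equal(ps$selected_mass, 1, tolerance = 1e-9)
})

test_that("exports are plain text with intact headers", {
  sigma <- 150
  fx <- data.frame(time = t0() + c(0, 600), x = c(0, 0), y = c(0, 0))
  ud <- build_ud(fx, brb_params(hmin = sigma, D = 0, Tmax = 1e9, tau = 600,
                                cell_size = 50))
  f <- withr::local_tempfile(fileext = ".asc")
  ud_to_asc(ud, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_match(hdr[5], "^cellsize 50")
  ps <- extract_patches(ud)
  g <- withr::local_tempfile(fileext = ".geojson")
  patches_to_geojson(ps, g, center = c(lon0 = 25, lat0 = -28))
  gj <- jsonlite::read_json(g)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
})
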