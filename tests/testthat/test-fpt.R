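test_that("radius grid realises the arithmetic progression", {
  r <- radius_grid(100, 10000, 80)
  expect_equal(r[1], 100)
  expect_equal(diff(as.numeric(r))[1], 80)
  expect_equal(as.numeric(r[length(r)]), 9940)  # 10,000 unreachable by step 80
  expect_length(r, 124)
  expect_error(radius_grid(0, 100, 10))
})

test_that("constant-speed straight line gives FPT = 2r/v and zero variance", {
  v <- 1                                       # m/s, fixes every 100 s
  tr <- mk_planar_track((0:20) * 100, rep(0, 21), dt = 100)
  radii <- c(150, 300, 450)
  prof <- compute_fpt(tr, radii)
  for (k in seq_along(radii))
    expect_equal(prof$fpt[11, k], 2 * radii[k] / v)
  prof <- var_log_fpt(prof)
  expect_equal(max(prof$var_log, na.rm = TRUE), 0)
})

test_that("FPT is undefined when the path never leaves the circle", {
  tr <- mk_planar_track(c(0, 10, 0, -10, 0), c(0, 0, 10, 0, -10), dt = 100)
  prof <- compute_fpt(tr, radii = 500)          # whole path within 500 m
  expect_true(all(is.na(prof$fpt)))
})

test_that("interpolated FPT matches the dense-resampling oracle", {
  for (s in 1:10) {
    tr <- mk_random_track(n = 20, seed = s)
    radii <- c(50, 100, 200, 400)
    got <- compute_fpt(tr, radii)$fpt
    want <- oracle_fpt(tr, radii)
    expect_identical(is.na(got), is.na(want))
    expect_lt(max(abs(got - want), na.rm = TRUE), 2)
  }
})

test_that("FPT is nondecreasing in radius and symmetric under time reversal", {
  tr <- mk_random_track(n = 30, seed = 11)
  radii <- seq(50, 600, by = 50)
  prof <- compute_fpt(tr, radii)
  for (i in seq_len(nrow(prof$fpt))) {
    row <- prof$fpt[i, ]
    def <- which(!is.na(row))
    if (length(def) > 1) expect_true(all(diff(row[def]) >= -1e-9))
  }
  ## reverse time: same geometry walked backwards
  n <- nrow(tr$fixes)
  tt <- as.numeric(tr$fixes$time)
  rev_tr <- track(data.frame(time = t0() + (max(tt) - rev(tt)),
                             x = rev(tr$fixes$x), y = rev(tr$fixes$y)),
                  id = "rev")
  rev_tr$crs_note <- "planar (test fixture)"
  prof_rev <- compute_fpt(rev_tr, radii)
  expect_equal(prof_rev$fpt[n:1, ], prof$fpt, tolerance = 1e-9)
})

test_that("the FPT profile is invariant under translation and rotation", {
  tr <- mk_random_track(n = 25, seed = 5)
  radii <- c(100, 250, 500)
  base <- compute_fpt(tr, radii)$fpt
  th <- 1.1
  moved <- track(data.frame(
    time = tr$fixes$time,
    x = 2000 + cos(th) * tr$fixes$x - sin(th) * tr$fixes$y,
    y = -500 + sin(th) * tr$fixes$x + cos(th) * tr$fixes$y), id = "mv")
  moved$crs_note <- "planar (test fixture)"
  expect_equal(compute_fpt(moved, radii)$fpt, base, tolerance = 1e-9)
})

test_that("log-FPT variance matches hand arithmetic", {
  prof <- structure(list(id = "h", radii = 1,
                         fpt = matrix(c(exp(1), exp(1), exp(2)), ncol = 1),
                         time = t0() + 0:2),
                    class = "fpt_profile")
  prof <- var_log_fpt(prof)
  expect_equal(prof$var_log, var(c(1, 1, 2)))   # = 1/3
  ## a single defined value is not enough for a variance
  prof2 <- structure(list(id = "h", radii = 1,
                          fpt = matrix(c(3, NA, NA), ncol = 1),
                          time = t0() + 0:2),
                     class = "fpt_profile")
  expect_true(is.na(var_log_fpt(prof2)$var_log))
})

test_that("population peak pools individuals and breaks ties small", {
  mk_prof <- function(vls, radii = c(100, 200, 300)) {
    p <- structure(list(id = "x", radii = radii,
                        fpt = matrix(NA_real_, 2, length(radii)),
                        time = t0() + 0:1, var_log = vls,
                        r_max_individual = radii[which.max(vls)]),
                   class = "fpt_profile")
    p
  }
  one <- mk_prof(c(0.1, 0.5, 0.2))
  expect_equal(population_peak(list(one))$r_pop, one$r_max_individual)
  two <- mk_prof(c(0.3, 0.7, 0.1))
  expect_equal(population_peak(list(one, two))$r_pop, 200)
  ## exact tie -> smaller radius
  tie1 <- mk_prof(c(0.4, 0.2, 0.4))
  expect_equal(population_peak(list(tie1))$r_pop, 100)
  ## NA at a radius: individual omitted from that radius's mean
  na1 <- mk_prof(c(NA, 0.2, 0.1)); na2 <- mk_prof(c(5, 0.1, 0.1))
  pp <- population_peak(list(na1, na2))
  expect_equal(pp$var_fpt_mean[1], 5)
  expect_equal(pp$r_pop, 100)
  expect_error(population_peak(list()), "empty")
})

test_that("a simulated two-mode forager yields an interior variance peak", {
  sim <- simulate_forager(forager_config(seed = 42, n_fixes = 500))
  prof <- var_log_fpt(compute_fpt(sim$track))
  r <- prof$radii
  expect_gt(prof$r_max_individual, min(r))
  expect_lt(prof$r_max_individual, max(r))
})
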