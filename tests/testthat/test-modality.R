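test_that("area samples validate and log-transform", {
  a <- area_sample(c(1, 10, 100), group = "g")
  expect_equal(a$log_areas, log(c(1, 10, 100)))
  expect_error(area_sample(c(1, -2)), "positive")
  expect_error(area_sample(numeric(0)), "empty")
})

test_that("KS comparison matches hand-enumerated ECDF gaps", {
  x <- area_sample(exp(c(1, 2, 3, 4)), "a")
  expect_equal(ks_compare(x, x)$D, 0)
  expect_equal(ks_compare(x, x)$p, 1)
  y <- area_sample(exp(c(5, 6, 7, 8)), "b")    # fully separated
  expect_equal(ks_compare(x, y)$D, 1)
  z <- area_sample(exp(c(3, 4, 5, 6)), "c")
  kz <- ks_compare(x, z)
  expect_equal(kz$D, 0.5)                      # ECDF gap on [2,3)
  expect_equal(kz$p, oracle_ks_p(0.5, 4, 4), tolerance = 1e-6)
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(10)
  a <- rlnorm(40, 10, 1); b <- rlnorm(60, 10.5, 0.8)
  D_area <- suppressWarnings(ks.test(a, b, exact = FALSE))$statistic
  D_log <- ks_compare(area_sample(a), area_sample(b))$D
  expect_equal(unname(D_area), D_log)
})

test_that("mode counting handles separation, smoothing limits, and plateaus", {
  expect_equal(count_modes(c(-5, 5), 0.5), 2)
  expect_equal(count_modes(c(-5, 5), 100), 1)  # huge bandwidth merges all
  set.seed(1)
  x3 <- c(rnorm(50, -6, 0.4), rnorm(50, 0, 0.4), rnorm(50, 6, 0.4))
  expect_equal(count_modes(x3, 0.4), 3)
  expect_equal(count_modes(x3, 10), 1)
})

test_that("critical bandwidth brackets the mode-count transition", {
  set.seed(2)
  x <- c(rnorm(60, 0, 1), rnorm(60, 5, 1))
  for (k in 1:3) {
    h <- critical_bandwidth(x, k)
    expect_lte(count_modes(x, h), k)
    expect_gt(count_modes(x, h * (1 - 10 * 1e-4)), k)
  }
  ## h_crit is decreasing in k
  hs <- vapply(1:4, function(k) critical_bandwidth(x, k), numeric(1))
  expect_true(all(diff(hs) < 0))
  ## two points +-5: the k=1 merge bandwidth is the half-separation
  expect_equal(critical_bandwidth(c(-5, 5), 1), 5, tolerance = 0.05)
  expect_lt(critical_bandwidth(c(-5, 5), 2), 1)
  expect_error(critical_bandwidth(rep(1, 10), 1), "identical")
})

test_that("Silverman p and multimodality support are complementary", {
  set.seed(3)
  x <- rnorm(50)
  st <- silverman_test(x, k = 1, B = 99, seed = 4)
  expect_equal(st$p + st$m, 1)
  expect_gte(st$p, 1 / 100)          # add-one correction forbids p = 0
  expect_warning(silverman_test(x, 1, B = 50, seed = 1), "unstable")
  ## same seed, same result
  st2 <- silverman_test(x, k = 1, B = 99, seed = 4)
  expect_equal(st$p, st2$p)
})

test_that("Silverman declares the clear mixture but not the Gaussian", {
  uni_ok <- 0; bi_ok <- 0
  for (s in 1:5) {
    set.seed(s); x <- rnorm(200)
    if (silverman_test(x, 1, B = 199, seed = s)$m < 0.95) uni_ok <- uni_ok + 1
    set.seed(s + 50); y <- c(rnorm(100, -4), rnorm(100, 4))
    if (silverman_test(y, 1, B = 199, seed = s)$m >= 0.95) bi_ok <- bi_ok + 1
  }
  expect_gte(uni_ok, 3)
  expect_gte(bi_ok, 3)
})

test_that("the test is conservative under the unimodal null", {
  rej <- 0
  for (s in 1:200) {
    set.seed(s)
    x <- rnorm(200)
    if (silverman_test(x, 1, B = 99, seed = s)$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / 200, 0.12)
})

test_that("the modality scan flags the right k and degenerates cleanly", {
  set.seed(6)
  y <- c(rnorm(100, -4), rnorm(100, 4))
  sc <- modality_scan(y, k_max = 4, B = 199, seed = 2)
  expect_equal(nrow(sc$table), 4)
  expect_true(sc$table$decision[1])            # k = 1 rejected: > 1 mode
  expect_true(sc$any_multimodal)
  expect_true(all(diff(sc$table$h_crit) < 0))

  set.seed(7)
  x <- rnorm(200)
  sc1 <- modality_scan(x, k_max = 1, B = 199, seed = 3)
  st1 <- silverman_test(x, k = 1, B = 199, seed = 3 + 1)
  expect_equal(sc1$table$p, st1$p)             # k_max = 1 is one Silverman test
  expect_equal(sc1$best_k, 1)
})

test_that("a unimodal lognormal sample passes the scan undeclared", {
  a <- sample_patch_areas(400, log_mean = 12, log_sd = 1, seed = 9)
  sc <- modality_scan(a, k_max = 5, B = 199, seed = 9)
  expect_false(sc$any_multimodal)
  expect_lt(sc$best_m, 0.95)
})

test_that("density histogram export carries both raw and smoothed layers", {
  a <- sample_patch_areas(200, 12, 1, seed = 1)
  dh <- density_histogram(a, bins = 20)
  expect_equal(sum(dh$counts), 200)
  expect_equal(length(dh$density_x), length(dh$density_y))
})
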