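test_that("pair-count estimator equals the brute-force double loop", {
  for (s in 1:4) {
    p <- random_pattern(30 + 5 * s, seed = s)
    radii <- ring_radii(14)
    rk <- ring_k(p, "all", radii)
    n <- nrow(p$points)
    oracle <- brute_k_cum(p$points, p$window, rep(TRUE, n), rep(TRUE, n),
                          radii, n * (n - 1))
    expect_equal(rk$k_cum, oracle, tolerance = 1e-10)
    m1 <- p$points$liana_host; m2 <- p$points$epi_host
    rkc <- ring_cross_k(p, "liana", "epi", radii)
    oracle2 <- brute_k_cum(p$points, p$window, m1, m2, radii,
                           sum(m1) * sum(m2) - sum(m1 & m2))
    expect_equal(rkc$k_cum, oracle2, tolerance = 1e-10)
  }
})

test_that("translation-corrected K matches spatstat on a shared pattern", {
  p <- random_pattern(40, seed = 9)
  rk <- ring_k(p, "all", radii = c(5, 10, 14))
  pp <- spatstat.geom::ppp(p$points$x, p$points$y,
                           window = spatstat.geom::owin(c(0, 60), c(0, 60)))
  ks <- spatstat.explore::Kest(pp, r = c(0, 5, 10, 14),
                               correction = "translate")
  expect_equal(rk$k_cum, ks$trans[-1], tolerance = 1e-8)
})

test_that("ring values telescope back to the cumulative K", {
  p <- random_pattern(45, seed = 3)
  radii <- seq(2, 14, by = 2)
  rk <- ring_k(p, "all", radii, ring_width = 2)
  expect_equal(sum(rk$ring_k), rk$k_cum[length(radii)], tolerance = 1e-10)
  # a ring spanning the whole range reduces to the plain K
  wide <- ring_k(p, "all", radii, ring_width = 14)
  expect_equal(wide$ring_k, wide$k_cum, tolerance = 1e-12)
})

test_that("all pair mass lands in the annulus containing the pair distance", {
  # two marked trees 3 m apart: only the (2,4] ring is hit
  p <- mapped_pattern(c(20, 23, 5, 50), c(20, 20, 5, 50),
                      list(x = c(0, 60), y = c(0, 60)),
                      liana_host = c(TRUE, TRUE, FALSE, FALSE),
                      epi_host = c(FALSE, FALSE, TRUE, TRUE),
                      dbh = 20, species = "s")
  rk <- ring_k(p, "liana", radii = c(2, 4, 6))
  expect_equal(rk$ring_k[c(1, 3)], c(0, 0))
  expect_gt(rk$ring_k[2], 0)
  # cross: liana at (10,10), epiphyte 5 m away -> only (4,6]
  p2 <- mapped_pattern(c(10, 15), c(10, 10), list(x = c(0, 60), y = c(0, 60)),
                       liana_host = c(TRUE, FALSE), epi_host = c(FALSE, TRUE),
                       dbh = 20, species = "s")
  rkc <- ring_cross_k(p2, "liana", "epi", radii = c(2, 4, 6))
  expect_equal(rkc$ring_k[c(1, 2)], c(0, 0))
  expect_gt(rkc$ring_k[3], 0)
})

test_that("cross-K of identical mark sets equals the univariate K", {
  p <- random_pattern(35, seed = 12)
  expect_equal(ring_cross_k(p, "liana", "liana")$ring_k,
               ring_k(p, "liana")$ring_k, tolerance = 1e-12)
})

test_that("CSR ring expectation is pi(r^2 - (r-w)^2)", {
  set.seed(20)
  radii <- ring_radii(10)
  sims <- replicate(80, {
    n <- rpois(1, 100)
    p <- mapped_pattern(runif(n, 0, 60), runif(n, 0, 60),
                        list(x = c(0, 60), y = c(0, 60)),
                        liana_host = TRUE, epi_host = TRUE,
                        dbh = 20, species = "s")
    ring_k(p, "all", radii)$ring_k
  })
  theory <- pi * (radii^2 - pmax(radii - 2, 0)^2)
  mc_se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  expect_true(all(abs(rowMeans(sims) - theory) < 4 * mc_se + 0.02 * theory))
})

test_that("guard rails: too-large radii and too-few points error", {
  p <- random_pattern(20, seed = 5)
  expect_error(ring_k(p, "all", radii = c(10, 40)),
               class = "lianepi_validation_error")
  p1 <- mapped_pattern(c(5, 10), c(5, 10), list(x = c(0, 60), y = c(0, 60)),
                       liana_host = c(TRUE, FALSE), epi_host = TRUE,
                       dbh = 20, species = "s")
  expect_error(ring_k(p1, "liana"), class = "lianepi_validation_error")
})

test_that("envelopes are seed-reproducible and monotone in alpha", {
  blk <- generate_mapped_block(stand_params(), seed = 77)
  p <- as_mapped_pattern(blk)
  e1 <- covariate_null_envelope(p, "liana", "epi", n_sim = 199, seed = 42)
  e2 <- covariate_null_envelope(p, "liana", "epi", n_sim = 199, seed = 42)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  e05 <- covariate_null_envelope(p, "liana", "epi", n_sim = 399, seed = 1,
                                 alpha = 0.05)
  e01 <- covariate_null_envelope(p, "liana", "epi", n_sim = 399, seed = 1,
                                 alpha = 0.01)
  expect_true(all(e01$lower <= e05$lower + 1e-12))
  expect_true(all(e01$upper >= e05$upper - 1e-12))
})

test_that("deterministic marks collapse the envelope onto the observed curve", {
  set.seed(30)
  n <- 60
  x <- runif(n, 0, 60); y <- runif(n, 0, 60)
  dbh <- c(rep(15, 30), rep(80, 30))
  p <- mapped_pattern(x, y, list(x = c(0, 60), y = c(0, 60)),
                      liana_host = rep(TRUE, n), epi_host = dbh > 40,
                      dbh = dbh, species = "s")
  expect_warning(
    env <- covariate_null_envelope(p, "liana", "epi", n_sim = 99, seed = 2),
    regexp = NA)
  expect_equal(env$lower, env$upper, tolerance = 1e-9)
  expect_true(all(!env$exceed))
})
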