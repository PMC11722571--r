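test_that("NB2 contrast estimate equals the log group-mean ratio", {
  set.seed(5)
  for (i in 1:10) {
    ref <- rnbinom(10, mu = 12, size = 3)
    alt <- rnbinom(10, mu = 5, size = 3)
    if (sum(ref) == 0 || sum(alt) == 0) next
    res <- nb_group_contrast(ref, alt)
    expect_equal(res$estimate, log(mean(alt) / mean(ref)), tolerance = 1e-6)
  }
})

test_that("estimate depends on totals only, not on the split across plots", {
  splits <- list(c(7, rep(0, 9)), c(rep(1, 7), 0, 0, 0), c(3, 4, rep(0, 8)))
  ests <- vapply(splits, function(lh) {
    nb_group_contrast(c(rep(12, 10)), lh)$estimate
  }, double(1))
  expect_equal(ests, rep(log(7 / 120), 3), tolerance = 1e-6)
})

test_that("swapping groups negates estimate and z", {
  a <- c(4, 6, 3, 7); b <- c(10, 13, 9, 12)
  f <- nb_group_contrast(a, b); r <- nb_group_contrast(b, a)
  expect_equal(f$estimate, -r$estimate, tolerance = 1e-8)
  expect_equal(f$z, -r$z, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with typed errors", {
  expect_error(nb_group_contrast(c(0, 0), c(1, 2)),
               class = "lianepi_separation_error")
  expect_error(nb_group_contrast(c(1, -2), c(1, 2)),
               class = "lianepi_validation_error")
  expect_error(nb_group_contrast(integer(0), c(1, 2)),
               class = "lianepi_validation_error")
  expect_error(nb_group_contrast(c(0, 0), c(0, 0)),
               class = "lianepi_validation_error")
})

test_that("underdispersed fixtures fall back to the Poisson limit cleanly", {
  res <- nb_group_contrast(c(2, 2), c(4, 4))
  expect_equal(res$estimate, log(2), tolerance = 1e-6)
  # theta -> Inf reproduces the Poisson GLM Wald statistic
  df <- data.frame(count = c(2, 2, 4, 4),
                   group = factor(c("r", "r", "a", "a"), levels = c("r", "a")))
  pz <- summary(glm(count ~ group, poisson(), df))$coefficients["groupa", 3]
  if (res$family == "poisson") expect_equal(res$z, pz, tolerance = 1e-8)
})

test_that("patch contrasts reproduce per-patch closed forms", {
  ds <- generate_stand(small_stand_params(), seed = 31)
  pc <- patch_contrasts(ds)
  ps <- patch_summaries(ds)
  for (i in seq_len(nrow(pc))) {
    row <- ps[ps$patch_id == pc$patch_id[i], ]
    if (row$n_liana_hosts > 0 && row$n_epi_hosts > 0) {
      expect_equal(pc$estimate[i], log(row$n_liana_hosts / row$n_epi_hosts),
                   tolerance = 1e-6)
    }
  }
})

test_that("zone contrasts recover the crown bias of epiphytes", {
  ds <- generate_stand(small_stand_params(), seed = 32)
  zc <- zone_contrasts(ds)
  tvc <- zc[zc$contrast == "epiphyte_trunk_vs_crown", ]
  expect_lt(tvc$estimate, 0)  # generator places epiphytes crown-biased
  # closed-form fixture through the same code path
  expect_equal(nb_group_contrast(c(2, 2), c(4, 4))$estimate, log(2),
               tolerance = 1e-6)
})

test_that("mechanism contrast: closed form, generator sign, and shuffle null", {
  # two liana species, one specialized with 8 epiphyte co-occurrences vs 2
  trees <- data.frame(tree_id = c("T1", "T2"), patch_id = "P", plot_id = "p",
                      species = "s", dbh = c(30, 30))
  ds <- forest_dataset(
    trees,
    lianas = data.frame(tree_id = c("T1", "T2"),
                        species = c("spec sp", "lean sp"), diameter = 2,
                        mechanism = c("specialized", "leaning"),
                        zone = "trunk"),
    epiphytes = data.frame(
      tree_id = c(rep("T1", 8), rep("T2", 2)),
      species = paste0("e", 1:10), cover_class = 1L, zones = "crown"))
  expect_equal(mechanism_contrast(ds)$estimate, log(4), tolerance = 1e-6)

  gen <- generate_stand(small_stand_params(), seed = 33)
  expect_gt(mechanism_contrast(gen)$estimate, 0)

  # shuffling species mechanisms destroys the signal on average
  set.seed(99)
  mech_map <- gen$lianas[!duplicated(gen$lianas$species), c("species", "mechanism")]
  ests <- replicate(30, {
    shuffled <- gen
    perm <- sample(mech_map$mechanism)
    shuffled$lianas$mechanism <-
      perm[match(shuffled$lianas$species, mech_map$species)]
    mechanism_contrast(shuffled)$estimate
  })
  expect_lt(abs(mean(ests)), 0.35)

  one_mech <- gen
  one_mech$lianas$mechanism <- "leaning"
  expect_error(mechanism_contrast(one_mech), class = "lianepi_degenerate_error")
})
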