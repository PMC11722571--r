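hp_spec <- host_model_spec("liana_richness")
ln_spec <- host_model_spec("liana_ba")
cm_spec <- host_model_spec("epi_cover")

row_df <- function(y, mature = 0, dbh_z = 0, sp = 1L) {
  data.frame(y = y, mature = mature, dbh_z = dbh_z, species_idx = sp)
}

test_that("hurdle zero mass ignores the positive-part parameters", {
  pars1 <- list(beta = c(0, 0, 0), u = 0, alpha = c(qlogis(0.3), 0, 0))
  pars2 <- list(beta = c(5, -2, 3), u = 0, alpha = c(qlogis(0.3), 0, 0))
  expect_equal(host_loglik(hp_spec, pars1, row_df(0)), log(0.3))
  expect_equal(host_loglik(hp_spec, pars2, row_df(0)), log(0.3))
  pars_ln <- list(beta = c(1, 0, 0), u = 0, alpha = c(qlogis(0.3), 0, 0),
                  sigma = 0.7)
  expect_equal(host_loglik(ln_spec, pars_ln, row_df(0)), log(0.3))
})

test_that("truncated-Poisson point mass matches direct evaluation", {
  pars <- list(beta = c(0, 0, 0), u = 0, alpha = c(qlogis(0.5), 0, 0))
  # y = 2, pi0 = 0.5, lambda = 1
  expect_equal(host_loglik(hp_spec, pars, row_df(2)), -1.9276, tolerance = 1e-4)
})

test_that("hurdle-Poisson loglik agrees with a numeric-summation oracle", {
  set.seed(17)
  for (i in 1:20) {
    lam <- runif(1, 0.1, 8)
    pi0 <- runif(1, 0.05, 0.95)
    y <- sample(1:8, 1)
    pars <- list(beta = c(log(lam), 0, 0), u = 0,
                 alpha = c(qlogis(pi0), 0, 0))
    got <- host_loglik(hp_spec, pars, row_df(y))
    # normaliser by explicit summation of the truncated series
    norm <- sum(dpois(1:200, lam))
    oracle <- log(1 - pi0) + dpois(y, lam, log = TRUE) - log(norm)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("each family is a proper probability distribution", {
  pars <- list(beta = c(log(2.5), 0, 0), u = 0, alpha = c(qlogis(0.35), 0, 0))
  mass <- exp(host_loglik(hp_spec, pars, row_df(0))) +
    sum(vapply(1:200, function(y) exp(host_loglik(hp_spec, pars, row_df(y))),
               double(1)))
  expect_equal(mass, 1, tolerance = 1e-10)

  cpars <- list(beta = c(0.4, 0.8), u = 0, cutpoints = c(-1, 0, 1, 2))
  probs <- vapply(1:5, function(y) {
    exp(host_loglik(cm_spec, cpars, row_df(y, mature = 1, dbh_z = 0.3)))
  }, double(1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
})

test_that("symmetric cutpoints at zero give symmetric class probabilities", {
  cpars <- list(beta = c(0, 0), u = 0, cutpoints = c(-2, -0.7, 0.7, 2))
  p <- vapply(1:5, function(y) exp(host_loglik(cm_spec, cpars, row_df(y))),
              double(1))
  expect_equal(p[1], p[5], tolerance = 1e-12)
  expect_equal(p[2], p[4], tolerance = 1e-12)
})

test_that("out-of-support responses are domain errors", {
  pars <- list(beta = c(0, 0, 0), u = 0, alpha = c(0, 0, 0))
  expect_error(host_loglik(hp_spec, pars, row_df(-1)),
               class = "lianepi_domain_error")
  expect_error(host_loglik(hp_spec, pars, row_df(1.5)),
               class = "lianepi_domain_error")
  cpars <- list(beta = c(0, 0), u = 0, cutpoints = c(-1, 0, 1, 2))
  expect_error(host_loglik(cm_spec, cpars, row_df(6)),
               class = "lianepi_domain_error")
})

test_that("the sampler's hurdle part matches the closed logistic route", {
  ds <- generate_stand(micro_stand_params(plots_per_patch = 8L), seed = 55)
  fit <- suppressWarnings(
    fit_host_model(ds, "liana_richness", chains = 2, iter = 1500, seed = 3))
  dat <- host_model_data(ds, "liana_richness")
  dat$dbh_z <- (dat$dbh - mean(dat$dbh)) / sd(dat$dbh)
  ml <- glm(I(y == 0) ~ mature + dbh_z, binomial(), dat)
  td <- tidy(fit)
  for (term in c("alpha_intercept", "alpha_mature", "alpha_dbh_z")) {
    ml_term <- c(alpha_intercept = "(Intercept)", alpha_mature = "mature",
                 alpha_dbh_z = "dbh_z")[[term]]
    est <- td$estimate[td$term == term]
    se <- summary(ml)$coefficients[ml_term, 2]
    expect_lt(abs(est - coef(ml)[[ml_term]]), 3 * se + 0.05)
  }
})

test_that("a null species effect concentrates sigma_sp near zero", {
  pool <- lianepi:::default_tree_pool()
  pool$quality <- 0
  ds <- generate_stand(small_stand_params(tree_species_pool = pool), seed = 66)
  fit <- suppressWarnings(
    fit_host_model(ds, "epi_richness", chains = 2, iter = 1500, seed = 4))
  td <- tidy(fit)
  expect_lt(td$conf.high[td$term == "sigma_sp"], 0.5)
})

test_that("single forest type drops the forest effect with a warning", {
  p <- stand_params(n_patches = 2L, plots_per_patch = 4L,
                    patch_types = c(A = "successional", B = "successional"),
                    mapped_patch = "none")
  ds <- generate_stand(p, seed = 8)
  msgs <- character()
  fit <- withCallingHandlers(
    fit_host_model(ds, "liana_richness", chains = 2, iter = 400, seed = 1),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("forest-type effect dropped", msgs)))
  expect_false("b_mature" %in% tidy(fit)$term)
})

test_that("marginal curves follow the link structure", {
  # hand-built fit with known draws: zero slope -> flat curve
  mk_fit <- function(b_dbh, b_mature) {
    draws <- cbind(alpha_intercept = rep(0, 50), alpha_mature = 0,
                   alpha_dbh_z = 0, b_intercept = 0.2, b_mature = b_mature,
                   b_dbh_z = b_dbh, u_1 = 0, sigma_sp = 0.1)
    structure(list(spec = host_model_spec("liana_richness"),
                   draws = list(draws), par_names = colnames(draws),
                   summary = NULL, species_levels = "s", use_mature = TRUE,
                   dbh_mean = 25, dbh_sd = 10, n = 100, n_pos = 50,
                   chains = 1, iter = 100, warmup = 50, seed = 1,
                   converged = TRUE), class = "host_model_fit")
  }
  flat <- marginal_curves(mk_fit(0, 0.5), dbh_grid = c(10, 30, 60))
  expect_equal(diff(flat$mean[flat$forest_type == "successional"]),
               c(0, 0), tolerance = 1e-12)
  up <- marginal_curves(mk_fit(0.4, 0.5), dbh_grid = c(10, 30, 60))
  succ <- up$mean[up$forest_type == "successional"]
  expect_true(all(diff(succ) > 0))
  # positive mature offset lifts the whole curve
  expect_true(all(up$mean[up$forest_type == "mature"] > succ))
})
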