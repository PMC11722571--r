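#' Per-tree response table for a host model
#'
#' Builds the model frame the host models are fitted on: one row per
#' tree (colonized trees only for the cover model) with the response,
#' forest-type indicator, dbh and host-tree species.
#'
#' @param ds A `forest_dataset`.
#' @param response A [host_model_spec()] response name.
#' @return Tibble with `y`, `mature`, `dbh`, `species`.
#' @export
host_model_data <- function(ds, response) {
  spec <- host_model_spec(response)
  ts <- tree_summaries(ds)
  if (spec$response == "epi_cover") ts <- filter(ts, .data$epi_host)
  y <- switch(spec$response,
              liana_richness = as.double(ts$liana_richness),
              epi_richness = as.double(ts$epi_richness),
              liana_ba = ts$liana_ba,
              epi_cover = as.double(ts$epi_cover))
  tibble(y = y, mature = as.numeric(ts$forest_type == "mature"),
         dbh = ts$dbh, species = ts$species)
}

half_norm_lp <- function(x, sd) dnorm(x, 0, sd, log = TRUE)

#' Fit a Bayesian host model by MCMC
#'
#' Samples the posterior of a [host_model_spec()] model with an adaptive
#' random-walk Metropolis-within-Gibbs sampler: fixed effects (intercept,
#' forest-type effect, slope on z-scored dbh), a species random intercept
#' with scale `sigma_sp`, plus the hurdle logistic coefficients
#' (modelling Pr(zero) with the same covariates) for the hurdle families,
#' the lognormal scale for the basal-area model, and ordered cutpoints
#' for the cumulative model. Priors are weakly informative:
#' normal(0, 2.5) on coefficients (normal(0, 5) on cutpoints),
#' half-normal(0, 1) on `sigma_sp`, half-normal(0, 2.5) on the lognormal
#' scale. Proposal scales adapt only during warmup. Convergence is
#' declared when every parameter has split-Rhat < 1.01 and ESS > 1000;
#' failing that the fit is flagged with a warning, never an error.
#'
#' @param ds A `forest_dataset` (or a data frame already shaped like
#'   [host_model_data()] output).
#' @param response Response name, see [host_model_spec()].
#' @param chains Number of chains (default 4).
#' @param iter Iterations per chain including warmup (default 8000).
#' @param warmup Warmup iterations (default `iter / 2`).
#' @param seed Integer seed.
#' @return A `host_model_fit`: draws, a parameter summary (see
#'   [tidy.host_model_fit()]), diagnostics and the dbh scaling used.
#' @export
fit_host_model <- function(ds, response, chains = 4, iter = 8000,
                           warmup = floor(iter / 2), seed = 1) {
  spec <- host_model_spec(response)
  dat <- if (inherits(ds, "forest_dataset")) host_model_data(ds, response)
         else as_tibble(ds)
  if (length(unique(dat$species)) < 2) {
    abort("at least two host-tree species are required",
          class = "lianepi_validation_error")
  }
  use_mature <- length(unique(dat$mature)) > 1
  if (!use_mature) {
    warn("only one forest type present; forest-type effect dropped")
  }
  dbh_mean <- mean(dat$dbh); dbh_sd <- sd(dat$dbh)
  dat$dbh_z <- (dat$dbh - dbh_mean) / dbh_sd
  species_levels <- sort(unique(dat$species))
  spx <- match(dat$species, species_levels)

  set.seed(seed)
  runs <- lapply(seq_len(chains), function(ch) {
    if (spec$family == "cumulative_logit") {
      run_cumulative_chain(dat, spx, length(species_levels), iter, warmup,
                           use_mature)
    } else {
      run_hurdle_chain(spec$family, dat, spx, length(species_levels), iter,
                       warmup, use_mature)
    }
  })
  draws <- lapply(runs, `[[`, "draws")
  pn <- runs[[1]]$par_names
  smry <- summarise_draws(draws, pn)
  converged <- all(smry$rhat < 1.01, na.rm = TRUE) && all(smry$ess > 1000)
  if (!converged) {
    warn(sprintf(
      "host model '%s' not converged at %d x %d iterations (max rhat %.3f, min ess %.0f)",
      response, chains, iter, max(smry$rhat, na.rm = TRUE), min(smry$ess)))
  }
  structure(list(
    spec = spec, draws = draws, par_names = pn, summary = smry,
    species_levels = species_levels, use_mature = use_mature,
    dbh_mean = dbh_mean, dbh_sd = dbh_sd,
    n = nrow(dat), n_pos = sum(dat$y > 0),
    chains = chains, iter = iter, warmup = warmup, seed = seed,
    converged = converged
  ), class = "host_model_fit")
}

# log-scale random-walk update of the species-intercept scale (half-normal
# prior, N(0, sigma) density of the current intercepts; Jacobian term for
# the multiplicative proposal)
sigma_sp_step <- function(sigma_sp, u, scale, note_acc) {
  d <- rnorm(1, 0, scale)
  prop <- sigma_sp * exp(d)
  dlp <- sum(dnorm(u, 0, prop, log = TRUE)) -
    sum(dnorm(u, 0, sigma_sp, log = TRUE)) +
    half_norm_lp(prop, 1) - half_norm_lp(sigma_sp, 1) + d
  if (is.finite(dlp) && log(runif(1)) < dlp) {
    note_acc(TRUE)
    prop
  } else {
    note_acc(FALSE)
    sigma_sp
  }
}

adapt_scale <- function(scale, acc, n) {
  # diminishing-style doubling/halving toward 44% acceptance
  scale * exp(0.5 * (acc / n - 0.44))
}

run_hurdle_chain <- function(family, dat, spx, S, iter, warmup, use_mature) {
  y <- dat$y
  z <- as.numeric(y == 0)
  cols <- if (use_mature) c("mature", "dbh_z") else "dbh_z"
  Xall <- cbind(intercept = 1, as.matrix(dat[cols]))
  k <- ncol(Xall)
  pos <- y > 0
  ypos <- y[pos]; Xpos <- Xall[pos, , drop = FALSE]; spp <- spx[pos]
  rows_by_sp <- split(seq_along(ypos), factor(spp, levels = seq_len(S)))
  lognormal <- family == "hurdle_lognormal"

  posll <- if (lognormal) {
    function(yy, eta, sigma) sum(dlnorm(yy, eta, sigma, log = TRUE))
  } else {
    function(yy, eta, sigma) sum(pos_pois_ll(yy, eta))
  }
  bernll <- function(eta) sum(dbinom(z, 1, plogis(eta), log = TRUE))

  # overdispersed-but-plausible starts around quick ML fits
  alpha <- tryCatch(
    unname(coef(suppressWarnings(glm(z ~ Xall - 1, family = binomial())))),
    error = function(e) rep(0, k))
  alpha <- alpha + rnorm(k, 0, 0.3)
  beta <- if (lognormal) {
    unname(coef(stats::lm(log(ypos) ~ Xpos - 1)))
  } else {
    tryCatch(unname(coef(suppressWarnings(
      glm(ypos ~ Xpos - 1, family = poisson())))),
      error = function(e) rep(0, k))
  }
  beta <- beta + rnorm(k, 0, 0.3)
  u <- rnorm(S, 0, 0.1)
  sigma_sp <- abs(rnorm(1, 0.3, 0.1))
  sigma <- if (lognormal) sd(log(ypos)) * exp(rnorm(1, 0, 0.2)) else NA_real_

  eta0 <- drop(Xall %*% alpha)
  etap <- drop(Xpos %*% beta) + u[spp]
  ll0 <- bernll(eta0)
  llp <- posll(ypos, etap, sigma)

  par_names <- c(paste0("alpha_", colnames(Xall)), paste0("b_", colnames(Xall)),
                 paste0("u_", seq_len(S)), "sigma_sp",
                 if (lognormal) "sigma")
  P <- length(par_names)
  n_scalar <- 2 * k + S + 1 + lognormal
  scales <- rep(c(0.1, 0.1, 0.3, 0.2), c(k, k, S, 1 + lognormal))
  acc <- integer(n_scalar); tries <- integer(n_scalar)
  draws <- matrix(NA_real_, iter - warmup, P, dimnames = list(NULL, par_names))

  for (it in seq_len(iter)) {
    pid <- 0
    for (j in seq_len(k)) {  # hurdle logistic coefficients
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      new_eta0 <- eta0 + d * Xall[, j]
      new_ll0 <- bernll(new_eta0)
      dlp <- new_ll0 - ll0 +
        dnorm(alpha[j] + d, 0, 2.5, log = TRUE) - dnorm(alpha[j], 0, 2.5, log = TRUE)
      if (is.finite(dlp) && log(runif(1)) < dlp) {
        alpha[j] <- alpha[j] + d; eta0 <- new_eta0; ll0 <- new_ll0
        acc[pid] <- acc[pid] + 1
      }
    }
    for (j in seq_len(k)) {  # positive-part coefficients
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      new_etap <- etap + d * Xpos[, j]
      new_llp <- posll(ypos, new_etap, sigma)
      dlp <- new_llp - llp +
        dnorm(beta[j] + d, 0, 2.5, log = TRUE) - dnorm(beta[j], 0, 2.5, log = TRUE)
      if (is.finite(dlp) && log(runif(1)) < dlp) {
        beta[j] <- beta[j] + d; etap <- new_etap; llp <- new_llp
        acc[pid] <- acc[pid] + 1
      }
    }
    for (s in seq_len(S)) {  # species intercepts (affect only their rows)
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      r <- rows_by_sp[[s]]
      dll <- if (length(r)) {
        posll(ypos[r], etap[r] + d, sigma) - posll(ypos[r], etap[r], sigma)
      } else 0
      dlp <- dll + dnorm(u[s] + d, 0, sigma_sp, log = TRUE) -
        dnorm(u[s], 0, sigma_sp, log = TRUE)
      if (is.finite(dlp) && log(runif(1)) < dlp) {
        u[s] <- u[s] + d
        if (length(r)) etap[r] <- etap[r] + d
        llp <- llp + dll
        acc[pid] <- acc[pid] + 1
      }
    }
    pid <- pid + 1; tries[pid] <- tries[pid] + 1
    sigma_sp <- sigma_sp_step(sigma_sp, u, scales[pid],
                              function(ok) if (ok) acc[pid] <<- acc[pid] + 1)
    if (lognormal) {
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      if (sigma + d > 0) {
        new_llp <- posll(ypos, etap, sigma + d)
        dlp <- new_llp - llp + half_norm_lp(sigma + d, 2.5) -
          half_norm_lp(sigma, 2.5)
        if (is.finite(dlp) && log(runif(1)) < dlp) {
          sigma <- sigma + d; llp <- new_llp; acc[pid] <- acc[pid] + 1
        }
      }
    }
    # exact Gibbs recentering between the intercept and the species
    # intercepts: eta is invariant under (b0 + d, u - d), so d is drawn
    # from its Gaussian full conditional given the priors alone
    prec <- S / sigma_sp^2 + 1 / 2.5^2
    dmean <- (sum(u) / sigma_sp^2 - beta[1] / 2.5^2) / prec
    d <- rnorm(1, dmean, sqrt(1 / prec))
    beta[1] <- beta[1] + d
    u <- u - d
    if (it <= warmup && it %% 50 == 0) {
      scales <- adapt_scale(scales, acc, pmax(tries, 1))
      acc[] <- 0L; tries[] <- 0L
    }
    if (it > warmup) {
      draws[it - warmup, ] <- c(alpha, beta, u, sigma_sp,
                                if (lognormal) sigma)
    }
  }
  list(draws = draws, par_names = par_names)
}

run_cumulative_chain <- function(dat, spx, S, iter, warmup, use_mature) {
  y <- as.integer(dat$y)
  K <- 5L
  cols <- if (use_mature) c("mature", "dbh_z") else "dbh_z"
  X <- as.matrix(dat[cols])
  k <- ncol(X)
  rows_by_sp <- split(seq_along(y), factor(spx, levels = seq_len(S)))
  rows_by_class <- split(seq_along(y), factor(y, levels = seq_len(K)))

  llfun <- function(rows, eta, cp) {
    sum(log(pmax(cum_prob(y[rows], eta, cp), 1e-300)))
  }
  # cutpoints from empirical cumulative frequencies; tiny jitter for spread
  cum_freq <- cumsum(tabulate(y, K))[1:(K - 1)] / length(y)
  cum_freq <- pmin(pmax(cum_freq, 1 / (2 * length(y))), 1 - 1 / (2 * length(y)))
  cp <- qlogis(cum_freq) + sort(rnorm(K - 1, 0, 0.1))
  cp <- sort(cp)
  beta <- rnorm(k, 0, 0.2)
  u <- rnorm(S, 0, 0.1)
  sigma_sp <- abs(rnorm(1, 0.3, 0.1))

  eta <- drop(X %*% beta) + u[spx]
  ll <- llfun(seq_along(y), eta, cp)

  par_names <- c(paste0("b_", colnames(X)), paste0("u_", seq_len(S)),
                 "sigma_sp", paste0("c_", seq_len(K - 1)))
  P <- length(par_names)
  n_scalar <- k + S + 1 + (K - 1)
  scales <- rep(c(0.1, 0.3, 0.2, 0.15), c(k, S, 1, K - 1))
  acc <- integer(n_scalar); tries <- integer(n_scalar)
  draws <- matrix(NA_real_, iter - warmup, P, dimnames = list(NULL, par_names))

  for (it in seq_len(iter)) {
    pid <- 0
    for (j in seq_len(k)) {
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      new_eta <- eta + d * X[, j]
      new_ll <- llfun(seq_along(y), new_eta, cp)
      dlp <- new_ll - ll +
        dnorm(beta[j] + d, 0, 2.5, log = TRUE) - dnorm(beta[j], 0, 2.5, log = TRUE)
      if (is.finite(dlp) && log(runif(1)) < dlp) {
        beta[j] <- beta[j] + d; eta <- new_eta; ll <- new_ll
        acc[pid] <- acc[pid] + 1
      }
    }
    for (s in seq_len(S)) {
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      r <- rows_by_sp[[s]]
      dll <- if (length(r)) llfun(r, eta[r] + d, cp) - llfun(r, eta[r], cp) else 0
      dlp <- dll + dnorm(u[s] + d, 0, sigma_sp, log = TRUE) -
        dnorm(u[s], 0, sigma_sp, log = TRUE)
      if (is.finite(dlp) && log(runif(1)) < dlp) {
        u[s] <- u[s] + d
        if (length(r)) eta[r] <- eta[r] + d
        ll <- ll + dll
        acc[pid] <- acc[pid] + 1
      }
    }
    pid <- pid + 1; tries[pid] <- tries[pid] + 1
    sigma_sp <- sigma_sp_step(sigma_sp, u, scales[pid],
                              function(ok) if (ok) acc[pid] <<- acc[pid] + 1)
    for (ci in seq_len(K - 1)) {  # ordered cutpoints; only classes ci, ci+1 react
      pid <- pid + 1; tries[pid] <- tries[pid] + 1
      d <- rnorm(1, 0, scales[pid])
      new_c <- cp[ci] + d
      lo <- if (ci > 1) cp[ci - 1] else -Inf
      hi <- if (ci < K - 1) cp[ci + 1] else Inf
      if (new_c > lo && new_c < hi) {
        r <- c(rows_by_class[[ci]], rows_by_class[[ci + 1]])
        new_cp <- cp; new_cp[ci] <- new_c
        dll <- if (length(r)) llfun(r, eta[r], new_cp) - llfun(r, eta[r], cp) else 0
        dlp <- dll + dnorm(new_c, 0, 5, log = TRUE) - dnorm(cp[ci], 0, 5, log = TRUE)
        if (is.finite(dlp) && log(runif(1)) < dlp) {
          cp <- new_cp; ll <- ll + dll; acc[pid] <- acc[pid] + 1
        }
      }
    }
    # exact Gibbs recentering: probabilities are invariant under shifting
    # all cutpoints and species intercepts together
    prec <- S / sigma_sp^2 + (K - 1) / 25
    dmean <- -(sum(u) / sigma_sp^2 + sum(cp) / 25) / prec
    d <- rnorm(1, dmean, sqrt(1 / prec))
    u <- u + d
    cp <- cp + d
    eta <- eta + d  # eta includes u
    if (it <= warmup && it %% 50 == 0) {
      scales <- adapt_scale(scales, acc, pmax(tries, 1))
      acc[] <- 0L; tries[] <- 0L
    }
    if (it > warmup) draws[it - warmup, ] <- c(beta, u, sigma_sp, cp)
  }
  list(draws = draws, par_names = par_names)
}

# split-Rhat and summed per-chain ESS over a list of draw matrices
summarise_draws <- function(draws, par_names) {
  purrr::map_dfr(seq_along(par_names), function(j) {
    per_chain <- lapply(draws, function(m) m[, j])
    x <- unlist(per_chain)
    ess <- sum(vapply(per_chain, function(v) {
      unname(coda::effectiveSize(coda::mcmc(v)))
    }, double(1)))
    tibble(term = par_names[j], estimate = mean(x), std.error = sd(x),
           conf.low = unname(quantile(x, 0.025)),
           conf.high = unname(quantile(x, 0.975)),
           rhat = split_rhat(per_chain), ess = ess)
  })
}

split_rhat <- function(per_chain) {
  halves <- unlist(lapply(per_chain, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (m < 2 || n < 2) return(NA_real_)
  means <- vapply(halves, mean, double(1))
  vars <- vapply(halves, stats::var, double(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.host_model_fit <- function(x, ...) {
  cat(sprintf("<host_model_fit> %s (%s), n=%d (%d positive), %d chains x %d iter%s\n",
              x$spec$response, x$spec$family, x$n, x$n_pos, x$chains, x$iter,
              if (x$converged) ", converged" else ", NOT converged"))
  print(as.data.frame(x$summary[!grepl("^u_", x$summary$term), ]), digits = 3)
  invisible(x)
}

#' Tidy a host-model fit
#'
#' Posterior summaries per parameter (mean, sd, central 95% interval,
#' split-Rhat, ESS). With `raw_scale = TRUE`, appends `b_dbh_raw`, the
#' dbh slope per cm (the z-scored slope divided by the dbh standard
#' deviation used in fitting).
#'
#' @param x A `host_model_fit`.
#' @param raw_scale Append the per-cm dbh slope (default `TRUE`).
#' @param ... Unused.
#' @export
tidy.host_model_fit <- function(x, raw_scale = TRUE, ...) {
  out <- x$summary
  if (raw_scale && "b_dbh_z" %in% out$term) {
    v <- unlist(lapply(x$draws, function(m) m[, "b_dbh_z"])) / x$dbh_sd
    out <- bind_rows(out, tibble(
      term = "b_dbh_raw", estimate = mean(v), std.error = sd(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975)),
      rhat = out$rhat[out$term == "b_dbh_z"],
      ess = out$ess[out$term == "b_dbh_z"]))
  }
  out
}

#' One-row fit summary
#' @param x A `host_model_fit`.
#' @param ... Unused.
#' @export
glance.host_model_fit <- function(x, ...) {
  tibble(response = x$spec$response, family = x$spec$family,
         n = x$n, n_pos = x$n_pos, chains = x$chains, iter = x$iter,
         converged = x$converged,
         max_rhat = max(x$summary$rhat, na.rm = TRUE),
         min_ess = min(x$summary$ess))
}

#' Posterior expected-response curves over dbh
#'
#' Population-level (species intercept at zero) posterior mean and 95%
#' interval of the expected response on a dbh grid, per forest type.
#' For hurdle families the expectation combines the hurdle and the
#' (truncated) positive part; for the cumulative family it is the
#' expected cover class.
#'
#' @param fit A `host_model_fit`.
#' @param dbh_grid Diameters (cm); defaults to 30 points over the fitted
#'   range.
#' @param forest_type Types to evaluate.
#' @param n_draws Posterior draws used (thinned evenly; default 400).
#' @return Tibble: `dbh`, `forest_type`, `mean`, `conf.low`, `conf.high`.
#' @export
marginal_curves <- function(fit, dbh_grid = NULL,
                            forest_type = c("successional", "mature"),
                            n_draws = 400) {
  stopifnot(inherits(fit, "host_model_fit"))
  if (is.null(dbh_grid)) {
    rng <- fit$dbh_mean + c(-1.5, 2.5) * fit$dbh_sd
    dbh_grid <- seq(max(10, rng[1]), rng[2], length.out = 30)
  }
  if (!fit$use_mature) forest_type <- forest_type[1]
  all_draws <- do.call(rbind, fit$draws)
  idx <- unique(round(seq(1, nrow(all_draws), length.out = min(n_draws, nrow(all_draws)))))
  dr <- all_draws[idx, , drop = FALSE]
  dz <- (dbh_grid - fit$dbh_mean) / fit$dbh_sd
  purrr::map_dfr(forest_type, function(ft) {
    mat <- as.numeric(ft == "mature")
    ev <- vapply(seq_along(dz), function(i) {
      expected_response(fit, dr, dz[i], mat)
    }, double(nrow(dr)))
    tibble(dbh = dbh_grid, forest_type = ft,
           mean = colMeans(ev),
           conf.low = apply(ev, 2, quantile, 0.025),
           conf.high = apply(ev, 2, quantile, 0.975))
  })
}

expected_response <- function(fit, dr, dz, mat) {
  fam <- fit$spec$family
  has_m <- fit$use_mature
  if (fam == "cumulative_logit") {
    eta <- (if (has_m) dr[, "b_mature"] * mat else 0) + dr[, "b_dbh_z"] * dz
    cps <- dr[, grep("^c_", colnames(dr)), drop = FALSE]
    up <- cbind(cps, Inf); lo <- cbind(-Inf, cps)
    probs <- plogis(up - eta) - plogis(lo - eta)
    return(drop(probs %*% 1:5))
  }
  eta0 <- dr[, "alpha_intercept"] +
    (if (has_m) dr[, "alpha_mature"] * mat else 0) + dr[, "alpha_dbh_z"] * dz
  etap <- dr[, "b_intercept"] +
    (if (has_m) dr[, "b_mature"] * mat else 0) + dr[, "b_dbh_z"] * dz
  p_pos <- 1 - plogis(eta0)
  if (fam == "hurdle_poisson") {
    lam <- exp(etap)
    p_pos * lam / (-expm1(-lam))
  } else {
    p_pos * exp(etap + dr[, "sigma"]^2 / 2)
  }
}
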