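#' Specification of a host-tree response model
#'
#' The four per-tree response models share one structure: fixed effects
#' for forest type and (standardised) dbh, a host-tree-species random
#' intercept, and a response family chosen by the measurement process —
#' hurdle-Poisson for species richness counts with many structural
#' zeros, hurdle-lognormal for total liana basal area, and a
#' cumulative-logit for the ordinal 1–5 epiphyte cover class (defined
#' only on colonized trees, so it carries no hurdle).
#'
#' @param response One of `"liana_richness"`, `"epi_richness"`,
#'   `"liana_ba"`, `"epi_cover"`.
#' @return A list of class `host_model_spec` with `response`, `family`
#'   and `has_hurdle`.
#' @export
host_model_spec <- function(response = c("liana_richness", "epi_richness",
                                         "liana_ba", "epi_cover")) {
  response <- match.arg(response)
  family <- switch(response,
                   liana_richness = "hurdle_poisson",
                   epi_richness = "hurdle_poisson",
                   liana_ba = "hurdle_lognormal",
                   epi_cover = "cumulative_logit")
  structure(list(response = response, family = family,
                 has_hurdle = family != "cumulative_logit"),
            class = "host_model_spec")
}

#' Log-likelihood of host-model observations
#'
#' Evaluates the exact per-row log-probability of each family:
#' * hurdle families: `log(pi0)` at zero; `log(1 - pi0)` plus the
#'   positive-part log-density for `y > 0`, with the Poisson part
#'   zero-truncated (renormalised by `1 - exp(-lambda)`) and the
#'   lognormal part needing no truncation;
#' * cumulative logit: `log(plogis(c_k - eta) - plogis(c_{k-1} - eta))`
#'   with `c_0 = -Inf`, `c_K = +Inf`.
#'
#' Exposed so the families can be checked against independent numeric
#' oracles; the sampler uses the same internals.
#'
#' @param spec A [host_model_spec()].
#' @param params Named list: `beta` (intercept, forest-type effect, dbh
#'   slope — no intercept for the cumulative family), `u` (species
#'   intercepts), `alpha` (hurdle logistic coefficients for Pr(zero);
#'   hurdle families only), `sigma` (lognormal sd; hurdle-lognormal
#'   only), `cutpoints` (cumulative only).
#' @param data Data frame with `y`, `mature` (0/1), `dbh_z` and
#'   `species_idx` (integers indexing `u`).
#' @return Total log-likelihood (scalar).
#' @export
host_loglik <- function(spec, params, data) {
  stopifnot(inherits(spec, "host_model_spec"))
  y <- data$y
  X <- cbind(1, data$mature, data$dbh_z)
  u <- params$u %||% rep(0, max(data$species_idx))
  re <- u[data$species_idx]
  if (spec$family == "cumulative_logit") {
    if (any(y < 1 | y > length(params$cutpoints) + 1 | y != round(y))) {
      abort("cumulative response must be an integer class 1..K",
            class = "lianepi_domain_error")
    }
    eta <- X[, 2:3, drop = FALSE] %*% params$beta + re
    return(sum(log(cum_prob(y, eta, params$cutpoints))))
  }
  if (any(y < 0)) {
    abort("hurdle response must be zero or positive",
          class = "lianepi_domain_error")
  }
  pi0 <- plogis(drop(X %*% params$alpha))
  z <- y == 0
  ll <- sum(log(pi0[z])) + sum(log1p(-pi0[!z]))
  eta <- drop(X %*% params$beta + re)[!z]
  yp <- y[!z]
  if (spec$family == "hurdle_poisson") {
    if (any(yp != round(yp))) {
      abort("hurdle-Poisson response must be integer",
            class = "lianepi_domain_error")
    }
    ll <- ll + sum(pos_pois_ll(yp, eta))
  } else {
    ll <- ll + sum(dlnorm(yp, eta, params$sigma, log = TRUE))
  }
  ll
}

# zero-truncated Poisson log-density at y >= 1 with log-rate eta
pos_pois_ll <- function(y, eta) {
  lam <- exp(eta)
  dpois(y, lam, log = TRUE) - log(-expm1(-lam))
}

# P(Y = y) under the cumulative-logit with linear predictor eta
cum_prob <- function(y, eta, cutpoints) {
  cp <- c(-Inf, cutpoints, Inf)
  plogis(cp[y + 1] - eta) - plogis(cp[y] - eta)
}
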