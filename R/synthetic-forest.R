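#' Parameters for the synthetic forest-stand generator
#'
#' Returns the full parameter set for [generate_stand()] /
#' [generate_mapped_block()], with defaults emulating the sampling design
#' the pipeline targets: 12 forest patches (8 successional, 4 mature) of
#' ten 20 x 20 m plots each, all trees >= 10 cm dbh, logistic
#' colonization probabilities increasing with dbh, higher in mature
#' forest and varying among host-tree species, and one contiguous mapped
#' block for spatial analyses. The default colonization intercepts are
#' calibrated numerically so the expected fraction of trees hosting
#' lianas is ~34% and epiphytes ~52%, the survey-level rates the design
#' emulates.
#'
#' @param ... Named overrides of any default component. Nested lists are
#'   merged shallowly (e.g. `colonization = list(liana = list(slope = 0))`
#'   replaces the liana colonization sub-list).
#' @return A list of class `stand_params`. Components:
#' \describe{
#'   \item{n_patches, plots_per_patch, plot_side}{Design geometry.}
#'   \item{patch_types}{Named character vector patch_id -> forest type.}
#'   \item{tree_intensity}{Trees per m² per forest type (Poisson process).}
#'   \item{spatial_process}{`list(kind = "poisson")` or
#'     `list(kind = "thomas", kappa =, sigma =, mu =)` (parents per m²,
#'     offspring s.d. in m, mean offspring per parent).}
#'   \item{dbh_lognormal}{Per forest type `c(meanlog, sdlog)` of the dbh
#'     distribution, left-truncated at 10 cm.}
#'   \item{tree_species_pool}{Tibble: species, relative abundance per
#'     forest type, colonization offset (log-odds), and a `quality`
#'     offset entering every positive-part response model — the
#'     species-level heterogeneity the mixed models absorb as a random
#'     intercept.}
#'   \item{liana_species_pool, epiphyte_species_pool}{Tibbles of species
#'     with relative weights; liana species carry a climbing `mechanism`
#'     (`"specialized"`/`"leaning"`).}
#'   \item{colonization}{Per guild: logistic `intercept` (NA = calibrate
#'     to `target_host_frac`), `slope` per cm dbh, `mature_offset`,
#'     `target_host_frac`.}
#'   \item{richness, liana_ba, epi_cover}{Positive-part response models:
#'     zero-truncated Poisson log-rate for richness, lognormal for total
#'     liana basal area, latent-logistic cumulative model with
#'     `cutpoints` for the 1-5 cover class. Slopes are per cm dbh.}
#'   \item{zones}{Zone assignment probabilities (epiphytes crown-biased).}
#'   \item{mech_dbh_bonus}{Log-weight bonus per standardised dbh unit for
#'     specialized-mechanism liana species when drawing species on a
#'     colonized tree; makes specialized climbers concentrate on large
#'     trees.}
#'   \item{mapped_patch}{Patch whose first 9 plots form the contiguous
#'     mapped block inside [generate_stand()].}
#' }
#' @export
stand_params <- function(...) {
  patch_types <- c(setNames(rep("successional", 8), paste0("S", 1:8)),
                   setNames(rep("mature", 4), paste0("M", 1:4)))
  p <- list(
    n_patches = 12L,
    plots_per_patch = 10L,
    plot_side = 20,
    patch_types = patch_types,
    tree_intensity = c(successional = 0.044, mature = 0.044),
    spatial_process = list(kind = "poisson"),
    dbh_lognormal = list(successional = c(meanlog = 2.85, sdlog = 0.70),
                         mature = c(meanlog = 3.05, sdlog = 0.75)),
    dbh_max = 120,
    tree_species_pool = default_tree_pool(),
    liana_species_pool = default_liana_pool(),
    epiphyte_species_pool = default_epiphyte_pool(),
    colonization = list(
      liana = list(intercept = NA_real_, slope = 0.050, mature_offset = 0.40,
                   target_host_frac = 0.34),
      epiphyte = list(intercept = NA_real_, slope = 0.060, mature_offset = 0.60,
                      target_host_frac = 0.52)
    ),
    richness = list(
      liana = list(intercept = log(0.40), slope = 0.015, mature_offset = 0.25),
      epiphyte = list(intercept = log(1.10), slope = 0.015, mature_offset = 0.30)
    ),
    liana_ba = list(intercept = -7.3, slope = 0.020, mature_offset = 0.30,
                    sigma = 0.80),
    epi_cover = list(slope = 0.030, mature_offset = 0.40,
                     cutpoints = c(1.6, 3.1, 4.4, 5.6)),
    zones = list(liana_trunk = 0.55,
                 epiphyte = c(trunk = 0.25, crown = 0.45, both = 0.30)),
    mech_dbh_bonus = 0.8,
    mapped_patch = "S1",
    block_intensity = 120 / 3600,
    seed = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(p[[nm]]) && is.list(over[[nm]]) && !is.data.frame(over[[nm]])) {
      p[[nm]] <- modifyList(p[[nm]], over[[nm]])
    } else {
      p[[nm]] <- over[[nm]]
    }
  }
  if (any(!unlist(p$patch_types) %in% c("successional", "mature"))) {
    abort("patch_types must be 'successional' or 'mature'",
          class = "lianepi_config_error")
  }
  if (is.unsorted(p$epi_cover$cutpoints, strictly = TRUE)) {
    abort("epi_cover cutpoints must be strictly increasing",
          class = "lianepi_config_error")
  }
  if (p$plot_side <= 0) abort("plot_side must be positive",
                              class = "lianepi_config_error")
  for (pool in c("liana_species_pool", "epiphyte_species_pool")) {
    if (nrow(p[[pool]]) < 1 || any(p[[pool]]$weight <= 0)) {
      abort(sprintf("%s must be non-empty with positive weights", pool),
            class = "lianepi_config_error")
    }
  }
  class(p) <- "stand_params"
  p
}

default_tree_pool <- function() {
  tibble(
    species = c("Canopia grandis", "Canopia media", "Umbra excelsa",
                "Umbra tinctoria", "Media sylvatica", "Media robusta",
                "Subcanopa mollis", "Subcanopa parva", "Pioneria alba",
                "Pioneria lutea", "Exotica vulgaris", "Exotica pallida"),
    w_successional = c(2, 2, 3, 3, 6, 6, 8, 8, 12, 12, 10, 8),
    w_mature       = c(10, 9, 8, 7, 7, 6, 5, 5, 2, 2, 1, 1),
    colonization_offset = c(0.35, 0.25, 0.15, 0.10, 0.05, 0.00,
                            -0.05, -0.10, -0.15, -0.20, -0.25, -0.15),
    # species-level response heterogeneity, deliberately uncorrelated with
    # the successional-affinity ordering above so forest-type effects stay
    # identified through the species random intercept
    quality = c(0.30, -0.20, 0.10, -0.30, 0.40, 0.00,
                -0.10, 0.20, -0.25, 0.15, -0.05, 0.05)
  )
}

default_liana_pool <- function() {
  tibble(
    species = c(sprintf("Tendrila species%02d", 1:8),
                sprintf("Apoyada species%02d", 1:8)),
    weight = c(10, 8, 6, 5, 4, 3, 2, 2, 9, 7, 5, 4, 3, 2, 2, 1),
    mechanism = rep(c("specialized", "leaning"), each = 8)
  )
}

default_epiphyte_pool <- function() {
  tibble(
    species = sprintf("Epifita species%02d", 1:24),
    weight = c(12, 11, 9, 8, 8, 7, 6, 6, 5, 5, 4, 4,
               3, 3, 3, 2, 2, 2, 2, 1, 1, 1, 1, 1)
  )
}

# Expected host fraction under the logistic colonization model, integrating
# over the truncated-lognormal dbh distribution, species pool and forest-type
# mix implied by the design. Used to calibrate intercepts.
expected_host_frac <- function(p, guild, intercept) {
  co <- p$colonization[[guild]]
  fts <- unlist(p$patch_types)
  n_pl <- p$plots_per_patch * p$plot_side^2
  w_ft <- vapply(c("successional", "mature"), function(ft) {
    sum(fts == ft) * n_pl * p$tree_intensity[[ft]]
  }, double(1))
  w_ft <- w_ft / sum(w_ft)
  u <- seq(0.5 / 400, 1 - 0.5 / 400, length.out = 400)
  tot <- 0
  for (ft in names(w_ft)) {
    dl <- p$dbh_lognormal[[ft]]
    p0 <- stats::plnorm(10, dl[["meanlog"]], dl[["sdlog"]])
    p1 <- stats::plnorm(p$dbh_max, dl[["meanlog"]], dl[["sdlog"]])
    d <- stats::qlnorm(p0 + u * (p1 - p0), dl[["meanlog"]], dl[["sdlog"]])
    pool <- p$tree_species_pool
    wsp <- pool[[paste0("w_", ft)]]
    wsp <- wsp / sum(wsp)
    for (s in seq_len(nrow(pool))) {
      eta <- intercept + co$slope * d + co$mature_offset * (ft == "mature") +
        pool$colonization_offset[s]
      tot <- tot + w_ft[[ft]] * wsp[s] * mean(plogis(eta))
    }
  }
  tot
}

calibrated_intercept <- function(p, guild) {
  co <- p$colonization[[guild]]
  if (!is.na(co$intercept %||% NA_real_)) return(co$intercept)
  target <- co$target_host_frac
  f <- function(a) expected_host_frac(p, guild, a) - target
  stats::uniroot(f, c(-30, 10), tol = 1e-8)$root
}

# zero-truncated Poisson draws by inverse cdf
rztpois <- function(n, lambda) {
  lambda <- pmax(lambda, 1e-12)
  u <- runif(n, dpois(0, lambda), 1)
  pmax(1L, qpois(pmin(u, 1 - 1e-16), lambda))
}

# point locations within a rectangle for one plot/block
draw_points <- function(proc, intensity, wx, wy) {
  area <- diff(wx) * diff(wy)
  if (identical(proc$kind, "poisson")) {
    n <- rpois(1, intensity * area)
    return(tibble(x = runif(n, wx[1], wx[2]), y = runif(n, wy[1], wy[2])))
  }
  if (identical(proc$kind, "thomas")) {
    buf <- 4 * proc$sigma
    ax <- wx + c(-buf, buf); ay <- wy + c(-buf, buf)
    np <- rpois(1, proc$kappa * diff(ax) * diff(ay))
    px <- runif(np, ax[1], ax[2]); py <- runif(np, ay[1], ay[2])
    noff <- rpois(np, proc$mu)
    x <- rep(px, noff) + rnorm(sum(noff), 0, proc$sigma)
    y <- rep(py, noff) + rnorm(sum(noff), 0, proc$sigma)
    keep <- x >= wx[1] & x <= wx[2] & y >= wy[1] & y <= wy[2]
    return(tibble(x = x[keep], y = y[keep]))
  }
  abort("spatial_process$kind must be 'poisson' or 'thomas'",
        class = "lianepi_config_error")
}

# standardised dbh used by the species-choice weighting (fixed reference
# scale so the bonus has stable units across datasets)
dbh_std <- function(dbh) (dbh - 20) / 10

#' Generate a synthetic forest stand
#'
#' Draws a complete `forest_dataset` from [stand_params()]: tree
#' locations per plot from the configured spatial process, dbh from a
#' truncated lognormal, guild colonization from per-tree logistic
#' probabilities, then per-colonized-tree species sets, liana stem
#' diameters (from a lognormal total basal area split across species)
#' and epiphyte cover classes from a latent-logistic cumulative model.
#' Coordinates are attached only to trees in the first nine plots of
#' `params$mapped_patch`, arranged as a contiguous 3 x 3 block — the
#' analogue of a permanent mapped plot. The same `params` and `seed`
#' always produce the identical dataset.
#'
#' @param params A [stand_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A validated [forest_dataset()].
#' @export
#' @examples
#' ds <- generate_stand(stand_params(n_patches = 2,
#'   patch_types = c(A = "successional", B = "mature")), seed = 1)
#' ds
generate_stand <- function(params = stand_params(), seed = params$seed) {
  stopifnot(inherits(params, "stand_params"))
  if (!is.null(seed)) set.seed(seed)
  fts <- unlist(params$patch_types)
  if (length(fts) != params$n_patches) {
    abort("patch_types must name exactly n_patches patches",
          class = "lianepi_config_error")
  }
  a_liana <- calibrated_intercept(params, "liana")
  a_epi <- calibrated_intercept(params, "epiphyte")

  side <- params$plot_side
  trees <- purrr::map_dfr(names(fts), function(pid) {
    ft <- fts[[pid]]
    purrr::map_dfr(seq_len(params$plots_per_patch), function(pl) {
      pts <- draw_points(params$spatial_process, params$tree_intensity[[ft]],
                         c(0, side), c(0, side))
      mapped <- identical(pid, params$mapped_patch) && pl <= 9
      if (mapped) {  # 3 x 3 contiguous block, plot pl at grid cell
        gx <- ((pl - 1) %% 3) * side
        gy <- ((pl - 1) %/% 3) * side
        pts$x <- pts$x + gx; pts$y <- pts$y + gy
      } else {
        pts$x <- NA_real_; pts$y <- NA_real_
      }
      pts$patch_id <- pid
      pts$plot_id <- sprintf("%s-p%02d", pid, pl)
      pts
    })
  })
  n <- nrow(trees)
  trees$tree_id <- sprintf("T%05d", seq_len(n))
  dl <- params$dbh_lognormal
  trees$forest_type <- fts[trees$patch_id]
  trees$dbh <- vapply(seq_len(n), function(i) {
    d <- dl[[trees$forest_type[i]]]
    p0 <- stats::plnorm(10, d[["meanlog"]], d[["sdlog"]])
    p1 <- stats::plnorm(params$dbh_max, d[["meanlog"]], d[["sdlog"]])
    stats::qlnorm(runif(1, p0, p1), d[["meanlog"]], d[["sdlog"]])
  }, double(1))
  pool <- params$tree_species_pool
  trees$species <- vapply(seq_len(n), function(i) {
    w <- pool[[paste0("w_", trees$forest_type[i])]]
    sample(pool$species, 1, prob = w)
  }, character(1))

  poolmap <- setNames(seq_len(nrow(pool)), pool$species)
  sp_idx <- poolmap[trees$species]
  mature <- as.numeric(trees$forest_type == "mature")
  quality <- pool$quality[sp_idx]

  col_eta <- function(guild, a) {
    co <- params$colonization[[guild]]
    a + co$slope * trees$dbh + co$mature_offset * mature +
      pool$colonization_offset[sp_idx]
  }
  liana_host <- rbinom(n, 1, plogis(col_eta("liana", a_liana))) == 1
  epi_host <- rbinom(n, 1, plogis(col_eta("epiphyte", a_epi))) == 1

  lianas <- make_liana_records(params, trees, liana_host, mature, quality)
  epiphytes <- make_epiphyte_records(params, trees, epi_host, mature, quality)

  patches <- tibble(patch_id = names(fts), forest_type = unname(fts))
  forest_dataset(trees = select(trees, "tree_id", "patch_id", "plot_id",
                                "species", "dbh", "x", "y"),
                 lianas = lianas, epiphytes = epiphytes, patches = patches)
}

make_liana_records <- function(params, trees, host, mature, quality) {
  idx <- which(host)
  if (!length(idx)) return(empty_liana_table())
  rp <- params$richness$liana
  lam <- exp(rp$intercept + rp$slope * trees$dbh[idx] +
               rp$mature_offset * mature[idx] + quality[idx])
  pool <- params$liana_species_pool
  rich <- pmin(rztpois(length(idx), lam), nrow(pool))
  bp <- params$liana_ba
  mu <- bp$intercept + bp$slope * trees$dbh[idx] +
    bp$mature_offset * mature[idx] + quality[idx]
  total_ba <- rlnorm(length(idx), mu, bp$sigma)
  spec_bonus <- as.numeric(pool$mechanism == "specialized")
  purrr::map_dfr(seq_along(idx), function(j) {
    i <- idx[j]
    w <- pool$weight * exp(params$mech_dbh_bonus * dbh_std(trees$dbh[i]) *
                             spec_bonus)
    sp <- sample(pool$species, rich[j], prob = w)
    min_ba <- basal_area(1)
    ba <- NULL
    for (try in 1:20) {  # keep the drawn total exact whenever feasible
      shares <- rgamma(rich[j], shape = 2)
      cand <- total_ba[j] * shares / sum(shares)
      if (all(cand >= min_ba)) { ba <- cand; break }
    }
    if (is.null(ba)) ba <- pmax(cand, min_ba)
    d <- 200 * sqrt(ba / pi)
    tibble(tree_id = trees$tree_id[i], species = sp, diameter = d,
           mechanism = pool$mechanism[match(sp, pool$species)],
           zone = ifelse(runif(rich[j]) < params$zones$liana_trunk,
                         "trunk", "crown"))
  })
}

make_epiphyte_records <- function(params, trees, host, mature, quality) {
  idx <- which(host)
  if (!length(idx)) return(empty_epiphyte_table())
  rp <- params$richness$epiphyte
  lam <- exp(rp$intercept + rp$slope * trees$dbh[idx] +
               rp$mature_offset * mature[idx] + quality[idx])
  pool <- params$epiphyte_species_pool
  rich <- pmin(rztpois(length(idx), lam), nrow(pool))
  cv <- params$epi_cover
  latent <- cv$slope * trees$dbh[idx] + cv$mature_offset * mature[idx] +
    quality[idx] + stats::rlogis(length(idx))
  cover <- findInterval(latent, cv$cutpoints) + 1L
  zp <- params$zones$epiphyte
  zone_sets <- list(list("trunk"), list("crown"), list(c("trunk", "crown")))
  purrr::map_dfr(seq_along(idx), function(j) {
    i <- idx[j]
    sp <- sample(pool$species, rich[j], prob = pool$weight)
    zi <- sample(1:3, rich[j], replace = TRUE, prob = zp)
    tibble(tree_id = trees$tree_id[i], species = sp,
           cover_class = cover[j],
           zones = lapply(zi, function(k) zone_sets[[k]][[1]]))
  })
}

#' Generate one fully mapped contiguous block
#'
#' A single-patch dataset in which every tree carries coordinates inside
#' a contiguous rectangle of `n_plots` plots (arranged as close to square
#' as the plot count allows), at a tree density matching a 120-tree
#' 0.36-ha permanent plot. Used as input for the spatial-association
#' stage.
#'
#' @param params A [stand_params()]; the block is successional and uses
#'   `params$block_intensity` trees per m².
#' @param n_plots Number of contiguous plots (default 9, i.e. 0.36 ha of
#'   20 m plots).
#' @param seed Integer seed.
#' @return A [forest_dataset()] whose trees all have `x`, `y`; the block
#'   window is attached as `attr(ds, "window")`
#'   (`list(x = c(0, W), y = c(0, H))`).
#' @export
generate_mapped_block <- function(params = stand_params(), n_plots = 9,
                                  seed = params$seed) {
  stopifnot(inherits(params, "stand_params"))
  if (!is.null(seed)) set.seed(seed)
  nr <- max(which(sapply(seq_len(floor(sqrt(n_plots))),
                         function(k) n_plots %% k == 0)))
  nc <- n_plots / nr
  side <- params$plot_side
  wx <- c(0, nc * side); wy <- c(0, nr * side)
  pts <- draw_points(params$spatial_process, params$block_intensity, wx, wy)
  n <- nrow(pts)
  trees <- pts
  trees$tree_id <- sprintf("B%04d", seq_len(n))
  trees$patch_id <- "B1"
  trees$plot_id <- sprintf("B1-p%02d", pmin(floor(trees$x / side), nc - 1) +
                             nc * pmin(floor(trees$y / side), nr - 1) + 1)
  dl <- params$dbh_lognormal$successional
  p0 <- stats::plnorm(10, dl[["meanlog"]], dl[["sdlog"]])
  p1 <- stats::plnorm(params$dbh_max, dl[["meanlog"]], dl[["sdlog"]])
  trees$dbh <- stats::qlnorm(runif(n, p0, p1), dl[["meanlog"]], dl[["sdlog"]])
  pool <- params$tree_species_pool
  trees$species <- sample(pool$species, n, replace = TRUE,
                          prob = pool$w_successional)
  sp_idx <- match(trees$species, pool$species)
  quality <- pool$quality[sp_idx]
  mature <- rep(0, n)
  a_liana <- calibrated_intercept(params, "liana")
  a_epi <- calibrated_intercept(params, "epiphyte")
  co_l <- params$colonization$liana; co_e <- params$colonization$epiphyte
  liana_host <- rbinom(n, 1, plogis(a_liana + co_l$slope * trees$dbh +
                                      pool$colonization_offset[sp_idx])) == 1
  epi_host <- rbinom(n, 1, plogis(a_epi + co_e$slope * trees$dbh +
                                    pool$colonization_offset[sp_idx])) == 1
  lianas <- make_liana_records(params, trees, liana_host, mature, quality)
  epiphytes <- make_epiphyte_records(params, trees, epi_host, mature, quality)
  ds <- forest_dataset(
    trees = select(trees, "tree_id", "patch_id", "plot_id", "species",
                   "dbh", "x", "y"),
    lianas = lianas, epiphytes = epiphytes,
    patches = tibble(patch_id = "B1", forest_type = "successional")
  )
  attr(ds, "window") <- list(x = wx, y = wy)
  ds
}
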