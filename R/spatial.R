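#' Marked point pattern of mapped host trees
#'
#' Container for the spatial stage: tree coordinates in a rectangular
#' window, host-status marks for both guilds, and the covariates (dbh,
#' species) the permutation null adjusts for.
#'
#' @param x,y Coordinates in metres.
#' @param window `list(x = c(x0, x1), y = c(y0, y1))`.
#' @param liana_host,epi_host Logical marks per point.
#' @param dbh,species Covariates per point.
#' @return A `mapped_pattern` (list with a points tibble and the window).
#' @export
mapped_pattern <- function(x, y, window, liana_host, epi_host,
                           dbh = NA_real_, species = NA_character_) {
  pts <- tibble(x = as.double(x), y = as.double(y),
                liana_host = as.logical(liana_host),
                epi_host = as.logical(epi_host),
                dbh = dbh, species = as.character(species))
  if (any(!is.finite(pts$x) | !is.finite(pts$y))) {
    abort("all points need finite coordinates", class = "lianepi_validation_error")
  }
  if (any(pts$x < window$x[1] | pts$x > window$x[2] |
          pts$y < window$y[1] | pts$y > window$y[2])) {
    abort("points must lie inside the window", class = "lianepi_validation_error")
  }
  structure(list(points = pts, window = window), class = "mapped_pattern")
}

#' @export
print.mapped_pattern <- function(x, ...) {
  cat(sprintf("<mapped_pattern> %d trees in [%g,%g] x [%g,%g] m; %d liana hosts, %d epiphyte hosts\n",
              nrow(x$points), x$window$x[1], x$window$x[2],
              x$window$y[1], x$window$y[2],
              sum(x$points$liana_host), sum(x$points$epi_host)))
  invisible(x)
}

#' Extract the mapped pattern from a forest dataset
#'
#' Uses the trees that carry coordinates (optionally restricted to one
#' patch); host marks come from the liana/epiphyte record tables. The
#' window is taken from `attr(ds, "window")` when present, otherwise
#' the bounding box snapped outward to plot-side multiples.
#'
#' @param ds A `forest_dataset`.
#' @param patch Optional patch id to restrict to.
#' @param plot_side Snapping unit for the inferred window (default 20 m).
#' @return A [mapped_pattern()].
#' @export
as_mapped_pattern <- function(ds, patch = NULL, plot_side = 20) {
  tr <- ds$trees
  if (!is.null(patch)) tr <- filter(tr, .data$patch_id == patch)
  tr <- filter(tr, !is.na(.data$x))
  if (nrow(tr) < 2) {
    abort("fewer than two mapped trees", class = "lianepi_validation_error")
  }
  win <- attr(ds, "window") %||% list(
    x = c(0, ceiling(max(tr$x) / plot_side) * plot_side),
    y = c(0, ceiling(max(tr$y) / plot_side) * plot_side))
  mapped_pattern(tr$x, tr$y, win,
                 liana_host = tr$tree_id %in% ds$lianas$tree_id,
                 epi_host = tr$tree_id %in% ds$epiphytes$tree_id,
                 dbh = tr$dbh, species = tr$species)
}

#' Default radii grid for the ring statistics
#' @param max_r Largest radius (default 14 m).
#' @param by Step (default 1 m).
#' @export
ring_radii <- function(max_r = 14, by = 1) seq(2, max_r, by = by)

# Precompute the ordered-pair structure used by every K evaluation on a
# pattern: pair endpoints, translation edge weights 1/((a-|dx|)(b-|dy|)),
# and the index of the first grid radius >= pair distance.
pair_structure <- function(p, rr) {
  pts <- p$points
  n <- nrow(pts)
  a <- diff(p$window$x); b <- diff(p$window$y)
  if (max(rr) > min(a, b) / 2) {
    abort("max radius exceeds half the window's shorter side",
          class = "lianepi_validation_error")
  }
  i <- rep(seq_len(n), each = n); j <- rep(seq_len(n), n)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  dx <- abs(pts$x[i] - pts$x[j]); dy <- abs(pts$y[i] - pts$y[j])
  d <- sqrt(dx^2 + dy^2)
  inrange <- d <= max(rr)
  i <- i[inrange]; j <- j[inrange]
  w <- 1 / ((a - dx[inrange]) * (b - dy[inrange]))
  bin <- findInterval(d[inrange], rr, left.open = TRUE) + 1L
  list(i = i, j = j, w = w, bin = bin, n = n, area = a * b, n_bins = length(rr))
}

# cumulative translation-corrected K at grid rr for foci set m1, targets m2
k_from_pairs <- function(ps, m1, m2, denom) {
  sel <- which(m1[ps$i] & m2[ps$j])
  ws <- numeric(ps$n_bins)
  if (length(sel)) {
    agg <- rowsum(ps$w[sel], ps$bin[sel])
    ws[as.integer(rownames(agg))] <- agg[, 1]
  }
  ps$area^2 * cumsum(ws) / denom
}

ring_from_cum <- function(rr, kcum, radii, ring_width) {
  k_at <- function(r) {
    out <- numeric(length(r))
    pos <- r > 0
    out[pos] <- kcum[match(r[pos], rr)]
    out
  }
  k_at(radii) - k_at(pmax(radii - ring_width, 0))
}

mark_vector <- function(p, which) {
  m <- switch(which,
              liana = p$points$liana_host,
              epi = p$points$epi_host,
              all = rep(TRUE, nrow(p$points)))
  if (is.null(m)) abort("mark must be 'liana', 'epi' or 'all'",
                        class = "lianepi_validation_error")
  m
}

union_grid <- function(radii, ring_width) {
  rr <- sort(unique(c(radii, radii - ring_width)))
  rr[rr > 0]
}

#' Ring-differenced K of a marked subpattern
#'
#' Translation-corrected Ripley K of the trees carrying the given mark,
#' returned as annulus (ring) values: `K(r) - K(r - ring_width)`, with
#' `K` taken as 0 at non-positive radii. The annuli remove the
#' cumulative autocorrelation of the raw K curve; under complete spatial
#' randomness each ring value has expectation
#' \eqn{\pi(r^2 - (r - w)^2)}.
#'
#' @param p A [mapped_pattern()].
#' @param which `"liana"`, `"epi"` or `"all"`.
#' @param radii Radii (m); default [ring_radii()]. Must not exceed half
#'   the window's shorter side.
#' @param ring_width Annulus width in m (default 2).
#' @return Tibble: `r`, `k_cum`, `ring_k`.
#' @export
ring_k <- function(p, which = "all", radii = ring_radii(), ring_width = 2) {
  stopifnot(inherits(p, "mapped_pattern"))
  m <- mark_vector(p, which)
  if (sum(m) < 2) {
    abort("fewer than two marked points", class = "lianepi_validation_error")
  }
  rr <- union_grid(radii, ring_width)
  ps <- pair_structure(p, rr)
  kcum <- k_from_pairs(ps, m, m, denom = sum(m) * (sum(m) - 1))
  tibble(r = radii,
         k_cum = kcum[match(radii, rr)],
         ring_k = ring_from_cum(rr, kcum, radii, ring_width))
}

#' Ring-differenced cross-K between the two guilds' host trees
#'
#' Cross-type K with trees of `from_mark` as foci and trees of `to_mark`
#' as targets (trees holding both marks belong to both sets; a tree is
#' never paired with itself), ring-differenced as in [ring_k()].
#'
#' @param p A [mapped_pattern()].
#' @param from_mark,to_mark `"liana"`, `"epi"` or `"all"`.
#' @inheritParams ring_k
#' @return Tibble: `r`, `k_cum`, `ring_k`.
#' @export
ring_cross_k <- function(p, from_mark, to_mark, radii = ring_radii(),
                         ring_width = 2) {
  stopifnot(inherits(p, "mapped_pattern"))
  m1 <- mark_vector(p, from_mark); m2 <- mark_vector(p, to_mark)
  if (sum(m1) < 1 || sum(m2) < 1) {
    abort("both mark sets must be non-empty", class = "lianepi_validation_error")
  }
  rr <- union_grid(radii, ring_width)
  ps <- pair_structure(p, rr)
  denom <- sum(m1) * sum(m2) - sum(m1 & m2)  # same-tree pairs never counted
  kcum <- k_from_pairs(ps, m1, m2, denom = denom)
  tibble(r = radii,
         k_cum = kcum[match(radii, rr)],
         ring_k = ring_from_cum(rr, kcum, radii, ring_width))
}

# logistic colonization model for the permutation null; falls back to a
# dbh-only model when species separates the mark perfectly
fit_mark_model <- function(p, mark) {
  pts <- p$points
  m <- as.numeric(mark_vector(p, mark))
  multi_sp <- length(unique(pts$species[!is.na(pts$species)])) > 1
  fml <- if (multi_sp) m ~ dbh + species else m ~ dbh
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = cbind(pts, m = m)),
    warning = function(wn) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(wn))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (sep && multi_sp) {
    warn("species separates the mark perfectly; falling back to a dbh-only null model")
    fit <- suppressWarnings(glm(m ~ dbh, family = binomial(),
                                data = cbind(pts, m = m)))
  }
  fitted(fit)
}

#' Covariate-adjusted random-labelling envelope for the ring cross-K
#'
#' Tests spatial association between the two guilds' host trees while
#' holding tree locations fixed and accounting for which trees are
#' likely hosts anyway. A logistic model `presence ~ dbh + species` is
#' fitted for the reshuffled mark; each simulation reassigns that mark
#' across trees by weighted sampling without replacement with the fitted
#' probabilities as weights (preserving the observed number of marked
#' trees; set `scheme = "bernoulli"` for independent draws instead),
#' recomputes the ring cross-K, and the envelope is the per-radius
#' `alpha/2` and `1 - alpha/2` quantile band. With all fitted
#' probabilities 0 or 1 every permutation reproduces the observed
#' marking and the band has zero width.
#'
#' @param p A [mapped_pattern()].
#' @param from_mark Focal mark (held fixed).
#' @param to_mark Mark reshuffled under the null.
#' @param radii,ring_width As [ring_k()].
#' @param n_sim Simulations (default 10000).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Integer seed.
#' @param scheme `"permutation"` (count-preserving, default) or
#'   `"bernoulli"`.
#' @return A `ring_k_envelope`: tibble `r`, `observed`, `lower`,
#'   `upper`, `exceed` (outside the band), `direction`, with the call
#'   settings in attributes.
#' @export
covariate_null_envelope <- function(p, from_mark = "liana", to_mark = "epi",
                                    radii = ring_radii(), ring_width = 2,
                                    n_sim = 10000, alpha = 0.05, seed = 1,
                                    scheme = c("permutation", "bernoulli")) {
  stopifnot(inherits(p, "mapped_pattern"))
  scheme <- match.arg(scheme)
  set.seed(seed)
  m1 <- mark_vector(p, from_mark)
  m2 <- mark_vector(p, to_mark)
  n <- nrow(p$points)
  n2 <- sum(m2)
  pr <- fit_mark_model(p, to_mark)

  rr <- union_grid(radii, ring_width)
  ps <- pair_structure(p, rr)
  n1 <- sum(m1)
  kden <- function(mm2) sum(m1) * sum(mm2) - sum(m1 & mm2)
  ring_of <- function(mm2) {
    kcum <- k_from_pairs(ps, m1, mm2, denom = max(kden(mm2), 1))
    ring_from_cum(rr, kcum, radii, ring_width)
  }
  observed <- ring_of(m2)
  sims <- matrix(NA_real_, n_sim, length(radii))
  for (s in seq_len(n_sim)) {
    mm <- logical(n)
    if (scheme == "permutation") {
      mm[sample.int(n, n2, prob = pr)] <- TRUE
    } else {
      mm <- runif(n) < pr
    }
    sims[s, ] <- if (sum(mm) >= 1) ring_of(mm) else 0
  }
  lower <- apply(sims, 2, quantile, alpha / 2, names = FALSE)
  upper <- apply(sims, 2, quantile, 1 - alpha / 2, names = FALSE)
  out <- tibble(r = radii, observed = observed, lower = lower, upper = upper,
                exceed = observed < lower | observed > upper,
                direction = dplyr::case_when(observed > upper ~ "above",
                                             observed < lower ~ "below",
                                             TRUE ~ "inside"))
  structure(out, class = c("ring_k_envelope", class(out)),
            from_mark = from_mark, to_mark = to_mark, n_sim = n_sim,
            alpha = alpha, ring_width = ring_width, scheme = scheme,
            seed = seed)
}

#' @export
print.ring_k_envelope <- function(x, ...) {
  cat(sprintf("<ring_k_envelope> %s -> %s, %d sims, alpha = %g, %d/%d radii outside\n",
              attr(x, "from_mark"), attr(x, "to_mark"), attr(x, "n_sim"),
              attr(x, "alpha"), sum(x$exceed), nrow(x)))
  NextMethod()
}
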