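#' Negative-binomial two-group contrast
#'
#' Fits `count ~ group` with a log link and NB2 error (dispersion
#' estimated by maximum likelihood via [MASS::glm.nb()]) and returns the
#' alt-vs-ref coefficient with its Wald test. Under NB2 the group-mean
#' MLEs equal the sample means, so the estimate is always
#' `log(mean(counts_alt) / mean(counts_ref))`; the z and p values depend
#' on the dispersion. When the theta ML iteration fails to converge
#' (e.g. equidispersed or sparse fixtures) the fit falls back to a
#' Poisson GLM (`theta = Inf`), flagged in the result — the estimate is
#' unchanged by the fallback.
#'
#' @param counts_ref,counts_alt Non-negative integer count vectors (the
#'   reference and alternative groups).
#' @return A tibble of class `nb_contrast`: `estimate` (log ratio), `z`,
#'   `p`, `theta`, `family` (`"nb2"` or `"poisson"`).
#' @export
#' @examples
#' nb_group_contrast(c(12, 11, 13, 12), c(4, 5, 3, 4))
nb_group_contrast <- function(counts_ref, counts_alt) {
  if (!length(counts_ref) || !length(counts_alt)) {
    abort("both groups must be non-empty", class = "lianepi_validation_error")
  }
  if (any(counts_ref < 0) || any(counts_alt < 0) ||
      any(counts_ref != round(counts_ref)) || any(counts_alt != round(counts_alt))) {
    abort("counts must be non-negative integers",
          class = "lianepi_validation_error")
  }
  if (sum(counts_ref) + sum(counts_alt) == 0) {
    abort("at least one positive count is required",
          class = "lianepi_validation_error")
  }
  if (sum(counts_ref) == 0 || sum(counts_alt) == 0) {
    abort("an all-zero group separates the log-link fit (infinite estimate)",
          class = "lianepi_separation_error")
  }
  df <- tibble(count = c(counts_ref, counts_alt),
               group = factor(rep(c("ref", "alt"),
                                  c(length(counts_ref), length(counts_alt))),
                              levels = c("ref", "alt")))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ group, data = df)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    fit <- glm(count ~ group, family = poisson(), data = df)
    theta <- Inf
    fam <- "poisson"
  } else {
    theta <- fit$theta
    fam <- "nb2"
  }
  sm <- summary(fit)$coefficients
  out <- tibble(estimate = sm["groupalt", "Estimate"],
                z = sm["groupalt", 3],
                p = sm["groupalt", 4],
                theta = theta, family = fam)
  class(out) <- c("nb_contrast", class(out))
  out
}

per_plot_host_counts <- function(ds) {
  ts <- tree_summaries(ds)
  ts %>%
    group_by(.data$patch_id, .data$plot_id) %>%
    summarise(liana = sum(.data$liana_host), epi = sum(.data$epi_host),
              .groups = "drop")
}

#' Patch-wise liana-vs-epiphyte host-count contrasts
#'
#' For every patch, contrasts the number of liana-host trees against the
#' number of epiphyte-host trees over that patch's plots with a
#' negative-binomial GLM (epiphyte hosts are the reference, so a
#' negative estimate means fewer liana hosts). Patches whose fit is
#' degenerate (an all-zero group) are returned with `NA` statistics and
#' a `note`.
#'
#' @param ds A `forest_dataset`.
#' @return Tibble: one row per patch with `estimate`, `z`, `p`, `theta`,
#'   `family`, `note`.
#' @export
patch_contrasts <- function(ds) {
  counts <- per_plot_host_counts(ds)
  purrr::map_dfr(unique(ds$patches$patch_id), function(pid) {
    sub <- filter(counts, .data$patch_id == pid)
    res <- tryCatch(
      nb_group_contrast(sub$epi, sub$liana),
      error = function(e) tibble(estimate = NA_real_, z = NA_real_,
                                 p = NA_real_, theta = NA_real_,
                                 family = NA_character_)
    )
    note <- if (is.na(res$estimate)) "degenerate (all-zero group)" else ""
    tibble(patch_id = pid, res, note = note)
  }) %>%
    left_join(ds$patches, by = "patch_id") %>%
    select("patch_id", "forest_type", dplyr::everything())
}

#' Zone-scale occurrence contrasts
#'
#' The four negative-binomial contrasts on per-plot zone occurrence
#' counts: liana vs epiphyte within each zone, and trunk vs crown within
#' each guild. Signs follow the `alt` column (e.g. for
#' `contrast = "epiphyte_trunk_vs_crown"` a negative estimate means
#' fewer occurrences on the trunk than the crown).
#'
#' @param ds A `forest_dataset`.
#' @return Tibble with `contrast`, `ref`, `alt` and the
#'   [nb_group_contrast()] columns.
#' @export
zone_contrasts <- function(ds) {
  z <- zone_occurrences(ds) %>%
    tidyr::pivot_wider(names_from = c("guild", "zone"), values_from = "n")
  specs <- list(
    list(name = "trunk_liana_vs_epi", ref = "epiphyte_trunk", alt = "liana_trunk"),
    list(name = "crown_liana_vs_epi", ref = "epiphyte_crown", alt = "liana_crown"),
    list(name = "liana_trunk_vs_crown", ref = "liana_crown", alt = "liana_trunk"),
    list(name = "epiphyte_trunk_vs_crown", ref = "epiphyte_crown",
         alt = "epiphyte_trunk")
  )
  purrr::map_dfr(specs, function(s) {
    res <- tryCatch(
      nb_group_contrast(z[[s$ref]], z[[s$alt]]),
      error = function(e) tibble(estimate = NA_real_, z = NA_real_,
                                 p = NA_real_, theta = NA_real_,
                                 family = NA_character_)
    )
    tibble(contrast = s$name, ref = s$ref, alt = s$alt, res)
  })
}

#' Epiphyte co-occurrence by liana climbing mechanism
#'
#' For every liana species, counts the epiphyte occurrences (records) on
#' the trees that species occupies, then contrasts those per-species
#' counts between specialized climbers (alt) and species that merely
#' lean on branches (ref) with a negative-binomial GLM. A positive
#' estimate means epiphytes co-occur more with specialized climbers.
#'
#' @param ds A `forest_dataset`.
#' @return An [nb_group_contrast()] result with the per-species counts
#'   attached as `attr(, "species_counts")`.
#' @export
mechanism_contrast <- function(ds) {
  mech <- ds$lianas %>% distinct(.data$species, .data$mechanism)
  if (length(unique(mech$mechanism)) < 2) {
    abort("both climbing mechanisms must be present",
          class = "lianepi_degenerate_error")
  }
  epi_per_tree <- ds$epiphytes %>% count(.data$tree_id, name = "n_epi")
  counts <- ds$lianas %>%
    distinct(.data$species, .data$mechanism, .data$tree_id) %>%
    left_join(epi_per_tree, by = "tree_id") %>%
    group_by(.data$species, .data$mechanism) %>%
    summarise(n_epi = sum(dplyr::coalesce(.data$n_epi, 0L)), .groups = "drop")
  res <- nb_group_contrast(
    counts$n_epi[counts$mechanism == "leaning"],
    counts$n_epi[counts$mechanism == "specialized"]
  )
  attr(res, "species_counts") <- counts
  res
}
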