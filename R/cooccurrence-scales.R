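#' 2x2 presence/absence contingency table for the two guilds
#'
#' Cell counts of trees by liana presence x epiphyte presence. "Host"
#' means at least one record of the guild on the tree, regardless of
#' zone.
#'
#' @param n_both,n_liana_only,n_epi_only,n_neither Non-negative counts.
#' @return An object of class `cooccurrence_table` (a named list with a
#'   `total`).
#' @export
cooccurrence_table <- function(n_both, n_liana_only, n_epi_only, n_neither) {
  cells <- c(n_both = n_both, n_liana_only = n_liana_only,
             n_epi_only = n_epi_only, n_neither = n_neither)
  if (any(!is.finite(cells) | cells < 0)) {
    abort("all cells must be non-negative counts",
          class = "lianepi_validation_error")
  }
  structure(c(as.list(cells), list(total = sum(cells))),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("<2x2 co-occurrence> both=%d liana-only=%d epi-only=%d neither=%d (n=%d)\n",
              x$n_both, x$n_liana_only, x$n_epi_only, x$n_neither, x$total))
  invisible(x)
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$n_both, t$n_liana_only, t$n_epi_only, t$n_neither), 2, 2,
         dimnames = list(liana = c("yes", "no"), epiphyte = c("yes", "no")))
}

#' Chi-square association test on a 2x2 co-occurrence table
#'
#' Continuity-corrected (Yates) chi-square with 1 df by default:
#' \eqn{\sum (\max(|O-E| - 0.5, 0))^2 / E} with expectations from the
#' margins. Set `correct = FALSE` for the uncorrected statistic.
#'
#' @param t A [cooccurrence_table()].
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return Tibble with `chi2`, `p`, `df`.
#' @export
#' @examples
#' yates_chi2(cooccurrence_table(27, 96, 103, 302))
yates_chi2 <- function(t, correct = TRUE) {
  stopifnot(inherits(t, "cooccurrence_table"))
  if (t$total <= 0) {
    abort("empty table", class = "lianepi_degenerate_error")
  }
  m <- as_matrix_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("a zero margin leaves expected counts undefined",
          class = "lianepi_degenerate_error")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble(chi2 = unname(ct$statistic), p = ct$p.value, df = 1L)
}

#' Shared-host percentage (union denominator)
#'
#' Percentage of host trees (of either guild) that host both:
#' \eqn{100\, s / (l + e - s)} for `l` liana hosts, `e` epiphyte hosts
#' and `s` shared. Returns `NA` when no tree hosts either guild.
#'
#' @param n_liana_hosts,n_epi_hosts,n_shared Counts (vectorised).
#' @return Percentage in `[0, 100]`, `NA` for an empty union.
#' @export
#' @examples
#' shared_pct(123, 130, 27)  # 11.9
shared_pct <- function(n_liana_hosts, n_epi_hosts, n_shared) {
  if (any(n_shared > pmin(n_liana_hosts, n_epi_hosts))) {
    abort("n_shared cannot exceed either host count",
          class = "lianepi_validation_error")
  }
  union <- n_liana_hosts + n_epi_hosts - n_shared
  if_else(union > 0, 100 * n_shared / union, NA_real_)
}

#' Tree-scale co-occurrence by diameter class
#'
#' One row per dbh class with host counts, the shared-host percentage
#' and the (Yates-corrected) chi-square association test — the
#' tree-scale summary table of the pipeline. Classes with no trees get
#' zero counts and `NA` test columns.
#'
#' @param ds A `forest_dataset`.
#' @param scheme A [dbh_class_scheme()].
#' @param correct Continuity correction flag passed to [yates_chi2()].
#' @return Tibble: `class`, `class_label`, `n_trees`, `n_liana_hosts`,
#'   `n_epi_hosts`, `n_shared`, `shared_pct`, `chi2`, `p`.
#' @export
contingency_by_class <- function(ds, scheme = dbh_class_scheme(),
                                 correct = TRUE) {
  ts <- tree_summaries(ds)
  ts$class <- dbh_class(ts$dbh, scheme)
  k <- length(scheme$breakpoints) + 1L
  labs <- dbh_class_labels(scheme)
  out <- purrr::map_dfr(seq_len(k), function(ci) {
    sub <- ts[ts$class == ci, ]
    n <- nrow(sub)
    l <- sum(sub$liana_host); e <- sum(sub$epi_host)
    s <- sum(sub$liana_host & sub$epi_host)
    tab <- cooccurrence_table(s, l - s, e - s, n - l - e + s)
    test <- tryCatch(yates_chi2(tab, correct = correct),
                     error = function(err) tibble(chi2 = NA_real_,
                                                  p = NA_real_, df = 1L))
    tibble(class = ci, class_label = labs[ci], n_trees = n,
           n_liana_hosts = l, n_epi_hosts = e, n_shared = s,
           shared_pct = shared_pct(l, e, s),
           chi2 = test$chi2, p = test$p)
  })
  out
}

#' The per-class 2x2 tables behind [contingency_by_class()]
#'
#' @inheritParams contingency_by_class
#' @return A named list of [cooccurrence_table()] objects, one per class.
#' @export
class_tables <- function(ds, scheme = dbh_class_scheme()) {
  tab <- contingency_by_class(ds, scheme)
  setNames(
    purrr::map(seq_len(nrow(tab)), function(i) {
      with(tab[i, ], cooccurrence_table(
        n_shared, n_liana_hosts - n_shared, n_epi_hosts - n_shared,
        n_trees - n_liana_hosts - n_epi_hosts + n_shared))
    }),
    tab$class_label
  )
}

#' Patch-scale host summaries
#'
#' One row per forest patch with tree and host counts and the shared
#' percentage (union denominator), plus exclusive-host counts.
#'
#' @param ds A `forest_dataset`.
#' @return Tibble: `patch_id`, `forest_type`, `n_trees`, `n_liana_hosts`,
#'   `n_epi_hosts`, `n_shared`, `n_liana_only`, `n_epi_only`,
#'   `shared_pct`.
#' @export
patch_summaries <- function(ds) {
  ts <- tree_summaries(ds)
  ds$patches %>%
    left_join(
      ts %>% group_by(.data$patch_id) %>%
        summarise(n_trees = n(),
                  n_liana_hosts = sum(.data$liana_host),
                  n_epi_hosts = sum(.data$epi_host),
                  n_shared = sum(.data$liana_host & .data$epi_host),
                  .groups = "drop"),
      by = "patch_id") %>%
    mutate(across(c("n_trees", "n_liana_hosts", "n_epi_hosts", "n_shared"),
                  ~ dplyr::coalesce(.x, 0L)),
           n_liana_only = .data$n_liana_hosts - .data$n_shared,
           n_epi_only = .data$n_epi_hosts - .data$n_shared,
           shared_pct = shared_pct(.data$n_liana_hosts, .data$n_epi_hosts,
                                   .data$n_shared))
}

#' Zone-scale occurrence counts per plot
#'
#' Per plot, the number of liana and epiphyte occurrences on trunks and
#' crowns. A liana record contributes to its single recorded zone; an
#' epiphyte record contributes one occurrence to every zone it occupies
#' (so a record spanning trunk and crown counts once in each).
#'
#' @param ds A `forest_dataset`.
#' @return Tibble: `patch_id`, `plot_id`, `guild`, `zone`, `n`, complete
#'   over all plot x guild x zone combinations.
#' @export
zone_occurrences <- function(ds) {
  plots <- distinct(ds$trees, .data$patch_id, .data$plot_id)
  tree_plot <- select(ds$trees, "tree_id", "patch_id", "plot_id")
  li <- ds$lianas %>%
    inner_join(tree_plot, by = "tree_id") %>%
    count(.data$patch_id, .data$plot_id, .data$zone) %>%
    mutate(guild = "liana")
  ep <- ds$epiphytes %>%
    inner_join(tree_plot, by = "tree_id") %>%
    tidyr::unnest_longer("zones", values_to = "zone") %>%
    count(.data$patch_id, .data$plot_id, .data$zone) %>%
    mutate(guild = "epiphyte")
  grid <- tidyr::crossing(plots, guild = c("liana", "epiphyte"),
                          zone = c("trunk", "crown"))
  grid %>%
    left_join(bind_rows(li, ep), by = c("patch_id", "plot_id", "guild", "zone")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    arrange(.data$patch_id, .data$plot_id, .data$guild, .data$zone)
}
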