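manual_chi2 <- function(t, correct = TRUE) {
  O <- matrix(c(t$n_both, t$n_liana_only, t$n_epi_only, t$n_neither), 2, 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  adj <- if (correct) pmin(0.5, abs(O - E)) else 0
  chi2 <- sum((abs(O - E) - adj)^2 / E)
  c(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

test_that("continuity-corrected chi-square matches the clamped-Yates formula", {
  set.seed(42)
  for (i in 1:25) {
    cells <- rpois(4, lambda = sample(c(5, 40, 200), 1)) + 1
    t <- cooccurrence_table(cells[1], cells[2], cells[3], cells[4])
    for (corr in c(TRUE, FALSE)) {
      got <- yates_chi2(t, correct = corr)
      ref <- manual_chi2(t, correct = corr)
      expect_equal(got$chi2, unname(ref["chi2"]), tolerance = 1e-12)
      expect_equal(got$p, unname(ref["p"]), tolerance = 1e-12)
    }
  }
})

test_that("correction only matters within the half-count bound", {
  set.seed(7)
  for (i in 1:10) {
    cells <- rpois(4, 80) + 20
    t <- cooccurrence_table(cells[1], cells[2], cells[3], cells[4])
    corr <- yates_chi2(t, correct = TRUE)$chi2
    un <- yates_chi2(t, correct = FALSE)$chi2
    expect_lte(corr, un)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(yates_chi2(cooccurrence_table(0, 0, 5, 5)),
               class = "lianepi_degenerate_error")
  expect_equal(yates_chi2(cooccurrence_table(10, 10, 10, 10))$chi2, 0)
  expect_equal(yates_chi2(cooccurrence_table(10, 10, 10, 10))$p, 1)
})

test_that("shared percentage uses the union-of-hosts denominator", {
  expect_equal(round(shared_pct(123, 130, 27), 1), 11.9)
  expect_equal(round(shared_pct(270, 423, 215), 1), 45.0)
  expect_equal(shared_pct(8, 8, 8), 100)
  expect_true(is.na(shared_pct(0, 0, 0)))
  expect_error(shared_pct(3, 5, 4), class = "lianepi_validation_error")
  set.seed(3)
  l <- rpois(50, 30); e <- rpois(50, 30); s <- pmin(l, e)
  s <- rbinom(50, s, 0.5)
  pct <- shared_pct(l, e, s)
  expect_true(all(is.na(pct) | (pct >= 0 & pct <= 100)))
})

test_that("class table cells match a per-tree enumeration oracle", {
  ds <- generate_stand(micro_stand_params(), seed = 21)
  tab <- contingency_by_class(ds)
  # brute force: walk every tree
  scheme <- dbh_class_scheme()
  li_hosts <- unique(ds$lianas$tree_id)
  ep_hosts <- unique(ds$epiphytes$tree_id)
  for (ci in 1:4) {
    ids <- ds$trees$tree_id[dbh_class(ds$trees$dbh, scheme) == ci]
    l <- sum(ids %in% li_hosts); e <- sum(ids %in% ep_hosts)
    s <- sum(ids %in% li_hosts & ids %in% ep_hosts)
    row <- tab[tab$class == ci, ]
    expect_equal(row$n_trees, length(ids))
    expect_equal(row$n_liana_hosts, l)
    expect_equal(row$n_epi_hosts, e)
    expect_equal(row$n_shared, s)
  }
  # partition property: class sums recover whole-stand counts
  expect_equal(sum(tab$n_trees), nrow(ds$trees))
  expect_equal(sum(tab$n_liana_hosts), length(li_hosts))
  expect_equal(sum(tab$n_shared), length(intersect(li_hosts, ep_hosts)))
})

test_that("guild-free datasets give zero co-occurrence columns", {
  ds <- forest_dataset(tiny_trees(),
                       lianas = tiny_dataset()$lianas)
  tab <- contingency_by_class(ds)
  expect_true(all(tab$n_epi_hosts == 0))
  expect_true(all(tab$n_shared == 0))
})

test_that("zone occurrences count record-zone pairs per plot", {
  ds <- tiny_dataset()
  z <- zone_occurrences(ds)
  # T1 (plot p1): epiphyte on both zones -> one occurrence in each
  expect_equal(z$n[z$plot_id == "p1" & z$guild == "epiphyte" & z$zone == "trunk"], 1L)
  expect_equal(z$n[z$plot_id == "p1" & z$guild == "epiphyte" & z$zone == "crown"], 1L)
  expect_equal(z$n[z$plot_id == "p1" & z$guild == "liana" & z$zone == "trunk"], 1L)
  # totals conserve record counts
  gen <- generate_stand(micro_stand_params(), seed = 13)
  zg <- zone_occurrences(gen)
  expect_equal(sum(zg$n[zg$guild == "liana"]), nrow(gen$lianas))
  expect_equal(sum(zg$n[zg$guild == "epiphyte"]),
               sum(lengths(gen$epiphytes$zones)))
})

test_that("patch summaries reproduce the shared percentage and handle empties", {
  expect_equal(round(shared_pct(91, 110, 60), 1), 42.6)
  expect_equal(round(shared_pct(7, 120, 4), 1), 3.3)
  ds <- forest_dataset(
    tiny_trees(),
    patches = data.frame(patch_id = c("P1", "P2"),
                         forest_type = c("successional", "mature")))
  ps <- patch_summaries(ds)
  p2 <- ps[ps$patch_id == "P2", ]
  expect_equal(p2$n_trees, 0L)
  expect_true(is.na(p2$shared_pct))
  ps1 <- ps[ps$patch_id == "P1", ]
  expect_equal(ps1$n_liana_hosts + ps1$n_epi_hosts - ps1$n_shared,
               ps1$n_liana_only + ps1$n_epi_only + ps1$n_shared)
})
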