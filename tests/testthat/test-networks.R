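test_that("liana-tree weights are summed basal areas", {
  ds <- tiny_dataset()
  m <- liana_tree_matrix(ds)
  # Cissus striata sits on two Ocotea trees with 2 and 3.5 cm stems
  expect_equal(m["Cissus striata", "Ocotea porphyria"],
               basal_area(2) + basal_area(3.5))
  expect_equal(m["Celtis iguanaea", "Ocotea porphyria"], basal_area(1))
  expect_equal(attr(m, "weight_kind"), "basal_area_m2")
})

test_that("epiphyte-tree weights count occupied zones", {
  ds <- tiny_dataset()
  m <- epiphyte_tree_matrix(ds)
  expect_equal(m["Pleopeltis tweediana", "Ocotea porphyria"], 2)  # both zones
  expect_equal(m["Aechmea distichantha", "Ocotea porphyria"], 1)
})

test_that("epiphyte-liana matrix counts shared trees with sane bounds", {
  ds <- tiny_dataset()
  m <- epiphyte_liana_matrix(ds)
  expect_equal(m["Pleopeltis tweediana", "Cissus striata"], 1)
  expect_equal(m["Pleopeltis tweediana", "Celtis iguanaea"], 1)
  expect_equal(m["Aechmea distichantha", "Cissus striata"], 1)
  # no co-occurring trees -> empty matrix
  no_shared <- forest_dataset(
    tiny_trees(),
    lianas = data.frame(tree_id = "T2", species = "l", diameter = 2,
                        mechanism = "leaning", zone = "trunk"),
    epiphytes = data.frame(tree_id = "T1", species = "e", cover_class = 1L,
                           zones = "crown"))
  expect_equal(dim(epiphyte_liana_matrix(no_shared)), c(0L, 0L))
})

test_that("conservation invariants hold across generated datasets", {
  for (s in 1:12) {
    ds <- generate_stand(micro_stand_params(), seed = 200 + s)
    lt <- liana_tree_matrix(ds)
    expect_equal(sum(lt), sum(basal_area(ds$lianas$diameter)), tolerance = 1e-12)
    et <- epiphyte_tree_matrix(ds)
    expect_equal(sum(et), sum(lengths(ds$epiphytes$zones)))
    el <- epiphyte_liana_matrix(ds)
    if (nrow(el)) {
      li_hosts <- table(unique(ds$lianas[c("tree_id", "species")])$species)
      ep_hosts <- table(unique(ds$epiphytes[c("tree_id", "species")])$species)
      for (e in rownames(el)) for (l in colnames(el)) {
        expect_lte(el[e, l], min(ep_hosts[[e]], li_hosts[[l]]))
      }
    }
    # cross-validation: brute per-tree scan of shared counts
    if (nrow(el)) {
      e1 <- rownames(el)[1]; l1 <- colnames(el)[1]
      trees_e <- unique(ds$epiphytes$tree_id[ds$epiphytes$species == e1])
      trees_l <- unique(ds$lianas$tree_id[ds$lianas$species == l1])
      expect_equal(el[e1, l1], length(intersect(trees_e, trees_l)))
    }
  }
})

test_that("per-tree-species zone totals match the matrix columns", {
  ds <- generate_stand(micro_stand_params(), seed = 250)
  et <- epiphyte_tree_matrix(ds)
  joined <- merge(ds$epiphytes, ds$trees[c("tree_id", "species")],
                  by = "tree_id", suffixes = c("", "_tree"))
  per_tree_sp <- tapply(lengths(joined$zones), joined$species_tree, sum)
  for (tsp in colnames(et)) {
    expect_equal(sum(et[, tsp]), unname(per_tree_sp[[tsp]]))
  }
})

test_that("network report ranks by marginal with alphabetical ties", {
  m <- new_bipartite_matrix_for_test(
    data.frame(row_species = c("b", "a", "c"), col_species = "t",
               weight = c(2, 2, 5)))
  rep_ <- network_report(m)
  expect_equal(rep_$rows$species, c("c", "a", "b"))
  ds <- generate_stand(micro_stand_params(), seed = 260)
  rep2 <- network_report(epiphyte_tree_matrix(ds))
  expect_equal(rep2$cols$marginal, sort(rep2$cols$marginal, decreasing = TRUE))
})
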