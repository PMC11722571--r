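# Hand fixtures and small generator settings shared across tests.

tiny_trees <- function() {
  data.frame(
    tree_id = c("T1", "T2", "T3"),
    patch_id = "P1", plot_id = c("p1", "p1", "p2"),
    species = c("Ocotea porphyria", "Eugenia uniflora", "Ocotea porphyria"),
    dbh = c(25, 12, 40)
  )
}

tiny_dataset <- function() {
  forest_dataset(
    trees = tiny_trees(),
    lianas = data.frame(
      tree_id = c("T1", "T1", "T3"),
      species = c("Cissus striata", "Celtis iguanaea", "Cissus striata"),
      diameter = c(2, 1, 3.5),
      mechanism = c("specialized", "specialized", "specialized"),
      zone = c("trunk", "crown", "trunk")
    ),
    epiphytes = data.frame(
      tree_id = c("T1", "T3"),
      species = c("Pleopeltis tweediana", "Aechmea distichantha"),
      cover_class = c(1L, 3L),
      zones = c("trunk|crown", "crown")
    ),
    patches = data.frame(patch_id = "P1", forest_type = "successional")
  )
}

# six-patch design: ~1000 trees, both forest types, fast to generate
small_stand_params <- function(...) {
  stand_params(
    n_patches = 6L,
    patch_types = c(S1 = "successional", S2 = "successional",
                    S3 = "successional", M1 = "mature", M2 = "mature",
                    M3 = "mature"),
    ...
  )
}

# two-patch micro design for bulk property checks
micro_stand_params <- function(...) {
  stand_params(
    n_patches = 2L, plots_per_patch = 4L,
    patch_types = c(A = "successional", B = "mature"),
    mapped_patch = "none",
    ...
  )
}

# brute-force translation-corrected cumulative K (double loop), the
# independent oracle for the pair-structure implementation
brute_k_cum <- function(pts, window, m1, m2, radii, denom) {
  a <- diff(window$x); b <- diff(window$y)
  area <- a * b
  out <- numeric(length(radii))
  n <- nrow(pts)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !m1[i] || !m2[j]) next
      dx <- abs(pts$x[i] - pts$x[j]); dy <- abs(pts$y[i] - pts$y[j])
      d <- sqrt(dx^2 + dy^2)
      w <- 1 / ((a - dx) * (b - dy))
      out <- out + w * (d <= radii)
    }
  }
  area^2 * out / denom
}

new_bipartite_matrix_for_test <- function(df) {
  lianepi:::new_bipartite_matrix(df, "shared_tree_count")
}

random_pattern <- function(n, side = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mapped_pattern(runif(n, 0, side), runif(n, 0, side),
                 list(x = c(0, side), y = c(0, side)),
                 liana_host = runif(n) < 0.5, epi_host = runif(n) < 0.5,
                 dbh = rlnorm(n, 3, 0.5) + 10,
                 species = sample(c("A", "B", "C"), n, replace = TRUE))
}
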