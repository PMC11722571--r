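#' Weighted bipartite interaction matrix
#'
#' Thin container for the three interaction matrices the pipeline
#' builds: rows are one species set, columns the other, weights are
#' non-negative interaction strengths. All-zero rows/columns are never
#' retained.
#'
#' @param df Tibble with columns `row_species`, `col_species`, `weight`.
#' @param weight_kind One of `"basal_area_m2"`, `"zone_count"`,
#'   `"shared_tree_count"`.
#' @return A `bipartite_matrix`: a numeric matrix with attributes.
#' @keywords internal
new_bipartite_matrix <- function(df, weight_kind) {
  df <- df %>%
    group_by(.data$row_species, .data$col_species) %>%
    summarise(weight = sum(.data$weight), .groups = "drop") %>%
    filter(.data$weight > 0)
  rows <- sort(unique(df$row_species))
  cols <- sort(unique(df$col_species))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(df)) m[cbind(df$row_species, df$col_species)] <- df$weight
  structure(m, weight_kind = weight_kind, class = c("bipartite_matrix", "matrix"))
}

#' @export
print.bipartite_matrix <- function(x, ...) {
  cat(sprintf("<bipartite_matrix> %d x %d species, weights: %s, total %.4g\n",
              nrow(x), ncol(x), attr(x, "weight_kind"), sum(x)))
  invisible(x)
}

#' Liana x tree interaction matrix (total basal area)
#'
#' Weight of (liana species l, tree species t) is the summed basal area
#' (m²) of all stems of l recorded on trees of species t.
#'
#' @param ds A `forest_dataset`.
#' @return A `bipartite_matrix` with `weight_kind = "basal_area_m2"`.
#' @export
liana_tree_matrix <- function(ds) {
  df <- ds$lianas %>%
    inner_join(select(ds$trees, "tree_id", tree_species = "species"),
               by = "tree_id") %>%
    mutate(row_species = .data$species, col_species = .data$tree_species,
           weight = basal_area_or_zero(.data$diameter))
  new_bipartite_matrix(df, "basal_area_m2")
}

basal_area_or_zero <- function(d) if (length(d)) basal_area(d) else double()

#' Epiphyte x tree interaction matrix (zone occupancy)
#'
#' Weight of (epiphyte species e, tree species t) is the total number of
#' tree zones (trunk and/or crown, so 1 or 2 per record) occupied by e
#' across trees of species t.
#'
#' @param ds A `forest_dataset`.
#' @return A `bipartite_matrix` with `weight_kind = "zone_count"`.
#' @export
epiphyte_tree_matrix <- function(ds) {
  df <- ds$epiphytes %>%
    inner_join(select(ds$trees, "tree_id", tree_species = "species"),
               by = "tree_id") %>%
    mutate(row_species = .data$species, col_species = .data$tree_species,
           weight = lengths(.data$zones))
  new_bipartite_matrix(df, "zone_count")
}

#' Epiphyte x liana co-occurrence matrix (shared trees)
#'
#' Built from trees hosting both guilds only: weight of (epiphyte
#' species e, liana species l) is the number of trees carrying records
#' of both e and l. Set `weight_kind = "occurrence_count"` to count
#' (epiphyte record, liana species) pairs instead of distinct trees.
#'
#' @param ds A `forest_dataset`.
#' @param weight_kind `"shared_tree_count"` (default) or
#'   `"occurrence_count"`.
#' @return A `bipartite_matrix` (possibly 0 x 0 when no tree hosts both).
#' @export
epiphyte_liana_matrix <- function(ds, weight_kind = c("shared_tree_count",
                                                      "occurrence_count")) {
  weight_kind <- match.arg(weight_kind)
  both <- intersect(unique(ds$lianas$tree_id), unique(ds$epiphytes$tree_id))
  ep <- ds$epiphytes %>% filter(.data$tree_id %in% both)
  li <- ds$lianas %>% filter(.data$tree_id %in% both) %>%
    distinct(.data$tree_id, liana_species = .data$species)
  if (weight_kind == "shared_tree_count") {
    ep <- distinct(ep, .data$tree_id, .data$species)
  }
  df <- ep %>%
    inner_join(li, by = "tree_id", relationship = "many-to-many") %>%
    distinct(.data$tree_id, .data$species, .data$liana_species,
             .keep_all = FALSE) %>%
    count(row_species = .data$species, col_species = .data$liana_species,
          name = "weight")
  if (weight_kind == "occurrence_count") {
    df <- ep %>%
      inner_join(li, by = "tree_id", relationship = "many-to-many") %>%
      count(row_species = .data$species, col_species = .data$liana_species,
            name = "weight")
  }
  new_bipartite_matrix(df, weight_kind)
}

#' Ranked marginal report of a bipartite matrix
#'
#' Rows and columns ranked by marginal weight (descending, ties broken
#' alphabetically) with the top-k species of each side.
#'
#' @param m A `bipartite_matrix`.
#' @param top_k Species to list per side (default 5).
#' @return List with tibbles `rows`, `cols` (species, marginal, rank)
#'   and `top_rows`, `top_cols` character vectors. Empty matrix gives an
#'   empty report.
#' @export
network_report <- function(m, top_k = 5) {
  stopifnot(inherits(m, "bipartite_matrix"))
  rank_side <- function(w) {
    tibble(species = names(w), marginal = unname(w)) %>%
      arrange(dplyr::desc(.data$marginal), .data$species) %>%
      mutate(rank = row_number())
  }
  rows <- rank_side(rowSums(m))
  cols <- rank_side(colSums(m))
  list(rows = rows, cols = cols,
       top_rows = head(rows$species, top_k),
       top_cols = head(cols$species, top_k),
       weight_kind = attr(m, "weight_kind"))
}

#' Write a bipartite matrix as labelled CSV
#' @param m A `bipartite_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bipartite_csv <- function(m, path) {
  df <- as_tibble(as.data.frame.table(unclass(m), stringsAsFactors = FALSE))
  names(df) <- c("row_species", "col_species", "weight")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
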