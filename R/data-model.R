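#' Assemble and validate a forest census dataset
#'
#' Bundles the four census tables used throughout the pipeline — trees,
#' liana records, epiphyte records and patch metadata — into a single
#' validated `forest_dataset` object. Validation enforces the census
#' protocol: trees at or above the 10 cm dbh threshold, liana stems at or
#' above 1 cm diameter, Braun-Blanquet cover classes 1–5, non-empty zone
#' sets, resolvable host-tree references, and a forest type
#' (`"successional"` or `"mature"`) for every patch.
#'
#' @param trees Data frame with columns `tree_id`, `patch_id`, `plot_id`,
#'   `species`, `dbh` (cm) and optionally `x`, `y` (metres; either both
#'   present or both absent per tree).
#' @param lianas Data frame with columns `tree_id`, `species`, `diameter`
#'   (cm, measured at 130 cm from the rooting point), `mechanism`
#'   (`"specialized"` or `"leaning"`) and `zone` (`"trunk"` or `"crown"`).
#'   Trees hosting no lianas simply have no rows here.
#' @param epiphytes Data frame with columns `tree_id`, `species`,
#'   `cover_class` (integer 1–5) and `zones` (list-column of character
#'   vectors, or a character column with zones pipe-joined as
#'   `"trunk|crown"`).
#' @param patches Data frame with columns `patch_id`, `forest_type`.
#'
#' @return A `forest_dataset`: a list of the four tibbles with class
#'   `"forest_dataset"`. Epiphyte `zones` is always a list-column.
#' @seealso [read_forest_dataset()], [generate_stand()]
#' @export
#' @examples
#' ds <- forest_dataset(
#'   trees = data.frame(tree_id = "T1", patch_id = "P1", plot_id = "p1",
#'                      species = "Ocotea porphyria", dbh = 25),
#'   lianas = data.frame(tree_id = "T1", species = "Cissus striata",
#'                       diameter = 2, mechanism = "specialized", zone = "trunk"),
#'   epiphytes = data.frame(tree_id = "T1", species = "Pleopeltis tweediana",
#'                          cover_class = 1, zones = "trunk|crown"),
#'   patches = data.frame(patch_id = "P1", forest_type = "successional")
#' )
#' ds
forest_dataset <- function(trees, lianas = NULL, epiphytes = NULL, patches = NULL) {
  trees <- as_tibble(trees)
  lianas <- as_tibble(lianas %||% empty_liana_table())
  epiphytes <- as_tibble(epiphytes %||% empty_epiphyte_table())
  if (is.null(patches)) {
    patches <- tibble(patch_id = unique(trees$patch_id), forest_type = "successional")
  }
  patches <- as_tibble(patches)

  need_cols(trees, c("tree_id", "patch_id", "plot_id", "species", "dbh"), "trees")
  need_cols(lianas, c("tree_id", "species", "diameter", "mechanism", "zone"), "lianas")
  need_cols(epiphytes, c("tree_id", "species", "cover_class", "zones"), "epiphytes")
  need_cols(patches, c("patch_id", "forest_type"), "patches")

  if (!("x" %in% names(trees))) trees$x <- NA_real_
  if (!("y" %in% names(trees))) trees$y <- NA_real_
  trees <- mutate(trees,
    tree_id = as.character(.data$tree_id),
    patch_id = as.character(.data$patch_id),
    plot_id = as.character(.data$plot_id),
    species = as.character(.data$species),
    dbh = as.double(.data$dbh),
    x = as.double(.data$x), y = as.double(.data$y)
  )
  lianas <- mutate(lianas,
    tree_id = as.character(.data$tree_id),
    species = as.character(.data$species),
    diameter = as.double(.data$diameter),
    mechanism = as.character(.data$mechanism),
    zone = as.character(.data$zone)
  )
  epiphytes$tree_id <- as.character(epiphytes$tree_id)
  epiphytes$species <- as.character(epiphytes$species)
  epiphytes$cover_class <- as.integer(epiphytes$cover_class)
  if (!is.list(epiphytes$zones)) {
    epiphytes$zones <- strsplit(as.character(epiphytes$zones), "|", fixed = TRUE)
  }
  patches <- mutate(patches,
    patch_id = as.character(.data$patch_id),
    forest_type = as.character(.data$forest_type)
  )

  ds <- structure(
    list(trees = trees, lianas = lianas, epiphytes = epiphytes, patches = patches),
    class = "forest_dataset"
  )
  validate_forest_dataset(ds)
  ds
}

empty_liana_table <- function() {
  tibble(tree_id = character(), species = character(), diameter = double(),
         mechanism = character(), zone = character())
}

empty_epiphyte_table <- function() {
  tibble(tree_id = character(), species = character(),
         cover_class = integer(), zones = list())
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("table '%s' is missing column(s): %s", what,
                  paste(miss, collapse = ", ")),
          class = "lianepi_validation_error")
  }
}

row_fail <- function(what, rows, msg) {
  abort(sprintf("%s: %s (row %s)", what, msg,
                paste(head(rows, 5), collapse = ", ")),
        class = "lianepi_validation_error")
}

#' Validate a forest_dataset against the census invariants
#'
#' Called by [forest_dataset()]; exported so round-tripped or hand-edited
#' objects can be re-checked. Errors carry row numbers of offending records.
#'
#' @param ds A `forest_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_forest_dataset <- function(ds) {
  trees <- ds$trees; lianas <- ds$lianas; epiphytes <- ds$epiphytes
  patches <- ds$patches

  bad <- which(!is.finite(trees$dbh) | trees$dbh < 10)
  if (length(bad)) row_fail("trees", bad, "dbh below the 10 cm census threshold")
  bad <- which(is.na(trees$x) != is.na(trees$y))
  if (length(bad)) row_fail("trees", bad, "x and y must be both present or both absent")
  dup <- which(duplicated(trees[c("patch_id", "plot_id", "tree_id")]))
  if (length(dup)) row_fail("trees", dup, "duplicated (patch_id, plot_id, tree_id)")
  if (anyDuplicated(trees$tree_id)) {
    row_fail("trees", which(duplicated(trees$tree_id)), "tree_id must be unique")
  }

  bad <- which(!trees$patch_id %in% patches$patch_id)
  if (length(bad)) row_fail("trees", bad, "patch_id has no row in the patches table")
  bad <- which(!patches$forest_type %in% c("successional", "mature"))
  if (length(bad)) row_fail("patches", bad, "forest_type must be 'successional' or 'mature'")

  bad <- which(!lianas$tree_id %in% trees$tree_id)
  if (length(bad)) {
    abort(sprintf("lianas: tree_id not found among trees (row %s)",
                  paste(head(bad, 5), collapse = ", ")),
          class = "lianepi_integrity_error")
  }
  bad <- which(!is.finite(lianas$diameter) | lianas$diameter < 1)
  if (length(bad)) row_fail("lianas", bad, "stem diameter below the 1 cm threshold")
  bad <- which(!lianas$mechanism %in% c("specialized", "leaning"))
  if (length(bad)) row_fail("lianas", bad, "mechanism must be 'specialized' or 'leaning'")
  bad <- which(!lianas$zone %in% c("trunk", "crown"))
  if (length(bad)) row_fail("lianas", bad, "zone must be 'trunk' or 'crown'")

  bad <- which(!epiphytes$tree_id %in% trees$tree_id)
  if (length(bad)) {
    abort(sprintf("epiphytes: tree_id not found among trees (row %s)",
                  paste(head(bad, 5), collapse = ", ")),
          class = "lianepi_integrity_error")
  }
  bad <- which(is.na(epiphytes$cover_class) | epiphytes$cover_class < 1L |
                 epiphytes$cover_class > 5L)
  if (length(bad)) row_fail("epiphytes", bad, "cover_class must be an integer 1-5")
  zl <- lengths(ds$epiphytes$zones)
  zok <- vapply(ds$epiphytes$zones, function(z) {
    length(z) > 0 && all(z %in% c("trunk", "crown")) && !anyDuplicated(z)
  }, logical(1))
  bad <- which(!zok)
  if (length(bad)) row_fail("epiphytes", bad, "zones must be a non-empty subset of {trunk, crown}")

  invisible(ds)
}

#' @export
print.forest_dataset <- function(x, ...) {
  ft <- table(x$patches$forest_type)
  cat(sprintf(
    "<forest_dataset> %d trees in %d patches (%s), %d liana records, %d epiphyte records\n",
    nrow(x$trees), nrow(x$patches),
    paste(sprintf("%d %s", as.integer(ft), names(ft)), collapse = ", "),
    nrow(x$lianas), nrow(x$epiphytes)
  ))
  nm <- sum(!is.na(x$trees$x))
  if (nm) cat(sprintf("  %d trees carry x-y coordinates\n", nm))
  invisible(x)
}

#' Read a forest dataset from four delimited-text tables
#'
#' Expects `trees.csv`, `lianas.csv`, `epiphytes.csv` and `patches.csv`
#' (UTF-8, header row, "." decimal separator) with the columns documented
#' in [forest_dataset()]. Epiphyte zones are pipe-joined (`"trunk|crown"`).
#'
#' @param dir Directory holding the four files, or `NULL` to pass paths.
#' @param tree_path,liana_path,epiphyte_path,patch_path Individual file
#'   paths; default to the standard names inside `dir`.
#' @return A validated [forest_dataset()].
#' @export
read_forest_dataset <- function(dir = NULL,
                                tree_path = file.path(dir, "trees.csv"),
                                liana_path = file.path(dir, "lianas.csv"),
                                epiphyte_path = file.path(dir, "epiphytes.csv"),
                                patch_path = file.path(dir, "patches.csv")) {
  for (p in c(tree_path, liana_path, epiphyte_path, patch_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p), class = "lianepi_io_error")
    }
  }
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  forest_dataset(trees = rd(tree_path), lianas = rd(liana_path),
                 epiphytes = rd(epiphyte_path), patches = rd(patch_path))
}

#' Write a forest dataset as four delimited-text tables
#'
#' Inverse of [read_forest_dataset()]: writes `trees.csv`, `lianas.csv`,
#' `epiphytes.csv`, `patches.csv` into `dir`, zones pipe-joined.
#'
#' @param ds A `forest_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_forest_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "forest_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  epi <- ds$epiphytes
  epi$zones <- vapply(epi$zones, paste, character(1), collapse = "|")
  trees <- ds$trees
  if (all(is.na(trees$x))) trees <- select(trees, -"x", -"y")
  readr::write_csv(trees, file.path(dir, "trees.csv"), progress = FALSE)
  readr::write_csv(ds$lianas, file.path(dir, "lianas.csv"), progress = FALSE)
  readr::write_csv(epi, file.path(dir, "epiphytes.csv"), progress = FALSE)
  readr::write_csv(ds$patches, file.path(dir, "patches.csv"), progress = FALSE)
  invisible(dir)
}

#' Basal area of a stem from its diameter
#'
#' Cross-sectional area at measurement height, \eqn{\pi (d/200)^2} for a
#' diameter in centimetres, returned in square metres. This is the
#' abundance currency for lianas: per-tree liana abundance is the summed
#' basal area of its stems.
#'
#' @param diameter Stem diameter(s) in cm; must be positive.
#' @return Basal area in m², same length as `diameter`.
#' @export
#' @examples
#' basal_area(2)   # 3.1416e-4 m2
#' basal_area(c(1, 5.64))
basal_area <- function(diameter) {
  if (any(!is.finite(diameter) | diameter <= 0)) {
    abort("diameter must be positive and finite", class = "lianepi_domain_error")
  }
  pi * (diameter / 200)^2
}

#' Diameter-class breakpoints
#'
#' Defines the dbh classification used by the tree-scale association
#' tables. The default breakpoints are the stand quartiles of the survey
#' this pipeline emulates (13.15, 19.75 and 33.76 cm), giving four
#' near-equal classes of trees at or above the 10 cm census threshold.
#' Classes are half-open on the right: class i covers
#' \eqn{[b_{i-1}, b_i)}, the top class \eqn{[b_k, \infty)}, so every dbh
#' maps to exactly one class and exact ties go to the upper class.
#'
#' @param breakpoints Strictly increasing dbh values in cm.
#' @return An object of class `dbh_class_scheme`.
#' @export
dbh_class_scheme <- function(breakpoints = c(13.15, 19.75, 33.76)) {
  breakpoints <- as.double(breakpoints)
  if (length(breakpoints) < 1 || any(!is.finite(breakpoints)) ||
      is.unsorted(breakpoints, strictly = TRUE)) {
    abort("breakpoints must be finite and strictly increasing",
          class = "lianepi_validation_error")
  }
  structure(list(breakpoints = breakpoints), class = "dbh_class_scheme")
}

#' Assign trees to diameter classes
#'
#' @param dbh Numeric vector of diameters (cm), all at least 10.
#' @param scheme A [dbh_class_scheme()].
#' @return Integer class indices in `1:(k+1)` for k breakpoints.
#' @export
#' @examples
#' dbh_class(c(12, 25, 40))
dbh_class <- function(dbh, scheme = dbh_class_scheme()) {
  stopifnot(inherits(scheme, "dbh_class_scheme"))
  if (any(!is.finite(dbh) | dbh < 10)) {
    abort("dbh must be finite and >= 10 cm", class = "lianepi_domain_error")
  }
  findInterval(dbh, scheme$breakpoints) + 1L
}

#' Class labels for a dbh scheme, e.g. "1 (<13.15 cm)"
#' @param scheme A [dbh_class_scheme()].
#' @return Character vector of k+1 labels.
#' @export
dbh_class_labels <- function(scheme = dbh_class_scheme()) {
  b <- scheme$breakpoints
  k <- length(b)
  lab <- character(k + 1)
  lab[1] <- sprintf("1 (<%g cm)", b[1])
  if (k > 1) {
    for (i in 2:k) lab[i] <- sprintf("%d (%g-%g)", i, b[i - 1], b[i])
  }
  lab[k + 1] <- sprintf("%d (>=%g)", k + 1, b[k])
  lab
}

#' Per-tree host status and aggregates
#'
#' One row per tree with its covariates and the per-tree quantities the
#' host models use: liana species richness, total liana basal area (m²),
#' epiphyte species richness, epiphyte cover class (maximum recorded
#' class; NA for non-hosts) and host flags for both guilds.
#'
#' @param ds A `forest_dataset`.
#' @return A tibble with one row per tree.
#' @export
tree_summaries <- function(ds) {
  stopifnot(inherits(ds, "forest_dataset"))
  li <- ds$lianas %>%
    group_by(.data$tree_id) %>%
    summarise(liana_richness = dplyr::n_distinct(.data$species),
              liana_ba = sum(basal_area(.data$diameter)), .groups = "drop")
  ep <- if (nrow(ds$epiphytes)) {
    ds$epiphytes %>%
      group_by(.data$tree_id) %>%
      summarise(epi_richness = dplyr::n_distinct(.data$species),
                epi_cover = max(.data$cover_class), .groups = "drop")
  } else {
    tibble(tree_id = character(), epi_richness = integer(),
           epi_cover = integer())
  }
  ds$trees %>%
    left_join(ds$patches, by = "patch_id") %>%
    left_join(li, by = "tree_id") %>%
    left_join(ep, by = "tree_id") %>%
    mutate(
      liana_richness = dplyr::coalesce(.data$liana_richness, 0L),
      liana_ba = dplyr::coalesce(.data$liana_ba, 0),
      epi_richness = dplyr::coalesce(.data$epi_richness, 0L),
      liana_host = .data$liana_richness > 0,
      epi_host = .data$epi_richness > 0
    )
}
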