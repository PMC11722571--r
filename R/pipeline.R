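#' Configuration for a full pipeline run
#'
#' Collects every stage's settings with full defaulting; the defaults
#' echo the analysis conventions the package implements (four dbh
#' classes at the survey quartile breakpoints, 4 chains of 8000 MCMC
#' iterations with the Rhat < 1.01 / ESS > 1000 convergence rule,
#' 10000 spatial permutations at alpha = 0.05 with 2 m rings).
#'
#' @param input Either a directory containing the four CSV tables, a
#'   `forest_dataset`, or `NULL` to simulate from `stand`.
#' @param stand A [stand_params()] used when `input` is `NULL`.
#' @param dbh_breakpoints Class breakpoints in cm.
#' @param host_models List: `responses`, `chains`, `iter`.
#' @param spatial List: `n_sim`, `alpha`, `ring_width`, `max_r`, `patch`.
#' @param seed Integer seed recorded in every output artefact.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param skip Character vector of stage names to skip (among
#'   `"scales"`, `"counts"`, `"host_models"`, `"networks"`,
#'   `"spatial"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, stand = stand_params(),
                       dbh_breakpoints = c(13.15, 19.75, 33.76),
                       host_models = list(), spatial = list(),
                       seed = 1, out_dir = NULL, skip = character()) {
  hm <- modifyList(list(responses = c("liana_richness", "epi_richness",
                                      "liana_ba", "epi_cover"),
                        chains = 4, iter = 8000), host_models)
  sp <- modifyList(list(n_sim = 10000, alpha = 0.05, ring_width = 2,
                        max_r = 14, patch = NULL), spatial)
  structure(list(input = input, stand = stand,
                 dbh_breakpoints = dbh_breakpoints, host_models = hm,
                 spatial = sp, seed = seed, out_dir = out_dir, skip = skip),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `stand` accepts
#' the scalar [stand_params()] overrides.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  stand <- if (is.null(y$stand)) stand_params() else do.call(stand_params, y$stand)
  run_config(input = y$input, stand = stand,
             dbh_breakpoints = y$dbh_breakpoints %||% c(13.15, 19.75, 33.76),
             host_models = y$host_models %||% list(),
             spatial = y$spatial %||% list(),
             seed = y$seed %||% 1, out_dir = y$out_dir,
             skip = y$skip %||% character())
}

#' Run the full co-occurrence pipeline
#'
#' Executes, in order: scale summaries (tree-zone / tree / patch),
#' count-model contrasts, host models, interaction networks and the
#' spatial stage, on the configured input (or a freshly simulated
#' stand). Each stage's tables are returned in one bundle and, when
#' `out_dir` is set, written as CSV plus a `summary.json` recording the
#' seed and stage status. A stage that cannot run on the given data
#' (e.g. spatial with no coordinates when skipped) is recorded as
#' skipped rather than failing the run; a genuine stage error aborts
#' with a stage-named error, retaining earlier outputs on disk.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_bundle` with one element per stage plus
#'   `dataset`, `config` and `status`.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  ds <- if (inherits(cfg$input, "forest_dataset")) {
    cfg$input
  } else if (is.character(cfg$input)) {
    read_forest_dataset(cfg$input)
  } else {
    generate_stand(cfg$stand, seed = cfg$seed)
  }
  scheme <- dbh_class_scheme(cfg$dbh_breakpoints)
  bundle <- list(dataset = ds, config = cfg)
  status <- list()
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, df) {
    if (!is.null(out_dir) && is.data.frame(df)) {
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }
  stage <- function(name, fun) {
    if (name %in% cfg$skip) {
      status[[name]] <<- "skipped: by config"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "lianepi_stage_error")
    })
    if (is.null(status[[name]])) status[[name]] <<- "ok"
    res
  }

  bundle$scales <- stage("scales", function() {
    res <- list(by_class = contingency_by_class(ds, scheme),
                by_patch = patch_summaries(ds),
                by_zone = zone_occurrences(ds))
    emit("scales_by_class", res$by_class)
    emit("scales_by_patch", res$by_patch)
    emit("scales_by_zone", res$by_zone)
    res
  })
  bundle$counts <- stage("counts", function() {
    res <- list(patch = patch_contrasts(ds), zone = zone_contrasts(ds),
                mechanism = tryCatch(mechanism_contrast(ds),
                                     error = function(e) NULL))
    emit("counts_patch", res$patch)
    emit("counts_zone", res$zone)
    if (!is.null(res$mechanism)) emit("counts_mechanism", res$mechanism)
    res
  })
  bundle$host_models <- stage("host_models", function() {
    fits <- purrr::map(cfg$host_models$responses, function(resp) {
      fit_host_model(ds, resp, chains = cfg$host_models$chains,
                     iter = cfg$host_models$iter, seed = cfg$seed)
    })
    names(fits) <- cfg$host_models$responses
    emit("host_model_params",
         purrr::map_dfr(fits, tidy, .id = "response"))
    emit("host_model_diagnostics", purrr::map_dfr(fits, glance))
    fits
  })
  bundle$networks <- stage("networks", function() {
    res <- list(liana_tree = liana_tree_matrix(ds),
                epiphyte_tree = epiphyte_tree_matrix(ds),
                epiphyte_liana = epiphyte_liana_matrix(ds))
    if (!is.null(out_dir)) {
      for (nm in names(res)) {
        if (nrow(res[[nm]]) > 0) {
          write_bipartite_csv(res[[nm]],
                              file.path(out_dir, paste0("network_", nm, ".csv")))
        }
      }
    }
    res
  })
  bundle$spatial <- stage("spatial", function() {
    if (!any(!is.na(ds$trees$x))) {
      status[["spatial"]] <<- "skipped: no coordinates"
      return(NULL)
    }
    pat <- as_mapped_pattern(ds, patch = cfg$spatial$patch)
    radii <- ring_radii(min(cfg$spatial$max_r,
                            floor(min(diff(pat$window$x),
                                      diff(pat$window$y)) / 2)))
    res <- list(
      epi_around_liana = covariate_null_envelope(
        pat, "liana", "epi", radii = radii,
        ring_width = cfg$spatial$ring_width, n_sim = cfg$spatial$n_sim,
        alpha = cfg$spatial$alpha, seed = cfg$seed),
      liana_around_epi = covariate_null_envelope(
        pat, "epi", "liana", radii = radii,
        ring_width = cfg$spatial$ring_width, n_sim = cfg$spatial$n_sim,
        alpha = cfg$spatial$alpha, seed = cfg$seed))
    emit("spatial_epi_around_liana", as_tibble(res$epi_around_liana))
    emit("spatial_liana_around_epi", as_tibble(res$liana_around_epi))
    res
  })
  bundle$status <- status
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = cfg$seed, stages = status,
           n_trees = nrow(ds$trees), n_liana_records = nrow(ds$lianas),
           n_epiphyte_records = nrow(ds$epiphytes)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  class(bundle) <- "run_bundle"
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>\n")
  for (nm in names(x$status)) cat(sprintf("  %-12s %s\n", nm, x$status[[nm]]))
  invisible(x)
}
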