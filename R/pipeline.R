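#' Configuration of the end-to-end pipeline
#'
#' @param input path to a site-table CSV/TSV, or `NULL` to generate
#'   synthetic data from `generator`.
#' @param generator a [generator_config()] used when `input` is `NULL`; its
#'   seed is overridden by `seed`.
#' @param simplified use the five-function simplified multifunctionality.
#' @param c aridity split level for the regional analyses.
#' @param w moving-window size.
#' @param B bootstrap resamples (windows and validation). Values below 100
#'   trigger a warning.
#' @param seed top-level seed; every stochastic stage derives its stream
#'   from it (stage offsets of 1000, window offsets of 1).
#' @param out_dir directory for CSV/JSON reports, or `NULL` to skip writing.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            simplified = FALSE, c = 0.80, w = 60, B = 500,
                            seed = 1L, out_dir = NULL) {
  if (B < 100) warning("B < 100 gives unstable bootstrap intervals")
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input, call. = FALSE)
  structure(list(input = input, generator = generator,
                 simplified = simplified, c = c, w = w, B = B,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full aridity-shift analysis pipeline
#'
#' Executes, in order: data loading or generation; multifunctionality and
#' diversity indices with the trade-off screen and the multiple-threshold
#' analysis; per-function and multifunctionality aridity-threshold
#' detection; the full and simplified mixed models; the moving-window
#' bootstrap with trajectory change points; and the region-split OLS
#' regressions. Per-stage status is recorded in a machine-readable manifest;
#' a stage failure is captured there (stage named) and later stages that
#' depend on it are skipped.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `"pipeline_result"` with elements `data`,
#'   `indices`, `thresholds`, `mixed`, `moving_window`, `region_split`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  response <- if (config$simplified) "multifunctionality_simplified"
              else "multifunctionality"
  manifest <- list(seed = config$seed, B = config$B, w = config$w,
                   c = config$c, simplified = config$simplified,
                   package_version = as.character(utils::packageVersion("aridishift")),
                   r_version = R.version.string,
                   stages = list())
  out <- list(manifest = NULL)
  stage <- function(name, fun) {
    res <- tryCatch(list(value = fun(), status = "ok"),
                    error = function(e)
                      list(value = NULL,
                           status = paste0("error: ", conditionMessage(e))))
    manifest$stages[[name]] <<- res$status
    res$value
  }

  out$data <- stage("data", function() {
    if (!is.null(config$input)) return(read_site_table(config$input))
    gen <- config$generator
    gen$seed <- config$seed
    generate_sites(validate_generator_config(gen))
  })

  if (!is.null(out$data)) {
    tab <- out$data
    out$indices <- stage("indices", function() {
      mf <- multifunctionality_index(tab, simplified = config$simplified)
      list(multifunctionality = mf,
           microbial_index = microbial_diversity_index(tab),
           tradeoffs = tradeoff_screen(tab),
           multiple_threshold = multiple_threshold_analysis(
             log10(tab$plant_richness + 1), tab))
    })

    out$thresholds <- stage("thresholds", function() {
      mf <- multifunctionality_index(tab, simplified = config$simplified)
      targets <- c(list(multifunctionality = mf),
                   lapply(stats::setNames(nm = soil_function_names(config$simplified)),
                          function(f) log10(tab[[f]])))
      lapply(seq_along(targets), function(i)
        detect_threshold(tab$aridity, targets[[i]], B = config$B,
                         seed = config$seed + 1000L + i)) |>
        stats::setNames(names(targets))
    })

    out$mixed <- stage("mixed", function() {
      list(full = fit_mixed(build_design(tab, model_spec("full", response))),
           simplified = fit_mixed(build_design(tab,
                                               model_spec("simplified", response))))
    })

    out$moving_window <- stage("moving_window", function()
      moving_window_analysis(tab, model_spec("simplified", response),
                             w = config$w, B = config$B,
                             seed = config$seed + 2000L))

    out$region_split <- stage("region_split", function()
      ols_by_region(tab, c = config$c, response = response))
  }

  manifest$ok <- all(vapply(manifest$stages, identical, logical(1), "ok"))
  out$manifest <- manifest

  if (!is.null(config$out_dir)) write_pipeline_reports(out, config)
  class(out) <- "pipeline_result"
  out
}

write_pipeline_reports <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(out$data)) write_site_table(out$data, p("site_table.csv"))
  if (!is.null(out$indices)) {
    utils::write.csv(data.frame(site_id = out$data$site_id,
                                multifunctionality = out$indices$multifunctionality,
                                microbial_index = out$indices$microbial_index),
                     p("indices.csv"), row.names = FALSE)
    utils::write.csv(out$indices$tradeoffs$pairs, p("tradeoffs.csv"),
                     row.names = FALSE)
    utils::write.csv(out$indices$multiple_threshold$per_threshold,
                     p("multiple_threshold.csv"), row.names = FALSE)
  }
  if (!is.null(out$mixed)) {
    utils::write.csv(out$mixed$full$table, p("mixed_full_table.csv"),
                     row.names = FALSE)
    utils::write.csv(out$mixed$simplified$table,
                     p("mixed_simplified_table.csv"), row.names = FALSE)
  }
  if (!is.null(out$moving_window))
    utils::write.csv(trajectory_table(out$moving_window),
                     p("trajectories.csv"), row.names = FALSE)
  if (!is.null(out$region_split))
    utils::write.csv(as.data.frame(out$region_split), p("region_split.csv"),
                     row.names = FALSE)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("aridishift pipeline run (seed", x$manifest$seed, ")\n")
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-14s %s\n", nm, x$manifest$stages[[nm]]))
  invisible(x)
}
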