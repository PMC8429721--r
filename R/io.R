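#' Write a site or microcosm table as CSV with a sidecar metadata file
#'
#' Writes the table as a plain CSV with a header row, plus a `<path>.meta`
#' sidecar in DCF (key: value) format recording the generator configuration
#' and seed when the table carries one, and the units metadata.
#'
#' @param table a site or microcosm table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(written = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
               n_rows = nrow(table), n_cols = ncol(table))
  truth <- attr(table, "truth")
  if (!is.null(truth$config)) {
    cfg <- truth$config
    meta$seed <- cfg$seed
    meta$n_sites <- cfg$n_sites
    meta$changepoint <- cfg$changepoint
    meta$aridity_range <- paste(cfg$aridity_range, collapse = ", ")
    meta$beta_plant <- paste(cfg$beta_plant_low, cfg$beta_plant_high, sep = " -> ")
    meta$beta_mic <- paste(cfg$beta_mic_low, cfg$beta_mic_high, sep = " -> ")
  }
  units <- attr(table, "units")
  if (!is.null(units))
    meta$units <- paste(names(units), units, sep = "=", collapse = "; ")
  write.dcf(as.data.frame(meta, stringsAsFactors = FALSE),
            paste0(path, ".meta"))
  invisible(path)
}

#' Read a site table from CSV or TSV
#'
#' The delimiter is auto-detected (comma or tab) from the header line.
#' Column names are validated against the expected schema and numeric
#' columns are checked cell by cell, with errors naming the offending
#' row and column.
#'
#' @param path file path.
#' @param required columns that must be present; defaults to the columns the
#'   analysis pipeline needs.
#' @return A data.frame of class `"site_table"`.
#' @export
read_site_table <- function(path,
                            required = c("aridity", "plant_richness",
                                         "archaeal_richness",
                                         "bacterial_richness",
                                         "fungal_richness",
                                         soil_function_names())) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  numeric_cols <- intersect(
    c("aridity", "latitude", "longitude", "elevation", "soil_pH", "clay",
      "perennial_cover", "plant_richness", "archaeal_richness",
      "bacterial_richness", "fungal_richness", "saprotroph_richness",
      "pathogen_richness", "symbiont_richness", "ndvi", "agb",
      "root_biomass", soil_function_names()),
    names(tab))
  for (cl in numeric_cols) {
    v <- tab[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", cl, "', row ", bad[1],
             ": '", v[bad[1]], "'", call. = FALSE)
      tab[[cl]] <- conv
    }
  }
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path))
    attr(tab, "meta") <- as.list(as.data.frame(read.dcf(meta_path),
                                               stringsAsFactors = FALSE))
  class(tab) <- c("site_table", "data.frame")
  tab
}
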