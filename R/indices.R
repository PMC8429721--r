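#' Build a sites-by-functions matrix
#'
#' Extracts the soil-function block from a site table (or accepts a numeric
#' matrix directly) together with per-function log10 flags. The seven
#' nutrient-pool functions are log10-transformed before standardization, as
#' is conventional for right-skewed soil concentrations.
#'
#' @param x a site table (data.frame) or numeric matrix.
#' @param function_names columns to use; defaults to the seven soil
#'   functions, or all columns of a matrix.
#' @param log10_flags logical vector (recycled) marking columns to
#'   log10-transform before standardization.
#' @return An object of class `"function_matrix"`: the raw values plus
#'   attributes `function_names` and `log10_flags`.
#' @export
function_matrix <- function(x, function_names = NULL, log10_flags = TRUE) {
  if (is.data.frame(x)) {
    if (is.null(function_names)) function_names <- soil_function_names()
    missing_cols <- setdiff(function_names, names(x))
    if (length(missing_cols))
      stop("missing function columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    m <- as.matrix(x[, function_names, drop = FALSE])
  } else {
    m <- as.matrix(x)
    if (is.null(function_names))
      function_names <- colnames(m) %||% sprintf("F%d", seq_len(ncol(m)))
    colnames(m) <- function_names
  }
  if (nrow(m) < 2L) stop("need at least 2 sites", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 functions", call. = FALSE)
  if (anyNA(m)) stop("function matrix contains missing cells", call. = FALSE)
  flags <- rep_len(as.logical(log10_flags), ncol(m))
  if (any(flags) && any(m[, flags] <= 0))
    stop("log10-flagged columns must be strictly positive", call. = FALSE)
  structure(m, function_names = function_names, log10_flags = flags,
            class = c("function_matrix", class(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score standardization of a function matrix
#'
#' Log10-transforms flagged columns, then centers and scales every column to
#' mean 0 and (sample, n-1 denominator) SD 1.
#'
#' @param matrix a [function_matrix()] (or anything it accepts).
#' @param ... passed to [function_matrix()] when `matrix` is not one already.
#' @return A list of class `"standardized_functions"`: `z_matrix`, plus the
#'   per-column `center` and `scale` applied after any log10 transform.
#' @examples
#' sf <- standardize_functions(generate_sites(generator_config(seed = 1)))
#' colMeans(sf$z_matrix)  # all ~0
#' @export
standardize_functions <- function(matrix, ...) {
  if (!inherits(matrix, "function_matrix")) matrix <- function_matrix(matrix, ...)
  flags <- attr(matrix, "log10_flags")
  m <- unclass(matrix)
  m[, flags] <- log10(m[, flags])
  sds <- apply(m, 2, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate))
    stop("zero-variance function column(s): ",
         paste(colnames(m)[degenerate], collapse = ", "), call. = FALSE)
  z <- scale(m)
  structure(list(z_matrix = z[, , drop = FALSE],
                 center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale"),
                 log10_flags = flags),
            class = "standardized_functions")
}

#' Averaging multifunctionality index
#'
#' Row means of a standardized (Z-scored) matrix: the averaging approach to
#' ecosystem multifunctionality. Also used for the soil microbial diversity
#' index (mean of Z-scored archaeal, bacterial and fungal richness).
#'
#' @param z a `"standardized_functions"` object or a numeric z-matrix.
#' @return Numeric vector, one index value per row.
#' @export
averaging_index <- function(z) {
  if (inherits(z, "standardized_functions")) z <- z$z_matrix
  rowMeans(as.matrix(z))
}

#' Soil multifunctionality index of a site table
#'
#' Convenience wrapper: standardizes the seven soil functions (log10 first)
#' and averages the Z-scores. `simplified = TRUE` drops total N and total P
#' and averages the remaining five.
#'
#' @param table a site table.
#' @param simplified use the five-function simplified index.
#' @return Numeric vector of per-site multifunctionality.
#' @export
multifunctionality_index <- function(table, simplified = FALSE) {
  fm <- function_matrix(table, soil_function_names(simplified))
  averaging_index(standardize_functions(fm))
}

#' Soil microbial diversity index
#'
#' Mean of the Z-scored archaeal, bacterial and fungal OTU richness of each
#' site (richness is not log-transformed). With `rescale = TRUE` the index
#' itself is re-standardized to SD 1, convenient for standardized-coefficient
#' models.
#'
#' @param table a site or microcosm table.
#' @param rescale standardize the resulting index.
#' @return Numeric vector.
#' @export
microbial_diversity_index <- function(table, rescale = FALSE) {
  cols <- c("archaeal_richness", "bacterial_richness", "fungal_richness")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing richness columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  idx <- rowMeans(vapply(cols, function(cl) as.numeric(scale(table[[cl]])),
                         numeric(nrow(table))))
  if (rescale) as.numeric(scale(idx)) else idx
}

#' Weighted site-level aggregation of vegetated and bare-ground measurements
#'
#' `cover * veg_mean + (1 - cover) * bare_mean`: the weighted average of the
#' mean values observed under perennial vegetation and in bare ground,
#' weighted by their respective cover.
#'
#' @param veg_mean,bare_mean stratum means.
#' @param perennial_cover fraction in \[0, 1\].
#' @return Aggregated site-level value.
#' @examples
#' site_level_aggregate(10, 2, 0.3)  # 4.4
#' @export
site_level_aggregate <- function(veg_mean, bare_mean, perennial_cover) {
  if (any(perennial_cover < 0 | perennial_cover > 1))
    stop("perennial_cover must lie in [0, 1]", call. = FALSE)
  perennial_cover * veg_mean + (1 - perennial_cover) * bare_mean
}

#' Belowground net primary productivity from the biomass ratio
#'
#' Under the approximation aboveground biomass / root biomass = ANPP / BNPP,
#' with NDVI used as the ANPP proxy, BNPP = ANPP proxy * root biomass /
#' aboveground biomass.
#'
#' @param agb aboveground biomass (g m-2), > 0.
#' @param root_biomass root biomass (g m-2), > 0.
#' @param anpp_proxy ANPP proxy (mean NDVI over the sampling dates).
#' @return BNPP in the proxy's units.
#' @examples
#' estimate_bnpp(100, 200, 0.5)  # 1
#' @export
estimate_bnpp <- function(agb, root_biomass, anpp_proxy) {
  if (any(agb <= 0) || any(root_biomass <= 0))
    stop("biomass values must be strictly positive", call. = FALSE)
  anpp_proxy * root_biomass / agb
}

#' Classify an aridity level into dryland subtypes
#'
#' Drylands begin at aridity (1 - AI) 0.35; the semiarid/arid boundary sits
#' at 0.80. The 0.50 and 0.95 boundaries follow the UNEP aridity-index
#' convention (AI 0.2 and 0.05). Intervals are half-open upward: a site
#' exactly at a boundary takes the drier class.
#'
#' @param aridity numeric in \[0, 1).
#' @return Factor with levels non-dryland < dry-subhumid < semiarid < arid <
#'   hyperarid.
#' @examples
#' classify_aridity(c(0.3, 0.5, 0.8, 0.97))
#' @export
classify_aridity <- function(aridity) {
  if (any(aridity < 0 | aridity >= 1))
    stop("aridity must lie in [0, 1)", call. = FALSE)
  bands <- aridity_bands()
  cut(aridity, breaks = c(bands$lower, 1), labels = bands$subtype,
      right = FALSE, ordered_result = TRUE)
}

#' Trade-off and redundancy screen among soil functions
#'
#' Pearson correlations between every unordered pair of soil functions.
#' Significant negative pairs indicate trade-offs; pairs with r above
#' `redundancy_r` indicate redundancy.
#'
#' @param matrix a [function_matrix()] or site table.
#' @param alpha two-sided significance level.
#' @param redundancy_r correlation magnitude above which a pair is flagged
#'   redundant.
#' @return A list of class `"tradeoff_report"`: `pairs` (data.frame with
#'   function_1, function_2, r, P, significant, redundant), `n_pairs`,
#'   `n_significant_positive`, `n_significant_negative`, `n_redundant`.
#' @export
tradeoff_screen <- function(matrix, alpha = 0.05, redundancy_r = 0.7) {
  if (!inherits(matrix, "function_matrix")) matrix <- function_matrix(matrix)
  m <- unclass(matrix)
  if (nrow(m) < 3L) stop("need at least 3 sites", call. = FALSE)
  cmb <- utils::combn(colnames(m), 2)
  pairs <- data.frame(function_1 = cmb[1, ], function_2 = cmb[2, ],
                      r = NA_real_, P = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    a <- m[, cmb[1, i]]; b <- m[, cmb[2, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next  # undefined pair
    ct <- stats::cor.test(a, b, method = "pearson")
    pairs$r[i] <- unname(ct$estimate)
    pairs$P[i] <- ct$p.value
  }
  pairs$significant <- !is.na(pairs$P) & pairs$P < alpha
  pairs$redundant <- !is.na(pairs$r) & pairs$r > redundancy_r
  structure(list(pairs = pairs,
                 n_pairs = nrow(pairs),
                 n_significant_positive = sum(pairs$significant & pairs$r > 0,
                                              na.rm = TRUE),
                 n_significant_negative = sum(pairs$significant & pairs$r < 0,
                                              na.rm = TRUE),
                 n_redundant = sum(pairs$redundant)),
            class = "tradeoff_report")
}

#' @export
print.tradeoff_report <- function(x, ...) {
  cat("Trade-off / redundancy screen:", x$n_pairs, "function pairs\n")
  cat("  significant positive:", x$n_significant_positive,
      " significant negative:", x$n_significant_negative,
      " redundant (r > 0.7):", x$n_redundant, "\n")
  invisible(x)
}
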