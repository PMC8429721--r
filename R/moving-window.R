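#' Build the sliding windows along the aridity gradient
#'
#' Sorts sites by aridity (ties broken by `site_id` for determinism) and
#' forms every window of `w` consecutive sites, shifting one site at a time:
#' the first window holds the `w` lowest-aridity sites and the last the `w`
#' highest. A table of `n` sites yields `n - w + 1` windows (one initial
#' window plus `n - w` one-site shifts).
#'
#' @param table a site table.
#' @param w window size (sites per window).
#' @return A list of class `"window_set"`: `indices` (list of row-index
#'   vectors into `table`), `w`, `n_windows`, `n_shifts` (`n_windows - 1`),
#'   `mean_aridity` per window.
#' @examples
#' ws <- make_windows(generate_sites(generator_config(seed = 1)), w = 60)
#' ws$n_windows  # 71
#' @export
make_windows <- function(table, w = 60) {
  n <- nrow(table)
  if (n < w) stop("need at least w = ", w, " sites, got ", n, call. = FALSE)
  ord <- if ("site_id" %in% names(table)) order(table$aridity, table$site_id)
         else order(table$aridity)
  starts <- seq_len(n - w + 1L)
  indices <- lapply(starts, function(s) ord[s:(s + w - 1L)])
  structure(list(indices = indices, w = w, n_windows = length(starts),
                 n_shifts = length(starts) - 1L,
                 mean_aridity = vapply(indices, function(i)
                   mean(table$aridity[i]), numeric(1))),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("Moving windows: ", x$n_windows, " windows of ", x$w,
      " sites (", x$n_shifts, " one-site shifts)\n", sep = "")
  invisible(x)
}

#' Bootstrap standardized coefficients within one window
#'
#' Fits the biodiversity--multifunctionality model on the `w` sites of a
#' window and bootstraps its standardized coefficients by resampling sites
#' with replacement `B` times. The point fit is the mixed model (random
#' soil-/vegetation-type intercepts, dropped when singular); bootstrap
#' resamples are refit by ordinary least squares on the standardized fixed
#' design, the design-based choice for a site bootstrap (resampling
#' fragments the few group labels inside a window, making random-intercept
#' variances unidentifiable there).
#'
#' A term is flagged significant when the one-sided bootstrap tail
#' probability of disagreeing with the sign of its median coefficient is at
#' most 0.05, i.e. at least 95% of draws share the median's sign.
#'
#' @param table a site table.
#' @param window integer vector of row indices (one element of a
#'   [make_windows()] `indices` list).
#' @param spec a [model_spec()] (region is forced to `"all"`: the window is
#'   the subset).
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param max_fail_frac flag the window unusable when more than this
#'   fraction of resamples fails (degenerate design).
#' @return A list of class `"bootstrap_coefficients"`: `window_mean_aridity`,
#'   `coefficients` (B x terms matrix), `summary` (per-term median, lo, hi,
#'   significant), `point` (the window's mixed-model report), `n_failed`,
#'   `usable`.
#' @export
window_bootstrap <- function(table, window, spec = model_spec("simplified"),
                             B = 500, seed = 1L, max_fail_frac = 0.2) {
  spec$region <- "all"
  rows <- table[window, , drop = FALSE]
  point <- fit_mixed(build_design(rows, spec))
  terms <- point$design$terms

  set.seed(seed)
  w <- nrow(rows)
  coefs <- matrix(NA_real_, B, length(terms),
                  dimnames = list(NULL, terms))
  n_failed <- 0L

  ## precompute raw (pre-standardization) ingredients once; per resample the
  ## same standardize-within-subset construction as build_design, vectorized
  L <- log10(as.matrix(rows[, soil_function_names(
    spec$response == "multifunctionality_simplified"), drop = FALSE]))
  rich <- as.matrix(rows[, c("archaeal_richness", "bacterial_richness",
                             "fungal_richness")])
  raw_mains <- list(year = as.numeric(rows$year),
                    plant_richness = log10(rows$plant_richness + 1),
                    aridity = rows$aridity,
                    archaeal_richness = as.numeric(rows$archaeal_richness),
                    bacterial_richness = as.numeric(rows$bacterial_richness),
                    fungal_richness = as.numeric(rows$fungal_richness))
  if (spec$variant == "full") {
    raw_mains$bnpp <- estimate_bnpp(rows$agb, rows$root_biomass, rows$ndvi)
    raw_mains$soil_pH <- rows$soil_pH
    raw_mains$clay <- rows$clay
    raw_mains$elevation <- log10(rows$elevation)
    raw_mains$latitude <- rows$latitude
    raw_mains$longitude <- rows$longitude
  }
  needed <- unique(unlist(strsplit(terms, "_x_", fixed = TRUE)))
  zcol <- function(v) {
    s <- stats::sd(v)
    if (s == 0 || !is.finite(s)) return(NULL)
    (v - mean(v)) / s
  }
  resample_fit <- function(idx) {
    mains <- list()
    for (nm in needed) {
      if (nm == "microbial_index") {
        zr <- apply(rich[idx, , drop = FALSE], 2, zcol)
        if (is.null(dim(zr))) return(NULL)
        mains[[nm]] <- zcol(rowMeans(zr))
      } else mains[[nm]] <- zcol(raw_mains[[nm]][idx])
      if (is.null(mains[[nm]])) return(NULL)
    }
    zL <- apply(L[idx, , drop = FALSE], 2, zcol)
    if (is.null(dim(zL))) return(NULL)
    y <- zcol(rowMeans(zL))
    if (is.null(y)) return(NULL)
    X <- matrix(1, length(idx), length(terms) + 1L)
    for (j in seq_along(terms)) {
      parts <- strsplit(terms[j], "_x_", fixed = TRUE)[[1]]
      X[, j + 1L] <- Reduce(`*`, mains[parts])
    }
    fit <- stats::lm.fit(X, y)
    if (any(is.na(fit$coefficients))) return(NULL)
    fit$coefficients[-1L]
  }
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in 1:25) {
      cf <- resample_fit(sample.int(w, w, replace = TRUE))
      if (!is.null(cf)) { coefs[b, ] <- cf; ok <- TRUE; break }
    }
    if (!ok) n_failed <- n_failed + 1L
  }
  usable <- n_failed <= max_fail_frac * B
  drawn <- coefs[stats::complete.cases(coefs), , drop = FALSE]
  med <- apply(drawn, 2, stats::median)
  lo <- apply(drawn, 2, stats::quantile, probs = 0.025)
  hi <- apply(drawn, 2, stats::quantile, probs = 0.975)
  # one-sided tail probability of sign disagreement with the median
  tail_p <- vapply(terms, function(tm)
    mean(sign(drawn[, tm]) != sign(med[tm])), numeric(1))
  structure(list(window_mean_aridity = mean(rows$aridity),
                 coefficients = coefs,
                 summary = data.frame(term = terms, median = med, lo = lo,
                                      hi = hi, tail_P = tail_p,
                                      significant = tail_p <= 0.05,
                                      row.names = NULL),
                 point = point, B = B, n_failed = n_failed, usable = usable),
            class = "bootstrap_coefficients")
}

#' Assemble a coefficient trajectory across windows
#'
#' Collects one term's bootstrap summaries from every usable window into an
#' ordered series indexed by window-mean aridity, and fits a GAM smoother to
#' the medians.
#'
#' @param boot_list list of [window_bootstrap()] results, in window order.
#' @param term fixed-term name.
#' @return A list of class `"trajectory"`: `term`, `series` (window_id,
#'   mean_aridity, median, lo, hi, significant), `smoother` (mgcv fit),
#'   `smoothed` (fitted values at the window positions).
#' @export
assemble_trajectory <- function(boot_list, term) {
  usable <- vapply(boot_list, function(b) isTRUE(b$usable), logical(1))
  if (sum(usable) < 10L)
    stop("need at least 10 usable windows, got ", sum(usable), call. = FALSE)
  boots <- boot_list[usable]
  s0 <- boots[[1]]$summary
  if (!term %in% s0$term)
    stop("term not in bootstrap summaries: ", term, call. = FALSE)
  series <- do.call(rbind, lapply(seq_along(boots), function(i) {
    s <- boots[[i]]$summary
    r <- s[s$term == term, ]
    data.frame(window_id = which(usable)[i],
               mean_aridity = boots[[i]]$window_mean_aridity,
               median = r$median, lo = r$lo, hi = r$hi,
               significant = r$significant)
  }))
  series <- series[order(series$mean_aridity), ]
  kbasis <- max(4L, min(10L, nrow(series) - 2L))
  smoother <- mgcv::gam(median ~ s(mean_aridity, k = kbasis), data = series,
                        method = "GCV.Cp")
  structure(list(term = term, series = series, smoother = smoother,
                 smoothed = as.numeric(stats::fitted(smoother))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Coefficient trajectory for '", x$term, "': ", nrow(x$series),
      " windows, mean aridity ", sprintf("%.2f", min(x$series$mean_aridity)),
      "-", sprintf("%.2f", max(x$series$mean_aridity)), "\n", sep = "")
  invisible(x)
}

#' Detect a change point in a coefficient trajectory
#'
#' Runs the full threshold-detection protocol ([detect_threshold()]) on the
#' series of per-window median coefficients against window-mean aridity.
#'
#' The unimodality gate is off by default here: window-mean aridity is a
#' deterministic ordered grid induced by the window construction, not a
#' random sample, so a mixture-component screen carries no information about
#' it (the screen remains on for site-level series in [detect_threshold()]).
#'
#' @param trajectory an [assemble_trajectory()] result.
#' @param B bootstrap resamples for validation.
#' @param seed integer seed.
#' @param require_unimodal gate on bimodality of the window means.
#' @param ... passed to [detect_threshold()].
#' @return A `"threshold_decision"`.
#' @export
trajectory_threshold <- function(trajectory, B = 200, seed = 1L,
                                 require_unimodal = FALSE, ...) {
  stopifnot(inherits(trajectory, "trajectory"))
  detect_threshold(trajectory$series$mean_aridity, trajectory$series$median,
                   B = B, seed = seed, require_unimodal = require_unimodal,
                   ...)
}

#' Moving-window bootstrap analysis along the aridity gradient
#'
#' End-to-end engine: builds the windows, bootstraps the standardized
#' coefficients of the biodiversity--multifunctionality model within each
#' window, assembles per-term trajectories, and detects change points in the
#' trajectories of the diversity terms.
#'
#' Each window derives its bootstrap stream deterministically from the
#' top-level seed (`seed + window index`).
#'
#' @param table a site table.
#' @param spec a [model_spec()]; default the simplified variant.
#' @param w window size.
#' @param B bootstrap resamples per window.
#' @param seed integer seed.
#' @param trajectory_terms terms whose trajectories get change-point
#'   detection; defaults to the diversity mains and their aridity
#'   interactions.
#' @return A list of class `"moving_window_result"`: `windows`,
#'   `bootstraps`, `trajectories` (named list), `thresholds` (named list of
#'   `"threshold_decision"`), `spec`, `seed`.
#' @export
moving_window_analysis <- function(table, spec = model_spec("simplified"),
                                   w = 60, B = 500, seed = 1L,
                                   trajectory_terms = NULL) {
  windows <- make_windows(table, w)
  boots <- lapply(seq_len(windows$n_windows), function(i)
    window_bootstrap(table, windows$indices[[i]], spec, B = B,
                     seed = seed + i))
  terms <- boots[[1]]$summary$term
  if (is.null(trajectory_terms))
    trajectory_terms <- intersect(
      c("plant_richness", "microbial_index", "aridity_x_plant_richness",
        "aridity_x_microbial_index"), terms)
  trajectories <- lapply(trajectory_terms, function(tm)
    assemble_trajectory(boots, tm))
  names(trajectories) <- trajectory_terms
  thresholds <- lapply(seq_along(trajectories), function(i)
    trajectory_threshold(trajectories[[i]], B = B, seed = seed + 10000L + i))
  names(thresholds) <- trajectory_terms
  structure(list(windows = windows, bootstraps = boots,
                 trajectories = trajectories, thresholds = thresholds,
                 spec = spec, seed = seed),
            class = "moving_window_result")
}

#' Long-format trajectory table
#'
#' @param result a `"moving_window_result"`.
#' @return data.frame (term, window_id, mean_aridity, median, lo, hi,
#'   significant).
#' @export
trajectory_table <- function(result) {
  stopifnot(inherits(result, "moving_window_result"))
  do.call(rbind, lapply(result$trajectories, function(tr)
    cbind(term = tr$term, tr$series, row.names = NULL)))
}
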