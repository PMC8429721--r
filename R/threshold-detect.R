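#' Unimodality check via Gaussian mixture fitting
#'
#' Fits 1- and 2-component Gaussian mixtures (equal- and unequal-variance
#' parameterizations), selects the component count by BIC, and — because two
#' Gaussian components routinely fit skewed, flat-topped or otherwise
#' non-Gaussian unimodal densities better than one — resolves the verdict
#' from the shape of the selected mixture density: the sample is called
#' bimodal only when the density has two local maxima separated by a deep
#' valley (the density between the modes falling below 10% of the lower
#' peak, i.e. two essentially separated clusters). Used as a screen before
#' change-point fitting: threshold regressions are appropriate when the
#' variables are unimodal.
#'
#' @param values numeric vector, length >= 20.
#' @return A list of class `"modality_report"`: `n_components` (BIC-selected
#'   mixture size), `n_modes` (local maxima of the selected density),
#'   `dip_depth` (relative depth of the valley between modes, 0 when
#'   unimodal), `unimodal`, `bic`, `degenerate` (no-variance input).
#' @examples
#' check_unimodality(rnorm(100))$unimodal
#' @export
check_unimodality <- function(values) {
  if (length(values) < 20L) stop("need at least 20 values", call. = FALSE)
  degenerate <- structure(list(n_components = NA_integer_,
                               n_modes = NA_integer_, dip_depth = NA_real_,
                               unimodal = NA, bic = NULL, degenerate = TRUE),
                          class = "modality_report")
  if (stats::sd(values) == 0 || !is.finite(stats::sd(values)))
    return(degenerate)
  fit <- mclust::Mclust(values, G = 1:2, modelNames = c("E", "V"),
                        verbose = FALSE)
  if (is.null(fit)) return(degenerate)
  shape <- if (fit$G == 1L) list(n_modes = 1L, dip = 0)
           else mixture_shape(fit)
  structure(list(n_components = fit$G, n_modes = shape$n_modes,
                 dip_depth = shape$dip,
                 unimodal = shape$n_modes == 1L || shape$dip <= 0.9,
                 bic = fit$BIC, degenerate = FALSE),
            class = "modality_report")
}

# mode count and relative valley depth of a univariate Gaussian mixture
mixture_shape <- function(fit) {
  p <- fit$parameters
  mu <- p$mean
  sd <- sqrt(if (length(p$variance$sigmasq) == 1L)
    rep(p$variance$sigmasq, length(mu)) else p$variance$sigmasq)
  grid <- seq(min(mu) - 3 * max(sd), max(mu) + 3 * max(sd),
              length.out = 1024)
  dens <- colSums(p$pro * vapply(grid, function(g)
    stats::dnorm(g, mu, sd), numeric(length(mu))))
  interior <- 2:(length(dens) - 1L)
  peaks <- which(dens[interior] > dens[interior - 1L] &
                   dens[interior] >= dens[interior + 1L]) + 1L
  if (length(peaks) < 2L) return(list(n_modes = max(1L, length(peaks)), dip = 0))
  valley <- min(dens[seq(min(peaks), max(peaks))])
  list(n_modes = length(peaks), dip = 1 - valley / min(dens[peaks]))
}

#' @export
print.modality_report <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("Modality check: degenerate input\n")
  else cat("Modality check:", x$n_components, "component(s),", x$n_modes,
           "mode(s) ->", if (x$unimodal) "unimodal" else "bimodal", "\n")
  invisible(x)
}

#' Bootstrap validation of a change point
#'
#' Bootstraps linear regressions independently on each side of a candidate
#' change point `c` (resampling observations with replacement within each
#' side), collects the per-resample OLS slope and the predicted value at
#' `x = c`, and compares the two sides with two-sided Mann-Whitney U-tests
#' on the slope and predicted-value distributions. The threshold is
#' `validated` when both tests reject at the 5% level.
#'
#' The Mann-Whitney tests treat the bootstrap draws as samples and are
#' descriptive: the draws are not independent observations, so the P-values
#' characterize the separation of the bootstrap distributions rather than a
#' calibrated error rate.
#'
#' @param x,y numeric vectors.
#' @param c change-point location; sides are `x < c` and `x >= c`.
#' @param B bootstrap resamples per side.
#' @param seed integer seed.
#' @param min_side minimum points required per side.
#' @return A list of class `"validation_report"`: `B`, `slope_before`,
#'   `slope_after`, `pred_at_c_before`, `pred_at_c_after`,
#'   `mann_whitney_P_slope`, `mann_whitney_P_pred`, `validated`.
#' @export
validate_threshold <- function(x, y, c, B = 500, seed = 1L, min_side = 5) {
  left <- x < c
  if (sum(left) < min_side || sum(!left) < min_side)
    stop("fewer than ", min_side, " points on one side of c = ", c,
         call. = FALSE)
  set.seed(seed)
  before <- side_bootstrap(x[left], y[left], c, B)
  after <- side_bootstrap(x[!left], y[!left], c, B)
  p_slope <- stats::wilcox.test(before$slope, after$slope, exact = FALSE)$p.value
  p_pred <- stats::wilcox.test(before$pred, after$pred, exact = FALSE)$p.value
  structure(list(B = B,
                 slope_before = before$slope, slope_after = after$slope,
                 pred_at_c_before = before$pred, pred_at_c_after = after$pred,
                 mann_whitney_P_slope = p_slope, mann_whitney_P_pred = p_pred,
                 validated = p_slope < 0.05 && p_pred < 0.05),
            class = "validation_report")
}

# B bootstrap OLS fits on one side; degenerate resamples (no x spread) are
# redrawn
side_bootstrap <- function(xs, ys, c, B) {
  n <- length(xs)
  slope <- pred <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      vx <- stats::var(xs[idx])
      if (vx > 0) break
    }
    if (vx == 0) { slope[b] <- NA; pred[b] <- NA; next }
    sl <- stats::cov(xs[idx], ys[idx]) / vx
    ic <- mean(ys[idx]) - sl * mean(xs[idx])
    slope[b] <- sl
    pred[b] <- ic + sl * c
  }
  list(slope = slope, pred = pred)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Change-point validation (B = %d): slope P = %.3g, predicted-value P = %.3g -> %s\n",
              x$B, x$mann_whitney_P_slope, x$mann_whitney_P_pred,
              if (x$validated) "validated" else "not validated"))
  invisible(x)
}

#' Full aridity-threshold detection protocol
#'
#' Runs the complete change-point detection pipeline for a response `y`
#' along a gradient `x`:
#'
#' 1. fit linear, quadratic and GAM trends and select by AIC; the protocol
#'    proceeds only if a nonlinear family beats the linear fit by more than
#'    `delta` AIC units;
#' 2. check unimodality of `x` (and report `y`'s modality as well); when
#'    `require_unimodal` and `x` is bimodal the protocol stops (threshold
#'    regressions assume a unimodal predictor);
#' 3. fit the three change-point forms (step, segmented, stegmented), select
#'    among them by AIC with ties resolved to the simpler form, and require
#'    the winner to beat the linear fit by more than `delta`;
#' 4. validate the selected change point with [validate_threshold()].
#'
#' `threshold_kind` is `"continuous"` for a validated segmented winner,
#' `"discontinuous"` for a validated step/stegmented winner, and `"none"`
#' when the protocol stops at any gate. The fitted change-point location `c`
#' is reported whenever step 3 ran, regardless of the validation verdict.
#'
#' @param x,y numeric vectors.
#' @param B bootstrap resamples for validation.
#' @param seed integer seed.
#' @param min_side minimum points per side for the change-point grid and
#'   validation.
#' @param delta AIC-difference rule.
#' @param require_unimodal stop when `x` is bimodal.
#' @return A list of class `"threshold_decision"`: `threshold_kind`,
#'   `nonlinear_preferred`, `trend_selection`, `modality_x`, `modality_y`,
#'   `best_form`, `c`, `changepoint_fit`, `changepoint_selection`,
#'   `validation`, `reason` (why the protocol stopped, if it did).
#' @examples
#' x <- sort(runif(60)); y <- ifelse(x > 0.5, 1, 0) + rnorm(60, 0, 0.05)
#' detect_threshold(x, y, B = 100, seed = 1)$threshold_kind
#' @export
detect_threshold <- function(x, y, B = 200, seed = 1L, min_side = 5,
                             delta = 2, require_unimodal = TRUE) {
  trends <- list(linear = fit_trend(x, y, "linear"),
                 quadratic = fit_trend(x, y, "quadratic"))
  gamfit <- tryCatch(fit_trend(x, y, "gam"), error = function(e) NULL)
  if (!is.null(gamfit)) trends$gam <- gamfit
  trend_sel <- compare_aic(trends, reference = "linear", delta = delta)
  nonlinear <- trend_sel$preferred

  out <- list(nonlinear_preferred = nonlinear, trend_selection = trend_sel,
              modality_x = NULL, modality_y = NULL, best_form = NA_character_,
              c = NA_real_, changepoint_fit = NULL,
              changepoint_selection = NULL, validation = NULL,
              threshold_kind = "none", reason = NA_character_)
  class(out) <- "threshold_decision"
  if (!nonlinear) {
    out$reason <- "linear trend not rejected (delta AIC <= 2)"
    return(out)
  }

  out$modality_x <- check_unimodality(x)
  out$modality_y <- tryCatch(check_unimodality(y), error = function(e) NULL)

  forms <- c("step", "segmented", "stegmented")
  cps <- lapply(forms, function(f) fit_changepoint(x, y, f, min_side))
  names(cps) <- forms
  cp_sel <- compare_aic(c(cps, list(linear = trends$linear)),
                        reference = "linear", delta = delta)
  out$changepoint_selection <- cp_sel
  if (cp_sel$selection != "linear") {
    best <- cps[[cp_sel$selection]]
    out$best_form <- best$form
    out$c <- best$c
    out$changepoint_fit <- best
  }
  if (require_unimodal && isFALSE(out$modality_x$unimodal)) {
    out$reason <- "gradient variable is bimodal"
    return(out)
  }
  if (cp_sel$selection == "linear" || !cp_sel$preferred) {
    out$reason <- "no change-point form beats the linear fit by delta AIC > 2"
    return(out)
  }
  best <- cps[[cp_sel$selection]]

  out$validation <- tryCatch(
    validate_threshold(x, y, best$c, B = B, seed = seed, min_side = min_side),
    error = function(e) NULL)
  if (is.null(out$validation) || !out$validation$validated) {
    out$reason <- "bootstrap side-regression validation failed"
    return(out)
  }
  out$threshold_kind <- if (best$form == "segmented") "continuous"
                        else "discontinuous"
  out
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat("Threshold decision:", x$threshold_kind, "\n")
  if (!is.na(x$c))
    cat(sprintf("  best form %s at c = %.4f\n", x$best_form, x$c))
  if (!is.na(x$reason)) cat("  stopped:", x$reason, "\n")
  invisible(x)
}
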