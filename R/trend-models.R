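#' Fit a trend model for a response along the aridity gradient
#'
#' Least-squares fit of one of three trend families used to screen for
#' nonlinearity before change-point fitting: `linear`, `quadratic`, or `gam`
#' (a penalized cubic regression spline whose smoothing parameter is chosen
#' by REML — the selector recommended for mgcv smoothers, since GCV tends to
#' undersmooth and so to exaggerate the nonlinearity of plain linear data;
#' the total effective degrees of freedom enter the parameter count).
#'
#' AIC is computed from the Gaussian log-likelihood on a common scale across
#' all families (and across [fit_changepoint()] fits), so fits on the same
#' data are directly comparable with [compare_aic()].
#'
#' @param x,y numeric vectors (length >= 10, finite).
#' @param family one of `"linear"`, `"quadratic"`, `"gam"`.
#' @param gam_method smoothing-parameter selection criterion passed to
#'   [mgcv::gam()] (`"REML"`; `"GCV.Cp"` for generalized cross-validation).
#' @return A list of class `"trend_fit"`: `family`, `model`, `fitted`,
#'   `sse`, `n_params` (mean-structure parameters; effective df for GAM),
#'   `aic`, `n`.
#' @examples
#' x <- seq(0, 1, length.out = 50)
#' fit_trend(x, x^2, "quadratic")$aic
#' @export
fit_trend <- function(x, y, family = c("linear", "quadratic", "gam"),
                      gam_method = "REML") {
  family <- match.arg(family)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 10L) stop("need at least 10 points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  n <- length(y)
  if (family == "linear") {
    model <- stats::lm(y ~ x)
    k <- 2
  } else if (family == "quadratic") {
    model <- stats::lm(y ~ x + I(x^2))
    k <- 3
  } else {
    kbasis <- max(4L, min(10L, length(unique(x)) - 1L))
    model <- mgcv::gam(y ~ s(x, k = kbasis), method = gam_method)
    k <- sum(model$edf)  # total effective df (intercept included)
  }
  fitted <- as.numeric(stats::fitted(model))
  sse <- sum((y - fitted)^2)
  structure(list(family = family, model = model, fitted = fitted, sse = sse,
                 n_params = k, aic = gaussian_aic(sse, n, k), n = n),
            class = "trend_fit")
}

# AIC from the Gaussian log-likelihood with sigma^2 = SSE/n profiled out;
# k counts mean-structure parameters, +1 for sigma.
gaussian_aic <- function(sse, n, k) {
  n * log(2 * pi * sse / n) + n + 2 * (k + 1)
}

#' Select among fits by AIC with a parsimony rule
#'
#' Returns the best of several fits on the same data. A model counts as
#' "preferred" over the reference only when its AIC is more than `delta`
#' units lower; fits whose AIC lies within `delta` of the minimum are treated
#' as ties and resolved toward the simplest model (fewest parameters).
#'
#' @param fits named list of `"trend_fit"`/`"threshold_fit"` objects on the
#'   same data.
#' @param reference name of the reference fit (e.g. `"linear"`); defaults to
#'   the simplest fit in the list.
#' @param delta the AIC-difference rule (default 2).
#' @return A list of class `"aic_selection"`: `selection` (name), `fit`,
#'   `preferred` (selected fit beats the reference by more than `delta`),
#'   `table` (name, aic, n_params, delta_aic).
#' @export
compare_aic <- function(fits, reference = NULL, delta = 2) {
  if (length(fits) < 2L) stop("need at least 2 fits", call. = FALSE)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$family %||% f$form, "")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("fits were made on differing numbers of observations", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, `[[`, numeric(1), "n_params")
  if (is.null(reference)) reference <- names(fits)[which.min(npar)]
  if (!reference %in% names(fits)) stop("unknown reference fit", call. = FALSE)
  tied <- which(aic <= min(aic) + delta)
  sel <- tied[order(npar[tied], aic[tied])][1]
  preferred <- names(fits)[sel] != reference &&
    aic[sel] < aic[[reference]] - delta
  structure(list(selection = names(fits)[sel], fit = fits[[sel]],
                 preferred = preferred, reference = reference,
                 table = data.frame(model = names(fits), aic = aic,
                                    n_params = npar,
                                    delta_aic = aic - min(aic),
                                    row.names = NULL)),
            class = "aic_selection")
}

#' Fit a change-point (threshold) regression by exhaustive grid search
#'
#' Fits one of three change-point forms at every candidate change point and
#' returns the global SSE minimizer:
#' * `step`: `y = b0 + b1 * 1[x > c]` (intercept shift only);
#' * `segmented`: `y = b0 + b1 x + b2 (x - c) 1[x > c]` (slope change,
#'   continuous at `c`);
#' * `stegmented`: `y = b0 + b1 x + b2 (x - c) 1[x > c] + b3 * 1[x > c]`
#'   (both intercept and slope change).
#'
#' Candidate change points are the midpoints between consecutive distinct
#' sorted `x` values with at least `min_side` observations on each side,
#' which avoids ties in side assignment. At each candidate the coefficients
#' are ordinary least squares. The AIC parameter count includes the change
#' point itself as one parameter.
#'
#' @param x,y numeric vectors.
#' @param form change-point model form.
#' @param min_side minimum observations required on each side of a candidate.
#' @return A list of class `"threshold_fit"`: `form`, `c`, `coefficients`,
#'   `sse`, `aic`, `n_params`, `fitted`, `search_grid`, `sse_curve`
#'   (candidate c vs SSE), `n`.
#' @examples
#' x <- 1:10; y <- rep(0:1, each = 5)
#' fit_changepoint(x, y, "step")$c  # 5.5
#' @export
fit_changepoint <- function(x, y, form = c("step", "segmented", "stegmented"),
                            min_side = 5) {
  form <- match.arg(form)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 2 * min_side)
    stop("need at least 2 * min_side = ", 2 * min_side, " points", call. = FALSE)
  xs <- sort(unique(x))
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  n_left <- vapply(mids, function(m) sum(x < m), integer(1))
  grid <- mids[n_left >= min_side & (n - n_left) >= min_side]
  if (length(grid) == 0L)
    stop("window too small: no candidate change point leaves ", min_side,
         " points per side", call. = FALSE)

  best <- NULL
  sse_curve <- numeric(length(grid))
  for (i in seq_along(grid)) {
    X <- changepoint_design(x, grid[i], form)
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    sse_curve[i] <- sse
    if (is.null(best) || sse < best$sse)
      best <- list(c = grid[i], coef = fit$coefficients, sse = sse,
                   fitted = y - fit$residuals)
  }
  k <- length(best$coef) + 1  # regression coefficients + the change point
  structure(list(form = form, c = best$c, coefficients = best$coef,
                 sse = best$sse, aic = gaussian_aic(best$sse, n, k),
                 n_params = k, fitted = as.numeric(best$fitted),
                 search_grid = grid,
                 sse_curve = data.frame(c = grid, sse = sse_curve),
                 n = n),
            class = "threshold_fit")
}

changepoint_design <- function(x, c, form) {
  up <- as.numeric(x > c)
  switch(form,
         step = cbind(b0 = 1, b1 = up),
         segmented = cbind(b0 = 1, b1 = x, b2 = pmax(x - c, 0)),
         stegmented = cbind(b0 = 1, b1 = x, b2 = pmax(x - c, 0), b3 = up))
}

#' Predict from a fitted change-point model
#'
#' @param object a `"threshold_fit"`.
#' @param newdata numeric vector of x values.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.threshold_fit <- function(object, newdata, ...) {
  X <- changepoint_design(newdata, object$c, object$form)
  as.numeric(X %*% object$coefficients)
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("%s change-point fit: c = %.4f, SSE = %.4g, AIC = %.2f (%d candidates)\n",
              x$form, x$c, x$sse, x$aic, length(x$search_grid)))
  invisible(x)
}
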