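test_that("trend fits are exact on polynomial data and AIC matches the closed form", {
  x <- seq(0, 1, length.out = 40)
  lin <- fit_trend(x, 2 + 3 * x, "linear")
  expect_lt(lin$sse, 1e-20)

  quad <- fit_trend(x, x^2, "quadratic")
  expect_equal(unname(stats::coef(quad$model)), c(0, 0, 1), tolerance = 1e-8)

  set.seed(1)
  y <- 1 + 2 * x + stats::rnorm(40, 0, 0.3)
  f <- fit_trend(x, y, "linear")
  n <- 40
  # independent oracle: profiled Gaussian log-likelihood
  ll <- sum(stats::dnorm(y, stats::fitted(f$model), sqrt(f$sse / n),
                         log = TRUE))
  expect_equal(f$aic, -2 * ll + 2 * 3, tolerance = 1e-8)
  expect_equal(f$aic, stats::AIC(f$model), tolerance = 1e-8)
  expect_error(fit_trend(x[1:5], y[1:5], "linear"), "10 points")
})

test_that("AIC comparison applies the delta rule with parsimony ties", {
  mk <- function(aic, k) structure(list(aic = aic, n_params = k, n = 50),
                                   class = "trend_fit")
  sel <- compare_aic(list(linear = mk(100, 2), gam = mk(97, 5)),
                     reference = "linear")
  expect_equal(sel$selection, "gam")
  expect_true(sel$preferred)

  sel2 <- compare_aic(list(linear = mk(100, 2), gam = mk(99, 5)),
                      reference = "linear")
  expect_equal(sel2$selection, "linear")
  expect_false(sel2$preferred)

  sel3 <- compare_aic(list(a = mk(120, 2), b = mk(80, 3), c = mk(110, 4)),
                      reference = "a")
  expect_equal(sel3$selection, "b")

  bad <- list(a = mk(1, 2), b = structure(list(aic = 2, n_params = 2, n = 10),
                                          class = "trend_fit"))
  expect_error(compare_aic(bad), "differing")
})

test_that("a perfect step is recovered exactly", {
  x <- 1:10
  y <- rep(c(0, 1), each = 5)
  fit <- fit_changepoint(x, y, "step", min_side = 5)
  expect_gt(fit$c, 5); expect_lt(fit$c, 6)
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-12)
  expect_lt(fit$sse, 1e-20)
})

test_that("grid search equals an exhaustive re-scan and respects min_side", {
  set.seed(7)
  x <- stats::runif(35)
  y <- x + ifelse(x > 0.6, 1.5 * (x - 0.6), 0) + stats::rnorm(35, 0, 0.1)
  for (form in c("step", "segmented", "stegmented")) {
    fit <- fit_changepoint(x, y, form, min_side = 5)
    # independent oracle: lm() at every candidate midpoint
    xs <- sort(unique(x))
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    mids <- mids[vapply(mids, function(m)
      sum(x < m) >= 5 && sum(x > m) >= 5, logical(1))]
    sses <- vapply(mids, function(cc) {
      up <- as.numeric(x > cc)
      f <- switch(form,
                  step = stats::lm(y ~ up),
                  segmented = stats::lm(y ~ x + I(pmax(x - cc, 0))),
                  stegmented = stats::lm(y ~ x + I(pmax(x - cc, 0)) + up))
      sum(stats::residuals(f)^2)
    }, numeric(1))
    expect_equal(fit$search_grid, mids)
    expect_equal(fit$sse, min(sses), tolerance = 1e-12)
    expect_true(all(fit$sse <= fit$sse_curve$sse + 1e-12))
  }
  expect_error(fit_changepoint(1:8, rnorm(8), "step", min_side = 5),
               "min_side")
})

test_that("a noise-free slope change is localized within one grid gap", {
  x <- seq(0.4, 1, length.out = 100)
  y <- 2 - 0.5 * x - 2 * pmax(x - 0.8, 0)
  fit <- fit_changepoint(x, y, "segmented")
  gap <- max(diff(sort(unique(x))))
  expect_lt(abs(fit$c - 0.8), gap + 1e-12)
  expect_lt(fit$sse, 1e-3)
})

test_that("segmented predictions are continuous at c; step and stegmented jump", {
  set.seed(8)
  x <- stats::runif(60)
  y <- x + ifelse(x > 0.5, 0.8, 0) + stats::rnorm(60, 0, 0.05)
  eps <- 1e-9
  seg <- fit_changepoint(x, y, "segmented")
  expect_lt(abs(diff(predict(seg, seg$c + c(-eps, eps)))), 1e-8)
  stp <- fit_changepoint(x, y, "step")
  expect_equal(diff(predict(stp, stp$c + c(-eps, eps))),
               unname(stp$coefficients["b1"]), tolerance = 1e-6)
  stg <- fit_changepoint(x, y, "stegmented")
  expect_equal(diff(predict(stg, stg$c + c(-eps, eps))),
               unname(stg$coefficients["b3"]), tolerance = 1e-6)
})

test_that("AIC ordering is invariant to shifting the response", {
  set.seed(9)
  x <- stats::runif(50)
  y <- sin(3 * x) + stats::rnorm(50, 0, 0.2)
  fits1 <- lapply(c("linear", "quadratic", "gam"), fit_trend, x = x, y = y)
  fits2 <- lapply(c("linear", "quadratic", "gam"), fit_trend, x = x,
                  y = y + 100)
  expect_equal(order(vapply(fits1, `[[`, numeric(1), "aic")),
               order(vapply(fits2, `[[`, numeric(1), "aic")))
})

test_that("mixture modality check separates one hump from two", {
  set.seed(10)
  uni <- vapply(1:25, function(i) check_unimodality(stats::rnorm(500))$unimodal,
                logical(1))
  expect_gte(mean(uni), 0.9)
  bi <- vapply(1:25, function(i)
    check_unimodality(c(stats::rnorm(250), stats::rnorm(250, 8)))$unimodal,
    logical(1))
  expect_lte(mean(bi), 0.1)
  expect_true(check_unimodality(rep(1, 30))$degenerate)
  expect_error(check_unimodality(stats::rnorm(10)), "20 values")
})

test_that("bootstrap validation rejects a real jump and spares a smooth line", {
  set.seed(11)
  x <- sort(stats::runif(80))
  ystep <- ifelse(x > 0.5, 1, 0) + stats::rnorm(80, 0, 0.01)
  v <- validate_threshold(x, ystep, 0.5, B = 500, seed = 2)
  expect_length(v$slope_before, 500)
  expect_length(v$pred_at_c_after, 500)
  expect_lt(v$mann_whitney_P_pred, 1e-6)
  expect_true(v$validated)

  # identical line on both sides: the side distributions overlap heavily.
  # The Mann-Whitney P on bootstrap draws is descriptive (the draws are not
  # independent observations) and anti-conservative under the null, so the
  # check is on the distributions themselves, not the rejection rate.
  overlaps <- vapply(1:20, function(i) {
    xx <- sort(stats::runif(60))
    yy <- 1 + 2 * xx + stats::rnorm(60, 0, 0.3)
    vn <- validate_threshold(xx, yy, 0.5, B = 100, seed = i)
    gap <- abs(stats::median(vn$slope_before) - stats::median(vn$slope_after))
    spread <- stats::IQR(c(vn$slope_before, vn$slope_after))
    gap < 3 * spread
  }, logical(1))
  expect_gte(mean(overlaps), 0.9)
  expect_error(validate_threshold(x, ystep, 0.02, B = 10, seed = 1), "side")
})

test_that("the detection protocol short-circuits on linear data and maps forms", {
  set.seed(12)
  x <- sort(stats::runif(80, 0.4, 1))
  dec_lin <- detect_threshold(x, 1 - x + stats::rnorm(80, 0, 0.1), B = 100,
                              seed = 1)
  expect_equal(dec_lin$threshold_kind, "none")
  expect_false(dec_lin$nonlinear_preferred)

  ystep <- ifelse(x > 0.7, 0, 1) + stats::rnorm(80, 0, 0.05)
  dec_step <- detect_threshold(x, ystep, B = 200, seed = 1)
  expect_equal(dec_step$threshold_kind, "discontinuous")
  expect_lt(abs(dec_step$c - 0.7), 0.05)
  # the reported change point lies inside the searched grid
  expect_true(dec_step$c >= min(dec_step$changepoint_fit$search_grid) &
                dec_step$c <= max(dec_step$changepoint_fit$search_grid))
})
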