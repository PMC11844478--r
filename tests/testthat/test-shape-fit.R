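test_that("default knots sit at thirds of the representative range", {
  expect_equal(default_knots(c(0, 1, 2, 3)), c(1, 2))
  expect_equal(default_knots(c(15, 20, 30, 45)), c(25, 35))
  expect_error(default_knots(c(1, 2, 2, 1)),
               class = "rgshape_insufficient_support")
})

test_that("spline design rows are segment-placed cubic differences", {
  D <- spline_design(tibble::tibble(x_case = 1, x_control = 2),
                     knots = c(1.5, 2.5))
  # f2(2) - f1(1) = 8 b5 + 4 b6 + 2 b7 + b8 - (b1 + b2 + b3 + b4)
  expect_equal(unname(D[1, ]), c(-1, -1, -1, -1, 8, 4, 2, 1, 0, 0, 0, 0))

  # both endpoints in one segment: intercept entries cancel
  D1 <- spline_design(tibble::tibble(x_case = 0.5, x_control = 1),
                      knots = c(1.5, 2.5))
  expect_equal(unname(D1[1, 4]), 0)
  expect_true(all(D1[1, 5:12] == 0))

  # straddling segments 1 and 3 touches b1..b4 and b9..b12 only
  D3 <- spline_design(tibble::tibble(x_case = 1, x_control = 3),
                      knots = c(1.5, 2.5))
  expect_true(all(D3[1, 5:8] == 0))
  expect_true(any(D3[1, 1:4] != 0) && any(D3[1, 9:12] != 0))
})

test_that("noiseless cubic data are recovered exactly up to a constant", {
  g <- function(x) x^3 - 2 * x
  x_reps <- seq(-2, 2, length.out = 9)
  d <- exact_distances(g, x_reps)
  fit <- fit_shape(d)
  expect_equal(fit$kind, "spline")
  expect_lt(fit$objective, 1e-12 * max(1, sum(d$dy^2)))
  # evaluations match g up to one additive constant
  xs <- seq(-2, 2, length.out = 101)
  resid <- evaluate_curve(fit, xs) - g(xs)
  expect_lt(diff(range(resid)), 1e-6)

  # derivative and value matching at the knots, directly from coefficients
  b <- fit$coefficients
  for (ki in 1:2) {
    t <- fit$knots[ki]
    lo <- (ki - 1) * 4
    val <- function(o) b[o + 1] * t^3 + b[o + 2] * t^2 + b[o + 3] * t + b[o + 4]
    d1 <- function(o) 3 * b[o + 1] * t^2 + 2 * b[o + 2] * t + b[o + 3]
    d2 <- function(o) 6 * b[o + 1] * t + 2 * b[o + 2]
    expect_lt(abs(val(lo) - val(lo + 4)), 1e-8)
    expect_lt(abs(d1(lo) - d1(lo + 4)), 1e-8)
    expect_lt(abs(d2(lo) - d2(lo + 4)), 1e-8)
  }
  # continuity when evaluating just left/right of a knot
  eps <- 1e-9
  expect_equal(evaluate_curve(fit, fit$knots[1] - eps),
               evaluate_curve(fit, fit$knots[1] + eps), tolerance = 1e-8)
})

test_that("linear data yield a curve with negligible second derivative", {
  d <- exact_distances(function(x) 2 * x, seq(0, 3, length.out = 8))
  fit <- fit_shape(d)
  f2 <- rgshape:::curve_second_derivative(
    fit, seq(0.1, 2.9, length.out = 50), h = 1e-3)
  expect_lt(max(abs(f2)), 1e-6)
})

test_that("zero distances give the constant anchored curve", {
  d <- exact_distances(function(x) 0, seq(0, 3, length.out = 6))
  for (m in c("spline", "polynomial")) {
    fit <- fit_shape(d, method = m)
    expect_equal(evaluate_curve(fit, c(0, 1.5, 3)), rep(0, 3))
  }
})

test_that("curves are invariant to constant shifts of the generating function", {
  g <- function(x) 0.3 * x^2 - x
  x_reps <- seq(-1, 3, length.out = 7)
  f1 <- fit_shape(exact_distances(g, x_reps))
  f2 <- fit_shape(exact_distances(function(x) g(x) + 57, x_reps))
  xs <- seq(-1, 3, length.out = 40)
  expect_equal(evaluate_curve(f1, xs), evaluate_curve(f2, xs),
               tolerance = 1e-8)
})

test_that("polynomial estimator recovers representable curves", {
  x_reps <- seq(-2, 2, length.out = 9)
  d <- exact_distances(function(x) x^2, x_reps)
  fit <- fit_shape(d, method = "polynomial")
  expect_equal(fit$kind, "polynomial")
  # coefficients are on the centred basis; centre is 0 here
  expect_equal(unname(fit$coefficients["c2"]), 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[c("c3", "c4", "c5")])), 1e-6)

  d5 <- exact_distances(function(x) x^5 - x^3, x_reps)
  fit5 <- fit_shape(d5, method = "polynomial")
  expect_lt(fit5$objective, 1e-12 * sum(d5$dy^2))
})

test_that("data confined to the middle segment fall back to the polynomial", {
  g <- function(x) x^3 - 2 * x
  x_reps <- seq(1.2, 1.8, length.out = 6)  # entirely inside the knots below
  d <- exact_distances(g, x_reps)
  expect_warning(fit <- fit_shape(d, knots = c(1, 2)), "polynomial")
  expect_equal(fit$kind, "polynomial")
  expect_lt(fit$objective, 1e-12 * max(1, sum(d$dy^2)))
})

test_that("constrained solution matches independent curve-space oracles", {
  # noisy distances so the objective is genuinely positive
  g <- function(x) 0.4 * x^2
  x_reps <- seq(-2, 2, length.out = 8)
  d <- exact_distances(g, x_reps)
  set.seed(9)
  d$dy <- d$dy + rnorm(nrow(d), 0, 0.2)
  knots <- default_knots(x_reps)
  fit <- fit_shape(d, knots = knots)

  # oracle 1: unconstrained least squares on the truncated-power basis
  # (identical function space, different parameterisation and solver)
  tp <- truncated_power_fit(d, knots)
  expect_equal(fit$objective, tp$objective, tolerance = 1e-8)
  xs <- seq(-2, 2, length.out = 30)
  y1 <- evaluate_curve(fit, xs)
  y2 <- tp$predict(xs)
  expect_equal(y1 - mean(y1), y2 - mean(y2), tolerance = 1e-6)

  # oracle 2: brute-force numerical minimisation over the same function
  # space with random restarts
  obj <- function(theta) {
    f <- function(x) {
      cbind(x, x^2, x^3, pmax(x - knots[1], 0)^3,
            pmax(x - knots[2], 0)^3) %*% theta
    }
    sum(((-d$dy) - (f(d$x_control) - f(d$x_case)))^2)
  }
  best <- Inf
  set.seed(11)
  for (r in 1:5) {
    o <- optim(rnorm(5), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$objective, best, tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  d <- exact_distances(function(x) x, seq(0, 3, length.out = 4))
  expect_error(fit_shape(d[1:3, ]), class = "rgshape_underdetermined")
  d$included <- FALSE
  expect_error(fit_shape(d), class = "rgshape_empty_fit")
  d2 <- exact_distances(function(x) x, seq(0, 3, length.out = 8))
  expect_error(fit_shape(d2, knots = c(2, 1)), class = "rgshape_domain")
  fit <- fit_shape(d2)
  expect_error(evaluate_curve(fit, 3.5), class = "rgshape_domain")
})

test_that("excluded records are dropped from the fit, never imputed", {
  g <- function(x) 0.5 * x^2
  d <- exact_distances(g, seq(-2, 2, length.out = 8))
  d$included <- TRUE
  d$exclusion_reason <- NA_character_
  # poison two records; with included = FALSE they must not influence the fit
  d_poison <- d
  d_poison$dy[c(3, 10)] <- 99
  d_poison$included[c(3, 10)] <- FALSE
  d_poison$exclusion_reason[c(3, 10)] <- "out_of_bounds"
  f_clean <- fit_shape(d[-c(3, 10), ])
  f_poison <- fit_shape(d_poison)
  xs <- seq(-2, 2, length.out = 20)
  expect_equal(evaluate_curve(f_clean, xs), evaluate_curve(f_poison, xs),
               tolerance = 1e-10)
  expect_equal(unname(f_poison$exclusions["out_of_bounds"]), 2L)
  expect_equal(glance(f_poison)$n_pairs_used, nrow(d) - 2)
})

test_that("dy orientation flag flips the fitted curve", {
  g <- function(x) x^2
  cts <- grid_contrasts(seq(-2, 2, length.out = 8))
  d_cc <- tibble::tibble(cts, dy = g(cts$x_case) - g(cts$x_control))
  d_rev <- tibble::tibble(cts, dy = g(cts$x_control) - g(cts$x_case))
  xs <- seq(-2, 2, length.out = 20)
  f1 <- fit_shape(d_cc, dy_sign = "case_minus_control")
  f2 <- fit_shape(d_rev, dy_sign = "control_minus_case")
  expect_equal(evaluate_curve(f1, xs), evaluate_curve(f2, xs),
               tolerance = 1e-10)
})

test_that("tidy, glance, predict and autoplot work on fits", {
  d <- exact_distances(function(x) x^2, seq(-2, 2, length.out = 8))
  fit <- fit_shape(d)
  td <- tidy(fit)
  expect_equal(td$term, paste0("b", 1:12))
  gl <- glance(fit)
  expect_equal(gl$kind, "spline")
  expect_gte(gl$objective, 0)
  expect_equal(predict(fit, c(0, 1)), evaluate_curve(fit, c(0, 1)))
  expect_s3_class(autoplot(fit), "ggplot")
  # mean-zero anchor over representative values
  expect_equal(mean(evaluate_curve(fit, fit$x_reps)), 0, tolerance = 1e-10)
})
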