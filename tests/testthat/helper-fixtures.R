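# shared fixtures: all built in code, nothing read from disk

# contrasts over equally spaced representative values
grid_contrasts <- function(x_reps) {
  enumerate_contrasts(tibble::tibble(bin = seq_along(x_reps), x_rep = x_reps))
}

# exact distance table from a generating function g, oriented as the
# pipeline reports it: dy = f(x_case) - f(x_control)
exact_distances <- function(g, x_reps) {
  cts <- grid_contrasts(x_reps)
  tibble::tibble(cts, dy = g(cts$x_case) - g(cts$x_control))
}

# small synthetic rg table with a known U-shaped generating curve; rg values
# are exact pairwise differences mapped back through the inverse transform
# so that transform_rg() reproduces dy = g(x_case) - g(x_control)
synthetic_rg_table <- function(g = function(x) 0.05 * x^2,
                               x_reps = seq(-2, 2, length.out = 8),
                               se = 0.02) {
  cts <- grid_contrasts(x_reps)
  dy <- g(cts$x_case) - g(cts$x_control)
  # invert dy = dx * c / sqrt(1 - c^2) with c = rg / dx
  cc <- dy / sqrt(dy^2 + cts$dx^2)
  tibble::tibble(
    cts[, c("case_bin", "control_bin", "x_case", "x_control")],
    rg = cc * cts$dx, se = se
  )
}

# independent oracle for the two-step transform
closed_form_dy <- function(cor, dx) {
  cc <- cor / dx
  dx * cc / sqrt(1 - cc^2)
}

# independent curve-space oracle: least squares on the truncated-power cubic
# spline basis (same function space as the three constrained local cubics)
truncated_power_fit <- function(distances, knots,
                                dy_sign = "case_minus_control") {
  basis <- function(x) {
    cbind(x, x^2, x^3,
          pmax(x - knots[1], 0)^3, pmax(x - knots[2], 0)^3)
  }
  delta <- if (dy_sign == "case_minus_control") -distances$dy else distances$dy
  D <- basis(distances$x_control) - basis(distances$x_case)
  fit <- lm.fit(D, delta)
  list(coef = fit$coefficients,
       objective = sum(fit$residuals^2),
       predict = function(x) as.vector(basis(x) %*% fit$coefficients))
}

# a small cohort reused across simulation unit tests
small_scenario <- function(...) {
  sim_scenario(n = 1500, m = 400, bins = 5, seed = 42, ...)
}
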