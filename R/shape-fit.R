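#' Default interior knot placement
#'
#' The curve estimator uses three local cubic polynomials joined smoothly at
#' two interior knots. Knot positions are not dictated by the estimator;
#' by default they are placed at the 1/3 and 2/3 points of the range of the
#' bin representative values, giving three segments of equal x-width.
#'
#' @param x_reps Numeric vector of bin representative values (at least four
#'   distinct values).
#' @return Numeric vector `c(i, j)` with `i < j`, both strictly interior.
#' @examples
#' default_knots(c(0, 1, 2, 3))  # c(1, 2)
#' @export
default_knots <- function(x_reps) {
  x <- sort(unique(as.numeric(x_reps)))
  if (length(x) < 4) {
    abort_rgshape("need at least four distinct representative values to place knots",
                  "rgshape_insufficient_support")
  }
  lo <- min(x); hi <- max(x)
  c(lo + (hi - lo) / 3, lo + 2 * (hi - lo) / 3)
}

# segment of each x given knots (i, j): 1 for x < i, 2 for i <= x < j,
# 3 for x >= j
segment_of <- function(x, knots) {
  1L + (x >= knots[1]) + (x >= knots[2])
}

# 12-column local-cubic basis: columns 1:4 are (x^3, x^2, x, 1) active in
# segment 1, columns 5:8 in segment 2, columns 9:12 in segment 3
spline_basis <- function(x, knots) {
  seg <- segment_of(x, knots)
  B <- matrix(0, length(x), 12)
  off <- (seg - 1L) * 4L
  B[cbind(seq_along(x), off + 1L)] <- x^3
  B[cbind(seq_along(x), off + 2L)] <- x^2
  B[cbind(seq_along(x), off + 3L)] <- x
  B[cbind(seq_along(x), off + 4L)] <- 1
  B
}

# smoothness constraints at the two knots: matching value, first and second
# derivative between neighbouring cubics (6 x 12). Matching values as well
# as derivatives is what makes the three local cubics collectively a smooth
# function.
spline_constraints <- function(knots) {
  cubic_rows <- function(t) {
    rbind(
      c(t^3, t^2, t, 1),
      c(3 * t^2, 2 * t, 1, 0),
      c(6 * t, 2, 0, 0)
    )
  }
  C <- matrix(0, 6, 12)
  C[1:3, 1:4] <- cubic_rows(knots[1]); C[1:3, 5:8] <- -cubic_rows(knots[1])
  C[4:6, 5:8] <- cubic_rows(knots[2]); C[4:6, 9:12] <- -cubic_rows(knots[2])
  C
}

# orthonormal basis of the nullspace of a matrix
nullspace <- function(M) {
  s <- svd(M, nu = 0, nv = ncol(M))
  tol <- max(dim(M)) * .Machine$double.eps * max(s$d, 0)
  rank <- sum(s$d > tol)
  s$v[, seq(rank + 1, ncol(M)), drop = FALSE]
}

#' Design rows of pairwise curve differences
#'
#' For each bin pair, the difference `f(x_control) - f(x_case)` of the
#' piecewise-cubic curve is a linear combination of the twelve local-cubic
#' coefficients `b1..b12`; this returns one such coefficient row per pair.
#' Segment membership of each endpoint is decided by the knot intervals
#' (`x < i`: first cubic; `i <= x < j`: second; `x >= j`: third). Within a
#' segment the two intercept entries cancel, which is why the curve is only
#' identified up to an additive constant.
#'
#' @param contrasts Data frame with columns `x_case` and `x_control`.
#' @param knots Numeric `c(i, j)`, interior knots.
#' @return A numeric matrix with `nrow(contrasts)` rows and 12 columns named
#'   `b1..b12`.
#' @examples
#' spline_design(tibble::tibble(x_case = 1, x_control = 2), knots = c(1.5, 2.5))
#' @export
spline_design <- function(contrasts, knots) {
  stopifnot(is.data.frame(contrasts),
            all(c("x_case", "x_control") %in% names(contrasts)),
            length(knots) == 2, knots[1] < knots[2])
  D <- spline_basis(contrasts$x_control, knots) -
    spline_basis(contrasts$x_case, knots)
  colnames(D) <- paste0("b", 1:12)
  D
}

# centred monomial difference basis x^1..x^degree (the intercept cancels in
# differences and is fixed later by the anchor)
poly_design <- function(x_case, x_control, degree, center) {
  pows <- seq_len(degree)
  outer(x_control - center, pows, `^`) - outer(x_case - center, pows, `^`)
}

# minimum-norm least squares via SVD; returns solution, effective rank and
# condition number of the retained spectrum
min_norm_lsq <- function(M, d, w = NULL) {
  if (!is.null(w)) {
    M <- M * sqrt(w)
    d <- d * sqrt(w)
  }
  s <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(s$d)
  keep <- s$d > tol
  z <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], d)) / s$d[keep])
  list(z = as.vector(z), rank = sum(keep),
       condition = max(s$d) / min(s$d[keep]))
}

#' Fit the shape curve to a table of paired distances
#'
#' Reconstructs the curve `y = f(x)` from estimated pairwise distances on y.
#' Only differences `f(x_a) - f(x_b)` are observed, so the objective is the
#' sum of squared differences between the observed distances and the
#' model-implied differences, minimised over the curve coefficients. For the
#' spline estimator the curve is three local cubics (`b1..b12`) constrained
#' to match in value, first and second derivative at the two interior knots,
#' solved as equality-constrained linear least squares by nullspace
#' elimination -- deterministic, with no iterative optimisation. The
#' polynomial estimator uses a single fifth-degree polynomial.
#'
#' Pairwise differences leave `f` identified only up to an additive
#' constant; the `anchor` policy fixes it (default: the mean of `f` over the
#' bin representative values is zero, matching the relative y-liability
#' scale on which results are reported).
#'
#' @param distances Data frame with columns `x_case`, `x_control`, `dy`, and
#'   optionally `included` (rows with `included = FALSE` or non-finite `dy`
#'   are dropped from the objective, never imputed) and `se`.
#' @param method `"spline"` (default) or `"polynomial"`. If a knot interval
#'   contains no pair endpoint the spline coefficients of that segment would
#'   be unidentified; a warning is emitted and the polynomial estimator is
#'   used instead.
#' @param knots Interior knots `c(i, j)`; default [default_knots()] of the
#'   representative values.
#' @param degree Polynomial degree (default 5).
#' @param anchor `"mean_zero"` (default) or `"none"`.
#' @param weight_by_se If `TRUE`, weight each pair by `1/se^2`. Off by
#'   default: the objective is unweighted.
#' @param dy_sign Orientation of the `dy` column. The transform reports
#'   `dy` as `f(x_case) - f(x_control)` (the case group is the lower bin),
#'   which is the default `"case_minus_control"`. Use
#'   `"control_minus_case"` when supplying distances already oriented as
#'   `f(x_control) - f(x_case)`.
#'
#' @return An object of class `shape_fit` with elements `kind`, `knots`,
#'   `coefficients`, `domain`, `anchor`, `x_reps`, `n_pairs_used`,
#'   `objective`, `condition` and `exclusions`. Use [evaluate_curve()],
#'   [curve_grid()], [tidy()], [glance()] and [autoplot()] on it.
#'
#' @examples
#' g <- function(x) 0.2 * (x - 1)^2
#' cts <- enumerate_contrasts(
#'   tibble::tibble(bin = 1:8, x_rep = seq(-2, 2, length.out = 8)))
#' d <- tibble::tibble(cts, dy = g(cts$x_case) - g(cts$x_control))
#' fit <- fit_shape(d)
#' glance(fit)
#' @export
fit_shape <- function(distances,
                      method = c("spline", "polynomial"),
                      knots = NULL, degree = 5,
                      anchor = c("mean_zero", "none"),
                      weight_by_se = FALSE,
                      dy_sign = c("case_minus_control", "control_minus_case")) {
  method <- match.arg(method)
  anchor <- match.arg(anchor)
  dy_sign <- match.arg(dy_sign)
  stopifnot(is.data.frame(distances),
            all(c("x_case", "x_control", "dy") %in% names(distances)))
  d <- as_tibble(distances)
  if (!"included" %in% names(d)) d$included <- TRUE
  use <- d$included & is.finite(d$dy)
  exclusions <- c(
    table(if ("exclusion_reason" %in% names(d)) {
      d$exclusion_reason[!use]
    } else {
      rep("not_included", sum(!use))
    })
  )
  dd <- d[use, , drop = FALSE]
  if (nrow(dd) == 0) {
    abort_rgshape("no included distance estimates to fit", "rgshape_empty_fit")
  }
  x_reps <- sort(unique(c(dd$x_case, dd$x_control)))
  domain <- range(x_reps)
  # observed f(x_control) - f(x_case)
  delta <- if (dy_sign == "case_minus_control") -dd$dy else dd$dy
  w <- NULL
  if (isTRUE(weight_by_se)) {
    if (!"se" %in% names(dd) || any(!is.finite(dd$se)) || any(dd$se <= 0)) {
      abort_rgshape("weight_by_se = TRUE requires finite positive `se`",
                    "rgshape_invalid_input")
    }
    w <- 1 / dd$se^2
  }

  if (method == "spline") {
    if (is.null(knots)) knots <- default_knots(x_reps)
    stopifnot(length(knots) == 2)
    if (knots[1] >= knots[2]) {
      abort_rgshape("knots must be ordered, i < j", "rgshape_domain")
    }
    seg <- segment_of(c(dd$x_case, dd$x_control), knots)
    if (length(unique(seg)) < 3) {
      warning("a knot interval contains no pair endpoint; falling back to the polynomial estimator",
              call. = FALSE)
      method <- "polynomial"
    }
  }

  if (method == "spline") {
    if (nrow(dd) < 5) {
      abort_rgshape("too few included distances for the spline fit (need >= 5)",
                    "rgshape_underdetermined")
    }
    A <- spline_design(dd, knots)
    N <- nullspace(spline_constraints(knots))   # 12 x 6
    sol <- min_norm_lsq(A %*% N, delta, w)
    # one nullspace direction (the constant shift) is always unidentified;
    # anything further means an underdetermined system
    if (sol$rank < ncol(N) - 1) {
      abort_rgshape(
        sprintf("underdetermined spline system: effective rank %d < %d",
                sol$rank, ncol(N) - 1),
        "rgshape_underdetermined"
      )
    }
    beta <- as.vector(N %*% sol$z)
    names(beta) <- paste0("b", 1:12)
    fitted_delta <- as.vector(A %*% beta)
    center <- NULL
  } else {
    if (nrow(dd) < degree) {
      abort_rgshape(sprintf("too few included distances for a degree-%d polynomial",
                            degree),
                    "rgshape_underdetermined")
    }
    center <- mean(domain)
    A <- poly_design(dd$x_case, dd$x_control, degree, center)
    sol <- min_norm_lsq(A, delta, w)
    if (sol$rank < degree) {
      abort_rgshape(
        sprintf("underdetermined polynomial system: effective rank %d < %d",
                sol$rank, degree),
        "rgshape_underdetermined"
      )
    }
    beta <- c(0, sol$z)
    names(beta) <- paste0("c", 0:degree)
    fitted_delta <- as.vector(A %*% sol$z)
    knots <- NULL
  }

  fit <- structure(
    list(kind = method, knots = knots, coefficients = beta,
         center = center, domain = domain, anchor = 0, x_reps = x_reps,
         n_pairs_used = nrow(dd),
         objective = sum((delta - fitted_delta)^2),
         condition = sol$condition,
         exclusions = exclusions, dy_sign = dy_sign,
         weighted = isTRUE(weight_by_se)),
    class = "shape_fit"
  )
  if (anchor == "mean_zero") {
    shift <- mean(evaluate_curve(fit, x_reps))
    fit$anchor <- -shift
    if (method == "spline") {
      fit$coefficients[c(4, 8, 12)] <- fit$coefficients[c(4, 8, 12)] - shift
    } else {
      fit$coefficients[1] <- fit$coefficients[1] - shift
    }
  }
  fit
}

#' Evaluate a fitted shape curve
#'
#' Piecewise evaluation of the fitted curve at the given x values, with the
#' segment chosen by the knot intervals. No extrapolation: values outside
#' the fitted domain raise an error.
#'
#' @param curve A [fit_shape()] object.
#' @param grid Numeric vector of x values inside the curve domain.
#' @return Numeric vector of curve values (relative y-liability scale).
#' @export
evaluate_curve <- function(curve, grid) {
  stopifnot(inherits(curve, "shape_fit"))
  grid <- as.numeric(grid)
  eps <- 1e-8 * max(1, diff(curve$domain))
  if (any(grid < curve$domain[1] - eps | grid > curve$domain[2] + eps)) {
    abort_rgshape("x outside the fitted domain (no extrapolation)",
                  "rgshape_domain")
  }
  if (curve$kind == "spline") {
    as.vector(spline_basis(grid, curve$knots) %*% curve$coefficients)
  } else {
    u <- grid - curve$center
    pows <- outer(u, seq(0, length(curve$coefficients) - 1), `^`)
    as.vector(pows %*% curve$coefficients)
  }
}

#' Evaluate a fitted curve on a regular grid
#'
#' @param curve A [fit_shape()] object.
#' @param n Number of grid points spanning the fitted domain (default 200).
#' @return A tibble with columns `x` and `y_hat`.
#' @export
curve_grid <- function(curve, n = 200) {
  stopifnot(inherits(curve, "shape_fit"))
  x <- seq(curve$domain[1], curve$domain[2], length.out = n)
  tibble(x = x, y_hat = evaluate_curve(curve, x))
}

#' @export
predict.shape_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(curve_grid(object)$y_hat)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  evaluate_curve(object, x)
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf("<shape_fit: %s>\n", x$kind))
  if (x$kind == "spline") {
    cat(sprintf("knots: %.4g, %.4g\n", x$knots[1], x$knots[2]))
  }
  cat(sprintf("domain: [%.4g, %.4g]   pairs used: %d   objective: %.4g\n",
              x$domain[1], x$domain[2], x$n_pairs_used, x$objective))
  if (length(x$exclusions) > 0) {
    cat("excluded:", paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_shape
#' @param x,object A `shape_fit` object.
#' @param ... Unused.
#' @export
tidy.shape_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname fit_shape
#' @export
glance.shape_fit <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_pairs_used = x$n_pairs_used,
    n_excluded = sum(x$exclusions),
    objective = x$objective,
    condition = x$condition,
    anchor = x$anchor
  )
}

#' @rdname fit_shape
#' @export
autoplot.shape_fit <- function(object, n = 200, ...) {
  df <- curve_grid(object, n)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y_hat)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "x (trait scale)",
                  y = "expected y liability (relative scale)") +
    ggplot2::theme_minimal()
  if (object$kind == "spline") {
    p <- p + ggplot2::geom_vline(xintercept = object$knots,
                                 linetype = "dashed", colour = "grey60")
  }
  p
}

# numerical second derivative of a fitted curve over a grid, used by tests
# and simulations to characterise curvature
curve_second_derivative <- function(curve, x, h = NULL) {
  if (is.null(h)) h <- diff(curve$domain) * 1e-4
  x <- pmin(pmax(x, curve$domain[1] + h), curve$domain[2] - h)
  (evaluate_curve(curve, x + h) - 2 * evaluate_curve(curve, x) +
      evaluate_curve(curve, x - h)) / h^2
}
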