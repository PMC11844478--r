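#' Resample genetic correlations from their standard errors
#'
#' Each genetic correlation is replaced by an independent draw from
#' `Normal(rg, se^2)`; contrasts and standard errors are unchanged. Records
#' with missing `rg` are passed through untouched. The draw is deterministic
#' given the seed, and the caller's random-number state is left intact.
#'
#' @param records Data frame with columns `rg` and `se`.
#' @param seed Integer seed.
#' @return The input tibble with `rg` replaced by the resampled values.
#' @examples
#' rg <- tibble::tibble(rg = c(0.1, 0.3), se = c(0.05, 0))
#' resample_rg(rg, seed = 1)
#' @export
resample_rg <- function(records, seed) {
  stopifnot(is.data.frame(records), all(c("rg", "se") %in% names(records)))
  records <- as_tibble(records)
  draw <- !is.na(records$rg)
  if (any(draw & !is.finite(records$se))) {
    abort_rgshape("every record with an rg estimate needs a finite se to resample",
                  "rgshape_missing_se")
  }
  new_rg <- records$rg
  new_rg[draw] <- withr::with_seed(
    seed,
    rnorm(sum(draw), mean = records$rg[draw], sd = records$se[draw])
  )
  records$rg <- new_rg
  records
}

#' Resampling envelope around the fitted curve
#'
#' Propagates the standard errors of the bin-pair genetic correlations into
#' an uncertainty envelope: the correlations are resampled `B` times from
#' `Normal(rg, se^2)` and the *entire* pipeline -- filtering (including
#' out-of-bound exclusion of resampled values), angle/tangent transform and
#' curve fit -- is rerun on each resampled table. The default of 100
#' resamples matches standard practice for this estimator. All resampled
#' curves are evaluated on a shared grid; pointwise 2.5%/97.5% quantile
#' bands and the median are computed on top, and the raw curves are kept so
#' a spaghetti-style presentation is possible.
#'
#' Per-cycle refit failures (e.g. too many exclusions in a resample) are
#' counted and skipped, not retried -- retrying would bias the envelope. If
#' more than half the cycles fail, an error is raised.
#'
#' @param records A genetic-correlation table with columns `x_case`,
#'   `x_control`, `rg`, `se` (e.g. from [read_rg_table()] or
#'   [sim_rg_table()]).
#' @param B Number of resamples (default 100).
#' @param seed Integer seed controlling all resampling.
#' @param grid_n Number of grid points for curve evaluation (default 200).
#' @param ... Passed to [fit_shape()] (e.g. `method`, `knots`).
#' @return An object of class `curve_envelope`: list with `grid` (x values),
#'   `curves` (matrix, one column per successful resample), `bands` (tibble
#'   `x`, `lo`, `median`, `hi`), `point_fit` (the un-resampled [fit_shape()]
#'   object), `B`, `n_success`, `n_failed` and `seed`.
#' @export
curve_envelope <- function(records, B = 100, seed = 1, grid_n = 200, ...) {
  stopifnot(B >= 1)
  point_fit <- fit_shape(transform_rg(records), ...)
  grid <- seq(point_fit$domain[1], point_fit$domain[2], length.out = grid_n)

  cycle_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, B)
  )
  one_cycle <- function(s) {
    tryCatch(
      evaluate_curve(fit_shape(transform_rg(resample_rg(records, s)), ...),
                     grid),
      error = function(e) NULL
    )
  }
  curves <- suppressWarnings(purrr::map(cycle_seeds, one_cycle))
  ok <- !vapply(curves, is.null, logical(1))
  if (sum(ok) < B / 2) {
    abort_rgshape(
      sprintf("envelope failure: only %d of %d resampled refits succeeded",
              sum(ok), B),
      "rgshape_envelope_failure"
    )
  }
  cm <- do.call(cbind, curves[ok])
  qs <- apply(cm, 1, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(
    list(
      grid = grid,
      curves = cm,
      bands = tibble(x = grid, lo = qs[1, ], median = qs[2, ], hi = qs[3, ]),
      point_fit = point_fit,
      B = B, n_success = sum(ok), n_failed = sum(!ok), seed = seed
    ),
    class = "curve_envelope"
  )
}

#' @export
print.curve_envelope <- function(x, ...) {
  cat(sprintf("<curve_envelope: %d/%d resampled curves (seed %d)>\n",
              x$n_success, x$B, x$seed))
  cat(sprintf("grid: %d points on [%.4g, %.4g]; mean band half-width %.4g\n",
              length(x$grid), min(x$grid), max(x$grid),
              mean((x$bands$hi - x$bands$lo) / 2)))
  invisible(x)
}

#' @rdname curve_envelope
#' @param x,object A `curve_envelope` object.
#' @param ... Unused.
#' @export
tidy.curve_envelope <- function(x, ...) {
  pt <- evaluate_curve(x$point_fit, x$grid)
  dplyr::mutate(x$bands, point = pt)
}

#' @rdname curve_envelope
#' @export
glance.curve_envelope <- function(x, ...) {
  tibble(
    B = x$B, n_success = x$n_success, n_failed = x$n_failed,
    seed = x$seed,
    mean_half_width = mean((x$bands$hi - x$bands$lo) / 2)
  )
}

#' @rdname curve_envelope
#' @export
autoplot.curve_envelope <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median),
                       colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$point), linewidth = 0.8) +
    ggplot2::labs(x = "x (trait scale)",
                  y = "expected y liability (relative scale)") +
    ggplot2::theme_minimal()
}
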