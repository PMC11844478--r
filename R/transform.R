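#' Flag genetic-correlation records that cannot enter the transform
#'
#' Bin-pair genetic correlations are used regardless of statistical
#' significance, but two kinds of record are excluded: correlations that
#' could not be estimated at all (missing `rg`, reason `"not_estimated"`)
#' and out-of-bound estimates with `|rg| > 1` (reason `"out_of_bounds"`),
#' which arise because summary-statistic rg estimators are not constrained
#' to the correlation scale.
#'
#' @param records A data frame with at least columns `rg` and `se`
#'   (typically from [read_rg_table()] or [sim_rg_table()]).
#' @return The input tibble with logical column `included` and character
#'   column `exclusion_reason` (`NA` for retained records) added or
#'   overwritten. Row count and order are preserved.
#' @examples
#' filter_rg(tibble::tibble(rg = c(0.5, NA, -1.05), se = 0.1))
#' @export
filter_rg <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_rgshape("records must be a non-empty data frame", "rgshape_empty_input")
  }
  if (!"rg" %in% names(records)) {
    abort_rgshape("records must have an `rg` column", "rgshape_schema")
  }
  records <- as_tibble(records)
  if ("se" %in% names(records) &&
      any(!is.na(records$se) & records$se < 0)) {
    abort_rgshape("standard errors must be non-negative", "rgshape_invalid_input")
  }
  records %>%
    mutate(
      exclusion_reason = dplyr::case_when(
        is.na(.data$rg) ~ "not_estimated",
        abs(.data$rg) > 1 ~ "out_of_bounds",
        TRUE ~ NA_character_
      ),
      included = is.na(.data$exclusion_reason)
    )
}

#' Convert a genetic correlation and x-distance to an acute angle
#'
#' The correlation is first divided by the bin-pair distance `dx`, then
#' mapped to the acute angle (in degrees) of a right triangle:
#' `angle = 90 - acos(cor / dx) * 180 / pi`. A zero correlation maps to a
#' zero angle. Note the division happens inside the arc-cosine, which makes
#' the transform dependent on the measurement scale of x; see the package
#' vignette.
#'
#' @param cor Genetic correlation estimate(s), dimensionless.
#' @param dx Bin-pair distance(s) on x's scale, strictly positive.
#' @return Angle(s) in degrees, in the open interval (-90, 90).
#' @examples
#' cor_to_angle(0, 1)      # 0
#' cor_to_angle(0.5, 2)    # 14.4775...
#' @export
cor_to_angle <- function(cor, dx) {
  if (any(!is.finite(dx)) || any(dx <= 0)) {
    abort_rgshape("dx must be strictly positive", "rgshape_domain")
  }
  ratio <- cor / dx
  if (any(abs(ratio) > 1, na.rm = TRUE)) {
    abort_rgshape(
      "|cor/dx| > 1: the ratio is outside the arc-cosine domain (exclude the record upstream)",
      "rgshape_inadmissible_ratio"
    )
  }
  90 - acos(ratio) * 180 / pi
}

#' Convert an acute angle and x-distance to a distance on y
#'
#' The estimated distance on y is the side of a right triangle opposing the
#' angle, with adjacent side `dx`: `dy = tan(angle * pi / 180) * dx`.
#'
#' @param angle Angle(s) in degrees, strictly inside (-90, 90).
#' @param dx Bin-pair distance(s) on x's scale, strictly positive.
#' @return Distance(s) on y's relative liability scale.
#' @examples
#' angle_to_dy(45, 3)  # 3
#' @export
angle_to_dy <- function(angle, dx) {
  if (any(!is.finite(dx)) || any(dx <= 0)) {
    abort_rgshape("dx must be strictly positive", "rgshape_domain")
  }
  if (any(abs(angle) >= 90, na.rm = TRUE)) {
    abort_rgshape("|angle| >= 90 degrees gives a divergent distance",
                  "rgshape_divergent_distance")
  }
  tan(angle * pi / 180) * dx
}

#' Transform a bin-pair genetic-correlation table into y-distances
#'
#' Applies [filter_rg()], then the two-step angle/tangent transform to every
#' retained record. Records whose `|rg/dx|` ratio leaves the arc-cosine
#' domain (possible when `dx < 1` on the chosen x-scale) are excluded with
#' reason `"ratio_out_of_domain"` rather than clamped: clamping would
#' fabricate a 90-degree angle and an infinite distance. Per-record failures
#' never abort the batch, and the output has exactly one row per input row.
#'
#' The resulting `dy` carries the sign of `rg` and estimates the difference
#' in expected y-liability between the *case* (lower) bin and the *control*
#' (higher) bin, `f(x_case) - f(x_control)`: a genetic correlation between
#' "membership of the lower bin" and y is evidence that the lower bin sits
#' higher on y's liability scale. [fit_shape()] accounts for this
#' orientation (see its `dy_sign` argument).
#'
#' @param records A data frame with columns `x_case`, `x_control`, `rg`,
#'   `se` (a `dx` column is recomputed as `x_control - x_case` if absent).
#' @return A tibble with the input columns plus `dx`, `angle`, `dy`,
#'   `included` and `exclusion_reason`.
#' @examples
#' rg <- tibble::tibble(x_case = 1, x_control = 3, rg = 0.4, se = 0.1)
#' transform_rg(rg)
#' @export
transform_rg <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_rgshape("records must be a non-empty data frame", "rgshape_empty_input")
  }
  need <- c("x_case", "x_control", "rg")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort_rgshape(sprintf("missing required column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "rgshape_schema")
  }
  out <- filter_rg(records) %>%
    mutate(dx = .data$x_control - .data$x_case)
  if (any(out$dx <= 0)) {
    abort_rgshape("all contrasts must have dx = x_control - x_case > 0",
                  "rgshape_domain")
  }
  ratio <- out$rg / out$dx
  bad_ratio <- out$included & abs(ratio) >= 1
  out <- out %>%
    mutate(
      exclusion_reason = ifelse(bad_ratio, "ratio_out_of_domain",
                                .data$exclusion_reason),
      included = .data$included & !bad_ratio,
      angle = ifelse(.data$included, 90 - acos(pmin(1, pmax(-1, ratio))) * 180 / pi,
                     NA_real_),
      dy = ifelse(.data$included, tan(.data$angle * pi / 180) * .data$dx,
                  NA_real_)
    )
  out
}
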