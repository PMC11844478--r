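#' Construct a quantile bin scheme
#'
#' A bin scheme partitions the empirical distribution of a continuous trait
#' into ordered quantile bins. Widths are given in percent and must sum to
#' 100. Designs typically use narrow bins in the tails (where trait-specific
#' genetic signal is hypothesised to concentrate) and wide bins in the bulk
#' of the distribution, e.g. the 30-bin body-mass-index design of
#' [bmi_bin_widths()].
#'
#' @param widths Numeric vector of quantile widths in percent. All entries
#'   must be strictly positive and sum to 100 (absolute tolerance `1e-9`).
#'   At least two bins are required.
#'
#' @return An object of class `bin_scheme`: a list with elements `widths`,
#'   `edges` (cumulative quantile edges in percent, from 0 to 100) and `K`
#'   (number of bins).
#'
#' @examples
#' bin_scheme(rep(10, 10))
#' bin_scheme(bmi_bin_widths())
#' @export
bin_scheme <- function(widths) {
  widths <- as.numeric(widths)
  if (length(widths) < 2 || anyNA(widths)) {
    abort_rgshape("a bin scheme needs at least two finite widths",
                  "rgshape_invalid_scheme")
  }
  if (any(widths <= 0)) {
    abort_rgshape("all bin widths must be strictly positive",
                  "rgshape_invalid_scheme")
  }
  if (abs(sum(widths) - 100) > 1e-9) {
    abort_rgshape(
      sprintf("bin widths must sum to 100 percent (got %.12g)", sum(widths)),
      "rgshape_invalid_scheme"
    )
  }
  structure(
    list(widths = widths, edges = c(0, cumsum(widths)), K = length(widths)),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme: %d quantile bins>\n", x$K))
  cat("widths (%):", paste(format(x$widths, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Tail-emphasising 30-bin width design
#'
#' The 30-bin quantile design used for body mass index: from low to high,
#' 2 half-percentile bins, 4 one-percentile bins, 18 five-percentile bins,
#' 4 one-percentile bins and 2 half-percentile bins. Tail bins are narrow so
#' that genetic signal specific to the extremes of the distribution is not
#' averaged away.
#'
#' @return Numeric vector of 30 widths in percent, summing to 100.
#' @examples
#' bin_scheme(bmi_bin_widths())$K  # 30
#' @export
bmi_bin_widths <- function() {
  c(rep(0.5, 2), rep(1, 4), rep(5, 18), rep(1, 4), rep(0.5, 2))
}

# rank-based quantile cutpoints: the value at rank ceiling(q * n).
# Deterministic and platform independent (no interpolation).
scheme_cutpoints <- function(values_sorted, scheme) {
  n <- length(values_sorted)
  ranks <- pmin(n, pmax(1, ceiling(scheme$edges[-1] / 100 * n)))
  values_sorted[ranks]
}

#' Bin index of each value under a quantile scheme
#'
#' Maps every value to the quantile bin containing it. Cutpoints are the
#' empirical values at ranks `ceiling(q * n)`; a value lying exactly on a
#' cutpoint is assigned to the lower bin, so assignment is deterministic and
#' independent of input order.
#'
#' @param values Numeric vector of trait measurements.
#' @param scheme A [bin_scheme()].
#' @return Integer vector of bin indices in `1..K`.
#' @examples
#' bin_index(1:100, bin_scheme(c(50, 50)))
#' @export
bin_index <- function(values, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  values <- as.numeric(values)
  if (anyNA(values)) {
    abort_rgshape("values must not contain NA", "rgshape_invalid_input")
  }
  if (length(values) < scheme$K) {
    abort_rgshape("need at least one value per bin", "rgshape_invalid_input")
  }
  cuts <- scheme_cutpoints(sort(values), scheme)
  dup <- which(duplicated(cuts))
  if (length(dup) > 0) {
    abort_rgshape(
      sprintf("degenerate binning: bin %d is empty (tied values at its quantile edge)",
              dup[1]),
      "rgshape_degenerate_binning"
    )
  }
  # intervals (-Inf, c1], (c1, c2], ... : ties at an edge fall to the lower bin
  idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  pmin(idx, scheme$K)
}

bin_table_from_index <- function(values, idx, K, q_lo, q_hi,
                                 representative, min_count) {
  counts <- tabulate(idx, nbins = K)
  if (any(counts == 0)) {
    abort_rgshape(
      sprintf("degenerate binning: bin %d is empty", which(counts == 0)[1]),
      "rgshape_degenerate_binning"
    )
  }
  if (any(counts < min_count)) {
    small <- which(counts < min_count)
    warning(sprintf("bins with fewer than %d members: %s",
                    min_count, paste(small, collapse = ", ")),
            call. = FALSE)
  }
  split_vals <- split(values, factor(idx, levels = seq_len(K)))
  x_med <- vapply(split_vals, median, numeric(1))
  x_min <- vapply(split_vals, min, numeric(1))
  x_max <- vapply(split_vals, max, numeric(1))
  x_rep <- switch(representative,
    median   = x_med,
    midpoint = (x_min + x_max) / 2,
    index    = as.numeric(seq_len(K))
  )
  out <- tibble(
    bin = seq_len(K), q_lo = q_lo, q_hi = q_hi, n = counts,
    x_rep = unname(x_rep), x_min = unname(x_min), x_max = unname(x_max)
  )
  class(out) <- c("bin_table", class(out))
  attr(out, "assignment") <- idx
  out
}

#' Assign values to quantile bins and summarise each bin
#'
#' Cuts the values into the quantile bins of `scheme` and returns a per-bin
#' summary table. The representative value per bin (used as the bin's
#' coordinate in all downstream distance computations) is the within-bin
#' median by default.
#'
#' @param values Numeric vector of trait measurements.
#' @param scheme A [bin_scheme()].
#' @param representative One of `"median"` (default), `"midpoint"`
#'   (midpoint of the observed within-bin range) or `"index"` (the bin
#'   index itself). The choice fixes the x-scale of the inferred curve and
#'   therefore matters: the angle transform is scale dependent.
#' @param min_count Minimum bin size below which a warning (not an error) is
#'   emitted. Default 100; small tail bins are retained.
#'
#' @return A tibble of class `bin_table` with columns `bin`, `q_lo`, `q_hi`
#'   (quantile bounds in percent), `n`, `x_rep`, `x_min`, `x_max`. The
#'   per-value integer assignment is attached as attribute `"assignment"`.
#'
#' @examples
#' assign_bins(rnorm(5000, 25, 4), bin_scheme(rep(10, 10)))
#' @export
assign_bins <- function(values, scheme,
                        representative = c("median", "midpoint", "index"),
                        min_count = 100) {
  representative <- match.arg(representative)
  values <- as.numeric(values)
  idx <- bin_index(values, scheme)
  bin_table_from_index(values, idx, scheme$K,
                       q_lo = scheme$edges[-(scheme$K + 1)],
                       q_hi = scheme$edges[-1],
                       representative = representative,
                       min_count = min_count)
}

#' Assign values to fixed-value bins
#'
#' Bins by absolute trait value rather than by quantile position, e.g. sleep
#' duration categories "<4, 4, 5, ..., 10, >10 hours". Given `K - 1`
#' strictly increasing cut values, bin 1 is `x < edges[1]`, bin `k` is
#' `edges[k-1] <= x < edges[k]`, and the last bin is `x >= edges[K-1]`
#' (left-closed categories; the first and last bins are open ended).
#'
#' @param values Numeric vector of trait measurements.
#' @param edges Strictly increasing numeric cut values.
#' @inheritParams assign_bins
#' @return A `bin_table` tibble as in [assign_bins()]; `q_lo`/`q_hi` report
#'   the empirical quantile positions (percent) of the value edges in the
#'   observed sample.
#' @examples
#' value_bins(c(4, 4, 8, 8, 8, 11), edges = 4:11, min_count = 1)
#' @export
value_bins <- function(values, edges,
                       representative = c("median", "midpoint", "index"),
                       min_count = 100) {
  representative <- match.arg(representative)
  values <- as.numeric(values)
  edges <- as.numeric(edges)
  if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE)) {
    abort_rgshape("edges must be strictly increasing", "rgshape_invalid_scheme")
  }
  if (anyNA(values)) {
    abort_rgshape("values must not contain NA", "rgshape_invalid_input")
  }
  idx <- value_bin_index(values, edges)
  K <- length(edges) + 1L
  # express bounds as empirical quantile positions for reporting
  ecdf_pct <- function(v) 100 * vapply(v, function(e) mean(values < e), numeric(1))
  q_lo <- c(0, ecdf_pct(edges))
  q_hi <- c(ecdf_pct(edges), 100)
  bin_table_from_index(values, idx, K, q_lo = q_lo, q_hi = q_hi,
                       representative = representative, min_count = min_count)
}

#' Bin index of each value under fixed-value edges
#'
#' @inheritParams value_bins
#' @return Integer vector of bin indices in `1..(length(edges) + 1)`.
#' @export
value_bin_index <- function(values, edges) {
  findInterval(values, edges, left.open = FALSE) + 1L
}

#' Enumerate all pairwise bin contrasts
#'
#' Every unordered pair of bins defines one case/control contrast: the
#' lower-x bin is the case group, the higher-x bin the control group, and
#' the x-distance `dx` is the difference of the bins' representative values.
#' `K` bins give `choose(K, 2)` contrasts (435 for the 30-bin design, 36 for
#' 9 bins).
#'
#' @param bin_table A `bin_table` from [assign_bins()] or [value_bins()], or
#'   any data frame with columns `bin` and `x_rep`.
#' @return A tibble with columns `case_bin`, `control_bin`, `x_case`,
#'   `x_control`, `dx` and one row per bin pair.
#' @examples
#' bt <- assign_bins(rnorm(2000), bin_scheme(rep(20, 5)), min_count = 1)
#' enumerate_contrasts(bt)
#' @export
enumerate_contrasts <- function(bin_table) {
  stopifnot(is.data.frame(bin_table),
            all(c("bin", "x_rep") %in% names(bin_table)))
  bt <- dplyr::arrange(as_tibble(bin_table), .data$bin)
  K <- nrow(bt)
  if (K < 2) {
    abort_rgshape("need at least two bins to form contrasts",
                  "rgshape_invalid_input")
  }
  if (is.unsorted(bt$x_rep, strictly = TRUE)) {
    abort_rgshape("bin representative values must be strictly increasing",
                  "rgshape_ordering")
  }
  pairs <- utils::combn(K, 2)
  tibble(
    case_bin = bt$bin[pairs[1, ]],
    control_bin = bt$bin[pairs[2, ]],
    x_case = bt$x_rep[pairs[1, ]],
    x_control = bt$x_rep[pairs[2, ]],
    dx = bt$x_rep[pairs[2, ]] - bt$x_rep[pairs[1, ]]
  )
}
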