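#' Define a simulation scenario
#'
#' A scenario describes a synthetic two-trait cohort in which each trait is
#' the sum of an additive genetic and an environmental component
#' (`x = a_x + e_x`, `y = a_y + e_y`), with a configurable genetic coupling
#' between the two genetic components:
#'
#' * `"linear"`: `a_y = rho * a_x' + sqrt(1 - rho^2) * u` with `a_x'` the
#'   standardised genetic score of x and `u` an independent genetic score;
#'   `coupling_strength` is the genetic correlation `rho`.
#' * `"quadratic"`: `a_y = lambda * (a_x^2 - E[a_x^2]) + u` (the quadratic
#'   term standardised, `u` scaled so `var(a_y) = 1`). The genetic score of
#'   x additionally carries tail-activated components (distinct variant
#'   effects expressed in the lower and the upper half of the baseline
#'   score), because a purely homogeneous additive architecture renders any
#'   nonlinear coupling invisible to binned-GWAS genetic correlations --
#'   see the methods vignette.
#' * `"two_tail"`: the y liability displaces x away from its baseline, up or
#'   down depending on the individual (`x = a_x0 + kappa * w * max(a_y, 0)`
#'   with `w = +/-1` per individual, components standardised). Both tails of
#'   x are thereby enriched for y risk alleles, emulating the sleep-duration
#'   / depression structure where both short and long sleep load genetically
#'   on the disorder.
#' * `"null"`: `a_y` is an independent genetic score; the recovered curve
#'   should be flat.
#'
#' @param n Number of individuals (default 20000; must be at least 50 per
#'   bin).
#' @param m Number of biallelic variants in linkage equilibrium (default
#'   2000, minimum 200).
#' @param h2x Heritability of x, in (0, 1) (default 0.5).
#' @param coupling One of `"linear"`, `"quadratic"`, `"two_tail"`, `"null"`.
#' @param coupling_strength Dimensionless strength; defaults per coupling:
#'   0.5 (linear `rho`), 0.9 (quadratic `lambda`), 1 (two-tail `kappa`),
#'   0 (null).
#' @param noise_sd_y Environmental standard deviation of y (default 1, i.e.
#'   y is about 50% heritable).
#' @param heterogeneous_x For the quadratic coupling only: include the
#'   tail-activated heterogeneous components in x's genetic score (default
#'   `TRUE`). With `FALSE`, x is a plain homogeneous additive score and the
#'   quadratic coupling becomes *undetectable* from binned GWASs -- all bin
#'   contrasts are then genetically near-perfectly correlated with each
#'   other, so their correlations with y carry no shape information. Kept as
#'   an option because this blindness is an important negative property of
#'   the method.
#' @param bins Number of equal quantile bins (default 10), a vector of
#'   widths in percent, or a [bin_scheme()].
#' @param seed Integer seed; all randomness in the scenario flows from it.
#' @return An object of class `sim_scenario`.
#' @examples
#' sim_scenario(n = 2000, m = 400, coupling = "two_tail", seed = 7)
#' @export
sim_scenario <- function(n = 20000, m = 2000, h2x = 0.5,
                         coupling = c("linear", "quadratic", "two_tail", "null"),
                         coupling_strength = NULL,
                         noise_sd_y = 1, bins = 10, seed = 1,
                         heterogeneous_x = TRUE) {
  coupling <- match.arg(coupling)
  if (is.null(coupling_strength)) {
    coupling_strength <- switch(coupling, linear = 0.5, quadratic = 0.9,
                                two_tail = 1, null = 0)
  }
  scheme <- if (inherits(bins, "bin_scheme")) {
    bins
  } else if (length(bins) == 1) {
    bin_scheme(rep(100 / bins, bins))
  } else {
    bin_scheme(bins)
  }
  if (!(h2x > 0 && h2x < 1)) {
    abort_rgshape("h2x must be strictly inside (0, 1)", "rgshape_config")
  }
  if (m < 200) abort_rgshape("m must be at least 200", "rgshape_config")
  if (n < 50 * scheme$K) {
    abort_rgshape("n must be at least 50 per bin", "rgshape_config")
  }
  if (coupling == "linear" && abs(coupling_strength) > 1) {
    abort_rgshape("linear coupling strength is a correlation in [-1, 1]",
                  "rgshape_config")
  }
  if (coupling == "quadratic" && (coupling_strength < 0 || coupling_strength > 1)) {
    abort_rgshape("quadratic coupling strength must be in [0, 1]", "rgshape_config")
  }
  if (noise_sd_y < 0) abort_rgshape("noise_sd_y must be >= 0", "rgshape_config")
  structure(
    list(n = as.integer(n), m = as.integer(m), h2x = h2x,
         coupling = coupling, coupling_strength = coupling_strength,
         noise_sd_y = noise_sd_y, scheme = scheme, seed = as.integer(seed),
         heterogeneous_x = isTRUE(heterogeneous_x)),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario: n=%d m=%d h2x=%.2f coupling=%s (strength %.2f) bins=%d seed=%d>\n",
    x$n, x$m, x$h2x, x$coupling, x$coupling_strength, x$scheme$K, x$seed))
  invisible(x)
}

# standardised additive score of centred dosages
std_score <- function(G, b) {
  s <- as.vector(G %*% b)
  (s - mean(s)) / sd(s)
}

#' Simulate a two-trait polygenic cohort
#'
#' Generates genotype dosages for `m` independent biallelic variants with
#' allele frequencies uniform on (0.05, 0.95), builds the genetic and
#' environmental components of both traits under the scenario's coupling
#' (see [sim_scenario()]), and returns the cohort. `x` is standardised to
#' unit variance with `var(a_x) = h2x` by construction; `y = a_y + e_y`
#' with `var(a_y) = 1` and `e_y ~ Normal(0, noise_sd_y^2)`. Deterministic
#' given the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @return An object of class `sim_cohort`: list with the dosage matrix `G`
#'   (n x m), allele frequencies `p`, per-individual `a_x`, `e_x`, `x`,
#'   `a_y`, `e_y`, `y`, the per-variant effect draws in `effects`, and the
#'   scenario.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  withr::with_seed(sc$seed, {
    p <- runif(sc$m, 0.05, 0.95)
    G <- matrix(rbinom(sc$n * sc$m, 2, rep(p, each = sc$n)), sc$n, sc$m)
    storage.mode(G) <- "double"

    b0 <- rnorm(sc$m)
    bu <- rnorm(sc$m)
    s0 <- std_score(G, b0)
    su <- std_score(G, bu)
    effects <- list(b0 = b0, bu = bu)
    k <- sc$coupling_strength

    if (sc$coupling %in% c("linear", "null")) {
      a_x_raw <- s0
      a_y <- if (sc$coupling == "linear") {
        k * s0 + sqrt(1 - k^2) * su
      } else {
        su
      }
    } else if (sc$coupling == "quadratic") {
      # tail-activated components: variants whose effect on x is expressed
      # only in the lower (or upper) half of the baseline score -- the
      # genetic-effect heterogeneity without which a nonlinear coupling is
      # undetectable from binned GWASs
      if (sc$heterogeneous_x) {
        b_lo <- rnorm(sc$m); b_hi <- rnorm(sc$m)
        s_lo <- std_score(G, b_lo); s_hi <- std_score(G, b_hi)
        act_lo <- as.numeric(s0 < 0)
        a_x_raw <- s0 + s_lo * act_lo + s_hi * (1 - act_lo)
        a_x_raw <- (a_x_raw - mean(a_x_raw)) / sd(a_x_raw)
        effects$b_lo <- b_lo; effects$b_hi <- b_hi
      } else {
        a_x_raw <- s0
      }
      quad <- a_x_raw^2 - mean(a_x_raw^2)
      quad <- quad / sd(quad)
      a_y <- k * quad + sqrt(1 - k^2) * su
    } else { # two_tail
      b_y <- rnorm(sc$m)
      s_y <- std_score(G, b_y)
      w <- sample(c(-1, 1), sc$n, replace = TRUE)
      disp <- pmax(s_y, 0)
      disp <- (disp - mean(disp)) / sd(disp)
      a_x_raw <- s0 + k * w * disp
      a_x_raw <- (a_x_raw - mean(a_x_raw)) / sd(a_x_raw)
      a_y <- s_y
      effects$b_y <- b_y
    }

    a_x <- sqrt(sc$h2x) * (if (sc$coupling %in% c("linear", "null")) s0 else a_x_raw)
    e_x <- rnorm(sc$n, 0, sqrt(1 - sc$h2x))
    x <- a_x + e_x
    e_y <- rnorm(sc$n, 0, sc$noise_sd_y)
    y <- a_y + e_y

    structure(
      list(G = G, p = p, a_x = a_x, e_x = e_x, x = x,
           a_y = a_y, e_y = e_y, y = y,
           effects = effects, scenario = sc),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("<sim_cohort: n=%d m=%d coupling=%s>\n", sc$n, sc$m, sc$coupling))
  cat(sprintf("var(a_x)/var(x) = %.3f (target h2x = %.2f); cor(a_x, a_y) = %.3f\n",
              var(x$a_x) / var(x$x), sc$h2x, cor(x$a_x, x$a_y)))
  invisible(x)
}

#' Marginal per-variant effects on the y genetic component
#'
#' The per-variant regression slope of `a_y` (or of the noisy phenotype `y`
#' if `use_phenotype = TRUE`) on dosage across the full cohort. Used as the
#' y-side effect vector in [estimate_rg()]; using the noise-free genetic
#' component by default keeps the genetic-correlation noise driven by the
#' contrast GWAS, so moderate sample sizes suffice.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param use_phenotype Regress the phenotype `y` instead of `a_y`.
#' @return Numeric vector of length `m`.
#' @export
y_marginal_effects <- function(cohort, use_phenotype = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  yv <- if (use_phenotype) cohort$y else cohort$a_y
  yc <- yv - mean(yv)
  n <- nrow(cohort$G)
  cv <- as.vector(crossprod(cohort$G, yc)) / (n - 1)
  mg <- colMeans(cohort$G)
  vg <- (colSums(cohort$G^2) - n * mg^2) / (n - 1)
  cv / vg
}

#' Per-variant association effects for one bin-pair contrast
#'
#' For each variant, the slope of the simple regression of case/control
#' membership on dosage among members of the two bins, with the *lower* bin
#' coded as the case group (1) and the higher bin as the control group (0).
#' Monomorphic variants within the pair subsample get a zero effect and are
#' flagged.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param contrast One row of an [enumerate_contrasts()] table (or any list
#'   with `case_bin` and `control_bin`).
#' @param assignment Integer bin assignment per individual; computed from
#'   the scenario's bin scheme if omitted.
#' @return A tibble with columns `variant`, `beta`, `se` and `monomorphic`.
#' @export
contrast_association <- function(cohort, contrast, assignment = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(assignment)) {
    assignment <- bin_index(cohort$x, cohort$scenario$scheme)
  }
  idx_case <- which(assignment == contrast$case_bin)
  idx_ctrl <- which(assignment == contrast$control_bin)
  if (length(idx_case) == 0 || length(idx_ctrl) == 0) {
    abort_rgshape("both bins of the contrast must be non-empty",
                  "rgshape_degenerate_binning")
  }
  g <- cohort$G[c(idx_case, idx_ctrl), , drop = FALSE]
  ind <- c(rep(1, length(idx_case)), rep(0, length(idx_ctrl)))
  n_u <- length(ind)
  ind_c <- ind - mean(ind)
  cv <- as.vector(crossprod(g, ind_c)) / (n_u - 1)
  mg <- colMeans(g)
  vg <- (colSums(g^2) - n_u * mg^2) / (n_u - 1)
  mono <- vg <= 0
  beta <- ifelse(mono, 0, cv / ifelse(mono, 1, vg))
  v_ind <- sum(ind_c^2) / (n_u - 1)
  rss <- pmax(0, v_ind - beta^2 * vg)          # residual variance
  se <- ifelse(mono, NA_real_,
               sqrt(rss * (n_u - 1) / pmax(1, n_u - 2) / ((n_u - 1) * vg)))
  tibble(variant = seq_along(beta), beta = beta, se = se, monomorphic = mono)
}

#' Genetic correlation of two effect vectors with block-jackknife SE
#'
#' Stand-in for summary-statistic genetic-correlation estimation: with
#' variants in linkage equilibrium, the correlation between two per-variant
#' effect vectors estimates the genetic correlation between the underlying
#' traits, and a delete-one-block jackknife over contiguous variant blocks
#' gives its standard error. (Reference-panel based estimators are not
#' needed because the simulated variants are independent.)
#'
#' @param contrast_effects Numeric vector of per-variant effects (or a
#'   [contrast_association()] tibble).
#' @param y_effects Numeric vector of per-variant effects on y (or a tibble
#'   with a `beta` column).
#' @param n_blocks Number of contiguous jackknife blocks (default 20);
#'   requires at least 10 variants per block.
#' @return A one-row tibble with columns `rg`, `se` and `n_blocks`; `rg` is
#'   `NA` (not estimated) when either vector has zero variance.
#' @examples
#' b <- rnorm(400)
#' estimate_rg(b, b)   # rg = 1, se = 0
#' @export
estimate_rg <- function(contrast_effects, y_effects, n_blocks = 20) {
  bx <- if (is.data.frame(contrast_effects)) contrast_effects$beta else contrast_effects
  by <- if (is.data.frame(y_effects)) y_effects$beta else y_effects
  stopifnot(length(bx) == length(by))
  m <- length(bx)
  if (m < 10 * n_blocks) {
    abort_rgshape("need at least 10 variants per jackknife block",
                  "rgshape_config")
  }
  if (sd(bx) == 0 || sd(by) == 0) {
    return(tibble(rg = NA_real_, se = NA_real_, n_blocks = n_blocks))
  }
  rg <- cor(bx, by)
  block <- ceiling(seq_len(m) / (m / n_blocks))
  theta <- vapply(seq_len(n_blocks), function(b) {
    keep <- block != b
    cor(bx[keep], by[keep])
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))
  tibble(rg = rg, se = se, n_blocks = n_blocks)
}

#' Population (noise-free) contrast effect vectors
#'
#' Computes, analytically under the generative model, the per-variant slope
#' of case/control membership on dosage that a bin-pair contrast GWAS
#' estimates -- i.e. the effect vector free of sampling noise. Conditional
#' on dosage `g` at one variant, `x` is treated as Gaussian with mean
#' shifted by the variant's additive effect, which is exact in the limit of
#' many variants for a homogeneous additive architecture; the function is
#' therefore only available for the `"linear"` and `"null"` couplings, where
#' the architecture of x is homogeneous. Under that architecture the
#' population effect vectors of *all* bin pairs are proportional to a single
#' direction -- binned GWASs are genetically (near) perfectly correlated --
#' which is exactly why homogeneous architectures are blind to nonlinear
#' couplings.
#'
#' @param cohort A homogeneous-architecture [simulate_cohort()] object.
#' @param contrasts An [enumerate_contrasts()] table.
#' @param bin_table The corresponding bin table ([assign_bins()] of
#'   `cohort$x`); computed if omitted.
#' @return A matrix (m x number of contrasts) of population effect vectors.
#' @export
true_contrast_effects <- function(cohort, contrasts, bin_table = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  sc <- cohort$scenario
  homogeneous <- sc$coupling %in% c("linear", "null") ||
    (sc$coupling == "quadratic" && !sc$heterogeneous_x)
  if (!homogeneous) {
    abort_rgshape(
      "population contrast effects are only defined for homogeneous additive architectures of x",
      "rgshape_config"
    )
  }
  if (is.null(bin_table)) {
    bin_table <- assign_bins(cohort$x, sc$scheme, min_count = 0)
  }
  # per-dosage-unit additive effect of each variant on x
  raw <- as.vector(cohort$G %*% cohort$effects$b0)
  alpha <- sqrt(sc$h2x) * cohort$effects$b0 / sd(raw)
  p <- cohort$p
  m <- length(p)
  gprob <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)      # 3 x m
  mu_x <- mean(cohort$x)
  var_x <- var(cohort$x)
  # bin boundaries on x realised in the cohort
  lo <- c(-Inf, bin_table$x_max[-nrow(bin_table)])
  hi <- c(bin_table$x_max[-nrow(bin_table)], Inf)

  # P(x in bin | g) for each variant/dosage/bin
  bin_prob <- function(bin) {
    sapply(0:2, function(g) {
      mg <- mu_x + alpha * (g - 2 * p)
      tau <- sqrt(pmax(var_x - alpha^2 * 2 * p * (1 - p), 1e-12))
      stats::pnorm((hi[bin] - mg) / tau) - stats::pnorm((lo[bin] - mg) / tau)
    })  # m x 3
  }
  K <- nrow(bin_table)
  Pb <- lapply(seq_len(K), bin_prob)

  out <- matrix(NA_real_, m, nrow(contrasts))
  for (r in seq_len(nrow(contrasts))) {
    Pi <- Pb[[contrasts$case_bin[r]]] * t(gprob)   # joint P(z = g, bin i)
    Pj <- Pb[[contrasts$control_bin[r]]] * t(gprob)
    Pu <- Pi + Pj
    tot <- rowSums(Pu)
    gv <- matrix(0:2, m, 3, byrow = TRUE)
    Ez <- rowSums(Pu * gv) / tot
    Ez2 <- rowSums(Pu * gv^2) / tot
    Eind <- rowSums(Pi) / tot
    Ezind <- rowSums(Pi * gv) / tot
    out[, r] <- (Ezind - Ez * Eind) / pmax(Ez2 - Ez^2, 1e-12)
  }
  out
}

#' Bin-pair genetic-correlation table from a simulated cohort
#'
#' Bins the cohort on x, runs every pairwise bin contrast association, and
#' correlates each contrast effect vector with the y effect vector to
#' produce the genetic-correlation table consumed by [transform_rg()].
#'
#' @param cohort A [simulate_cohort()] object.
#' @param n_blocks Jackknife blocks for [estimate_rg()].
#' @param use_phenotype Passed to [y_marginal_effects()].
#' @param min_count Passed to [assign_bins()].
#' @return A tibble with columns `case_bin`, `control_bin`, `x_case`,
#'   `x_control`, `rg`, `se`.
#' @export
sim_rg_table <- function(cohort, n_blocks = 20, use_phenotype = FALSE,
                         min_count = 100) {
  stopifnot(inherits(cohort, "sim_cohort"))
  sc <- cohort$scenario
  bt <- assign_bins(cohort$x, sc$scheme, min_count = min_count)
  contrasts <- enumerate_contrasts(bt)
  assignment <- attr(bt, "assignment")
  by <- y_marginal_effects(cohort, use_phenotype = use_phenotype)

  # per-bin dosage sums allow all C(K,2) contrast regressions in two passes
  # over the genotype matrix
  K <- sc$scheme$K
  fac <- factor(assignment, levels = seq_len(K))
  S1 <- rowsum(cohort$G, fac)          # K x m sums of dosages
  S2 <- rowsum(cohort$G^2, fac)
  nb <- tabulate(assignment, nbins = K)

  est <- purrr::map_dfr(seq_len(nrow(contrasts)), function(r) {
    a <- contrasts$case_bin[r]; b <- contrasts$control_bin[r]
    n_u <- nb[a] + nb[b]
    mg <- (S1[a, ] + S1[b, ]) / n_u
    vg <- (S2[a, ] + S2[b, ]) / n_u - mg^2           # population variance
    cv <- S1[a, ] / n_u - (nb[a] / n_u) * mg          # cov(ind, g)
    beta <- ifelse(vg <= 0, 0, cv / ifelse(vg <= 0, 1, vg))
    estimate_rg(beta, by, n_blocks = n_blocks)
  })

  dplyr::bind_cols(contrasts[, c("case_bin", "control_bin", "x_case", "x_control")],
                   est[, c("rg", "se")])
}

#' Run the full pipeline on a simulated scenario
#'
#' Simulate a cohort, bin it, run all bin-pair contrast associations,
#' estimate genetic correlations with jackknife standard errors, transform
#' them to y-distances, fit the shape curve and compute the resampling
#' envelope. All randomness flows from the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @param B Number of envelope resamples (default 100).
#' @param grid_n Envelope grid size.
#' @param keep_cohort Keep the (large) cohort object in the result.
#' @param ... Passed to [fit_shape()] via [curve_envelope()].
#' @return An object of class `rg_run`: list with `scenario`, `rg_table`,
#'   `distances`, `fit`, `envelope` (and `cohort` if requested).
#' @export
run_end_to_end <- function(scenario, B = 100, grid_n = 200,
                           keep_cohort = FALSE, ...) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seeds <- withr::with_seed(scenario$seed,
                            sample.int(.Machine$integer.max, 2))
  cohort <- simulate_cohort(scenario)
  rg_table <- sim_rg_table(cohort)
  distances <- transform_rg(rg_table)
  fit <- fit_shape(distances, ...)
  envelope <- curve_envelope(rg_table, B = B, seed = seeds[2],
                             grid_n = grid_n, ...)
  out <- list(scenario = scenario, rg_table = rg_table,
              distances = distances, fit = fit, envelope = envelope)
  if (keep_cohort) out$cohort <- cohort
  structure(out, class = "rg_run")
}

#' @export
print.rg_run <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("rg table: %d pairs (%d excluded by the transform)\n",
              nrow(x$rg_table), sum(!x$distances$included)))
  print(x$fit)
  print(x$envelope)
  invisible(x)
}
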