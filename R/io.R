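# Tables are written as TSV at 12 significant digits: small, hand
# inspectable, and round-trip faithful without platform-dependent
# full-precision noise.

signif_cols <- function(df, digits = 12) {
  df %>% mutate(across(dplyr::where(is.double), ~ signif(.x, digits)))
}

#' Write a table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param digits Significant digits for double columns (default 12).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path, digits = 12) {
  utils::write.table(signif_cols(as.data.frame(df), digits), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a bin-pair genetic-correlation table
#'
#' Reads a TSV with required columns `case_bin`, `control_bin`, `x_case`,
#' `x_control`, `rg`, `se`. Extra columns are preserved and row order is
#' kept. Blank or `NA` values in `rg` mark correlations that could not be
#' estimated; such records are kept (and later excluded with reason
#' `"not_estimated"` by [filter_rg()]), not dropped at read time.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble, one row per bin-pair record.
#' @export
read_rg_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("case_bin", "control_bin", "x_case", "x_control", "rg", "se")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_rgshape(sprintf("rg table is missing required column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "rgshape_schema")
  }
  for (col in required) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))
      if (length(bad) > 0) {
        abort_rgshape(sprintf("non-numeric value in column `%s`, row %d",
                              col, bad[1]),
                      "rgshape_parse")
      }
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  as_tibble(df)
}

#' Write the coefficient sidecar of a fitted curve
#'
#' A small structured-text (JSON) record of the fit: estimator kind, knots,
#' coefficients, domain and anchor -- enough to re-evaluate the curve
#' without refitting.
#'
#' @param fit A [fit_shape()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_sidecar <- function(fit, path) {
  stopifnot(inherits(fit, "shape_fit"))
  jsonlite::write_json(
    list(kind = fit$kind, knots = fit$knots,
         coefficients = as.list(fit$coefficients),
         center = fit$center, domain = fit$domain, anchor = fit$anchor,
         n_pairs_used = fit$n_pairs_used, objective = fit$objective),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Write a machine-readable run-metadata record
#'
#' Every pipeline run writes a JSON record echoing its configuration, seed
#' and software versions, sufficient to reproduce the run.
#'
#' @param config Named list of run parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  meta <- list(
    config = config,
    package = "rgshape",
    package_version = as.character(utils::packageVersion("rgshape")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run a pipeline stage and write its artifacts
#'
#' Programmatic equivalent of the command-line interface. Subcommands:
#'
#' * `"bins"`: bin a phenotype vector (`values` + `widths` or `edges`) and
#'   write the bin table and contrast manifest.
#' * `"fit"`: read an rg table (`rg_table` path or data frame), transform,
#'   fit and write distance table, evaluated curve, coefficient sidecar and
#'   envelope.
#' * `"simulate"`: run [run_end_to_end()] for a scenario and write all of
#'   the above plus the simulated rg table.
#' * `"envelope"`: envelope only, from an rg table.
#'
#' @param subcommand One of `"bins"`, `"fit"`, `"simulate"`, `"envelope"`.
#' @param config Named list of parameters (see Details in the vignette);
#'   common entries: `out` (output directory, required), `seed`, `B`,
#'   `method`, `knots`, `grid_n`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(subcommand = c("bins", "fit", "simulate", "envelope"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  out_dir <- config$out
  if (is.null(out_dir)) abort_rgshape("config$out is required", "rgshape_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  written <- list()
  seed <- config$seed %||% 1L
  B <- config$B %||% 100L
  grid_n <- config$grid_n %||% 200L
  method <- config$method %||% "spline"

  get_rg <- function() {
    if (is.data.frame(config$rg_table)) {
      config$rg_table
    } else {
      read_rg_table(config$rg_table)
    }
  }
  fit_args <- list(method = method)
  if (!is.null(config$knots)) fit_args$knots <- config$knots

  if (subcommand == "bins") {
    values <- config$values
    if (is.character(values)) {
      values <- utils::read.delim(values, sep = "\t")[[1]]
    }
    bt <- if (!is.null(config$edges)) {
      value_bins(values, config$edges,
                 min_count = config$min_count %||% 100)
    } else {
      assign_bins(values, bin_scheme(config$widths),
                  min_count = config$min_count %||% 100)
    }
    written$bin_table <- write_tsv_table(bt, path("bin_table.tsv"))
    written$contrasts <- write_tsv_table(enumerate_contrasts(bt),
                                         path("contrasts.tsv"))
  } else if (subcommand %in% c("fit", "envelope")) {
    rg <- get_rg()
    if (subcommand == "fit") {
      distances <- transform_rg(rg)
      fit <- do.call(fit_shape, c(list(distances), fit_args))
      written$distances <- write_tsv_table(distances, path("distances.tsv"))
      written$curve <- write_tsv_table(curve_grid(fit, grid_n),
                                       path("curve.tsv"))
      written$sidecar <- write_curve_sidecar(fit, path("curve_coefficients.json"))
      message(sprintf("fit: %d pairs used, %d excluded",
                      fit$n_pairs_used, sum(fit$exclusions)))
    }
    env <- do.call(curve_envelope,
                   c(list(rg, B = B, seed = seed, grid_n = grid_n), fit_args))
    written$envelope <- write_tsv_table(env$bands, path("envelope.tsv"))
    raw <- as.data.frame(env$curves)
    names(raw) <- paste0("resample_", seq_len(ncol(raw)))
    written$envelope_curves <-
      write_tsv_table(dplyr::bind_cols(tibble(x = env$grid), raw),
                      path("envelope_curves.tsv"))
  } else { # simulate
    scenario <- sim_scenario(
      n = config$n %||% 20000, m = config$m %||% 2000,
      h2x = config$h2x %||% 0.5,
      coupling = config$coupling %||% "linear",
      coupling_strength = config$coupling_strength,
      noise_sd_y = config$noise_sd_y %||% 1,
      bins = config$bins %||% 10, seed = seed
    )
    run <- do.call(run_end_to_end,
                   c(list(scenario, B = B, grid_n = grid_n), fit_args))
    written$rg_table <- write_tsv_table(run$rg_table, path("rg_table.tsv"))
    written$distances <- write_tsv_table(run$distances, path("distances.tsv"))
    written$curve <- write_tsv_table(curve_grid(run$fit, grid_n),
                                     path("curve.tsv"))
    written$sidecar <- write_curve_sidecar(run$fit,
                                           path("curve_coefficients.json"))
    written$envelope <- write_tsv_table(run$envelope$bands,
                                        path("envelope.tsv"))
  }
  written$metadata <- write_run_metadata(
    c(list(subcommand = subcommand, seed = seed, B = B),
      config[setdiff(names(config), c("rg_table", "values"))]),
    path("run_metadata.json")
  )
  invisible(written)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()], used by the `exec/rgshape`
#' script: `rgshape <subcommand> --key value ...`. List-valued keys
#' (`widths`, `edges`, `knots`) take comma-separated values.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
rgshape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: rgshape <bins|fit|simulate|envelope> --key value ...")
    return(invisible(1L))
  }
  subcommand <- args[1]
  kv <- args[-1]
  config <- list()
  i <- 1
  while (i <= length(kv)) {
    key <- sub("^--", "", kv[i])
    val <- kv[i + 1]
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    config[[key]] <- if (anyNA(num)) val else num
    i <- i + 2
  }
  status <- tryCatch({
    run_pipeline(subcommand, config)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
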