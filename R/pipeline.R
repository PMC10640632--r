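#' Pipeline configuration
#'
#' Collects every setting of the end-to-end synthetic calibration study:
#' wavelength grid, working window, concentration ranges, band library and
#' noise seeds, calibration/validation split, and model hyperparameters.
#' Defaults reproduce the study conditions: a 200--400 nm scan at 0.2 nm,
#' a 250--300 nm window, the five-analyte concentration ranges, a 25-run
#' design split 15/10, PLS latent variables chosen by leave-one-out
#' cross-validation, and the linear network in its accurate preset.
#'
#' @param grid [wl_grid()] of the full scan.
#' @param window Numeric `c(low, high)` nm working window.
#' @param ranges Named list of `c(c_min, c_max)` per component.
#' @param library_seed,noise,split_seed Seeds and [noise_model()] controlling
#'   the stochastic stages.
#' @param n_validation Validation-set size out of the 25 runs.
#' @param models Character subset of `c("pls", "ann")`.
#' @param pls_max_lv Largest latent-variable count scanned by LOO CV.
#' @param pls_threshold_ratio Parsimony tolerance of [select_n_lv()].
#' @param ann_preset,ann_seed Network preset and initialization seed.
#' @param out_dir Optional directory for artifacts; `NULL` keeps everything
#'   in memory.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(grid = wl_grid(200, 400, 0.2),
                            window = c(250, 300),
                            ranges = assay_ranges(),
                            library_seed = 0,
                            noise = noise_model(),
                            split_seed = 1,
                            n_validation = 10,
                            models = c("pls", "ann"),
                            pls_max_lv = 10,
                            pls_threshold_ratio = 0.02,
                            ann_preset = "accurate",
                            ann_seed = 1,
                            out_dir = NULL) {
  if (is.null(ranges) || length(ranges) == 0) {
    stop("`ranges` must give a c(c_min, c_max) pair per component.", call. = FALSE)
  }
  bad <- names(ranges)[!vapply(ranges, function(r)
    length(r) == 2 && all(is.finite(r)) && r[1] > 0 && r[2] > r[1], logical(1))]
  if (length(bad) > 0) {
    stop("Invalid range(s) for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (window[1] < grid$start_nm || window[2] > grid$stop_nm) {
    stop("Window must lie within the grid.", call. = FALSE)
  }
  models <- match.arg(models, c("pls", "ann"), several.ok = TRUE)
  structure(
    list(grid = grid, window = window, ranges = ranges,
         library_seed = library_seed, noise = noise, split_seed = split_seed,
         n_validation = n_validation, models = models,
         pls_max_lv = pls_max_lv, pls_threshold_ratio = pls_threshold_ratio,
         ann_preset = ann_preset, ann_seed = ann_seed, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same fields as [pipeline_config()], with `grid` given as
#' `[start, stop, step]`, `window` as `[low, high]`, `ranges` as a mapping of
#' component to `[c_min, c_max]`, and `noise` as a mapping of
#' `sigma_base`, `sigma_below_250`, `baseline_drift_amplitude`, `seed`.
#' Fields omitted from the file keep the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$grid)) args$grid <- wl_grid(y$grid[[1]], y$grid[[2]], y$grid[[3]])
  if (!is.null(y$window)) args$window <- as.numeric(unlist(y$window))
  if (!is.null(y$ranges)) args$ranges <- lapply(y$ranges, as.numeric)
  if (!is.null(y$noise)) {
    args$noise <- do.call(noise_model, y$noise)
  }
  for (f in c("library_seed", "split_seed", "n_validation", "pls_max_lv",
              "pls_threshold_ratio", "ann_preset", "ann_seed", "out_dir")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$models)) args$models <- unlist(y$models)
  do.call(pipeline_config, args)
}

#' Run the full synthetic calibration study
#'
#' Executes the end-to-end sequence the assay follows on the bench: build
#' the 25-run design, realize concentrations, simulate mixture spectra,
#' slice the working window, split 15/10, calibrate PLS (latent variables by
#' leave-one-out cross-validation) and/or the linear network on the
#' calibration runs, predict the validation runs, and compute the
#' figures-of-merit report per model. With `out_dir` set, the design,
#' concentration and spectra CSVs, model JSONs and a JSON report are written
#' there, each carrying a provenance block with the seeds.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_config_yaml()]).
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_result` with elements `design`, `conc`,
#'   `spectra` (windowed), `split`, per-model fits (`pls`, `ann`), the
#'   chosen `pls_n_lv`, the `cv_curve`, and per-model `merit` reports.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  design <- stage("design", generate_design(length(config$ranges),
                                            factor_names = names(config$ranges)))
  conc <- stage("design", realize_concentrations(design, config$ranges))
  say("design: %d runs x %d factors", nrow(design), length(config$ranges))

  lib <- stage("simulate", default_library(config$library_seed))
  names(lib) <- names(config$ranges)
  spectra_full <- stage("simulate",
    simulate_mixtures(conc, lib, config$grid, config$noise,
                      sample_ids = paste0("run", design$run_id)))
  say("simulate: %d spectra x %d points", nrow(spectra_full$absorbance),
      config$grid$n_points)

  spectra <- stage("preprocess",
                   select_window(spectra_full, config$window[1], config$window[2]))
  say("preprocess: window %.1f-%.1f nm -> %d points",
      config$window[1], config$window[2], spectra$grid$n_points)

  split <- stage("split", split_runs(design, config$n_validation,
                                     seed = config$split_seed))
  cal <- split_indices(split, "calibration")
  val <- split_indices(split, "validation")
  X <- spectra$absorbance
  Y <- conc_to_matrix(conc)
  say("split: %d calibration / %d validation runs", length(cal), length(val))

  out <- list(config = config, design = design, conc = conc, split = split,
              spectra = spectra, library = lib)

  if ("pls" %in% config$models) {
    curve <- stage("pls", loo_curve(X[cal, ], Y[cal, ], a_max = config$pls_max_lv))
    n_lv <- select_n_lv(curve, config$pls_threshold_ratio)
    fit <- stage("pls", fit_pls(X[cal, ], Y[cal, ], n_lv = n_lv))
    pred <- predict(fit, X[val, ])
    out$cv_curve <- curve
    out$pls_n_lv <- n_lv
    out$pls <- fit
    out$merit_pls <- merit_report(pred, Y[val, ])
    say("pls: %d latent variables, validation RMSEP (pooled) %.4g",
        n_lv, sqrt(mean((pred - Y[val, ])^2)))
  }

  if ("ann" %in% config$models) {
    fit <- stage("ann", fit_ann(X[cal, ], Y[cal, ], preset = config$ann_preset,
                                seed = config$ann_seed))
    pred <- predict(fit, X[val, ])
    out$ann <- fit
    out$merit_ann <- merit_report(pred, Y[val, ])
    say("ann: %d-%d-%d network, validation RMSEP (pooled) %.4g",
        fit$config$n_in, fit$config$n_hidden, fit$config$n_out,
        sqrt(mean((pred - Y[val, ])^2)))
  }

  if (!is.null(config$out_dir)) {
    stage("write", write_pipeline_artifacts(out, config$out_dir))
    say("artifacts written to %s", config$out_dir)
  }
  class(out) <- "pipeline_result"
  out
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  provenance <- list(
    library_seed = cfg$library_seed, noise_seed = cfg$noise$seed,
    split_seed = cfg$split_seed, window = cfg$window,
    package_version = as.character(utils::packageVersion("specal"))
  )
  coded <- result$design
  utils::write.csv(coded, file.path(dir, "design_coded.csv"), row.names = FALSE)
  write_conc_csv(result$conc, file.path(dir, "design_concentrations.csv"))
  utils::write.csv(result$split, file.path(dir, "split.csv"), row.names = FALSE)
  write_spectra_csv(result$spectra, file.path(dir, "spectra_window.csv"))
  report <- list(schema_version = "1.0", provenance = provenance)
  if (!is.null(result$pls)) {
    save_model(result$pls, file.path(dir, "model_pls.json"), provenance)
    report$pls <- list(n_lv = result$pls_n_lv,
                       merit = as.data.frame(result$merit_pls))
  }
  if (!is.null(result$ann)) {
    save_model(result$ann, file.path(dir, "model_ann.json"), provenance)
    report$ann <- list(merit = as.data.frame(result$merit_ann))
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$pls_n_lv)) cat("  PLS latent variables:", x$pls_n_lv, "\n")
  for (m in c("pls", "ann")) {
    rep <- x[[paste0("merit_", m)]]
    if (!is.null(rep)) {
      cat(sprintf("  %s mean recoveries: %s\n", toupper(m),
                  paste(sprintf("%s %.1f%%", rep$component, rep$mean_recovery),
                        collapse = ", ")))
    }
  }
  invisible(x)
}
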