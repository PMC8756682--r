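# Orchestration of the full district workflow from one configuration:
# weights -> global Moran table -> LISA maps/counts -> three regressions ->
# AIC model comparison, with reproducibility metadata.

.config_defaults <- list(
  id_field = "unit_id",
  weights_scheme = "queen",
  standardize = TRUE,
  snap_tolerance = 1e-7,
  permutations = 999L,
  alpha = 0.05,
  seed = 42L,
  models = c("ols", "slm", "sem"),
  range_check = TRUE
)

.config_keys <- c("polygons", "attributes", "id_field", "outcome",
                  "covariates", "weights_scheme", "standardize",
                  "snap_tolerance", "permutations", "alpha", "seed",
                  "models", "out_dir", "range_check")

#' Validate a pipeline configuration
#'
#' Accepts a named list (or a YAML/JSON file path), fills defaults
#' (`permutations = 999`, `alpha = 0.05`, `weights_scheme = "queen"`,
#' `standardize = TRUE`, `models = ols, slm, sem`, `seed = 42`) and enforces
#' the invariants: the outcome is not among the covariates, `alpha` lies in
#' (0, 1), `permutations >= 19`, and no unknown keys are present.
#'
#' @param raw named list, or path to a YAML or JSON config file.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) {
    .assert(file.exists(raw), "config file not found: ", raw)
    raw <- if (grepl("\\.json$", raw, ignore.case = TRUE)) {
      jsonlite::fromJSON(raw, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(raw)
    }
  }
  .assert(is.list(raw), "config must be a named list or a file path")
  unknown <- setdiff(names(raw), .config_keys)
  .assert(length(unknown) == 0, "unknown config keys: ",
          paste(unknown, collapse = ", "))
  for (key in c("polygons", "attributes", "outcome", "covariates", "out_dir")) {
    .assert(!is.null(raw[[key]]), "config is missing required key '", key, "'")
  }
  cfg <- utils::modifyList(.config_defaults, raw)
  cfg$covariates <- as.character(cfg$covariates)
  .assert(length(cfg$covariates) >= 1, "at least one covariate is required")
  .assert(!(cfg$outcome %in% cfg$covariates),
          "outcome '", cfg$outcome, "' cannot be listed among the covariates")
  .assert(cfg$weights_scheme %in% c("queen", "shared_border"),
          "weights_scheme must be 'queen' or 'shared_border'")
  .assert(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
          "alpha must lie strictly in (0, 1)")
  .assert(cfg$permutations >= 19, "permutations must be >= 19")
  .assert(all(cfg$models %in% c("ols", "slm", "sem")),
          "models must be a subset of ols, slm, sem")
  .assert(length(cfg$models) >= 1, "at least one model is required")
  cfg$permutations <- as.integer(cfg$permutations)
  cfg$seed <- as.integer(cfg$seed)
  cfg <- cfg[.config_keys[.config_keys %in% names(cfg)]]
  structure(cfg, class = c("pipeline_config", "list"))
}

.stage <- function(name, expr, log) {
  log(sprintf("stage %s: start", name))
  out <- tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage %s failed: %s", name,
                                conditionMessage(e)),
                        class = c("sbaspatial_stage_error",
                                  "sbaspatial_error")))
  })
  log(sprintf("stage %s: done", name))
  out
}

# file-name-safe slug for a variable name
.slug <- function(x) {
  s <- gsub("[^A-Za-z0-9]+", "_", x)
  tolower(gsub("^_+|_+$", "", s))
}

#' Run the full district spatial-analysis pipeline
#'
#' Executes the whole workflow on one configuration: read and align polygons
#' and attributes; build (and optionally row-standardize) contiguity
#' weights and export them as GAL; compute the global Moran table (per
#' variable: univariate I and pseudo p, bivariate I against the outcome);
#' compute the outcome's univariate LISA and each covariate's bivariate LISA
#' against the outcome, exporting labelled GeoJSON layers and cluster
#' counts; fit the requested regression models and rank them by AIC. Every
#' stage draws its randomness from a seed derived from the master seed, so
#' reruns with identical config and inputs are byte-identical.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param quiet suppress progress messages?
#' @return list of class `pipeline_report` with `table1` (global Moran
#'   table), `lisa` (per-analysis file paths and cluster counts), `table2`
#'   (model comparison), `files`, and run `metadata`; also written to
#'   `report.json` in the output directory.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  log <- if (quiet) function(...) invisible() else
    function(msg) message("[sbaspatial] ", msg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  frame <- .stage("read_polygons",
                  read_polygons(cfg$polygons, cfg$id_field), log)
  table <- .stage("read_attributes", {
    tab <- read_attributes(cfg$attributes, cfg$id_field,
                           range_check = cfg$range_check)
    align_attributes(frame, tab)
  }, log)
  vars <- c(cfg$outcome, cfg$covariates)
  missing_v <- setdiff(vars, names(table))
  .assert(length(missing_v) == 0,
          "variables not in attribute table: ",
          paste(missing_v, collapse = ", "))

  weights <- .stage("weights", {
    Wb <- if (cfg$weights_scheme == "queen") {
      queen_adjacency(frame, cfg$snap_tolerance)
    } else {
      shared_border_adjacency(frame, cfg$snap_tolerance)
    }
    write_gal(Wb, file.path(cfg$out_dir, "weights.gal"))
    log(sprintf("  n = %d, links = %d, islands = %d", Wb$n,
                Matrix::nnzero(Wb$W), length(Wb$islands)))
    if (cfg$standardize) row_standardize(Wb) else Wb
  }, log)

  table1 <- .stage("global_moran", {
    rows <- lapply(vars, function(v) {
      uni <- global_moran(weights, table[[v]], variable = v,
                          permutations = cfg$permutations,
                          seed = .stage_seed(cfg$seed, paste0("moran_uni_", v)))
      if (v == cfg$outcome) {
        bi_stat <- NA_real_; bi_p <- NA_real_
      } else {
        bi <- global_moran_bivariate(
          weights, table[[cfg$outcome]], table[[v]],
          variable_x = cfg$outcome, variable_y = v,
          permutations = cfg$permutations,
          seed = .stage_seed(cfg$seed, paste0("moran_bi_", v)))
        bi_stat <- bi$statistic; bi_p <- bi$pseudo_p
      }
      data.frame(variable = v,
                 univariate_i = uni$statistic, univariate_p = uni$pseudo_p,
                 bivariate_i = bi_stat, bivariate_p = bi_p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    utils::write.csv(format(out, digits = 10),
                     file.path(cfg$out_dir, "table1.csv"), row.names = FALSE,
                     quote = FALSE)
    out
  }, log)

  lisa <- .stage("lisa", {
    analyses <- c(list(list(kind = "univariate", var = cfg$outcome)),
                  lapply(cfg$covariates, function(v)
                    list(kind = "bivariate", var = v)))
    counts <- list()
    paths <- character(0)
    for (a in analyses) {
      if (a$kind == "univariate") {
        st <- local_moran(weights, table[[a$var]], variable = a$var,
                          permutations = cfg$permutations,
                          seed = .stage_seed(cfg$seed, paste0("lisa_", a$var)),
                          alpha = cfg$alpha)
        fn <- sprintf("lisa_%s.geojson", .slug(a$var))
      } else {
        st <- local_moran_bivariate(
          weights, table[[cfg$outcome]], table[[a$var]],
          variable_x = cfg$outcome, variable_y = a$var,
          permutations = cfg$permutations,
          seed = .stage_seed(cfg$seed, paste0("bilisa_", a$var)),
          alpha = cfg$alpha)
        fn <- sprintf("lisa_%s_vs_%s.geojson", .slug(cfg$outcome),
                      .slug(a$var))
      }
      path <- file.path(cfg$out_dir, fn)
      write_lisa_geojson(frame, st, path)
      paths <- c(paths, path)
      counts[[length(counts) + 1L]] <-
        data.frame(analysis = if (a$kind == "univariate") a$var else
                     paste0(cfg$outcome, " vs ", a$var),
                   t(cluster_counts(st)), check.names = FALSE,
                   stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, counts)
    utils::write.csv(counts, file.path(cfg$out_dir, "cluster_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    list(files = paths, counts = counts)
  }, log)

  table2 <- .stage("regression", {
    design <- design_matrix(table, cfg$outcome, cfg$covariates)
    ev <- if (any(cfg$models %in% c("slm", "sem")))
      weights_eigenvalues(weights) else NULL
    fits <- lapply(cfg$models, function(m) switch(
      m,
      ols = fit_ols(design),
      slm = fit_spatial_lag(weights, design, ev = ev),
      sem = fit_spatial_error(weights, design, ev = ev)
    ))
    names(fits) <- cfg$models
    cmp <- if (length(fits) >= 2) compare_models(fits) else NULL
    # Table-2-shaped CSV: one row per predictor with (coef, p) per model,
    # then the spatial parameters, AIC, R2 and n
    coef_block <- do.call(cbind, lapply(cfg$models, function(m) {
      ct <- fits[[m]]$coefficients
      out <- data.frame(ct$estimate, ct$p_value)
      names(out) <- paste0(m, c("_coef", "_p"))
      out
    }))
    coef_block <- cbind(data.frame(predictor = fits[[1]]$coefficients$term,
                                   stringsAsFactors = FALSE), coef_block)
    extra <- data.frame(predictor = c("rho (SLM)", "lambda (SEM)", "AIC",
                                      "R2", "N"), stringsAsFactors = FALSE)
    for (m in cfg$models) {
      sp <- fits[[m]]$spatial_parameter
      extra[[paste0(m, "_coef")]] <- c(
        if (!is.null(sp) && sp$name == "delta") sp$estimate else NA_real_,
        if (!is.null(sp) && sp$name == "lambda") sp$estimate else NA_real_,
        fits[[m]]$aic, fits[[m]]$r2_measure$value, fits[[m]]$n)
      extra[[paste0(m, "_p")]] <- c(
        if (!is.null(sp) && sp$name == "delta") sp$p_value else NA_real_,
        if (!is.null(sp) && sp$name == "lambda") sp$p_value else NA_real_,
        NA_real_, NA_real_, NA_real_)
    }
    tab2 <- rbind(coef_block, extra)
    utils::write.csv(format(tab2, digits = 10),
                     file.path(cfg$out_dir, "table2.csv"),
                     row.names = FALSE, quote = FALSE)
    list(fits = fits, comparison = cmp, table = tab2)
  }, log)

  metadata <- list(
    package_version = as.character(utils::packageVersion("sbaspatial")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = .fnv1a(paste(utils::capture.output(utils::str(unclass(cfg))),
                               collapse = "\n")),
    n_units = n_units(frame),
    islands = length(weights$islands),
    timestamp = NA  # deliberately unset so reruns are byte-identical
  )
  report <- list(
    table1 = table1,
    lisa = lisa$counts,
    lisa_files = lisa$files,
    table2 = table2$table,
    comparison = if (!is.null(table2$comparison))
      as.data.frame(table2$comparison) else NULL,
    files = c(file.path(cfg$out_dir, c("weights.gal", "table1.csv",
                                       "cluster_counts.csv", "table2.csv")),
              lisa$files),
    metadata = metadata
  )
  jsonlite::write_json(report[c("table1", "lisa", "table2", "comparison",
                                "files", "metadata")],
                       file.path(cfg$out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  report$fits <- table2$fits
  structure(report, class = c("pipeline_report", "list"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> n = ", x$metadata$n_units, " units, seed = ",
      x$metadata$seed, "\n", sep = "")
  cat("  global Moran table: ", nrow(x$table1), " variables\n", sep = "")
  cat("  LISA layers: ", length(x$lisa_files), "\n", sep = "")
  if (!is.null(x$comparison)) {
    cat("  best model by AIC: ", x$comparison$model[1], " (AIC ",
        format(x$comparison$aic[1], digits = 6), ")\n", sep = "")
  }
  invisible(x)
}
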