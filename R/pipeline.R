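#' Pipeline configuration
#'
#' Everything the end-to-end pipeline needs beyond the data: the
#' distance-decay exponent and edge rule of the gravity stage, the policy
#' period splits (default: 2005-2007, 2008-2010, 2011-2014, 2015-2017),
#' the Moran permutation count, and the RNG seed.
#'
#' @param gravity_b distance-decay exponent (default 2).
#' @param sqrt_masses classical square-root gravity masses.
#' @param threshold_rule gravity edge rule (see [build_gravity_network()]).
#' @param splits list of stage year ranges; must partition the panel years
#'   when staged fits run.
#' @param n_perm Moran permutation count.
#' @param moran_variable panel variable tested for autocorrelation.
#' @param effects fixed-effects scheme for all model fits.
#' @param seed non-negative integer RNG seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gravity_b = 2, sqrt_masses = FALSE,
                            threshold_rule = "row-mean",
                            splits = list(c(2005, 2007), c(2008, 2010),
                                          c(2011, 2014), c(2015, 2017)),
                            n_perm = 999, moran_variable = "HC",
                            effects = "two_way", seed = 1) {
  stopifnot(gravity_b > 0, n_perm >= 0, seed >= 0)
  structure(list(gravity_b = gravity_b, sqrt_masses = sqrt_masses,
                 threshold_rule = threshold_rule, splits = splits,
                 n_perm = n_perm, moran_variable = moran_variable,
                 effects = effects, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Reproduces the analytical chain end to end: per-year gravity linkage
#' networks (when distances are available), the year-by-year Moran table,
#' the model-selection battery, the full-sample two-regime SDM fit with
#' its strategy verdict, and the staged fits. Stages are isolated: a
#' failing stage is recorded with its error and stages depending on it are
#' skipped with the same root cause, while independent stages still run.
#'
#' @param config a `pipeline_config`.
#' @param panel a `panel_data`.
#' @param adjacency two-column pair data frame (or path to adjacency CSV).
#' @param distances optional distance matrix or long table for the gravity
#'   stage; without it that stage is skipped with a reason.
#' @param out_dir optional directory; when given, every section is written
#'   there as JSON/CSV plus an `index.json`.
#' @return a `pipeline_report` list with sections `networks`, `moran`,
#'   `selection`, `full_fit`, `staged`, and `provenance`.
#' @export
run_pipeline <- function(config, panel, adjacency, distances = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(panel, "panel_data"))
  if (is.character(adjacency) && length(adjacency) == 1) {
    adjacency <- read_adjacency(adjacency)
  }
  report <- list(provenance = list(
    config = unclass(config), config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("smoglink")),
    n = length(panel$region_ids), years = range(panel$years)))
  skipped <- function(reason) list(skipped = TRUE, reason = reason)
  stage <- function(expr) {
    tryCatch(expr, error = function(e) skipped(conditionMessage(e)))
  }

  w <- stage(row_standardize(build_contiguity(adjacency, panel$region_ids)))
  w_failed <- is.list(w) && isTRUE(w$skipped)
  root <- if (w_failed) paste("weights stage failed:", w$reason) else NULL

  report$networks <- if (is.null(distances)) {
    skipped("no distance table supplied")
  } else {
    stage({
      nets <- lapply(seq_along(panel$years), function(t) {
        build_gravity_network(
          stats::setNames(panel$covariates$HC[, t], panel$region_ids),
          stats::setNames(panel$covariates$PG[, t], panel$region_ids),
          distances, year = panel$years[t],
          b = config$gravity_b, threshold_rule = config$threshold_rule,
          sqrt_masses = config$sqrt_masses)
      })
      list(networks = nets,
           metrics = lapply(nets, network_metrics),
           coordination = coordination_index(nets))
    })
  }

  report$moran <- if (w_failed) skipped(root) else stage(
    moran_by_year(panel, w, variable = config$moran_variable,
                  n_perm = config$n_perm, seed = config$seed))
  report$selection <- if (w_failed) skipped(root) else stage(
    model_selection_battery(panel, w, effects = config$effects))
  report$full_fit <- if (w_failed) skipped(root) else stage(
    fit_two_regime_sdm(panel, w, effects = config$effects))
  report$staged <- if (w_failed) skipped(root) else stage(
    staged_fit(panel, w, config$splits, effects = config$effects))

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report sections:\n")
  for (nm in setdiff(names(x), "provenance")) {
    sec <- x[[nm]]
    if (is.list(sec) && isTRUE(sec$skipped)) {
      cat(sprintf("  %-10s SKIPPED (%s)\n", nm, sec$reason))
    } else {
      cat(sprintf("  %-10s ok\n", nm))
    }
  }
  invisible(x)
}

# Serialize a pipeline report into a directory of JSON/CSV files.
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(provenance = report$provenance, files = list())
  put <- function(section, file, writer) {
    sec <- report[[section]]
    if (is.list(sec) && isTRUE(sec$skipped)) {
      index$files[[section]] <<- list(skipped = TRUE, reason = sec$reason)
    } else {
      writer(sec, file.path(out_dir, file))
      index$files[[section]] <<- file
    }
  }
  put("moran", "moran_by_year.csv",
      function(x, f) utils::write.csv(x, f, row.names = FALSE))
  put("full_fit", "full_fit.json", write_results)
  put("staged", "staged_summary.csv",
      function(x, f) utils::write.csv(x$summary, f, row.names = FALSE))
  if (!isTRUE(report$selection$skipped)) {
    sel <- report$selection
    tests <- c(sel$lm, list(lr_sdm_sar = sel$lr_sdm_sar,
                            wald_sdm_sar = sel$wald_sdm_sar,
                            hausman = sel$hausman))
    write_results(lapply(tests, results_payload),
                  file.path(out_dir, "selection_tests.json"))
    comp <- data.frame(
      model = names(sel$fits),
      loglik = vapply(sel$fits, function(f) f$loglik, numeric(1)),
      adj_r2 = vapply(sel$fits, function(f) f$adj_r2, numeric(1)))
    utils::write.csv(comp, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    index$files$selection <- c("selection_tests.json", "model_comparison.csv")
  } else {
    index$files$selection <- list(skipped = TRUE,
                                  reason = report$selection$reason)
  }
  if (!isTRUE(report$networks$skipped)) {
    for (net in report$networks$networks) {
      write_results(net, file.path(out_dir,
                                   sprintf("network_%s.csv", net$year)))
    }
    write_results(list(coordination = as.list(report$networks$coordination)),
                  file.path(out_dir, "coordination.json"))
    index$files$networks <- "network_<year>.csv + coordination.json"
  } else {
    index$files$networks <- list(skipped = TRUE,
                                 reason = report$networks$reason)
  }
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
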