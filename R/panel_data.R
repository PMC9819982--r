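# Canonical covariate order shared by every stage of the pipeline.
PANEL_COVARIATES <- c("HC", "PG", "PD", "ES", "URB", "IND")
PANEL_OUTCOME <- "RS"

#' Construct a balanced region-by-year panel
#'
#' `panel_data` is the spine of the pipeline: a balanced panel holding the
#' regulation-strength outcome (RS, the ratio of industrial added value to
#' industrial pollution-control investment projects) and six covariates --
#' haze concentration HC (annual mean PM2.5, ug/m3), per-capita GDP PG,
#' population density PD, energy strength ES, urbanization URB and
#' industrial structure IND (both fractions in [0, 1]).
#'
#' Regions are ordered lexicographically by id at construction and every
#' downstream matrix (spatial weights, regime indicators) shares that order.
#'
#' @param outcome numeric matrix `[n x T]` of RS values; rows are regions,
#'   columns are consecutive years.
#' @param covariates named list of six numeric `[n x T]` matrices, one per
#'   covariate in `HC, PG, PD, ES, URB, IND`.
#' @param region_ids character vector of n unique region identifiers.
#' @param years integer vector of T consecutive years.
#' @param validate if `TRUE` (default) stop on any invariant violation;
#'   see [validate_panel()] for the checks.
#' @return An object of class `panel_data`.
#' @seealso [load_panel()], [write_panel()], [validate_panel()]
#' @export
panel_data <- function(outcome, covariates, region_ids, years, validate = TRUE) {
  region_ids <- as.character(region_ids)
  years <- as.integer(years)
  ord <- order(region_ids)
  region_ids <- region_ids[ord]
  outcome <- as.matrix(outcome)[ord, , drop = FALSE]
  if (anyDuplicated(region_ids)) {
    stop("duplicate region ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  missing_cov <- setdiff(PANEL_COVARIATES, names(covariates))
  if (length(missing_cov)) {
    stop("missing covariates: ", paste(missing_cov, collapse = ", "))
  }
  covariates <- lapply(covariates[PANEL_COVARIATES],
                       function(m) as.matrix(m)[ord, , drop = FALSE])
  n <- length(region_ids)
  T_ <- length(years)
  dims_ok <- all(dim(outcome) == c(n, T_)) &&
    all(vapply(covariates, function(m) all(dim(m) == c(n, T_)), logical(1)))
  if (!dims_ok) stop("matrix dimensions do not match n regions x T years")
  dn <- list(region_ids, as.character(years))
  dimnames(outcome) <- dn
  covariates <- lapply(covariates, `dimnames<-`, dn)
  p <- structure(
    list(region_ids = region_ids, years = years,
         outcome = outcome, covariates = covariates),
    class = "panel_data")
  if (validate) {
    findings <- validate_panel(p)
    if (length(findings)) {
      stop("invalid panel:\n  ", paste(findings, collapse = "\n  "))
    }
  }
  p
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf("panel_data: %d regions x %d years (%d-%d)\n",
              length(x$region_ids), length(x$years),
              min(x$years), max(x$years)))
  cat("outcome: ", PANEL_OUTCOME, "; covariates: ",
      paste(names(x$covariates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.panel_data <- function(x) c(length(x$region_ids), length(x$years))

#' Validate panel invariants
#'
#' Checks every `panel_data` invariant and returns the violations as a
#' character vector of findings, one per violation -- it never throws on
#' finite numeric input. An empty vector means the panel is valid.
#'
#' Invariants: the panel is balanced with no missing values; years increase
#' in steps of 1; URB and IND lie in `[0, 1]`; HC, PG, PD and ES are
#' strictly positive.
#'
#' @param p a `panel_data` object.
#' @return character vector of findings (empty if valid).
#' @export
validate_panel <- function(p) {
  findings <- character(0)
  yrs <- p$years
  if (length(yrs) > 1 && !all(diff(yrs) == 1L)) {
    findings <- c(findings, "years are not consecutive (step 1)")
  }
  mats <- c(list(RS = p$outcome), p$covariates)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad)) {
      for (k in seq_len(nrow(bad))) {
        findings <- c(findings, sprintf(
          "%s missing/non-finite at region %s, year %s",
          nm, p$region_ids[bad[k, 1]], yrs[bad[k, 2]]))
      }
      next  # range checks on non-finite cells would duplicate findings
    }
    if (nm %in% c("URB", "IND")) {
      bad <- which(m < 0 | m > 1, arr.ind = TRUE)
      msg <- "%s out of [0,1] at region %s, year %s (value %g)"
    } else if (nm %in% c("HC", "PG", "PD", "ES")) {
      bad <- which(m <= 0, arr.ind = TRUE)
      msg <- "%s not strictly positive at region %s, year %s (value %g)"
    } else {
      bad <- matrix(integer(0), 0, 2)
    }
    if (nrow(bad)) {
      for (k in seq_len(nrow(bad))) {
        findings <- c(findings, sprintf(
          msg, nm, p$region_ids[bad[k, 1]], yrs[bad[k, 2]],
          m[bad[k, 1], bad[k, 2]]))
      }
    }
  }
  findings
}

#' Load a panel from a long-format CSV
#'
#' Reads a long CSV (one row per region-year) with columns
#' `region, year, RS, HC, PG, PD, ES, URB, IND` (or a caller-supplied
#' mapping onto those names) into a validated [panel_data()] object.
#' Rows are sorted by (region, year); the panel must be balanced.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(RS = "regulation")`.
#' @param log_transform if `TRUE`, apply `log()` to HC, PG, PD and ES after
#'   reading. Fractions URB/IND and the outcome are never transformed.
#' @return a validated `panel_data`.
#' @export
load_panel <- function(path, schema = NULL, log_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("region", "year", PANEL_OUTCOME, PANEL_COVARIATES)
  if (!is.null(schema)) {
    for (nm in names(schema)) {
      if (!schema[[nm]] %in% names(df)) {
        stop("schema error: mapped column '", schema[[nm]], "' not in file")
      }
      names(df)[names(df) == schema[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(canonical, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(canonical, c("region"))
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric '%s' in column %s at data row %d",
                   df[[nm]][bad[1]], nm, bad[1]))
    }
    df[[nm]] <- v
  }
  panel_from_long(df, log_transform = log_transform)
}

# Long data frame (region, year, RS, covariates) -> panel_data.
panel_from_long <- function(df, log_transform = FALSE) {
  df <- df[order(df$region, df$year), , drop = FALSE]
  regions <- sort(unique(as.character(df$region)))
  years <- sort(unique(as.integer(df$year)))
  full <- paste(rep(regions, each = length(years)),
                rep(years, times = length(regions)))
  have <- paste(df$region, df$year)
  missing_cells <- setdiff(full, have)
  if (length(missing_cells)) {
    stop("unbalanced panel: missing (region, year) cells: ",
         paste(missing_cells, collapse = "; "))
  }
  if (anyDuplicated(have)) {
    stop("duplicate (region, year) rows: ",
         paste(unique(have[duplicated(have)]), collapse = "; "))
  }
  to_mat <- function(v) {
    matrix(v[order(match(df$region, regions), df$year)],
           nrow = length(regions), ncol = length(years), byrow = TRUE)
  }
  covs <- lapply(stats::setNames(PANEL_COVARIATES, PANEL_COVARIATES),
                 function(nm) to_mat(df[[nm]]))
  if (log_transform) {
    for (nm in c("HC", "PG", "PD", "ES")) covs[[nm]] <- log(covs[[nm]])
    # logged series may be non-positive; re-validated as unconstrained below
    p <- panel_data(to_mat(df[[PANEL_OUTCOME]]), covs, regions, years,
                    validate = FALSE)
    attr(p, "log_transformed") <- TRUE
    return(p)
  }
  panel_data(to_mat(df[[PANEL_OUTCOME]]), covs, regions, years)
}

#' Convert a panel to a long data frame
#'
#' @param x a `panel_data`.
#' @param ... unused.
#' @return data frame with columns `region, year, RS, HC, PG, PD, ES, URB, IND`.
#' @export
as.data.frame.panel_data <- function(x, ...) {
  n <- length(x$region_ids); T_ <- length(x$years)
  df <- data.frame(
    region = rep(x$region_ids, each = T_),
    year = rep(x$years, times = n),
    RS = as.vector(t(x$outcome)),
    stringsAsFactors = FALSE)
  for (nm in names(x$covariates)) df[[nm]] <- as.vector(t(x$covariates[[nm]]))
  df
}

#' Write a panel to a long-format CSV
#'
#' Inverse of [load_panel()]: numeric cells are written with 17 significant
#' digits so a reload reproduces the in-memory panel to machine precision.
#'
#' @param p a `panel_data`.
#' @param path output CSV path (parent directory must exist).
#' @export
write_panel <- function(p, path) {
  df <- as.data.frame(p)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "year"
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a panel to a span of years
#'
#' @param p a `panel_data`.
#' @param years integer vector of years to keep (must be consecutive and
#'   present in the panel).
#' @return a `panel_data` covering only `years`.
#' @export
subset_years <- function(p, years) {
  years <- as.integer(years)
  if (!all(years %in% p$years)) {
    stop("years not in panel: ",
         paste(setdiff(years, p$years), collapse = ", "))
  }
  idx <- match(sort(years), p$years)
  panel_data(p$outcome[, idx, drop = FALSE],
             lapply(p$covariates, function(m) m[, idx, drop = FALSE]),
             p$region_ids, sort(years), validate = FALSE)
}
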