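#' Write a result artifact to disk
#'
#' One writer for every pipeline artifact. JSON is written with full
#' double precision so numeric fields survive a round trip to machine
#' precision; networks can also be exported as an edge-list CSV or
#' GraphML (via igraph).
#'
#' @param x a `moran_result`, `gravity_network`, fit object, test result,
#'   data frame, or plain list.
#' @param path output file path (parent directory must exist).
#' @param format `"json"`, `"csv"` or `"graphml"`; the default is inferred
#'   from the file extension.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!nzchar(format)) format <- "json"
  }
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  if (!format %in% c("json", "csv", "graphml")) {
    stop("unsupported format: ", format)
  }
  if (format == "graphml") {
    if (!inherits(x, "gravity_network")) {
      stop("graphml export is only defined for gravity networks")
    }
    igraph::write_graph(as_igraph(x), path, format = "graphml")
    return(invisible(path))
  }
  if (format == "csv") {
    df <- if (inherits(x, "gravity_network")) {
      e <- x$edges[x$edges$retained, c("src", "dst", "year", "T")]
      names(e) <- c("src", "dst", "year", "T_ij")
      e
    } else if (is.data.frame(x)) {
      x
    } else if (inherits(x, "staged_fit")) {
      x$summary
    } else {
      stop("csv export not defined for class ", paste(class(x), collapse = "/"))
    }
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(results_payload(x), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

# Flatten result objects into plain lists for JSON.
results_payload <- function(x) {
  if (inherits(x, "moran_result")) {
    out <- list(I = x$I, expected_I = x$expected_I, z = x$z,
                p_normal = x$p_normal, n = x$n)
    out$p_perm <- if (is.null(x$p_perm)) NULL else x$p_perm
    out$n_perm <- x$n_perm
    return(out)
  }
  if (inherits(x, "two_regime_sdm_fit")) {
    return(list(model = x$model, rho1 = x$rho1, rho2 = x$rho2,
                sigma2 = x$sigma2, loglik = x$loglik, adj_r2 = x$adj_r2,
                n = x$n, T = x$T, effects = x$effects,
                converged = x$converged,
                verdict = list(label = x$verdict$label,
                               rho_ratio = x$verdict$rho_ratio,
                               wald_equal_p = x$verdict$wald_equal_p),
                coefficients = x$coef_table))
  }
  if (inherits(x, "sdm_fit")) {
    return(list(model = x$model,
                rho = if (is.null(x$rho)) NULL else as.list(x$rho),
                sigma2 = x$sigma2, loglik = x$loglik, adj_r2 = x$adj_r2,
                coefficients = x$coef_table))
  }
  if (inherits(x, "spec_test_result")) {
    return(list(name = x$name, statistic = x$statistic, df = x$df,
                p = x$p, note = x$note))
  }
  if (inherits(x, "gravity_network")) {
    return(list(year = x$year, regions = x$regions, edges = x$edges))
  }
  if (inherits(x, "strategy_verdict")) {
    return(list(label = x$label, rho_ratio = x$rho_ratio,
                wald_equal_p = x$wald_equal_p,
                rho1 = x$rho1, rho2 = x$rho2))
  }
  if (inherits(x, "staged_fit")) {
    return(list(summary = x$summary,
                stages = lapply(x$fits, results_payload)))
  }
  if (is.list(x)) {
    cls <- class(x)
    if (!identical(cls, "list") && !identical(cls, "data.frame")) {
      x <- unclass(x)
    }
    if (is.data.frame(x)) return(x)
    return(lapply(x, function(el)
      if (is.list(el) || !is.null(attr(el, "class"))) results_payload(el)
      else el))
  }
  x
}

#' Read a JSON results file
#' @param path JSON path written by [write_results()].
#' @return a list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
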