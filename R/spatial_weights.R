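#' Spatial weight matrices
#'
#' A `spatial_weights` object wraps an n x n non-negative matrix `w` with a
#' zero diagonal, tied to the same lexicographic region order as
#' [panel_data()]. Two schemes are supported: binary first-order contiguity
#' (the main-analysis choice) and inverse-distance decay (a robustness
#' variant). Isolated units are an error: every row must have at least one
#' positive entry, because a region with no neighbours has an undefined
#' spatial lag.
#'
#' @name spatial_weights
NULL

new_spatial_weights <- function(w, scheme, standardized = FALSE) {
  structure(list(w = w, scheme = scheme, standardized = standardized),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d regions, scheme=%s, %s\n",
              nrow(x$w), x$scheme,
              if (x$standardized) "row-standardized" else "unstandardized"))
  invisible(x)
}

check_no_isolates <- function(w, regions) {
  deg <- rowSums(w > 0)
  if (any(deg == 0)) {
    iso <- regions[deg == 0]
    if (length(iso) == length(regions)) iso <- "all"
    stop("isolated units: ", paste(iso, collapse = ", "))
  }
}

#' Binary contiguity weights from an adjacency list
#'
#' Builds the symmetric 0/1 first-order contiguity matrix: `w[i, j] = 1`
#' iff regions i and j appear as a pair in the adjacency list. The matrix
#' is returned unstandardized; use [row_standardize()] before estimation.
#'
#' @param adjacency two-column object (data frame or matrix) of region-id
#'   pairs, or a character matrix; order within a pair does not matter.
#' @param regions ordered character vector of all region ids (the panel's
#'   region order).
#' @return an unstandardized `spatial_weights` with scheme `"contiguity"`.
#' @export
build_contiguity <- function(adjacency, regions) {
  regions <- as.character(regions)
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) < 2) stop("adjacency must have two columns")
  a <- as.character(adjacency[, 1]); b <- as.character(adjacency[, 2])
  unknown <- setdiff(c(a, b), regions)
  if (length(unknown)) {
    stop("unknown region id in adjacency: ", paste(unknown, collapse = ", "))
  }
  if (any(a == b)) {
    stop("self-pair in adjacency: ", paste(unique(a[a == b]), collapse = ", "))
  }
  n <- length(regions)
  w <- matrix(0, n, n, dimnames = list(regions, regions))
  w[cbind(match(a, regions), match(b, regions))] <- 1
  w[cbind(match(b, regions), match(a, regions))] <- 1
  check_no_isolates(w, regions)
  new_spatial_weights(w, "contiguity")
}

#' Inverse-distance weights
#'
#' `w[i, j] = d[i, j]^(-power)` for off-diagonal pairs with
#' `d[i, j] <= cutoff`, zero beyond the cutoff.
#'
#' @param distances symmetric numeric matrix of pairwise distances (km) with
#'   region-id dimnames, or a three-column data frame
#'   `region_a, region_b, km`.
#' @param regions ordered character vector of region ids.
#' @param power positive decay exponent (default 2).
#' @param cutoff distance beyond which weights are zero, or `NULL` for none.
#' @return an unstandardized `spatial_weights` with scheme
#'   `"inverse_distance"`.
#' @export
build_inverse_distance <- function(distances, regions, power = 2, cutoff = NULL) {
  regions <- as.character(regions)
  d <- as_distance_matrix(distances, regions)
  off <- row(d) != col(d)
  if (any(d[off] <= 0)) stop("zero or negative distance between distinct regions")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  w <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  keep <- off & (if (is.null(cutoff)) TRUE else d <= cutoff)
  w[keep] <- d[keep]^(-power)
  check_no_isolates(w, regions)
  new_spatial_weights(w, "inverse_distance")
}

# Accept either a dense matrix or a long (region_a, region_b, km) table.
as_distance_matrix <- function(distances, regions) {
  if (is.matrix(distances)) {
    d <- distances
    if (is.null(dimnames(d))) dimnames(d) <- list(regions, regions)
    d <- d[regions, regions]
    return(d)
  }
  df <- as.data.frame(distances)
  if (ncol(df) < 3) stop("distance table needs columns region_a, region_b, km")
  n <- length(regions)
  d <- matrix(NA_real_, n, n, dimnames = list(regions, regions))
  diag(d) <- 0
  ia <- match(as.character(df[[1]]), regions)
  ib <- match(as.character(df[[2]]), regions)
  if (anyNA(ia) || anyNA(ib)) stop("unknown region id in distance table")
  d[cbind(ia, ib)] <- df[[3]]
  d[cbind(ib, ia)] <- df[[3]]
  if (anyNA(d)) stop("distance table does not cover all region pairs")
  d
}

#' Row-standardize a weight matrix
#'
#' Divides each row by its sum so rows sum to one and the spatial lag `Wx`
#' is a neighbour average. Idempotent; errors on a zero row.
#'
#' @param w a `spatial_weights`.
#' @return the row-standardized `spatial_weights`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  rs <- rowSums(w$w)
  if (any(rs == 0)) {
    stop("cannot row-standardize: zero row for ",
         paste(rownames(w$w)[rs == 0], collapse = ", "))
  }
  new_spatial_weights(w$w / rs, w$scheme, standardized = TRUE)
}

#' Ring adjacency for n regions
#'
#' Convenience generator used by simulations: region i borders i-1 and i+1
#' with wrap-around, giving a connected graph with a known spectrum.
#'
#' @param n number of regions (>= 3).
#' @param ids optional region ids; default `R01..Rn`.
#' @return a two-column data frame of adjacent pairs.
#' @export
ring_adjacency <- function(n, ids = NULL) {
  stopifnot(n >= 3)
  if (is.null(ids)) ids <- sprintf("R%02d", seq_len(n))
  data.frame(region_a = ids, region_b = ids[c(2:n, 1)],
             stringsAsFactors = FALSE)
}

#' Rook-contiguity adjacency on an nr x nc grid
#'
#' A 5 x 6 grid approximates the spatial layout of ~30 provinces while
#' remaining fully reproducible.
#'
#' @param nr,nc grid dimensions.
#' @param ids optional region ids in row-major grid order.
#' @return a two-column data frame of adjacent pairs.
#' @export
grid_adjacency <- function(nr, nc, ids = NULL) {
  n <- nr * nc
  if (is.null(ids)) ids <- sprintf("R%02d", seq_len(n))
  at <- function(r, c) ids[(r - 1) * nc + c]
  pairs <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) pairs[[length(pairs) + 1]] <- c(at(r, c), at(r, c + 1))
    if (r < nr) pairs[[length(pairs) + 1]] <- c(at(r, c), at(r + 1, c))
  }
  m <- do.call(rbind, pairs)
  data.frame(region_a = m[, 1], region_b = m[, 2], stringsAsFactors = FALSE)
}

#' Read an adjacency CSV (`region_a,region_b`)
#' @param path CSV path.
#' @return two-column data frame of pairs.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("adjacency CSV needs two columns")
  df[, 1:2]
}

#' Write weights as a dense CSV with region-id header row and column
#' @param w a `spatial_weights`.
#' @param path output path.
#' @export
write_weights <- function(w, path) {
  m <- w$w
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Spatial lag of an n-vector or n x T matrix.
spatial_lag <- function(w, x) {
  if (inherits(w, "spatial_weights")) w <- w$w
  w %*% as.matrix(x)
}
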