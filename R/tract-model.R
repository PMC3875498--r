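#' @useDynLib tractclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble as_tibble
#' @importFrom stats approx dist median sd rnorm runif setNames spline
#' @importFrom utils head tail
NULL

# A tract is an n x 3 numeric matrix of points in mm world coordinates,
# ordered along the streamline. A tract dataset is a list of such matrices
# with dense integer ids 0..N-1 (the convention used by the on-disk formats).

#' Construct a streamline dataset
#'
#' Bundles a list of streamlines ("tracts") into a dataset object. Each tract
#' is an ordered polyline of at least two points in mm world coordinates.
#' Consecutive duplicate points (zero-length segments) are collapsed on
#' construction; tracts with fewer than two distinct points are rejected.
#'
#' @param tracts List of numeric matrices, each with 3 columns (x, y, z in mm)
#'   and at least 2 rows.
#' @param space Free-text label for the coordinate space (e.g. `"native"`,
#'   `"atlas"`).
#' @param provenance Optional list describing the source (path, format).
#' @return An object of class `tract_dataset`: a list with elements `tracts`
#'   (list of matrices), `space` and `provenance`. Tract ids are dense
#'   integers `0..N-1`, id `i` being `tracts[[i + 1]]`.
#' @export
tract_dataset <- function(tracts, space = "native", provenance = NULL) {
  stopifnot(is.list(tracts))
  tracts <- lapply(tracts, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("each tract must have 3 coordinate columns")
    storage.mode(p) <- "double"
    if (!all(is.finite(p))) stop("tract coordinates must be finite")
    p <- collapse_duplicate_points(p)
    if (nrow(p) < 2L) stop("a tract needs at least two distinct points")
    dimnames(p) <- list(NULL, c("x", "y", "z"))
    p
  })
  structure(
    list(tracts = tracts, space = space, provenance = provenance),
    class = "tract_dataset"
  )
}

collapse_duplicate_points <- function(p) {
  if (nrow(p) < 2L) return(p)
  keep <- c(TRUE, rowSums(abs(p[-1L, , drop = FALSE] -
                                p[-nrow(p), , drop = FALSE])) > 0)
  p[keep, , drop = FALSE]
}

#' @export
print.tract_dataset <- function(x, ...) {
  np <- sum(vapply(x$tracts, nrow, integer(1)))
  cat(sprintf("<tract_dataset> %d tracts, %d points, space '%s'\n",
              length(x$tracts), np, x$space))
  invisible(x)
}

#' @export
length.tract_dataset <- function(x) length(x$tracts)

#' Number of tracts in a dataset
#' @param dataset A `tract_dataset`.
#' @return Integer count.
#' @export
n_tracts <- function(dataset) length(dataset$tracts)

#' Subset a tract dataset by 0-based tract ids
#'
#' @param dataset A `tract_dataset`.
#' @param ids Integer vector of 0-based tract ids.
#' @return A new `tract_dataset` whose tracts are re-indexed densely from 0.
#' @export
subset_tracts <- function(dataset, ids) {
  stopifnot(all(ids >= 0), all(ids < n_tracts(dataset)))
  tract_dataset(dataset$tracts[ids + 1L], space = dataset$space,
                provenance = dataset$provenance)
}

#' Convert a tract dataset to a tidy point table
#'
#' @param x A `tract_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `tract_id` (0-based), `point` (1-based index
#'   along the tract), `x`, `y`, `z` (mm).
#' @export
as_tibble.tract_dataset <- function(x, ...) {
  n <- vapply(x$tracts, nrow, integer(1))
  pts <- do.call(rbind, x$tracts)
  tibble::tibble(
    tract_id = rep(seq_along(x$tracts) - 1L, n),
    point = unlist(lapply(n, seq_len), use.names = FALSE),
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
}

#' Build a tract dataset from a tidy point table
#'
#' Inverse of [as_tibble.tract_dataset()]: rows are grouped by `tract_id` and
#' ordered by appearance (or by a `point` column when present).
#'
#' @param tbl Data frame with columns `tract_id`, `x`, `y`, `z`.
#' @param space,provenance Passed to [tract_dataset()].
#' @return A `tract_dataset`.
#' @export
as_tract_dataset <- function(tbl, space = "native", provenance = NULL) {
  stopifnot(all(c("tract_id", "x", "y", "z") %in% names(tbl)))
  if ("point" %in% names(tbl)) tbl <- tbl[order(tbl$tract_id, tbl$point), ]
  split_idx <- split(seq_len(nrow(tbl)), tbl$tract_id)
  tracts <- lapply(split_idx, function(i)
    cbind(x = tbl$x[i], y = tbl$y[i], z = tbl$z[i]))
  tract_dataset(unname(tracts), space = space, provenance = provenance)
}

# ---- geometry primitives ---------------------------------------------------

#' Arc length of a tract
#'
#' Sum of the Euclidean lengths of all polyline segments, in mm.
#'
#' @param t Tract matrix (n x 3, mm).
#' @return Length in mm (> 0 for a valid tract).
#' @export
tract_length <- function(t) {
  sum(segment_lengths(t))
}

segment_lengths <- function(t) {
  d <- t[-1L, , drop = FALSE] - t[-nrow(t), , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Length-weighted centroid of a tract
#'
#' The centroid is the centre of gravity of the polyline: the average of all
#' segment midpoints weighted by segment length. Unlike the plain mean of the
#' points it is invariant to uneven point spacing along the same geometry.
#'
#' @param t Tract matrix (n x 3, mm).
#' @return Numeric length-3 point (mm).
#' @export
tract_centroid <- function(t) {
  w <- segment_lengths(t)
  L <- sum(w)
  if (L <= 0) stop("tract has zero length; cannot form a centroid")
  mids <- (t[-1L, , drop = FALSE] + t[-nrow(t), , drop = FALSE]) / 2
  colSums(mids * w) / L
}

#' Endpoint orientation of a tract
#'
#' Unit vector from the first to the last point. For closed loops (coincident
#' endpoints) the orientation is degenerate; by default this is an error, but
#' `fallback = TRUE` substitutes the first-to-middle-point direction (logged),
#' which keeps orientation-based measures defined for looping streamlines.
#'
#' @param t Tract matrix (n x 3, mm).
#' @param fallback Use the first-to-middle-point vector for closed loops.
#' @return Unit length-3 vector.
#' @export
endpoint_orientation <- function(t, fallback = FALSE) {
  v <- t[nrow(t), ] - t[1L, ]
  nv <- sqrt(sum(v * v))
  if (nv == 0) {
    if (!fallback)
      stop("degenerate orientation: tract endpoints coincide")
    message("closed-loop tract: falling back to first-to-middle orientation")
    mid <- t[max(2L, ceiling(nrow(t) / 2)), ]
    v <- mid - t[1L, ]
    nv <- sqrt(sum(v * v))
    if (nv == 0) stop("degenerate orientation: no usable direction")
  }
  v / nv
}

#' Resample a tract to equally spaced points
#'
#' Linear interpolation along the polyline at `n` arc-length-uniform
#' positions. Endpoints are preserved exactly.
#'
#' @param t Tract matrix (n x 3, mm).
#' @param n Number of output points (>= 2).
#' @return An `n` x 3 tract matrix.
#' @export
resample_tract <- function(t, n) {
  if (n < 2L) stop("n must be >= 2")
  s <- c(0, cumsum(segment_lengths(t)))
  target <- seq(0, s[length(s)], length.out = n)
  out <- cbind(
    x = approx(s, t[, 1], xout = target)$y,
    y = approx(s, t[, 2], xout = target)$y,
    z = approx(s, t[, 3], xout = target)$y
  )
  out[1L, ] <- t[1L, ]
  out[n, ] <- t[nrow(t), ]
  out
}

#' Centroids of all tracts in a dataset
#' @param dataset A `tract_dataset`.
#' @return N x 3 matrix of centroids (mm), row i for tract id i-1.
#' @export
tract_centroids <- function(dataset) {
  do.call(rbind, lapply(dataset$tracts, tract_centroid))
}

#' Lengths of all tracts in a dataset
#' @param dataset A `tract_dataset`.
#' @return Numeric vector of lengths (mm).
#' @export
tract_lengths <- function(dataset) {
  vapply(dataset$tracts, tract_length, numeric(1))
}
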