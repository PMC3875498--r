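# Streamline similarity measures. Every measure is a distance function in
# the weak sense used throughout the package: symmetric, nonnegative and
# reflexive (d(a, a) = 0); the triangle inequality is not required.

#' Tract centroid distance (TCD)
#'
#' Euclidean distance in mm between the length-weighted centroids of the two
#' tracts.
#'
#' @param a,b Tract matrices (n x 3, mm).
#' @return Distance in mm.
#' @export
tcd <- function(a, b) {
  d <- tract_centroid(a) - tract_centroid(b)
  sqrt(sum(d * d))
}

#' Tract orientation similarity (TOS)
#'
#' Angular distance in degrees between the endpoint-orientation vectors of
#' the two tracts, in \[0, 180\].
#'
#' @param a,b Tract matrices (n x 3, mm).
#' @param fallback Passed to [endpoint_orientation()] for closed loops.
#' @return Angle in degrees.
#' @export
tos <- function(a, b, fallback = FALSE) {
  va <- endpoint_orientation(a, fallback = fallback)
  vb <- endpoint_orientation(b, fallback = fallback)
  acos(max(-1, min(1, sum(va * vb)))) * 180 / pi
}

#' Two-sided Hausdorff distance (HD)
#'
#' Maximum over both directions of the largest point-to-nearest-point
#' distance between the two tracts' vertex sets.
#'
#' @param a,b Tract matrices (n x 3, mm).
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b) {
  cpp_hausdorff(a, b)
}

#' Partial tract matching
#'
#' Supports the combined distance measure's handling of incomplete tracts.
#' Both tracts are resampled to `n_resample` arc-length-uniform points; the
#' pair of points (one per tract) with minimal Euclidean distance anchors the
#' match, and sub-tracts of equal arc length are sliced out around the
#' anchors, extending toward both tract ends for the smaller of the two
#' remaining arc lengths on each side.
#'
#' @param a,b Tract matrices (n x 3, mm).
#' @param n_resample Resampling point count (>= 2), default 20.
#' @return A `subtract_pair`: list with `sub_a`, `sub_b` (fragment matrices),
#'   `anchor` (pair of 1-based point indices) and `anchor_dist` (mm).
#' @export
partial_match <- function(a, b, n_resample = 20) {
  if (n_resample < 2L) stop("n_resample must be >= 2")
  ra <- resample_tract(a, n_resample)
  rb <- resample_tract(b, n_resample)
  d2 <- outer(rowSums(ra^2), rowSums(rb^2), "+") - 2 * ra %*% t(rb)
  d2[d2 < 0] <- 0
  # argmin with ties broken toward the lowest a-index, then lowest b-index
  flat <- which(d2 == min(d2))
  ij <- arrayInd(flat, dim(d2))
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
  i <- ij[1]; j <- ij[2]
  step_a <- tract_length(a) / (n_resample - 1)
  step_b <- tract_length(b) / (n_resample - 1)
  l_left <- min((i - 1) * step_a, (j - 1) * step_b)
  l_right <- min((n_resample - i) * step_a, (n_resample - j) * step_b)
  slice <- function(r, anchor, step) {
    lo <- anchor - floor(l_left / step + 1e-9)
    hi <- anchor + floor(l_right / step + 1e-9)
    r[lo:hi, , drop = FALSE]
  }
  structure(
    list(sub_a = slice(ra, i, step_a), sub_b = slice(rb, j, step_b),
         anchor = c(i, j), anchor_dist = sqrt(d2[i, j])),
    class = "subtract_pair"
  )
}

#' Shape dissimilarity of two matched tract fragments
#'
#' Translation- and rotation-invariant comparison of fragment shapes: both
#' fragments are resampled to a common point count and described by their
#' sequences of turning angles (the angle between successive segment
#' directions); the distance is the mean absolute angle difference scaled to
#' \[0, 1\]. Congruent fragments (rigid-motion copies) score 0.
#'
#' @param p A `subtract_pair` from [partial_match()].
#' @param n_points Common resampling count for the comparison (default 20).
#' @return Dimensionless dissimilarity in \[0, 1\].
#' @export
shape_distance <- function(p, n_points = 20) {
  stopifnot(inherits(p, "subtract_pair"))
  if (nrow(p$sub_a) < 3L || nrow(p$sub_b) < 3L) {
    warning("fragment with fewer than 3 points: shape distance undefined, using 0")
    return(0)
  }
  ta <- turning_angles(resample_tract(p$sub_a, n_points))
  tb <- turning_angles(resample_tract(p$sub_b, n_points))
  mean(abs(ta - tb)) / 180
}

turning_angles <- function(t) {
  d <- t[-1L, , drop = FALSE] - t[-nrow(t), , drop = FALSE]
  u <- d / pmax(sqrt(rowSums(d * d)), .Machine$double.eps)
  dots <- rowSums(u[-1L, , drop = FALSE] * u[-nrow(u), , drop = FALSE])
  acos(pmax(-1, pmin(1, dots))) * 180 / pi
}

#' Combined distance measure (CD)
#'
#' Weighted sum of four normalized components: centroid distance, endpoint
#' orientation angle, centroid distance of the partially matched sub-tracts
#' and fragment shape dissimilarity. The mm-valued components are mapped into
#' \[0, 1\] with the bounded map `d / (d + c)` (scale constants
#' `norm_consts`), the angle with `angle / 180`, and the shape term is
#' already dimensionless. To account for reversed streamlines the one-sided
#' value is computed against `b` and against reversed `b`, and the minimum is
#' returned, so a tract and its reversal are at distance 0.
#'
#' @param a,b Tract matrices (n x 3, mm).
#' @param weights Nonnegative weights for (tcd, tos, partial-tcd, shape);
#'   default all 1. The result is the weighted mean of the components.
#' @param norm_consts Positive scale constants, mm: `c(tcd = 20, partial = 10)`.
#' @param n_resample Resampling count for the partial matching.
#' @return Dimensionless distance in \[0, 1\].
#' @export
combined_distance <- function(a, b, weights = c(1, 1, 1, 1),
                              norm_consts = c(tcd = 20, partial = 10),
                              n_resample = 20) {
  stopifnot(length(weights) == 4L, all(weights >= 0), sum(weights) > 0,
            all(norm_consts > 0))
  min(cd_one_sided(a, b, weights, norm_consts, n_resample),
      cd_one_sided(a, b[nrow(b):1, , drop = FALSE], weights, norm_consts,
                   n_resample))
}

cd_one_sided <- function(a, b, weights, norm_consts, n_resample) {
  bounded <- function(d, c) d / (d + c)
  p <- partial_match(a, b, n_resample)
  comp <- c(
    bounded(tcd(a, b), norm_consts[[1]]),
    tos(a, b, fallback = TRUE) / 180,
    bounded(fragment_tcd(p), norm_consts[[2]]),
    suppressWarnings(shape_distance(p))
  )
  sum(weights * comp) / sum(weights)
}

fragment_tcd <- function(p) {
  ca <- if (nrow(p$sub_a) >= 2L) tract_centroid(p$sub_a) else p$sub_a[1L, ]
  cb <- if (nrow(p$sub_b) >= 2L) tract_centroid(p$sub_b) else p$sub_b[1L, ]
  sqrt(sum((ca - cb)^2))
}

# ---- the precomputed triangular similarity matrix --------------------------

#' Compute the pairwise similarity matrix for a streamline sample
#'
#' Precomputes all pairwise distances once, so that clustering, Local Outlier
#' Factors and representative selection reuse them without recomputation.
#' The lower triangle is computed in contiguous row blocks, one worker per
#' block; since every entry is a pure function of the two tracts, the result
#' is bit-identical for any worker count.
#'
#' @param sample A [tract_dataset()] (the sampled tracts).
#' @param measure One of `"tcd"`, `"tos"`, `"hd"`, `"cd"`.
#' @param n_workers Number of parallel workers for row blocks (default 1).
#' @param cd_opts List of options for the combined distance
#'   (`weights`, `norm_consts`, `n_resample`); see [combined_distance()].
#' @return A `tract_simmat`: a dense symmetric `n x n` matrix of distances
#'   with attributes `measure` and zero diagonal.
#' @export
compute_similarity_matrix <- function(sample, measure = c("hd", "tcd", "tos", "cd"),
                                      n_workers = 1L, cd_opts = list()) {
  stopifnot(inherits(sample, "tract_dataset"), n_tracts(sample) >= 1L)
  measure <- match.arg(measure)
  n <- n_tracts(sample)
  m <- matrix(0, n, n)
  if (n > 1L) {
    rows <- 2:n
    blocks <- row_blocks(rows, n_workers)
    compute_block <- function(block) sim_rows(sample, measure, block, cd_opts)
    res <- if (n_workers > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(blocks, compute_block, mc.cores = n_workers)
    } else {
      lapply(blocks, compute_block)
    }
    for (b in seq_along(blocks)) {
      for (r in seq_along(blocks[[b]])) {
        i <- blocks[[b]][r]
        vals <- res[[b]][[r]]
        m[i, 1:(i - 1)] <- vals
        m[1:(i - 1), i] <- vals
      }
    }
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite ", measure, " distance for tract pair (",
         bad[1, 1] - 1L, ", ", bad[1, 2] - 1L, ")")
  structure(m, measure = measure, class = c("tract_simmat", "matrix", "array"))
}

# Split rows of the lower triangle into contiguous blocks with approximately
# balanced work (row i holds i-1 entries).
row_blocks <- function(rows, n_workers) {
  n_workers <- max(1L, min(as.integer(n_workers), length(rows)))
  work <- cumsum(rows - 1)
  cut_at <- work[length(work)] * seq_len(n_workers) / n_workers
  grp <- findInterval(work, cut_at, left.open = TRUE) + 1L
  grp <- pmin(grp, n_workers)
  unname(split(rows, grp))
}

sim_rows <- function(sample, measure, rows, cd_opts) {
  if (measure == "hd") return(cpp_hd_rows(sample$tracts, as.integer(rows)))
  if (measure == "tcd") {
    cents <- tract_centroids(sample)
    return(lapply(rows, function(i) {
      d <- sweep(cents[1:(i - 1), , drop = FALSE], 2, cents[i, ])
      sqrt(rowSums(d * d))
    }))
  }
  if (measure == "tos") {
    vs <- do.call(rbind, lapply(sample$tracts, endpoint_orientation,
                                fallback = TRUE))
    return(lapply(rows, function(i) {
      dots <- vs[1:(i - 1), , drop = FALSE] %*% vs[i, ]
      acos(pmax(-1, pmin(1, dots[, 1]))) * 180 / pi
    }))
  }
  # cd
  args <- utils::modifyList(
    list(weights = c(1, 1, 1, 1), norm_consts = c(tcd = 20, partial = 10),
         n_resample = 20), cd_opts)
  lapply(rows, function(i) {
    vapply(1:(i - 1), function(j)
      combined_distance(sample$tracts[[i]], sample$tracts[[j]],
                        weights = args$weights, norm_consts = args$norm_consts,
                        n_resample = args$n_resample),
      numeric(1))
  })
}

#' Save / load a similarity matrix
#'
#' The matrix is persisted as a flat little-endian binary file of doubles
#' (lower triangle, row by row) with a JSON sidecar recording `n`, the
#' measure tag and an MD5 checksum of the binary payload.
#'
#' @param m A `tract_simmat`.
#' @param path Path for the binary file; the sidecar is `<path>.json`.
#' @return `path` (save) or the reconstructed `tract_simmat` (load).
#' @export
save_simmat <- function(m, path) {
  stopifnot(inherits(m, "tract_simmat"))
  n <- nrow(m)
  vals <- m[lower.tri(m)]
  con <- file(path, "wb")
  writeBin(as.double(vals), con, size = 8, endian = "little")
  close(con)
  sidecar <- list(n = n, measure = attr(m, "measure"),
                  checksum = unname(tools::md5sum(path)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_simmat
#' @export
load_simmat <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(unname(tools::md5sum(path)), meta$checksum))
    stop("similarity matrix checksum mismatch for '", path, "'")
  n <- meta$n
  con <- file(path, "rb")
  vals <- readBin(con, "double", n * (n - 1) / 2, size = 8, endian = "little")
  close(con)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vals
  m <- m + t(m)
  structure(m, measure = meta$measure,
            class = c("tract_simmat", "matrix", "array"))
}

#' Evaluate one pairwise distance by measure tag
#'
#' @param a,b Tract matrices.
#' @param measure One of `"tcd"`, `"tos"`, `"hd"`, `"cd"`.
#' @param cd_opts Options for the combined distance.
#' @return The distance.
#' @export
pair_distance <- function(a, b, measure, cd_opts = list()) {
  switch(measure,
    tcd = tcd(a, b),
    tos = tos(a, b, fallback = TRUE),
    hd = hausdorff(a, b),
    cd = do.call(combined_distance, c(list(a = a, b = b), cd_opts)),
    stop("unknown measure '", measure, "'")
  )
}
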