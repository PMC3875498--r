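# Synthetic streamline bundles, outlier injection and clustering evaluation:
# every pipeline stage is exercisable without MRI data.

#' Specify a synthetic fiber bundle
#'
#' A bundle is a population of streamlines scattered around a smooth 3D
#' centerline (a cubic spline through the control points). Each generated
#' tract samples the centerline at a random point count, receives a constant
#' Gaussian radial offset (bundle thickness) plus small per-point jitter, and
#' may be truncated at the ends to emulate incomplete tracts.
#'
#' @param name Bundle label.
#' @param control_points k x 3 matrix of spline control points (mm), k >= 2.
#' @param n_tracts Number of streamlines (>= 1).
#' @param radial_sd Radial scatter around the centerline in mm (>= 0); the
#'   per-point jitter uses a quarter of this value.
#' @param point_count_range Integer (min, max) points per tract.
#' @param length_jitter Maximum fraction of arc length truncated from a
#'   random end (0 = complete tracts).
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(name, control_points, n_tracts, radial_sd = 1,
                        point_count_range = c(10L, 20L), length_jitter = 0) {
  control_points <- as.matrix(control_points)
  stopifnot(ncol(control_points) == 3L, nrow(control_points) >= 2L,
            n_tracts >= 1L, radial_sd >= 0, length_jitter >= 0,
            length_jitter < 1, point_count_range[1] >= 2L,
            point_count_range[2] >= point_count_range[1])
  structure(list(name = name, control_points = control_points,
                 n_tracts = as.integer(n_tracts), radial_sd = radial_sd,
                 point_count_range = as.integer(point_count_range),
                 length_jitter = length_jitter),
            class = "bundle_spec")
}

spline_centerline <- function(control_points, n = 200L) {
  u <- seq(0, 1, length.out = nrow(control_points))
  uu <- seq(0, 1, length.out = n)
  cbind(
    x = spline(u, control_points[, 1], xout = uu)$y,
    y = spline(u, control_points[, 2], xout = uu)$y,
    z = spline(u, control_points[, 3], xout = uu)$y
  )
}

#' Generate labeled synthetic bundles
#'
#' @param specs List of [bundle_spec()]s.
#' @param seed Optional integer seed (reproducible datasets).
#' @return List with `dataset` (a [tract_dataset()]) and `truth` (character
#'   vector of bundle names, one per tract).
#' @export
generate_bundles <- function(specs, seed = NULL) {
  stopifnot(length(specs) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tracts <- list(); truth <- character(0)
  for (sp in specs) {
    center <- spline_centerline(sp$control_points)
    for (i in seq_len(sp$n_tracts)) {
      npts <- sp$point_count_range[1] +
        floor(runif(1) * (sp$point_count_range[2] - sp$point_count_range[1] + 1L))
      lo <- 0; hi <- 1
      if (sp$length_jitter > 0) {
        cut <- runif(1) * sp$length_jitter
        if (runif(1) < 0.5) lo <- cut else hi <- 1 - cut
      }
      base <- resample_portion(center, lo, hi, npts)
      offset <- rnorm(3, sd = sp$radial_sd)
      jitter <- matrix(rnorm(3 * npts, sd = sp$radial_sd / 4), ncol = 3)
      tracts[[length(tracts) + 1L]] <- base +
        matrix(offset, npts, 3, byrow = TRUE) + jitter
      truth <- c(truth, sp$name)
    }
  }
  list(dataset = tract_dataset(tracts), truth = truth)
}

# Resample the sub-arc [lo, hi] (fractions of total arc length) to n points.
resample_portion <- function(center, lo, hi, n) {
  s <- c(0, cumsum(segment_lengths(center)))
  L <- s[length(s)]
  target <- seq(lo * L, hi * L, length.out = n)
  cbind(approx(s, center[, 1], xout = target)$y,
        approx(s, center[, 2], xout = target)$y,
        approx(s, center[, 3], xout = target)$y)
}

#' Inject isolated outlier tracts
#'
#' Appends `floor(fraction * N)` random jagged polylines placed uniformly in
#' the dataset's bounding box, labeled `"OUTLIER"` in the truth. The noise
#' fractions 0, 0.33, 0.66 and 0.99 reproduce the four graded noise
#' scenarios used in the outlier-elimination experiment.
#'
#' @param dataset A [tract_dataset()].
#' @param truth Character truth labels for `dataset`.
#' @param fraction Nonnegative noise fraction relative to the current size.
#' @param seed Optional integer seed.
#' @param points_per_tract Vertex count of each noise polyline (default 5).
#' @return List with the extended `dataset` and `truth`.
#' @export
add_outlier_tracts <- function(dataset, truth, fraction, seed = NULL,
                               points_per_tract = 5L) {
  stopifnot(fraction >= 0, length(truth) == n_tracts(dataset))
  if (!is.null(seed)) set.seed(seed)
  n_add <- floor(fraction * n_tracts(dataset))
  if (n_add == 0L) return(list(dataset = dataset, truth = truth))
  pts <- do.call(rbind, dataset$tracts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  tracts <- dataset$tracts
  for (i in seq_len(n_add)) {
    p <- cbind(runif(points_per_tract, lo[1], hi[1]),
               runif(points_per_tract, lo[2], hi[2]),
               runif(points_per_tract, lo[3], hi[3]))
    tracts[[length(tracts) + 1L]] <- p
  }
  list(dataset = tract_dataset(tracts, space = dataset$space,
                               provenance = dataset$provenance),
       truth = c(truth, rep("OUTLIER", n_add)))
}

#' Reduce tracts to their centroids for the point-clustering experiment
#'
#' Replaces every tract by a degenerate micro-segment at its length-weighted
#' centroid, so that the centroid distance measure (`"tcd"`) reproduces
#' plain Euclidean point clustering while the full pipeline (sampling, LOFs,
#' elimination, reassignment) stays unchanged.
#'
#' @param dataset A [tract_dataset()].
#' @param truth Truth labels (returned unchanged).
#' @param eps Micro-segment length in mm (default 1e-3).
#' @return List with the centroid `dataset` and `truth`.
#' @export
centroid_experiment <- function(dataset, truth, eps = 1e-3) {
  cents <- tract_centroids(dataset)
  tracts <- lapply(seq_len(nrow(cents)), function(i)
    rbind(cents[i, ], cents[i, ] + c(eps, 0, 0)))
  list(dataset = tract_dataset(tracts, space = dataset$space),
       truth = truth)
}

#' Toy probabilistic atlas from a labeled synthetic dataset
#'
#' Builds a one-dataset atlas with one class per bundle; `"OUTLIER"` tracts
#' are excluded.
#'
#' @param dataset A [tract_dataset()].
#' @param truth Character truth labels.
#' @param grid A [voxel_grid()].
#' @param prob_cutoff Passed to [build_atlas()] (default 0.3).
#' @return A `prob_atlas`.
#' @export
make_toy_atlas <- function(dataset, truth, grid, prob_cutoff = 0.3) {
  build_atlas(list(list(dataset = dataset, labels = truth)), grid,
              prob_cutoff = prob_cutoff)
}

#' Evaluate a clustering against synthetic ground truth
#'
#' Computes the Adjusted Rand Index over tracts whose true label is a bundle
#' (predicted outliers form their own category), and precision/recall of the
#' predicted outlier set against the injected `"OUTLIER"` tracts. When an
#' atlas is supplied, the per-bundle spatial agreement of each matched
#' cluster is reported as well.
#'
#' @param result A `catser_result`.
#' @param truth Character truth labels (length N).
#' @param dataset Optional [tract_dataset()] (needed for spatial agreement).
#' @param atlas Optional `prob_atlas`.
#' @param grid Grid for spatial agreement; defaults to the atlas grid.
#' @return List with `summary` (one-row tibble: `ari`, `outlier_precision`,
#'   `outlier_recall`, `n_clusters`, `n_outliers`) and `per_bundle` (tibble
#'   or `NULL`).
#' @export
evaluate_clustering <- function(result, truth, dataset = NULL, atlas = NULL,
                                grid = if (!is.null(atlas)) atlas$grid) {
  labels <- result$labels
  stopifnot(length(truth) == nrow(labels))
  pred <- ifelse(is.na(labels$cluster), "OUTLIER",
                 as.character(labels$cluster))
  keep <- truth != "OUTLIER"
  ari <- mclust::adjustedRandIndex(truth[keep], pred[keep])
  pred_out <- pred == "OUTLIER"
  true_out <- truth == "OUTLIER"
  tp <- sum(pred_out & true_out)
  precision <- if (sum(pred_out) > 0) tp / sum(pred_out) else NA_real_
  recall <- if (sum(true_out) > 0) tp / sum(true_out) else NA_real_
  per_bundle <- NULL
  if (!is.null(atlas) && !is.null(dataset)) {
    cl_tracts <- lapply(result$clusters, function(cl)
      dataset$tracts[cl$members + 1L])
    matched <- match_clusters_to_atlas(cl_tracts, atlas, grid)
    matched$spatial_agreement <- vapply(seq_len(nrow(matched)), function(r)
      spatial_agreement(cl_tracts[[matched$cluster[r]]],
                        atlas$classes[[matched$class[r]]], grid), numeric(1))
    per_bundle <- matched
  }
  list(
    summary = tibble::tibble(
      ari = ari, outlier_precision = precision, outlier_recall = recall,
      n_clusters = length(result$clusters),
      n_outliers = length(result$outlier_ids)),
    per_bundle = per_bundle
  )
}

#' Default synthetic study conditions: well-separated arc bundles
#'
#' Convenience generator for the package's standard evaluation scenario:
#' `n_bundles` U-shaped/arc bundles with centerlines spread on a coarse grid
#' (inter-bundle spacing about 40 mm, far above the 1 mm radial scatter),
#' each holding `tracts_per_bundle` streamlines.
#'
#' Tracts are incomplete by default (`length_jitter = 0.3`): deterministic
#' tractography streamlines end wherever anisotropy drops, so members of one
#' anatomical bundle differ substantially in length, and the acceptance
#' tests of the assignment stage rely on that within-bundle distance
#' dispersion being non-degenerate.
#'
#' @param n_bundles Number of bundles (default 8).
#' @param tracts_per_bundle Streamlines per bundle (default 250).
#' @param radial_sd Bundle thickness in mm (default 1).
#' @param length_jitter Maximum truncated arc-length fraction (default 0.3).
#' @param seed Optional integer seed.
#' @return As [generate_bundles()].
#' @export
standard_bundles <- function(n_bundles = 8L, tracts_per_bundle = 250L,
                             radial_sd = 1, length_jitter = 0.3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- lapply(seq_len(n_bundles), function(b) {
    gx <- ((b - 1L) %% 4L) * 40
    gy <- ((b - 1L) %/% 4L) * 40
    gz <- ((b - 1L) %% 2L) * 15
    # alternating arc and U-shape geometries
    cp <- if (b %% 2L == 0L) {
      rbind(c(gx, gy, gz), c(gx + 10, gy + 15, gz + 5),
            c(gx + 20, gy + 15, gz + 5), c(gx + 30, gy, gz))
    } else {
      rbind(c(gx, gy, gz), c(gx + 8, gy + 12, gz),
            c(gx + 22, gy + 18, gz + 8), c(gx + 30, gy + 25, gz + 10))
    }
    bundle_spec(paste0("bundle", sprintf("%02d", b)), cp,
                n_tracts = tracts_per_bundle, radial_sd = radial_sd,
                length_jitter = length_jitter)
  })
  generate_bundles(specs)
}
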