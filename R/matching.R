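# Post-hoc spatial matching of clusters to atlas classes, and the
# spatial-agreement quality score used for evaluation.

#' Normalized tract-density map of a cluster
#'
#' Rasterizes every member tract and counts, per voxel, how many member
#' tracts traverse it; counts are normalized to a maximum of 1 per cluster.
#'
#' @param tracts List of tract matrices (the cluster members).
#' @param grid A [voxel_grid()].
#' @return A `density_map`: list with `grid`, `keys` and `values` in (0, 1].
#' @export
cluster_density_map <- function(tracts, grid) {
  stopifnot(length(tracts) >= 1L)
  keys <- unlist(lapply(tracts, rasterize_keys, grid = grid))
  tb <- table_count(keys)
  structure(list(grid = grid, keys = tb$key, values = tb$count / max(tb$count)),
            class = "density_map")
}

#' Matching value between an atlas class and a cluster density map
#'
#' Combines three terms: the mean absolute difference between class
#' probability and cluster density over the intersecting voxels, and the mean
#' class probability / cluster density over each side's non-intersecting
#' voxels. The score is
#' `(1 - mean_abs_diff) - (mean_nonint_class + mean_nonint_cluster) / 2`,
#' in \[-1, 1\]: 1 for a density map identical to the class, decreasing with
#' disagreement in the overlap and with mass outside it. Pairs with no
#' intersecting voxel score the range minimum (-1), so disjoint pairs never
#' win a tie.
#'
#' @param cls Atlas class (list with `keys`, `prob`).
#' @param cd A `density_map` from [cluster_density_map()].
#' @return Score in \[-1, 1\].
#' @export
matching_value <- function(cls, cd) {
  inter <- intersect(cls$keys, cd$keys)
  if (length(inter) == 0L) return(-1)
  e <- mean(abs(cls$prob[match(inter, cls$keys)] -
                  cd$values[match(inter, cd$keys)]))
  only_cls <- !(cls$keys %in% inter)
  only_cd <- !(cd$keys %in% inter)
  n_cls <- if (any(only_cls)) mean(cls$prob[only_cls]) else 0
  n_cd <- if (any(only_cd)) mean(cd$values[only_cd]) else 0
  (1 - e) - (n_cls + n_cd) / 2
}

#' Greedy one-to-one matching of clusters to atlas classes
#'
#' Computes all class-cluster matching values, then iteratively assigns the
#' globally best unassigned (class, cluster) pair until every class has a
#' cluster or clusters are exhausted. The mapping is injective; ties break
#' lexicographically by class name, then by lower cluster index.
#'
#' @param clusters List of clusters, each a list of tract matrices.
#' @param atlas A `prob_atlas`.
#' @param grid Grid to rasterize on; defaults to the atlas grid.
#' @return A tibble with columns `class`, `cluster` (1-based index into
#'   `clusters`) and `matching_value`, ordered by assignment.
#' @export
match_clusters_to_atlas <- function(clusters, atlas, grid = atlas$grid) {
  stopifnot(length(clusters) >= 1L)
  check_same_grid(grid, atlas$grid)
  cls_names <- sort(names(atlas$classes))
  maps <- lapply(clusters, cluster_density_map, grid = grid)
  score <- matrix(-Inf, length(cls_names), length(clusters),
                  dimnames = list(cls_names, NULL))
  for (a in cls_names) for (c in seq_along(clusters))
    score[a, c] <- matching_value(atlas$classes[[a]], maps[[c]])
  out <- list()
  repeat {
    if (all(!is.finite(score))) break
    best <- max(score[is.finite(score)])
    hits <- which(score == best, arr.ind = TRUE)
    hits <- hits[order(rownames(score)[hits[, 1]], hits[, 2]), , drop = FALSE]
    a <- hits[1, 1]; c <- hits[1, 2]
    out[[length(out) + 1L]] <- tibble::tibble(
      class = rownames(score)[a], cluster = c, matching_value = score[a, c])
    score[a, ] <- -Inf
    score[, c] <- -Inf
  }
  dplyr::bind_rows(out)
}

#' Cluster-level spatial agreement with an atlas class
#'
#' Fraction of the voxels in the union of the cluster's rasterized tracts
#' that intersect the class. This is the evaluation variant computed on the
#' voxelized cluster as a whole; the per-tract-averaged membership used
#' during clustering is [cluster_class_membership()].
#'
#' @param tracts List of tract matrices (the cluster members).
#' @param cls Atlas class.
#' @param grid Grid to rasterize on.
#' @return Fraction in \[0, 1\].
#' @export
spatial_agreement <- function(tracts, cls, grid) {
  keys <- sort(unique(unlist(lapply(tracts, rasterize_keys, grid = grid))))
  if (length(keys) == 0L) return(0)
  sum(keys %in% cls$keys) / length(keys)
}
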