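# Probabilistic white-matter atlas: voxel grids, tract rasterization, class
# membership, atlas construction from labeled bundles and the four-case
# atlas-guided weighting factor.

#' Define a voxel grid
#'
#' Axis-aligned grid with isotropic resolution. World-to-index mapping uses
#' the half-open voxel convention `[i, i+1)`: a world point maps to the
#' 0-based index `floor((p - origin) / resolution)`.
#'
#' @param origin World coordinates (mm) of the corner of voxel (0, 0, 0).
#' @param shape Integer vector of 3 voxel counts.
#' @param resolution Isotropic voxel edge length in mm (default 1).
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(origin = c(0, 0, 0), shape, resolution = 1) {
  stopifnot(length(origin) == 3L, length(shape) == 3L, all(shape >= 1),
            resolution > 0)
  affine <- diag(c(rep(resolution, 3), 1))
  affine[1:3, 4] <- origin
  structure(list(shape = as.integer(shape), affine = affine,
                 resolution = resolution, origin = as.double(origin)),
            class = "voxel_grid")
}

#' Grid that covers a dataset's bounding box
#'
#' @param dataset A [tract_dataset()].
#' @param resolution Voxel size in mm.
#' @param margin Extra margin in mm on every side.
#' @return A [voxel_grid()].
#' @export
grid_for_dataset <- function(dataset, resolution = 1, margin = 2) {
  pts <- do.call(rbind, dataset$tracts)
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  voxel_grid(origin = lo, shape = ceiling((hi - lo) / resolution) + 1L,
             resolution = resolution)
}

world_to_index <- function(grid, pts) {
  idx <- floor(sweep(pts, 2, grid$origin) / grid$resolution)
  storage.mode(idx) <- "integer"
  idx
}

index_in_grid <- function(grid, idx) {
  idx[, 1] >= 0L & idx[, 1] < grid$shape[1] &
    idx[, 2] >= 0L & idx[, 2] < grid$shape[2] &
    idx[, 3] >= 0L & idx[, 3] < grid$shape[3]
}

voxel_key <- function(grid, idx) {
  idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3])
}

key_to_index <- function(grid, key) {
  i <- key %% grid$shape[1]
  rest <- key %/% grid$shape[1]
  j <- rest %% grid$shape[2]
  k <- rest %/% grid$shape[2]
  cbind(i, j, k)
}

#' Rasterize a tract onto a voxel grid
#'
#' Samples every segment at steps of at most a quarter voxel so no traversed
#' voxel is skipped, and returns the set of unique voxels. Points outside the
#' grid are clipped with a warning; a tract entirely outside is an error.
#'
#' @param t Tract matrix (n x 3, mm).
#' @param grid A [voxel_grid()].
#' @return Integer matrix of unique 0-based voxel indices (k x 3), with the
#'   linearized keys in attribute `"keys"`.
#' @export
rasterize_tract <- function(t, grid) {
  keys <- rasterize_keys(t, grid, warn = TRUE)
  if (length(keys) == 0L) stop("tract lies entirely outside the grid")
  idx <- key_to_index(grid, keys)
  attr(idx, "keys") <- keys
  idx
}

rasterize_keys <- function(t, grid, warn = FALSE) {
  step <- 0.25 * grid$resolution
  segs <- segment_lengths(t)
  pts <- vector("list", length(segs) + 1L)
  for (s in seq_along(segs)) {
    k <- max(1L, ceiling(segs[s] / step))
    u <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    pts[[s]] <- t[s, ] %o% (1 - u) + t[s + 1L, ] %o% u
  }
  dense <- t(do.call(cbind, pts))
  dense <- rbind(dense, t[nrow(t), ])
  idx <- world_to_index(grid, dense)
  inside <- index_in_grid(grid, idx)
  if (warn && !all(inside))
    warning(sum(!inside), " sampled point(s) outside the grid clipped")
  idx <- idx[inside, , drop = FALSE]
  if (nrow(idx) == 0L) return(numeric(0))
  sort(unique(voxel_key(grid, idx)))
}

#' Atlas class membership of a single tract
#'
#' Fraction of the tract's rasterized voxels that intersect the class's voxel
#' set (binarized class support: the probabilities only gate which voxels
#' survive the construction cutoff).
#'
#' @param t Tract matrix.
#' @param cls An atlas class (list with `keys`).
#' @param grid The atlas [voxel_grid()].
#' @return Fraction in \[0, 1\].
#' @export
tract_class_membership <- function(t, cls, grid) {
  keys <- rasterize_keys(t, grid)
  if (length(keys) == 0L) return(0)
  sum(keys %in% cls$keys) / length(keys)
}

#' Atlas class membership of a cluster
#'
#' Arithmetic mean of the member tracts' class memberships.
#'
#' @param tracts List of tract matrices (the cluster members).
#' @param cls An atlas class.
#' @param grid The atlas [voxel_grid()].
#' @return Fraction in \[0, 1\].
#' @export
cluster_class_membership <- function(tracts, cls, grid) {
  stopifnot(length(tracts) >= 1L)
  mean(vapply(tracts, tract_class_membership, numeric(1), cls = cls,
              grid = grid))
}

# Four-case weighting factor from per-class membership vectors.
# Case 1 (neither corresponds): 1. Case 2 (exactly one): 1 + s (repulsion).
# Case 3 (same best class): 1 / (1 + s_a * s_b) (attraction). Case 4
# (different best classes): 1 + s_a + s_b (strongest repulsion).
guidance_case_factor <- function(mem_a, mem_b, threshold = 0) {
  if (length(mem_a) == 0L || length(mem_b) == 0L) return(1)
  mem_a <- unname(mem_a); mem_b <- unname(mem_b)
  ba <- which.max(mem_a); sa <- mem_a[ba]
  bb <- which.max(mem_b); sb <- mem_b[bb]
  ca <- sa > threshold; cb <- sb > threshold
  if (!ca && !cb) return(1)
  if (ca && cb) {
    if (ba == bb) return(1 / (1 + sa * sb))
    return(1 + sa + sb)
  }
  1 + max(sa * ca, sb * cb)
}

#' Atlas-guided weighting factor for a cluster pair
#'
#' Determines each cluster's best-matching atlas class (maximum mean
#' membership; "no corresponding class" when the best membership does not
#' exceed `threshold`) and modulates the inter-cluster distance accordingly:
#' neutral (1) when neither cluster lies on the atlas, attractive (< 1) when
#' both correspond to the same class, and repulsive (> 1) when exactly one
#' corresponds or when they correspond to different classes — increasingly
#' so the stronger the memberships.
#'
#' @param a,b Lists of tract matrices (the two clusters' members).
#' @param atlas A `prob_atlas` from [build_atlas()].
#' @param grid Grid to rasterize on; defaults to the atlas grid.
#' @param threshold Minimum best membership to count as corresponding
#'   (default 0, i.e. any overlap).
#' @return Positive weighting factor.
#' @export
weighting_factor <- function(a, b, atlas, grid = atlas$grid, threshold = 0) {
  check_same_grid(grid, atlas$grid)
  mem <- function(tracts) vapply(atlas$classes, function(cls)
    cluster_class_membership(tracts, cls, grid), numeric(1))
  guidance_case_factor(mem(a), mem(b), threshold)
}

check_same_grid <- function(g1, g2) {
  if (!isTRUE(all.equal(g1$shape, g2$shape)) ||
      !isTRUE(all.equal(g1$affine, g2$affine)))
    stop("voxel grids do not match")
  invisible(TRUE)
}

#' Build a probabilistic white-matter atlas from labeled bundles
#'
#' Two-step construction. Per dataset and bundle, every bundle tract is
#' rasterized and each traversed voxel receives the dataset probability
#' (bundle tract count in the voxel) / (count of all labeled tracts of that
#' dataset in the voxel). Per class, the voxel probability is the mean of
#' the dataset probabilities over the datasets whose bundle reaches the
#' voxel; probabilities are then normalized to a per-class maximum of 1 and
#' voxels below `prob_cutoff` are removed as unreliable.
#'
#' @param bundled_datasets List of `list(dataset = <tract_dataset>,
#'   labels = <character vector>)`; labels are bundle names, `"OUTLIER"`
#'   marks tracts excluded from every bundle.
#' @param grid A [voxel_grid()].
#' @param prob_cutoff Minimum surviving probability (default 0.3).
#' @return A `prob_atlas`: list with `grid` and `classes`, each class a list
#'   with `name`, `keys` (linearized voxel keys) and `prob`.
#' @export
build_atlas <- function(bundled_datasets, grid, prob_cutoff = 0.3) {
  stopifnot(length(bundled_datasets) >= 1L)
  all_names <- sort(unique(unlist(lapply(bundled_datasets, function(b)
    setdiff(unique(b$labels), "OUTLIER")))))
  acc <- setNames(vector("list", length(all_names)), all_names)  # key -> (sum, n)
  for (b in bundled_datasets) {
    ds <- b$dataset; labels <- b$labels
    stopifnot(length(labels) == n_tracts(ds))
    labeled <- which(labels != "OUTLIER")
    keys_by_tract <- lapply(ds$tracts, rasterize_keys, grid = grid)
    total <- table_count(unlist(keys_by_tract[labeled]))
    for (nm in all_names) {
      in_bundle <- which(labels == nm)
      if (length(in_bundle) == 0L) next
      dens <- table_count(unlist(keys_by_tract[in_bundle]))
      p <- dens$count / total$count[match(dens$key, total$key)]
      prev <- acc[[nm]]
      if (is.null(prev)) {
        acc[[nm]] <- list(key = dens$key, sum = p, n = rep(1L, length(p)))
      } else {
        all_keys <- sort(union(prev$key, dens$key))
        s <- numeric(length(all_keys)); n <- integer(length(all_keys))
        ip <- match(prev$key, all_keys); s[ip] <- prev$sum; n[ip] <- prev$n
        id <- match(dens$key, all_keys)
        s[id] <- s[id] + p; n[id] <- n[id] + 1L
        acc[[nm]] <- list(key = all_keys, sum = s, n = n)
      }
    }
  }
  classes <- list()
  for (nm in all_names) {
    a <- acc[[nm]]
    if (is.null(a) || length(a$key) == 0L) {
      warning("bundle '", nm, "' has no tracts in any dataset; class omitted")
      next
    }
    prob <- a$sum / a$n
    prob <- prob / max(prob)            # per-class max-normalization to 1
    keep <- prob >= prob_cutoff
    classes[[nm]] <- list(name = nm, keys = a$key[keep], prob = prob[keep])
  }
  structure(list(grid = grid, classes = classes), class = "prob_atlas")
}

table_count <- function(keys) {
  if (length(keys) == 0L) return(list(key = numeric(0), count = numeric(0)))
  tb <- table(keys)
  list(key = as.numeric(names(tb)), count = as.numeric(tb))
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> %d classes on a %s grid (%.1f mm)\n",
              length(x$classes), paste(x$grid$shape, collapse = "x"),
              x$grid$resolution))
  invisible(x)
}

#' Write / read an atlas as NIfTI volumes with a JSON manifest
#'
#' One 3D probability volume per class plus `manifest.json` recording class
#' names, the grid and the cutoff.
#'
#' @param atlas A `prob_atlas`.
#' @param dir Output directory (created if missing).
#' @return `dir` (write) or the reconstructed `prob_atlas` (read).
#' @export
write_atlas_nifti <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cls in atlas$classes) {
    vol <- array(0, dim = atlas$grid$shape)
    idx <- key_to_index(atlas$grid, cls$keys)
    vol[idx + 1L] <- cls$prob
    f <- file.path(dir, paste0(cls$name, ".nii.gz"))
    img <- RNifti::asNifti(vol)
    RNifti::qform(img) <- structure(atlas$grid$affine, code = 2L)
    RNifti::writeNifti(img, f)
    files[cls$name] <- basename(f)
  }
  manifest <- list(classes = as.list(files),
                   grid = list(origin = atlas$grid$origin,
                               shape = atlas$grid$shape,
                               resolution = atlas$grid$resolution))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  grid <- voxel_grid(origin = manifest$grid$origin,
                     shape = manifest$grid$shape,
                     resolution = manifest$grid$resolution)
  classes <- list()
  for (nm in names(manifest$classes)) {
    vol <- RNifti::readNifti(file.path(dir, manifest$classes[[nm]]))
    hit <- which(vol > 0, arr.ind = TRUE) - 1L
    keys <- voxel_key(grid, hit)
    ord <- order(keys)
    classes[[nm]] <- list(name = nm, keys = keys[ord],
                          prob = vol[hit + 1L][ord])
  }
  structure(list(grid = grid, classes = classes), class = "prob_atlas")
}

#' Merge clusters whose union matches the atlas better than its parts
#'
#' Post-clustering cleanup: cluster pairs are merged greedily whenever the
#' merged cluster's spatial agreement with its best atlas class strictly
#' exceeds both parents' best agreements, repeated to a fixed point. The
#' agreement is the union-voxel variant ([spatial_agreement()]): the fraction
#' of the voxelized cluster that intersects the class. Splitting a bundle
#' leaves both parts sharing their off-atlas fringe, so re-joining them
#' raises this fraction; clusters matching different classes are untouched.
#'
#' @param result A `catser_result` from [run_catser()].
#' @param dataset The clustered [tract_dataset()] (for tract geometry).
#' @param atlas A `prob_atlas`.
#' @param grid Grid to rasterize on; defaults to the atlas grid.
#' @return The updated `catser_result` (merges appended to the tree).
#' @export
post_merge_by_atlas <- function(result, dataset, atlas, grid = atlas$grid) {
  check_same_grid(grid, atlas$grid)
  if (length(atlas$classes) == 0L || length(result$clusters) < 2L)
    return(result)
  clusters <- result$clusters
  keysets <- lapply(clusters, function(cl)
    sort(unique(unlist(lapply(cl$members, function(id)
      rasterize_keys(dataset$tracts[[id + 1L]], grid))))))
  best_agree <- function(keys) {
    if (length(keys) == 0L) return(0)
    max(vapply(atlas$classes, function(cls)
      sum(keys %in% cls$keys) / length(keys), numeric(1)))
  }
  merges <- result$tree$merges
  next_id <- if (nrow(merges) > 0) max(merges$new_id) + 1 else 1
  step <- if (nrow(merges) > 0) max(merges$step) + 1 else 1
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    self <- vapply(keysets, best_agree, numeric(1))
    best_pair <- NULL; best_gain <- -Inf; best_keys <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      uk <- sort(unique(c(keysets[[i]], keysets[[j]])))
      merged_best <- best_agree(uk)
      if (merged_best > self[i] && merged_best > self[j] &&
          merged_best > best_gain) {
        best_gain <- merged_best; best_pair <- c(i, j); best_keys <- uk
      }
    }
    if (is.null(best_pair)) break
    i <- best_pair[1]; j <- best_pair[2]
    sizes <- vapply(clusters, function(cl) length(cl$members), numeric(1))
    merged <- list(
      members = sort(c(clusters[[i]]$members, clusters[[j]]$members)),
      medoid = if (sizes[i] >= sizes[j]) clusters[[i]]$medoid else clusters[[j]]$medoid,
      reps = sort(unique(c(clusters[[i]]$reps, clusters[[j]]$reps))),
      tree_id = next_id)
    merges <- dplyr::bind_rows(merges, tibble::tibble(
      id_a = clusters[[i]]$tree_id, id_b = clusters[[j]]$tree_id,
      new_id = next_id, dist = NA_real_, step = step))
    keep <- setdiff(seq_len(k), c(i, j))
    clusters <- c(clusters[keep], list(merged))
    keysets <- c(keysets[keep], list(best_keys))
    next_id <- next_id + 1; step <- step + 1
  }
  result$clusters <- clusters
  result$tree$merges <- merges
  result$labels <- relabel_from_clusters(result$labels, clusters)
  result
}

relabel_from_clusters <- function(labels, clusters) {
  labels$cluster <- NA_integer_
  for (ci in seq_along(clusters)) {
    labels$cluster[match(clusters[[ci]]$members, labels$tract_id)] <- ci
  }
  labels
}
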