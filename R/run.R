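# End-to-end clustering runs: configuration, the eight-step pipeline and
# the result container with its broom-style methods.

#' Clustering run configuration
#'
#' Collects every tunable of the pipeline. Defaults follow the study
#' configuration where one is stated: 3 partitions, LOF neighbour count 15,
#' representative function with transition size 120 and maximum 40,
#' preclustering elimination after 80% of merges removing clusters of fewer
#' than 3 tracts, final elimination after 60% removing fewer than 4, target
#' of 250 prototype clusters, and acceptance factors gamma = 2 for both
#' reassignment and labeling. The default sample size is 20000 tracts
#' (clamped to the dataset); [estimate_sample_size()] gives a principled
#' alternative.
#'
#' @param measure Similarity measure: `"hd"`, `"tcd"`, `"tos"` or `"cd"`.
#' @param sample_size Reduced random sample size (clamped to N).
#' @param n_partitions Number of preclustering partitions.
#' @param k_lof LOF neighbour count.
#' @param use_lof Set `FALSE` to force unit LOFs (plain CURE-style run).
#' @param rep_ratio,n_t,m_max Representative-count function, see
#'   [rep_count_config()].
#' @param target_k Target number of prototype clusters.
#' @param strategy Optional preset name (`"low"`, `"moderate"`, `"high"`,
#'   see [outlier_strategy()]); overrides `t1`/`s1`/`t2`/`s2`.
#' @param t1,s1 Preclustering elimination: time point (percent of planned
#'   merges) and critical size (clusters of `<= s1` members removed;
#'   `s1 = 0` disables).
#' @param t2,s2 Final-stage elimination, same meaning.
#' @param gamma_reassign,gamma_label Acceptance factors for outlier
#'   reassignment and remainder labeling.
#' @param precluster_reduction Per-partition preclustering reduces the
#'   cluster count by about this factor before the join.
#' @param corr_threshold Minimum best membership for a cluster to count as
#'   corresponding to an atlas class.
#' @param cd_opts Options for the combined distance measure.
#' @param n_workers Worker count for the similarity matrix.
#' @param seed Integer seed; all randomness of the run flows from it.
#' @param atlas_post_merge Run the atlas-driven post-clustering merge when
#'   an atlas is supplied.
#' @return A `catser_config` list.
#' @export
catser_config <- function(measure = "hd", sample_size = 20000L,
                          n_partitions = 3L, k_lof = 15L, use_lof = TRUE,
                          rep_ratio = NULL, n_t = 120L, m_max = 40L,
                          target_k = 250L, strategy = NULL,
                          t1 = 80, s1 = 2, t2 = 60, s2 = 3,
                          gamma_reassign = 2, gamma_label = 2,
                          precluster_reduction = 3,
                          corr_threshold = 0, cd_opts = list(),
                          n_workers = 1L, seed = 1L,
                          atlas_post_merge = TRUE) {
  if (!is.null(strategy)) {
    st <- outlier_strategy(strategy)
    t1 <- st$t1; s1 <- st$s1; t2 <- st$t2; s2 <- st$s2
  }
  cfg <- list(measure = measure, sample_size = as.integer(sample_size),
              n_partitions = as.integer(n_partitions),
              k_lof = as.integer(k_lof), use_lof = isTRUE(use_lof),
              rep_ratio = rep_ratio, n_t = n_t, m_max = as.integer(m_max),
              target_k = as.integer(target_k),
              t1 = t1, s1 = s1, t2 = t2, s2 = s2,
              gamma_reassign = gamma_reassign, gamma_label = gamma_label,
              precluster_reduction = precluster_reduction,
              corr_threshold = corr_threshold, cd_opts = cd_opts,
              n_workers = as.integer(n_workers), seed = as.integer(seed),
              atlas_post_merge = isTRUE(atlas_post_merge))
  validate_config(cfg)
  structure(cfg, class = "catser_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$measure %in% c("hd", "tcd", "tos", "cd"),
            cfg$sample_size >= 1, cfg$n_partitions >= 1, cfg$k_lof >= 1,
            cfg$target_k >= 1, cfg$t1 > 0, cfg$t1 <= 100, cfg$t2 > 0,
            cfg$t2 <= 100, cfg$s1 >= 0, cfg$s2 >= 0,
            cfg$gamma_reassign > 0, cfg$gamma_label > 0,
            cfg$precluster_reduction >= 1, cfg$n_workers >= 1)
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected, so typos fail loudly instead of silently
#' running with defaults.
#'
#' @param path Path to the YAML configuration.
#' @return A `catser_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(catser_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(catser_config, vals)
}

make_guidance <- function(sample_ds, atlas, threshold) {
  n_classes <- length(atlas$classes)
  ns <- n_tracts(sample_ds)
  tract_mem <- matrix(0, ns, max(1L, n_classes))
  if (n_classes > 0) {
    for (i in seq_len(ns)) {
      keys <- rasterize_keys(sample_ds$tracts[[i]], atlas$grid)
      if (length(keys) == 0L) next
      tract_mem[i, ] <- vapply(atlas$classes, function(cls)
        sum(keys %in% cls$keys) / length(keys), numeric(1))
    }
  }
  list(n_classes = ncol(tract_mem), tract_mem = tract_mem,
       threshold = threshold, has_classes = n_classes > 0)
}

#' Run the full CATSER clustering pipeline
#'
#' Executes the eight pipeline steps: (1) Fisher-Yates random sampling,
#' (2) similarity matrix and LOFs for the sample, (3) shuffling and
#' partitioning, (4) per-partition preclustering with the first outlier
#' elimination, (5) join, (6) final clustering with the second elimination,
#' (7) reassignment of eliminated tracts to sufficiently close prototype
#' clusters, (8) labeling of the remaining (unsampled) tracts, whose LOF is
#' taken as 1. When `atlas` is supplied, all cluster distances in steps 4
#' and 6-8 are multiplied by the four-case atlas weighting factor, and an
#' atlas-driven post-clustering merge plus spatial matching is appended.
#' The run is fully reproducible from `config$seed` for any worker count.
#'
#' @param dataset A [tract_dataset()].
#' @param config A [catser_config()].
#' @param atlas Optional `prob_atlas` for guided clustering.
#' @return A `catser_result`: list with `clusters` (members/medoid/reps as
#'   0-based tract ids, plus the merge-tree id), `outlier_ids`, `labels`
#'   (tibble: `tract_id`, `cluster` with `NA` for outliers), `tree`
#'   (`merges`, `eliminations`, `leaves`), `sample_ids`, `remainder_ids`,
#'   `matching` (tibble or `NULL`), `config` and `seed`.
#' @export
run_catser <- function(dataset, config = catser_config(), atlas = NULL) {
  stopifnot(inherits(dataset, "tract_dataset"))
  validate_config(config)
  N <- n_tracts(dataset)
  if (N < 2L) stop("dataset must contain at least 2 tracts")
  if (config$sample_size > N)
    message("sample size clamped from ", config$sample_size, " to ", N)
  set.seed(config$seed)

  ## step 1: reduced random sample
  sp <- draw_sample(dataset, min(config$sample_size, N))
  sample_ids <- sort(sp$sample_ids)
  remainder_ids <- sort(sp$remainder_ids)
  ns <- length(sample_ids)
  sub <- subset_tracts(dataset, sample_ids)

  ## step 2: similarity matrix + LOFs
  m <- compute_similarity_matrix(sub, config$measure, config$n_workers,
                                 config$cd_opts)
  lofs <- if (config$use_lof && ns > config$k_lof) {
    compute_lofs(m, config$k_lof)$lof
  } else {
    if (config$use_lof)
      message("sample smaller than k_lof + 1; using unit LOFs")
    rep(1, ns)
  }
  guidance <- if (!is.null(atlas))
    make_guidance(sub, atlas, config$corr_threshold)
  rep_cfg <- rep_count_config(config$rep_ratio, config$n_t, config$m_max)

  ## step 3: shuffle + partition (local indices 1..ns)
  parts <- partition(seq_len(ns), min(config$n_partitions, ns))

  ## step 4: per-partition preclustering with first elimination
  next_id <- 1L; next_step <- 1L
  joined <- list(); outlier_local <- integer(0)
  merges <- list(); elims <- list()
  for (p in parts) {
    init <- lapply(sort(p), function(i)
      list(members = i, tree_id = -(sample_ids[i] + 1L)))
    tk <- max(1L, round(length(p) / config$precluster_reduction))
    tk <- max(tk, ceiling(config$target_k / length(parts)))
    tk <- min(tk, length(p))
    st <- agglomerate(init, tk, config$t1, config$s1, m, lofs, rep_cfg,
                      guidance, next_id, next_step)
    joined <- c(joined, st$clusters)
    outlier_local <- c(outlier_local, st$outliers)
    merges <- c(merges, list(st$merges))
    elims <- c(elims, list(st$eliminations))
    next_id <- st$next_id; next_step <- st$next_step
  }

  ## steps 5-6: join + final clustering with second elimination
  target_k <- min(config$target_k, length(joined))
  fin <- agglomerate(joined, target_k, config$t2, config$s2, m, lofs,
                     rep_cfg, guidance, next_id, next_step)
  clusters <- fin$clusters
  outlier_local <- sort(c(outlier_local, fin$outliers))
  merges <- dplyr::bind_rows(c(merges, list(fin$merges)))
  elims <- dplyr::bind_rows(c(elims, list(fin$eliminations)))

  labels_local <- rep(NA_integer_, ns)
  for (ci in seq_along(clusters))
    labels_local[clusters[[ci]]$members] <- ci

  ## step 7: reassignment of eliminated tracts
  if (length(clusters) > 0 && length(outlier_local) > 0) {
    global_med <- median(m[lower.tri(m)])
    spreads <- vapply(clusters, cluster_spread, numeric(1), m = m,
                      global_median = global_med)
    cl_mem <- if (!is.null(guidance))
      do.call(rbind, lapply(clusters, function(cl)
        colMeans(guidance$tract_mem[cl$members, , drop = FALSE])))
    for (o in outlier_local) {
      d <- vapply(seq_along(clusters), function(ci) {
        w <- if (is.null(guidance)) 1 else
          guidance_case_factor(guidance$tract_mem[o, ], cl_mem[ci, ],
                               guidance$threshold)
        min(m[o, clusters[[ci]]$reps]) * w
      }, numeric(1))
      k <- reassign_or_label(d, spreads, config$gamma_reassign)
      if (!is.na(k)) {
        clusters[[k]]$members <- sort(c(clusters[[k]]$members, o))
        labels_local[o] <- k
      }
    }
  }

  ## assemble global-id view of the sample clustering
  to_global <- function(loc) sample_ids[loc]
  g_clusters <- lapply(clusters, function(cl) list(
    members = to_global(cl$members), medoid = to_global(cl$medoid),
    reps = to_global(cl$reps), tree_id = cl$tree_id))
  labels <- tibble::tibble(tract_id = 0:(N - 1L), cluster = NA_integer_)
  labels$cluster[sample_ids + 1L] <- labels_local

  ## step 8: label remaining tracts (LOF assumed ~ 1)
  if (length(remainder_ids) > 0 && length(clusters) > 0) {
    global_med <- median(m[lower.tri(m)])
    spreads <- vapply(clusters, cluster_spread, numeric(1), m = m,
                      global_median = global_med)
    rep_tracts <- lapply(clusters, function(cl) sub$tracts[cl$reps])
    cl_mem <- if (!is.null(guidance))
      do.call(rbind, lapply(clusters, function(cl)
        colMeans(guidance$tract_mem[cl$members, , drop = FALSE])))
    for (r in remainder_ids) {
      tr <- dataset$tracts[[r + 1L]]
      mem_r <- if (!is.null(guidance) && guidance$has_classes) {
        keys <- rasterize_keys(tr, atlas$grid)
        if (length(keys) == 0L) rep(0, guidance$n_classes) else
          vapply(atlas$classes, function(cls)
            sum(keys %in% cls$keys) / length(keys), numeric(1))
      }
      d <- vapply(seq_along(clusters), function(ci) {
        w <- if (is.null(guidance)) 1 else
          guidance_case_factor(mem_r, cl_mem[ci, ], guidance$threshold)
        min(vapply(rep_tracts[[ci]], function(rt)
          pair_distance(tr, rt, config$measure, config$cd_opts),
          numeric(1))) * w
      }, numeric(1))
      k <- reassign_or_label(d, spreads, config$gamma_label)
      if (!is.na(k)) {
        g_clusters[[k]]$members <- sort(c(g_clusters[[k]]$members, r))
        labels$cluster[r + 1L] <- k
      }
    }
  }

  result <- structure(list(
    clusters = g_clusters,
    outlier_ids = labels$tract_id[is.na(labels$cluster)],
    labels = labels,
    tree = list(merges = merges, eliminations = elims, leaves = sample_ids),
    sample_ids = sample_ids, remainder_ids = remainder_ids,
    matching = NULL, config = config, seed = config$seed
  ), class = "catser_result")

  if (!is.null(atlas)) {
    if (config$atlas_post_merge)
      result <- post_merge_by_atlas(result, dataset, atlas)
    if (length(result$clusters) > 0 && length(atlas$classes) > 0) {
      cl_tracts <- lapply(result$clusters, function(cl)
        dataset$tracts[cl$members + 1L])
      result$matching <- match_clusters_to_atlas(cl_tracts, atlas)
    }
  }
  result
}

#' @export
print.catser_result <- function(x, ...) {
  cat(sprintf(paste0("<catser_result> %d tracts -> %d clusters, ",
                     "%d outliers (measure %s, seed %d)\n"),
              nrow(x$labels), length(x$clusters), length(x$outlier_ids),
              x$config$measure, x$seed))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-tract labels of a clustering result
#'
#' @param x A `catser_result`.
#' @param ... Unused.
#' @return Tibble with `tract_id` (0-based), `cluster` (integer, `NA` for
#'   outliers), `outlier` (logical) and `sampled` (logical).
#' @export
tidy.catser_result <- function(x, ...) {
  dplyr::mutate(x$labels,
                outlier = is.na(.data$cluster),
                sampled = .data$tract_id %in% x$sample_ids)
}

#' One-row summary of a clustering result
#'
#' @param x A `catser_result`.
#' @param ... Unused.
#' @return One-row tibble: tract/cluster/outlier counts, sample size,
#'   measure, seed and median cluster size.
#' @export
glance.catser_result <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), numeric(1))
  tibble::tibble(
    n_tracts = nrow(x$labels), n_sampled = length(x$sample_ids),
    n_clusters = length(x$clusters), n_outliers = length(x$outlier_ids),
    median_cluster_size = if (length(sizes)) median(sizes) else NA_real_,
    measure = x$config$measure, seed = x$seed)
}

#' Plot a clustering result
#'
#' `type = "sizes"` draws the cluster-size distribution; `type = "tracts"`
#' draws an x-y projection of the streamlines colored by cluster (outliers
#' in grey) and requires the clustered `dataset`.
#'
#' @param object A `catser_result`.
#' @param type `"sizes"` or `"tracts"`.
#' @param dataset The clustered [tract_dataset()] (for `type = "tracts"`).
#' @param max_tracts Subsample cap for the tract plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.catser_result <- function(object, type = c("sizes", "tracts"),
                                   dataset = NULL, max_tracts = 2000L, ...) {
  type <- match.arg(type)
  if (type == "sizes") {
    sizes <- tibble::tibble(
      cluster = seq_along(object$clusters),
      size = vapply(object$clusters, function(cl) length(cl$members),
                    numeric(1)))
    return(
      ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
        ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
        ggplot2::labs(x = "cluster size (tracts)", y = "clusters",
                      title = "Cluster size distribution"))
  }
  if (is.null(dataset)) stop("type = 'tracts' needs the clustered dataset")
  tb <- as_tibble.tract_dataset(dataset)
  lab <- tidy.catser_result(object)
  tb <- dplyr::left_join(tb, lab, by = "tract_id")
  keep_ids <- unique(tb$tract_id)
  if (length(keep_ids) > max_tracts)
    tb <- tb[tb$tract_id %in% keep_ids[seq_len(max_tracts)], ]
  tb$group <- ifelse(tb$outlier, "OUTLIER", as.character(tb$cluster))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$tract_id,
                                   colour = .data$group)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_colour_discrete(guide = "none") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Clustered streamlines (x-y projection)")
}

# ---- result serialization --------------------------------------------------

#' Write the tract-to-cluster labels as TSV
#'
#' Columns `tract_id` and `cluster_id`; outliers are written as `OUTLIER`.
#'
#' @param result A `catser_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(result, path) {
  out <- data.frame(
    tract_id = result$labels$tract_id,
    cluster_id = ifelse(is.na(result$labels$cluster), "OUTLIER",
                        as.character(result$labels$cluster)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the merge tree as JSON
#'
#' Leaves are encoded as negative ids `-(tract_id + 1)`, merged clusters as
#' positive ids in merge order; replaying `merges` and `eliminations`
#' reconstructs every intermediate clustering.
#'
#' @param result A `catser_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merge_tree_json <- function(result, path) {
  jsonlite::write_json(list(
    leaves = result$tree$leaves,
    merges = result$tree$merges,
    eliminations = result$tree$eliminations
  ), path, digits = NA)
  invisible(path)
}

#' Export each cluster's streamlines to its own file
#'
#' @param result A `catser_result`.
#' @param dataset The clustered [tract_dataset()].
#' @param dir Output directory.
#' @param format `"trk"`, `"tck"` or `"jsonl"`.
#' @return Vector of written paths, invisibly.
#' @export
export_cluster_tracts <- function(result, dataset, dir, format = "trk") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ci in seq_along(result$clusters)) {
    ds <- subset_tracts(dataset, result$clusters[[ci]]$members)
    f <- file.path(dir, sprintf("cluster_%03d.%s", ci, format))
    suppressMessages(write_tracts(ds, f, format))
    paths <- c(paths, f)
  }
  invisible(paths)
}
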