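# CATSER: two-pass representative-based agglomerative clustering with
# LOF-adjusted distances, staged outlier elimination and optional
# atlas-guided distance weighting.

#' Chernoff-bound minimum sample size
#'
#' Smallest random-sample size `s` such that, with probability at least
#' `1 - confidence_delta`, the sample contains at least
#' `fraction * min_cluster_size` tracts from every cluster of at least
#' `min_cluster_size` tracts (closed-form bound from the CURE sampling
#' derivation). The result is clamped to `n_total`.
#'
#' @param n_total Dataset size.
#' @param min_cluster_size Size `u` of the smallest cluster that must stay
#'   represented.
#' @param fraction Required represented fraction `f` in (0, 1].
#' @param confidence_delta Failure probability `delta` in (0, 1).
#' @return Integer sample size.
#' @export
estimate_sample_size <- function(n_total, min_cluster_size, fraction,
                                 confidence_delta) {
  stopifnot(n_total >= 1, min_cluster_size >= 1, min_cluster_size <= n_total,
            fraction > 0, fraction <= 1,
            confidence_delta > 0, confidence_delta < 1)
  u <- min_cluster_size
  lg <- log(1 / confidence_delta)
  s <- fraction * n_total + (n_total / u) * lg +
    (n_total / u) * sqrt(lg^2 + 2 * fraction * u * lg)
  as.integer(min(n_total, ceiling(s)))
}

#' Fisher-Yates shuffle
#'
#' Unbiased in-place shuffle driven by the current RNG state (or a given
#' seed). Exposed because the sampling and partitioning stages are specified
#' in terms of it.
#'
#' @param x Vector to shuffle.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Permuted `x`.
#' @export
fisher_yates <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (n < 2L) return(x)
  for (i in n:2) {
    j <- floor(runif(1) * i) + 1
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

#' Draw the reduced random sample
#'
#' @param dataset A [tract_dataset()].
#' @param size Sample size, `1 <= size <= N`.
#' @param seed Optional integer seed.
#' @return List with `sample_ids` and `remainder_ids` (0-based tract ids;
#'   their disjoint union is `0..N-1`).
#' @export
draw_sample <- function(dataset, size, seed = NULL) {
  n <- n_tracts(dataset)
  if (size < 1L || size > n) stop("sample size must be in [1, ", n, "]")
  ids <- fisher_yates(0:(n - 1L), seed = seed)
  list(sample_ids = ids[seq_len(size)],
       remainder_ids = if (size < n) ids[(size + 1L):n] else integer(0))
}

#' Partition sampled ids into approximately equal parts
#'
#' Shuffles (Fisher-Yates) and splits; part sizes differ by at most one.
#'
#' @param sample_ids Vector of ids.
#' @param n_parts Number of parts, `1 <= n_parts <= length(sample_ids)`.
#' @param seed Optional integer seed.
#' @return List of id vectors whose disjoint union is `sample_ids`.
#' @export
partition <- function(sample_ids, n_parts, seed = NULL) {
  n <- length(sample_ids)
  if (n_parts < 1L || n_parts > n) stop("n_parts must be in [1, ", n, "]")
  ids <- fisher_yates(sample_ids, seed = seed)
  base <- n %/% n_parts
  extra <- n %% n_parts
  sizes <- rep(base, n_parts) + c(rep(1L, extra), rep(0L, n_parts - extra))
  split(ids, rep(seq_len(n_parts), sizes))
}

#' Representative-count configuration
#'
#' The number of representatives per cluster follows a monotone piecewise
#' function of the cluster size: linear growth `round(ratio * n)` while the
#' cluster is smaller than the stage-transition size `n_t`, and the constant
#' `m_max` from `n_t` on. The defaults reproduce the study configuration
#' (`n_t = 120`, `m_max = 40`, hence ratio 1/3).
#'
#' @param ratio Representatives per tract in stage 1; defaults to
#'   `m_max / n_t` so the function is continuous at the transition.
#' @param n_t Stage-transition cluster size.
#' @param m_max Constant stage-2 representative count.
#' @return A `rep_count_config` list.
#' @export
rep_count_config <- function(ratio = NULL, n_t = 120L, m_max = 40L) {
  stopifnot(n_t >= 1, m_max >= 1)
  if (is.null(ratio)) ratio <- m_max / n_t
  stopifnot(ratio > 0)
  if (is.finite(n_t) && abs(ratio * n_t - m_max) > 1)
    warning("ratio * n_t differs from m_max by more than rounding; ",
            "the representative count will jump at the stage transition")
  structure(list(ratio = ratio, n_t = n_t, m_max = as.integer(m_max)),
            class = "rep_count_config")
}

#' Number of representatives for a cluster of a given size
#'
#' @param n_tracts Cluster size (>= 1).
#' @param cfg A [rep_count_config()].
#' @return Integer count in `[1, n_tracts]`.
#' @export
num_representatives <- function(n_tracts, cfg = rep_count_config()) {
  stopifnot(n_tracts >= 1)
  m <- if (n_tracts < cfg$n_t) max(1, round(cfg$ratio * n_tracts)) else cfg$m_max
  as.integer(min(m, n_tracts))
}

#' Outlier-elimination strategy presets
#'
#' Each strategy fires one elimination per clustering stage: after `t` percent
#' of the merges planned for the stage, live clusters holding no more than
#' the critical size are removed as outliers. The presets trade sensitivity
#' against the risk of discarding small true clusters.
#'
#' @param name `"low"`, `"moderate"` or `"high"`.
#' @return List with `t1`, `s1` (preclustering) and `t2`, `s2` (final stage).
#' @export
outlier_strategy <- function(name = c("low", "moderate", "high")) {
  name <- match.arg(name)
  switch(name,
    low      = list(t1 = 95, s1 = 1, t2 = 85, s2 = 4),
    moderate = list(t1 = 80, s1 = 2, t2 = 85, s2 = 6),
    high     = list(t1 = 80, s1 = 4, t2 = 85, s2 = 8)
  )
}

#' LOF-based correction factor for a tract pair
#'
#' Neutral (exactly 1) while both LOFs are at most 1; above that it grows
#' strictly and symmetrically with either LOF:
#' `alpha = max(1, lof_i) * max(1, lof_j)`.
#'
#' @param lof_i,lof_j Positive LOF values (vectorized).
#' @return Correction factor(s) >= 1.
#' @export
lof_correction <- function(lof_i, lof_j) {
  if (any(lof_i <= 0) || any(lof_j <= 0)) stop("LOFs must be positive")
  pmax(1, lof_i) * pmax(1, lof_j)
}

#' LOF-adjusted intra-cluster distance
#'
#' Raw distance divided by the correction factor: tracts with elevated LOFs
#' are pulled toward the cluster interior, which keeps them from being
#' selected as representatives.
#'
#' @param i,j 1-based matrix indices.
#' @param m Similarity matrix.
#' @param lofs Per-tract LOF vector.
#' @return Adjusted distance (<= raw distance; equal when both LOFs <= 1).
#' @export
intra_distance <- function(i, j, m, lofs) {
  m[i, j] / lof_correction(lofs[i], lofs[j])
}

#' Medoid of a cluster
#'
#' The member whose mean raw distance to all members is minimal; ties go to
#' the lowest index.
#'
#' @param members 1-based matrix indices of the cluster members.
#' @param m Similarity matrix.
#' @return The medoid's index.
#' @export
find_medoid <- function(members, m) {
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L) return(members)
  avg <- colMeans(m[members, members, drop = FALSE])
  members[which.min(avg)]   # which.min takes the first (lowest index) on ties
}

#' Greedy selection of well-spread cluster representatives
#'
#' Farthest-point selection under the LOF-adjusted intra-cluster distance:
#' the first representative maximizes the adjusted distance to the medoid,
#' each following one maximizes the minimum adjusted distance to the medoid
#' and all previously chosen representatives. High-LOF members see their
#' distances shrunk and are therefore avoided. Ties go to the lowest index.
#'
#' @param members 1-based matrix indices of the cluster members.
#' @param medoid The cluster medoid (one of `members`).
#' @param m Similarity matrix.
#' @param lofs Per-tract LOF vector.
#' @param count Number of representatives to select.
#' @return Ordered vector of representative indices.
#' @export
select_representatives <- function(members, medoid, m, lofs, count) {
  count <- min(count, length(members))
  if (length(members) == 1L) return(members)
  maxl <- pmax(1, lofs)
  dmin <- m[members, medoid] / (maxl[members] * maxl[medoid])
  chosen <- integer(0)
  avail <- rep(TRUE, length(members))
  for (r in seq_len(count)) {
    cand <- which(avail)
    pick <- cand[which.max(dmin[cand])]
    chosen <- c(chosen, members[pick])
    avail[pick] <- FALSE
    dm <- m[members, members[pick]] / (maxl[members] * maxl[members[pick]])
    dmin <- pmin(dmin, dm)
  }
  chosen
}

#' LOF- and atlas-adjusted distance between two clusters
#'
#' Minimum over representative pairs of the raw distance multiplied by the
#' LOF correction factor, optionally multiplied by the atlas weighting
#' factor. Elevated representative LOFs thus push clusters apart (repulsion),
#' delaying or preventing their merge.
#'
#' @param a,b Cluster objects (lists with at least `reps`, 1-based indices).
#' @param m Similarity matrix.
#' @param lofs Per-tract LOF vector.
#' @param weight Atlas weighting factor (default 1 = unguided).
#' @return Adjusted inter-cluster distance.
#' @export
cluster_distance <- function(a, b, m, lofs, weight = 1) {
  ra <- a$reps; rb <- b$reps
  sub <- m[ra, rb, drop = FALSE]
  alpha <- outer(pmax(1, lofs[ra]), pmax(1, lofs[rb]))
  min(sub * alpha) * weight
}

# ---- the agglomeration engine ---------------------------------------------

new_cluster <- function(members, tree_id, m, lofs, rep_cfg) {
  med <- find_medoid(members, m)
  reps <- select_representatives(members, med, m, lofs,
                                 num_representatives(length(members), rep_cfg))
  list(members = members, medoid = med, reps = reps, tree_id = tree_id)
}

#' Agglomerative clustering stage with representatives and elimination
#'
#' Repeatedly merges the globally closest cluster pair (adjusted distance per
#' [cluster_distance()]) until `target_k` live clusters remain or no
#' mergeable pair is left. Once per stage, after `ceiling(t_pct%)` of the
#' planned merges, clusters of size at most `s_crit` are removed as outliers.
#' Ties are broken toward the lexicographically smallest slot pair, making
#' the stage deterministic for fixed inputs.
#'
#' @param initial List of clusters: lists with `members` (1-based matrix
#'   indices) and `tree_id`; `medoid`/`reps` are computed when missing.
#' @param target_k Target number of live clusters (>= 1).
#' @param t_pct Elimination time point in percent of planned merges (0 < t <= 100).
#' @param s_crit Critical size: clusters with `<= s_crit` members are
#'   eliminated. `s_crit = 0` disables elimination.
#' @param m Similarity matrix.
#' @param lofs Per-tract LOF vector.
#' @param rep_cfg A [rep_count_config()].
#' @param guidance Optional internal guidance object (per-tract atlas
#'   memberships); see [run_catser()].
#' @param merge_id_start,step_start Counters threaded through multi-stage runs.
#' @return List with `clusters` (live clusters), `outliers` (member indices
#'   of eliminated clusters), `merges` and `eliminations` tibbles, and the
#'   updated counters `next_id`, `next_step`.
#' @export
agglomerate <- function(initial, target_k, t_pct, s_crit, m, lofs,
                        rep_cfg = rep_count_config(), guidance = NULL,
                        merge_id_start = 1L, step_start = 1L) {
  if (target_k < 1L) stop("target_k must be >= 1")
  if (target_k > length(initial)) stop("target_k exceeds the cluster count")
  c0 <- length(initial)
  planned <- c0 - target_k
  cap <- c0 + planned + 1L
  members <- vector("list", cap)
  reps <- vector("list", cap)
  medoid <- integer(cap)
  tree_id <- integer(cap)
  sizes <- integer(cap)
  active <- logical(cap)
  csums <- if (!is.null(guidance)) matrix(0, cap, guidance$n_classes)

  for (s in seq_len(c0)) {
    cl <- initial[[s]]
    if (is.null(cl$medoid) || is.null(cl$reps))
      cl <- new_cluster(cl$members, cl$tree_id, m, lofs, rep_cfg)
    members[[s]] <- cl$members
    reps[[s]] <- cl$reps
    medoid[s] <- cl$medoid
    tree_id[s] <- cl$tree_id
    sizes[s] <- length(cl$members)
    active[s] <- TRUE
    if (!is.null(guidance))
      csums[s, ] <- colSums(guidance$tract_mem[cl$members, , drop = FALSE])
  }

  pair_weight <- function(i, j) {
    if (is.null(guidance)) return(1)
    guidance_case_factor(csums[i, ] / sizes[i], csums[j, ] / sizes[j],
                         guidance$threshold)
  }
  slot_dist <- function(i, j) {
    cluster_distance(list(reps = reps[[i]]), list(reps = reps[[j]]),
                     m, lofs, weight = pair_weight(i, j))
  }

  D <- matrix(NA_real_, cap, cap)
  act <- which(active)
  for (ii in seq_along(act)) {
    i <- act[ii]
    for (jj in seq_len(ii - 1L)) {
      j <- act[jj]
      D[i, j] <- D[j, i] <- slot_dist(i, j)
    }
  }

  nn_idx <- integer(cap); nn_dist <- rep(Inf, cap)
  refresh_nn <- function(i) {
    others <- which(active); others <- others[others != i]
    if (length(others) == 0L) { nn_idx[i] <<- 0L; nn_dist[i] <<- Inf; return() }
    d <- D[i, others]
    k <- which.min(d)   # first minimum = lowest slot on ties
    nn_idx[i] <<- others[k]; nn_dist[i] <<- d[k]
  }
  for (i in which(active)) refresh_nn(i)

  merges <- list(); elims <- list()
  next_id <- as.integer(merge_id_start)
  step <- as.integer(step_start)
  outliers <- integer(0)
  fired <- s_crit < 1L || planned == 0L  # nothing to eliminate / empty stage
  elim_at <- if (planned > 0L) ceiling(t_pct / 100 * planned) else Inf
  merges_done <- 0L
  nslot <- c0

  eliminate <- function() {
    victims <- which(active & sizes <= s_crit)
    for (v in victims) {
      active[v] <<- FALSE
      outliers <<- c(outliers, members[[v]])
      elims[[length(elims) + 1L]] <<-
        list(cluster_id = tree_id[v], size = sizes[v], step = step)
    }
    if (length(victims) > 0L)
      for (i in which(active)) if (nn_idx[i] %in% victims) refresh_nn(i)
  }

  while (sum(active) > target_k) {
    if (!fired && merges_done >= elim_at) {
      eliminate(); fired <- TRUE
      next
    }
    live <- which(active)
    if (length(live) < 2L) break
    a <- live[which.min(nn_dist[live])]
    b <- nn_idx[a]
    if (!is.finite(nn_dist[a])) break
    pair <- sort(c(a, b)); a <- pair[1]; b <- pair[2]
    dist_ab <- D[a, b]
    nslot <- nslot + 1L
    cnew <- nslot
    mem <- sort(c(members[[a]], members[[b]]))
    members[[cnew]] <- mem
    sizes[cnew] <- length(mem)
    medoid[cnew] <- find_medoid(mem, m)
    reps[[cnew]] <- select_representatives(
      mem, medoid[cnew], m, lofs, num_representatives(length(mem), rep_cfg))
    tree_id[cnew] <- next_id
    if (!is.null(guidance)) csums[cnew, ] <- csums[a, ] + csums[b, ]
    merges[[length(merges) + 1L]] <- list(
      id_a = tree_id[a], id_b = tree_id[b], new_id = next_id,
      dist = dist_ab, step = step)
    active[a] <- FALSE; active[b] <- FALSE; active[cnew] <- TRUE
    live <- which(active); live <- live[live != cnew]
    for (j in live) D[cnew, j] <- D[j, cnew] <- slot_dist(cnew, j)
    refresh_nn(cnew)
    for (i in live) {
      if (nn_idx[i] %in% c(a, b)) refresh_nn(i)
      else if (D[i, cnew] < nn_dist[i]) { nn_idx[i] <- cnew; nn_dist[i] <- D[i, cnew] }
    }
    next_id <- next_id + 1L
    step <- step + 1L
    merges_done <- merges_done + 1L
  }
  if (!fired && merges_done >= elim_at) eliminate()

  live <- which(active)
  list(
    clusters = lapply(live, function(s) list(
      members = members[[s]], medoid = medoid[s], reps = reps[[s]],
      tree_id = tree_id[s])),
    outliers = sort(outliers),
    merges = tibble_from_records(merges,
      c("id_a", "id_b", "new_id", "dist", "step")),
    eliminations = tibble_from_records(elims, c("cluster_id", "size", "step")),
    next_id = next_id, next_step = step
  )
}

tibble_from_records <- function(records, fields) {
  if (length(records) == 0L) {
    out <- setNames(rep(list(numeric(0)), length(fields)), fields)
    return(tibble::as_tibble(out))
  }
  tibble::as_tibble(
    setNames(lapply(fields, function(f)
      vapply(records, function(r) as.numeric(r[[f]]), numeric(1))), fields))
}

# Spread (Eq.-style standard deviation) of a cluster's internal
# representative distances, with fallbacks for degenerate clusters.
cluster_spread <- function(cl, m, global_median) {
  p <- cl$reps
  if (length(p) >= 2L) {
    sub <- m[p, p, drop = FALSE]
    vals <- sub[lower.tri(sub)]
    if (length(vals) >= 2L) return(sd(vals))
    # a single representative pair has no dispersion estimate; fall through
    # to the mean internal distance
  }
  mem <- cl$members
  if (length(mem) >= 2L) {
    sub <- m[mem, mem, drop = FALSE]
    return(mean(sub[lower.tri(sub)]))
  }
  global_median
}

#' Assign a tract to its nearest prototype cluster or label it an outlier
#'
#' The tract is compared against every cluster's representatives; the nearest
#' cluster (smallest representative distance, atlas-weighted when guidance is
#' active) accepts the tract only if that distance is within `gamma` times
#' the spread of the cluster's internal representative distances (their
#' standard deviation; for clusters with fewer than two representative pairs
#' the mean internal member distance is used, and for singletons the global
#' median pairwise distance of the sample). Otherwise the tract is labeled
#' an outlier.
#'
#' @param dists_by_cluster Numeric vector: distance from the tract to the
#'   nearest representative of each cluster (already weighted if guided).
#' @param spreads Numeric vector of per-cluster spreads (same order).
#' @param gamma Positive acceptance factor; larger values admit more tracts.
#' @return 1-based cluster index, or `NA_integer_` for an outlier.
#' @export
reassign_or_label <- function(dists_by_cluster, spreads, gamma) {
  stopifnot(length(dists_by_cluster) == length(spreads), gamma > 0)
  k <- which.min(dists_by_cluster)
  if (length(k) == 0L) return(NA_integer_)
  if (dists_by_cluster[k] <= gamma * spreads[k]) k else NA_integer_
}
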