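# Local Outlier Factors (Breunig et al.) from a precomputed similarity
# matrix. LOF ~ 1 for tracts deep inside a cluster, >> 1 for isolated tracts.

#' k-nearest neighbours of a tract in a similarity matrix
#'
#' Ties are broken toward the lower index, and the result is sorted by
#' (distance, index), which makes every LOF quantity deterministic.
#'
#' @param m A `tract_simmat` (or plain symmetric distance matrix).
#' @param i 1-based row index of the query tract.
#' @param k Neighbour count, `1 <= k <= n - 1`.
#' @return A tibble with columns `id` (1-based neighbour index) and `dist`.
#' @export
k_nearest <- function(m, i, k) {
  n <- nrow(m)
  if (k < 1L || k > n - 1L) stop("k must be in [1, n-1]")
  d <- m[i, -i]
  ids <- seq_len(n)[-i]
  ord <- order(d, ids)[seq_len(k)]
  tibble::tibble(id = ids[ord], dist = d[ord])
}

#' Local Outlier Factors for all tracts of a similarity matrix
#'
#' Standard density-based LOF: for each tract the k-distance, the
#' reachability distances to its k nearest neighbours, the local reachability
#' density (LRD, the inverse mean reachability distance) and finally
#' `LOF = mean(LRD of neighbours) / LRD(self)`. Exact duplicates give
#' infinite LRDs; whenever a tract and all its neighbours have infinite LRD
#' the LOF is defined as 1 (the point is maximally embedded, not outlying).
#'
#' The neighbour count trades statistical stability (small k fluctuates)
#' against resolution: k should be at least about 10 and not exceed the size
#' of the smallest cluster expected in the data, otherwise LOFs of small
#' clusters are artificially elevated. The package default of `k = 15`
#' follows that guidance.
#'
#' @param m A `tract_simmat` (or plain symmetric distance matrix).
#' @param k Neighbour count (default 15).
#' @return A `lof_result`: list with `k`, and per-tract vectors `lof`,
#'   `k_distance`, `lrd`.
#' @export
compute_lofs <- function(m, k = 15L) {
  n <- nrow(m)
  if (n <= k) stop("need more tracts than k (n = ", n, ", k = ", k, ")")
  neigh <- matrix(0L, n, k)     # neighbour indices
  ndist <- matrix(0, n, k)      # distances to them
  for (i in seq_len(n)) {
    nn <- k_nearest(m, i, k)
    neigh[i, ] <- nn$id
    ndist[i, ] <- nn$dist
  }
  k_dist <- ndist[, k]
  # reachability of i from its neighbour o: max(k_distance(o), d(i, o))
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(k_dist[neigh[i, ]], ndist[i, ])
    mr <- mean(reach)
    lrd[i] <- if (mr == 0) Inf else 1 / mr
  }
  lof <- numeric(n)
  for (i in seq_len(n)) {
    ln <- lrd[neigh[i, ]]
    if (is.infinite(lrd[i])) {
      lof[i] <- if (all(is.infinite(ln))) 1 else mean(ln / lrd[i])
    } else {
      lof[i] <- mean(ln) / lrd[i]
    }
  }
  structure(list(k = as.integer(k), lof = lof, k_distance = k_dist, lrd = lrd),
            class = "lof_result")
}

#' @export
print.lof_result <- function(x, ...) {
  cat(sprintf("<lof_result> n = %d, k = %d, median LOF = %.3f, max LOF = %.3f\n",
              length(x$lof), x$k, median(x$lof), max(x$lof)))
  invisible(x)
}
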