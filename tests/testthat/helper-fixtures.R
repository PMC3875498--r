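# Shared fixtures and independent oracles for the test suite. Oracles are
# written as straightforward brute-force computations, independent of the
# package's implementation paths.

seg <- function(a, b) rbind(a, b)

# a random smooth-ish polyline with npts points inside a box of size `scale`
random_tract <- function(npts = NULL, scale = 50) {
  if (is.null(npts)) npts <- sample(5:15, 1)
  start <- runif(3, 0, scale)
  dirs <- matrix(rnorm(3 * (npts - 1), sd = 2), ncol = 3)
  apply(rbind(start, dirs), 2, cumsum)
}

# a smooth streamline-like tract (spline through a few control points)
smooth_tract <- function(n_ctrl = 5, npts = 100, scale = 60) {
  cp <- cbind(seq(0, scale, length.out = n_ctrl),
              runif(n_ctrl, 0, scale / 4), runif(n_ctrl, 0, scale / 8))
  u <- seq_len(n_ctrl)
  uu <- seq(1, n_ctrl, length.out = npts)
  cbind(spline(u, cp[, 1], xout = uu)$y,
        spline(u, cp[, 2], xout = uu)$y,
        spline(u, cp[, 3], xout = uu)$y)
}

# independent arc-length resampling oracle: walks the polyline segment by
# segment and linearly interpolates at the requested arc positions
walk_resample <- function(t, n) {
  lens <- sqrt(rowSums((t[-1, , drop = FALSE] - t[-nrow(t), , drop = FALSE])^2))
  total <- sum(lens)
  targets <- seq(0, total, length.out = n)
  out <- matrix(NA_real_, n, 3)
  for (q in seq_len(n)) {
    s <- targets[q]
    acc <- 0; row <- nrow(t)
    for (i in seq_along(lens)) {
      if (acc + lens[i] >= s - 1e-12) {
        f <- if (lens[i] == 0) 0 else (s - acc) / lens[i]
        out[q, ] <- t[i, ] + f * (t[i + 1, ] - t[i, ])
        row <- 0
        break
      }
      acc <- acc + lens[i]
    }
    if (row == nrow(t)) out[q, ] <- t[nrow(t), ]
  }
  out
}

random_dataset <- function(n, npts = NULL, scale = 50) {
  tract_dataset(lapply(seq_len(n), function(i) random_tract(npts, scale)))
}

# O(n*m) double-loop point-set Hausdorff oracle
naive_hausdorff <- function(a, b) {
  one <- function(p, q) {
    max(apply(p, 1, function(x) min(sqrt(colSums((t(q) - x)^2)))))
  }
  max(one(a, b), one(b, a))
}

# Naive Breunig LOF from a distance matrix (same duplicate convention as
# the package documents: LOF = 1 when self and all neighbours have
# infinite local reachability density).
naive_lof <- function(m, k) {
  n <- nrow(m)
  nn <- lapply(seq_len(n), function(i) {
    d <- m[i, -i]; ids <- seq_len(n)[-i]
    ord <- order(d, ids)[seq_len(k)]
    list(ids = ids[ord], d = d[ord])
  })
  kdist <- vapply(nn, function(x) x$d[k], numeric(1))
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nn[[i]]$ids], nn[[i]]$d)
    if (mean(reach) == 0) Inf else 1 / mean(reach)
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    ln <- lrd[nn[[i]]$ids]
    if (is.infinite(lrd[i])) {
      if (all(is.infinite(ln))) 1 else mean(ln / lrd[i])
    } else mean(ln) / lrd[i]
  }, numeric(1))
}

# distance matrix from a set of 3D points (used for LOF/point tests)
point_dist_matrix <- function(pts) {
  m <- as.matrix(dist(pts))
  attr(m, "measure") <- "tcd"
  class(m) <- c("tract_simmat", "matrix", "array")
  m
}

# tiny two-bundle scene used by several atlas/matching tests
two_bundle_scene <- function(n_per = 12, seed = 42) {
  set.seed(seed)
  specs <- list(
    bundle_spec("alpha", rbind(c(0, 0, 0), c(10, 2, 0), c(20, 0, 0)),
                n_tracts = n_per, radial_sd = 0.5),
    bundle_spec("beta", rbind(c(0, 30, 0), c(10, 32, 0), c(20, 30, 0)),
                n_tracts = n_per, radial_sd = 0.5)
  )
  generate_bundles(specs)
}
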