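test_that("rasterization covers traversed voxels and clips outside", {
  g <- voxel_grid(origin = c(0, 0, 0), shape = c(10, 10, 10), resolution = 1)
  # axis-aligned 3 mm segment on a 1 mm grid: 3-4 voxels
  idx <- rasterize_tract(seg(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5)), g)
  expect_true(nrow(idx) %in% 3:4)
  # superset check against a very dense sampling oracle
  dense <- seq(0, 1, by = 0.001)
  oracle <- unique(floor(cbind(0.5 + 3 * dense, 0.5, 0.5)))
  expect_true(all(oracle[, 1] %in% idx[, 1]))
  # tract inside one voxel
  one <- rasterize_tract(seg(c(2.1, 2.1, 2.1), c(2.8, 2.8, 2.8)), g)
  expect_equal(nrow(one), 1)
  expect_equal(unname(one[1, ]), c(2, 2, 2))
  # diagonal segment contains both endpoint voxels
  diag_idx <- rasterize_tract(seg(c(0.5, 0.5, 0.5), c(8.5, 8.5, 8.5)), g)
  expect_true(any(rowSums(diag_idx == 0) == 3))
  expect_true(any(rowSums(diag_idx == 8) == 3))
  # clipping and the all-outside error
  expect_warning(rasterize_tract(seg(c(-5, 0.5, 0.5), c(2.5, 0.5, 0.5)), g),
                 "clipped")
  expect_error(suppressWarnings(
    rasterize_tract(seg(c(-9, -9, -9), c(-5, -5, -5)), g)), "outside")
})

test_that("tract and cluster class membership are overlap fractions", {
  g <- voxel_grid(shape = c(20, 5, 5))
  cls <- list(name = "c", keys = tractclust:::voxel_key(g, cbind(0:9, 0, 0)),
              prob = rep(1, 10))
  inside <- seg(c(0.5, 0.5, 0.5), c(9.4, 0.5, 0.5))
  outside <- seg(c(10.6, 0.5, 0.5), c(19.4, 0.5, 0.5))
  expect_equal(tract_class_membership(inside, cls, g), 1)
  expect_equal(tract_class_membership(outside, cls, g), 0)
  # constructed tract occupying 10 voxels with 4 in class
  t_mixed <- seg(c(6.5, 0.5, 0.5), c(15.5, 0.5, 0.5))
  keys <- tractclust:::rasterize_keys(t_mixed, g)
  expect_equal(length(keys), 10)
  expect_equal(tract_class_membership(t_mixed, cls, g), 0.4)
  # cluster membership is the mean; order-invariant
  expect_equal(cluster_class_membership(list(inside, t_mixed), cls, g), 0.7)
  expect_equal(cluster_class_membership(list(t_mixed, inside), cls, g), 0.7)
  expect_equal(cluster_class_membership(list(inside), cls, g), 1)
})

test_that("the four weighting cases attract and repel as specified", {
  g <- voxel_grid(shape = c(40, 10, 10))
  atlas <- structure(list(grid = g, classes = list(
    A = list(name = "A", keys = tractclust:::voxel_key(g, cbind(0:9, 0, 0)),
             prob = rep(1, 10)),
    B = list(name = "B", keys = tractclust:::voxel_key(g, cbind(20:29, 0, 0)),
             prob = rep(1, 10))
  )), class = "prob_atlas")
  in_A <- list(seg(c(0.5, 0.5, 0.5), c(9.4, 0.5, 0.5)))
  in_B <- list(seg(c(20.5, 0.5, 0.5), c(29.4, 0.5, 0.5)))
  off <- list(seg(c(30.5, 5.5, 5.5), c(39.4, 5.5, 5.5)))
  # case 1: neither corresponds -> neutral
  expect_equal(weighting_factor(off, off, atlas), 1)
  # case 2: exactly one corresponds -> repulsion growing with membership
  w2 <- weighting_factor(in_A, off, atlas)
  expect_gt(w2, 1)
  # case 3: same class -> attraction
  w3 <- weighting_factor(in_A, in_A, atlas)
  expect_lt(w3, 1)
  # case 4: different classes -> strongest repulsion
  w4 <- weighting_factor(in_A, in_B, atlas)
  expect_gt(w4, 1)
  expect_gt(w4, w2)
  # symmetry
  expect_equal(weighting_factor(in_A, in_B, atlas),
               weighting_factor(in_B, in_A, atlas))
  expect_equal(weighting_factor(in_A, off, atlas),
               weighting_factor(off, in_A, atlas))
})

test_that("case factors are monotone in the memberships", {
  # case 2: repulsion increases with the corresponding membership
  w <- vapply(seq(0.1, 1, 0.1), function(s)
    tractclust:::guidance_case_factor(c(s, 0), c(0, 0)), numeric(1))
  expect_true(all(diff(w) > 0))
  # case 3: attraction deepens as memberships grow
  w3 <- vapply(seq(0.1, 1, 0.1), function(s)
    tractclust:::guidance_case_factor(c(s, 0), c(s, 0)), numeric(1))
  expect_true(all(diff(w3) < 0))
  expect_true(all(w3 < 1))
  # case 4: repulsion increases in both arguments
  w4a <- vapply(seq(0.1, 1, 0.1), function(s)
    tractclust:::guidance_case_factor(c(s, 0), c(0, 0.5)), numeric(1))
  expect_true(all(diff(w4a) > 0))
})

test_that("atlas construction follows density ratio, averaging and cutoff", {
  g <- voxel_grid(shape = c(30, 6, 6))
  # single dataset, bundle-exclusive voxels: probability 1 everywhere
  bA <- seg(c(0.5, 0.5, 0.5), c(9.4, 0.5, 0.5))
  bB <- seg(c(0.5, 3.5, 3.5), c(9.4, 3.5, 3.5))
  ds1 <- tract_dataset(list(bA, bA, bB))
  atlas1 <- build_atlas(list(list(dataset = ds1,
                                  labels = c("A", "A", "B"))), g)
  expect_setequal(names(atlas1$classes), c("A", "B"))
  expect_true(all(atlas1$classes$A$prob == 1))
  expect_true(all(atlas1$classes$B$prob == 1))
  # two datasets; a voxel with dataset probabilities 0.5 and 1 averages 0.75
  shared <- seg(c(0.5, 0.5, 0.5), c(9.4, 0.5, 0.5))    # A in both datasets
  ds2 <- tract_dataset(list(shared, shared))           # A and B overlap fully
  atlas2 <- build_atlas(list(
    list(dataset = ds2, labels = c("A", "B")),         # p_A = 0.5 per voxel
    list(dataset = tract_dataset(list(shared)), labels = "A")  # p_A = 1
  ), g, prob_cutoff = 0)
  # class A: mean(0.5, 1) = 0.75 pre-normalization; max-normalized to 1
  expect_equal(unique(atlas2$classes$A$prob), 1)
  # cutoff removes weak voxels after per-class max-normalization: bundle B
  # owns voxels x 0-4 alone (prob 1) but is diluted to 0.2 by four A-tracts
  # over x 5-9, so the 0.2 voxels fall below the 0.3 cutoff
  tB <- seg(c(0.5, 0.5, 0.5), c(9.4, 0.5, 0.5))
  tA <- seg(c(5.5, 0.5, 0.5), c(9.4, 0.5, 0.5))
  ds3 <- tract_dataset(list(tB, tA, tA, tA, tA))
  atlas3 <- build_atlas(list(
    list(dataset = ds3, labels = c("B", "A", "A", "A", "A"))), g,
    prob_cutoff = 0.3)
  kept <- tractclust:::key_to_index(g, atlas3$classes$B$keys)
  expect_setequal(kept[, 1], 0:4)
  # a voxel with final probability 0.25 and cutoff 0.3 is absent; with a
  # lower cutoff it survives
  atlas3b <- build_atlas(list(
    list(dataset = ds3, labels = c("B", "A", "A", "A", "A"))), g,
    prob_cutoff = 0.1)
  expect_setequal(tractclust:::key_to_index(g, atlas3b$classes$B$keys)[, 1], 0:9)
})

test_that("atlas round-trips through NIfTI volumes with manifest", {
  g <- voxel_grid(origin = c(-2, -2, -2), shape = c(12, 8, 8))
  bA <- seg(c(0.5, 0.5, 0.5), c(7.4, 0.5, 0.5))
  ds <- tract_dataset(list(bA, bA))
  atlas <- build_atlas(list(list(dataset = ds, labels = c("A", "A"))), g)
  dir <- withr::local_tempdir()
  write_atlas_nifti(atlas, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  atlas2 <- read_atlas_nifti(dir)
  expect_equal(names(atlas2$classes), names(atlas$classes))
  expect_equal(atlas2$classes$A$keys, atlas$classes$A$keys)
  expect_equal(atlas2$classes$A$prob, atlas$classes$A$prob, tolerance = 1e-6)
  expect_equal(atlas2$grid$shape, atlas$grid$shape)
})

test_that("atlas-driven post-merge rejoins split bundles and is idempotent", {
  # one bundle along y = 0.5, x 0..19, split into two halves whose tracts
  # share an off-atlas "stem" (both halves leave the class volume through
  # the same region): re-joining de-duplicates the shared fringe and raises
  # the union-voxel agreement above both halves
  g <- voxel_grid(shape = c(20, 12, 3))
  stem <- c(9.5, 9.5, 0.5)
  left <- rbind(stem, c(9.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  right <- rbind(stem, c(9.5, 0.5, 0.5), c(19.4, 0.5, 0.5))
  # atlas class: the full bundle row only (built from straight tracts)
  row_tract <- seg(c(0.5, 0.5, 0.5), c(19.4, 0.5, 0.5))
  atlas <- build_atlas(list(list(
    dataset = tract_dataset(list(row_tract, row_tract)),
    labels = c("bundle", "bundle"))), g)
  # a second, distant class that must stay untouched
  far_tract <- seg(c(0.5, 11.5, 2.5), c(19.4, 11.5, 2.5))
  atlas2 <- build_atlas(list(list(
    dataset = tract_dataset(list(row_tract, row_tract, far_tract)),
    labels = c("bundle", "bundle", "far"))), g)
  ds <- tract_dataset(list(left, left, right, right, far_tract, far_tract))
  res <- structure(list(
    clusters = list(
      list(members = c(0L, 1L), medoid = 0L, reps = c(0L, 1L), tree_id = 1),
      list(members = c(2L, 3L), medoid = 2L, reps = c(2L, 3L), tree_id = 2),
      list(members = c(4L, 5L), medoid = 4L, reps = c(4L, 5L), tree_id = 3)),
    outlier_ids = integer(0),
    labels = tibble::tibble(tract_id = 0:5, cluster = c(1L, 1L, 2L, 2L, 3L, 3L)),
    tree = list(merges = tibble::tibble(id_a = numeric(0), id_b = numeric(0),
                                        new_id = numeric(0), dist = numeric(0),
                                        step = numeric(0)),
                eliminations = NULL, leaves = 0:5)), class = "catser_result")
  merged <- post_merge_by_atlas(res, ds, atlas2)
  expect_equal(length(merged$clusters), 2)
  sizes <- sort(vapply(merged$clusters, function(cl)
    length(cl$members), numeric(1)))
  expect_equal(sizes, c(2, 4))
  # the two halves were merged; the far cluster was not absorbed
  big <- merged$clusters[[which.max(sizes == 4)]]
  four <- merged$clusters[[which(vapply(merged$clusters, function(cl)
    length(cl$members), numeric(1)) == 4)]]
  expect_setequal(four$members, 0:3)
  expect_equal(nrow(merged$tree$merges), 1)
  # idempotence: a second invocation changes nothing
  merged2 <- post_merge_by_atlas(merged, ds, atlas2)
  expect_equal(lapply(merged2$clusters, `[[`, "members"),
               lapply(merged$clusters, `[[`, "members"))
})
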