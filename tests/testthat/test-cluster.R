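grid_mask <- function(shape, name = "m") {
  network_mask(seq_len(prod(shape)), vol_geometry(shape, c(2, 2, 2)),
               name)
}

test_that("label_clusters finds signed components and partitions voxels", {
  shape <- c(8, 8, 6)
  mask <- grid_mask(shape)
  expect_equal(nrow(label_clusters(array(0, shape), mask, 1.96)), 0)
  ## one 3x3x3 block of z = +3
  z <- array(0, shape); z[3:5, 3:5, 2:4] <- 3
  cl <- label_clusters(z, mask, 1.96)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$sign, "+")
  expect_equal(cl$n_voxels, 27)
  ## random +/- map: partition identical to the label-propagation oracle
  set.seed(21)
  zr <- array(rnorm(prod(shape)), shape)
  for (adj in c(6, 18, 26)) {
    cl <- label_clusters(zr, mask, 1.0, adjacency = adj)
    pos <- which(as.vector(zr) > 1.0)
    neg <- which(as.vector(zr) < -1.0)
    got <- canon_components(cl$voxels)
    want <- canon_components(c(oracle_components(pos, shape, adj),
                               oracle_components(neg, shape, adj)))
    expect_identical(got, want)
    ## every suprathreshold voxel in exactly one cluster
    allv <- sort(unlist(cl$voxels))
    expect_identical(allv, sort(c(pos, neg)))
    expect_false(anyDuplicated(allv) > 0)
  }
})

test_that("positive and negative clusters never merge across signs", {
  shape <- c(6, 1, 1)
  z <- array(c(3, 3, -3, -3, 3, 3), shape)
  cl <- label_clusters(z, grid_mask(shape), 1.96)
  expect_equal(nrow(cl), 3)
  expect_equal(sum(cl$sign == "+"), 2)
  expect_equal(sum(cl$sign == "-"), 1)
})

test_that("cluster statistics follow the reporting conventions", {
  shape <- c(12, 12, 8)
  geom <- vol_geometry(shape, c(2, 2, 2),
                       world_convention = "right_positive_x")
  ## 44 voxels at 2-mm isotropic -> 352 mm^3 (table granularity: x8)
  vox44 <- block_region(1:11, 1:4, 1:1, shape)[1:44]
  z <- array(0, shape); z[vox44] <- 2.5; z[vox44[3]] <- 3.0
  st <- cluster_stats(vox44, z, geom)
  expect_equal(st$volume_mm3, 352)
  expect_equal(st$peak_z, 3.0)
  ## single voxel at 0-based (3,1,2): center (6,2,4)
  st1 <- cluster_stats(ijk_to_lin <- conmap:::ijk_to_linear(c(4, 2, 3), shape),
                       array(1, shape), geom)
  expect_equal(unname(unlist(st1[c("x", "y", "z")])), c(6, 2, 4))
  ## symmetric 3x3x3 block centers on its middle voxel
  blk <- block_region(4:6, 4:6, 3:5, shape)
  stb <- cluster_stats(blk, array(1, shape), geom)
  expect_equal(unname(unlist(stb[c("x", "y", "z")])),
               unname(world_coords(c(5, 5, 4), geom)))
  expect_error(cluster_stats(integer(0), z, geom), "empty")
})

test_that("size thresholds implement the exceedance rule", {
  ## all-null permutations -> threshold 1
  expect_equal(conmap:::size_threshold(rep(0L, 100), 0.05), 1L)
  ## smallest s with #{sizes >= s}/n < alpha
  sizes <- c(rep(0L, 90), 1L, 2L, 3L, 5L, 8L, 9L, 11L, 12L, 13L, 20L)
  thr <- conmap:::size_threshold(sizes, 0.05)
  expect_equal(thr, 10L)   # 5th-largest size is 9; counts: #{>=10}=4, #{>=9}=5
  expect_lt(mean(sizes >= thr), 0.05)
  expect_gte(mean(sizes >= thr - 1L), 0.05)
})

test_that("apply_cluster_threshold keeps sizes above max(threshold, floor)", {
  shape <- c(44, 5, 1)                 # separate clusters on rows 1/3/5
  z <- array(0, shape)
  z[1:5, 1, 1] <- 3; z[1:20, 3, 1] <- 3; z[1:44, 5, 1] <- 3
  cl <- label_clusters(z, grid_mask(shape), 1.96)
  expect_setequal(cl$n_voxels, c(5, 20, 44))
  kept <- apply_cluster_threshold(cl, 20)
  expect_setequal(kept$n_voxels, c(20, 44))
  ## driver rule: permutation gave single digits but a 20-voxel floor
  ## is imposed -> clusters of 7 and 15 voxels are both dropped
  z2 <- array(0, shape)
  z2[1:7, 1, 1] <- 4; z2[1:15, 3, 1] <- 4      # sizes 7, 15
  cl2 <- label_clusters(z2, grid_mask(shape), 3.291)
  expect_setequal(cl2$n_voxels, c(7, 15))
  expect_equal(nrow(apply_cluster_threshold(cl2, 7, floor_voxels = 20)), 0)
  expect_equal(nrow(apply_cluster_threshold(cl2[0, ], 5)), 0)
})

test_that("permutation null is exact under identical conditions", {
  set.seed(22)
  shape <- c(6, 6, 4)
  mask <- grid_mask(shape)
  A <- matrix(rnorm(8 * prod(shape)), 8)
  pd <- perm_cluster_threshold(A, A, mask, 1.96, n_perm = 50, seed = 5)
  expect_true(all(pd$max_cluster_sizes == 0))
  expect_equal(pd$threshold_voxels, 1L)
  ## determinism under a fixed seed
  B <- matrix(rnorm(8 * prod(shape)), 8)
  p1 <- perm_cluster_threshold(A, B, mask, 1.0, n_perm = 30, seed = 7)
  p2 <- perm_cluster_threshold(A, B, mask, 1.0, n_perm = 30, seed = 7)
  expect_identical(p1$max_cluster_sizes, p2$max_cluster_sizes)
  expect_identical(p1$threshold_voxels, p2$threshold_voxels)
})

test_that("sign-flip z matrix agrees with per-voxel paired t", {
  set.seed(23)
  n <- 9; V <- 40
  A <- matrix(rnorm(n * V), n); B <- matrix(rnorm(n * V), n)
  flip <- c(1, 4, 5, 8)
  S <- matrix(1, 1, n); S[flip] <- -1
  Z <- conmap:::signflip_z_matrix(A - B, S)
  ## oracle: physically swap (a, b) for the flipped subjects
  A2 <- A; B2 <- B
  A2[flip, ] <- B[flip, ]; B2[flip, ] <- A[flip, ]
  for (v in seq_len(V)) {
    pt_res <- paired_t(A2[, v], B2[, v])
    expect_equal(Z[1, v], t_to_z(pt_res$t, pt_res$df), tolerance = 1e-12)
  }
})

test_that("permutation threshold responds monotonically to leniency", {
  set.seed(24)
  shape <- c(8, 8, 4)
  mask <- grid_mask(shape)
  n <- 10
  base <- array(rnorm(prod(shape) * n), c(n, prod(shape)))
  B <- base + matrix(rnorm(n * prod(shape), sd = 0.5), n)
  A <- base + matrix(rnorm(n * prod(shape), sd = 0.5), n)
  thr_strict <- perm_cluster_threshold(A, B, mask, 2.5, n_perm = 60,
                                       seed = 9)$threshold_voxels
  thr_lenient <- perm_cluster_threshold(A, B, mask, 1.5, n_perm = 60,
                                        seed = 9)$threshold_voxels
  expect_gte(thr_lenient, thr_strict)
  a_small <- perm_cluster_threshold(A, B, mask, 1.5, n_perm = 60,
                                    alpha = 0.01, seed = 9)$threshold_voxels
  expect_gte(a_small, thr_lenient)
})

test_that("mask dilation grows by the chosen neighborhood", {
  shape <- c(7, 7, 5)
  g <- vol_geometry(shape)
  m <- network_mask(conmap:::ijk_to_linear(c(4, 4, 3), shape), g)
  d1 <- dilate_mask(m, 1, adjacency = 6)
  expect_length(d1, 7)
  d26 <- dilate_mask(m, 1, adjacency = 26)
  expect_length(d26, 27)
  expect_true(all(m$voxels %in% d1$voxels))
  expect_identical(dilate_mask(m, 0)$voxels, m$voxels)
  ## clipped at the grid edge
  corner <- network_mask(conmap:::ijk_to_linear(c(1, 1, 1), shape), g)
  expect_length(dilate_mask(corner, 1, adjacency = 6), 4)
})
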