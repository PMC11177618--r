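test_that("group seed map separates connected from unconnected voxels", {
  set.seed(71)
  shape <- c(8, 4, 2)
  nvox <- prod(shape)
  nt <- 150
  ## half the "brain" shares the seed's latent
  connected <- block_region(1:4, 1:4, 1:2, shape)
  runs <- lapply(1:8, function(s) {
    g <- rnorm(nt)
    X <- matrix(rnorm(nt * nvox), nt, nvox)
    X[, connected] <- X[, connected] + g
    run_from_matrix(X, shape)
  })
  seed <- network_mask(connected[1:2], vol_geometry(shape), "seed")
  gm <- group_seed_map(runs, seed)
  far <- setdiff(seq_len(nvox), connected)
  expect_gt(min(gm$z_map[setdiff(connected, seed$voxels)]), 2)
  expect_lt(mean(abs(gm$z_map[far]) > 2), 0.2)
  expect_equal(gm$df, 7L)
  expect_error(group_seed_map(runs[1], seed), "at least 2")
})

test_that("null group seed maps are standard-normal fieldwise", {
  set.seed(72)
  shape <- c(10, 6, 3)
  nvox <- prod(shape)
  runs <- lapply(1:10, function(s)
    run_from_matrix(matrix(rnorm(120 * nvox), 120), shape))
  seedm <- network_mask(1L, vol_geometry(shape), "seed")
  gm <- group_seed_map(runs, seedm)
  z <- gm$z_map[-1]                        # exclude the seed voxel itself
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_equal(sd(z), 1, tolerance = 0.15)
})

test_that("noise cluster threshold behaves at the independence limit", {
  g <- vol_geometry(c(12, 12, 8), c(2, 2, 2))
  mask <- network_mask(seq_len(prod(g$shape)), g, "brain")
  thr <- noise_cluster_threshold(mask, smooth_fwhm_mm = 0,
                                 voxel_p = 1e-8, n_sim = 100,
                                 alpha = 0.01, seed = 1)
  expect_equal(thr, 1L)
  thr2 <- noise_cluster_threshold(mask, smooth_fwhm_mm = 0,
                                  voxel_p = 1e-8, n_sim = 100,
                                  alpha = 0.01, seed = 1)
  expect_identical(thr, thr2)
})

test_that("noise cluster threshold grows with smoothness", {
  g <- vol_geometry(c(12, 12, 8), c(2, 2, 2))
  mask <- network_mask(seq_len(prod(g$shape)), g, "brain")
  thrs <- vapply(c(0, 4, 8), function(fw)
    noise_cluster_threshold(mask, smooth_fwhm_mm = fw, voxel_p = 0.01,
                            n_sim = 100, alpha = 0.05, seed = 2), 0L)
  expect_true(all(diff(thrs) >= 0))
  expect_gt(thrs[3], thrs[1])
})

test_that("define_network thresholds, filters, and dilates", {
  shape <- c(12, 12, 6)
  g <- vol_geometry(shape, c(2, 2, 2))
  mask <- network_mask(seq_len(prod(shape)), g, "brain")
  z <- array(0, shape)
  blob <- block_region(3:7, 3:7, 2:5, shape)           # 100 voxels
  z[blob] <- 7
  z[block_region(10:11, 10:11, 1:1, shape)] <- 7       # 4-voxel speck
  gm <- structure(list(z_map = z, t_map = z, df = 9L, n = 10L,
                       mask = mask), class = "group_map")
  net <- define_network(gm, voxel_p = 1e-8, cluster_threshold = 20,
                        dilate_iters = 1, name = "N")
  expect_true(all(blob %in% net$voxels))
  expect_gt(length(net), 100)                          # dilation grew it
  expect_length(setdiff(net$voxels, dilate_mask(
    network_mask(blob, g), 1)$voxels), 0)              # speck filtered
  net0 <- define_network(gm, voxel_p = 1e-8, cluster_threshold = 20,
                         dilate_iters = 0, name = "N")
  expect_identical(net0$voxels, sort(blob))
  ## leniency in voxel_p is monotone (superset)
  z2 <- z; z2[block_region(3:7, 9:11, 2:4, shape)] <- 5
  gm2 <- structure(list(z_map = z2, t_map = z2, df = 9L, n = 10L,
                        mask = mask), class = "group_map")
  strict <- define_network(gm2, 1e-8, 1, 0)
  lenient <- define_network(gm2, 1e-4, 1, 0)
  expect_true(all(strict$voxels %in% lenient$voxels))
  expect_gt(length(lenient), length(strict))
  ## empty network errors
  expect_error(define_network(
    structure(list(z_map = array(0, shape), mask = mask),
              class = "group_map"), 1e-8, 1, 0), "empty")
})

test_that("networks defined from synthetic sham data recover the truth", {
  shape <- c(14, 14, 8)
  truth_region <- block_region(3:10, 3:10, 3:6, shape)
  cfg <- sim_config(n_subjects = 12, n_frames = 300, grid_shape = shape,
                    conditions = "sham",
                    network_specs = list(network_spec("HCN", truth_region)))
  st <- generate_study(cfg, seed = 73)
  seed_vox <- block_region(6:7, 6:7, 4:5, shape)
  gm <- group_seed_map(st$runs$sham,
                       network_mask(seed_vox, st$geometry, "seed"))
  net <- define_network(gm, voxel_p = 1e-8, cluster_threshold = 5,
                        dilate_iters = 0, name = "HCN_est")
  expect_gte(truth_overlap(net$voxels, truth_region), 0.7)
  ## overlap bookkeeping between two masks
  expect_equal(mask_overlap(net, st$masks$HCN),
               length(intersect(net$voxels, truth_region)))
})
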