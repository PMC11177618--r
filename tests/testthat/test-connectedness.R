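test_that("connectedness equals dense correlation row means", {
  set.seed(31)
  shape <- c(5, 4, 3)
  nvox <- prod(shape)
  mask_vox <- sort(sample(nvox, 30))
  net <- network_mask(mask_vox, vol_geometry(shape), "net")
  run <- run_from_matrix(matrix(rnorm(100 * nvox), 100, nvox), shape,
                         censored = c(9L, 50L))
  cm <- connectedness_map(run, net)
  expect_equal(cm$values[mask_vox], oracle_connectedness(run, mask_vox),
               tolerance = 1e-10)
  expect_true(all(is.na(cm$values[setdiff(seq_len(nvox), mask_vox)])))
})

test_that("connectedness handles boundary and degenerate networks", {
  shape <- c(2, 1, 1)
  s <- sin(seq_len(50))
  run <- run_from_matrix(cbind(s, s), shape)
  net <- network_mask(1:2, vol_geometry(shape))
  ## two identical series: mean r = 1, clipped Fisher z with warning
  expect_warning(cm <- connectedness_map(run, net), "clipped")
  expect_equal(cm$values[1], atanh(1 - 1e-7))
  ## mutually orthogonal series -> values near 0
  n <- 64
  tt <- seq_len(n)
  X <- cbind(sin(2 * pi * tt / n), cos(2 * pi * tt / n),
             sin(4 * pi * tt / n), cos(4 * pi * tt / n))
  shape2 <- c(4, 1, 1)
  run2 <- run_from_matrix(X, shape2)
  cm2 <- connectedness_map(run2, network_mask(1:4, vol_geometry(shape2)))
  expect_lt(max(abs(cm2$values)), 3 / sqrt(n))
  ## constant voxel: dropped from others' means with warning
  X3 <- cbind(rnorm(50), rnorm(50), rep(1, 50))
  shape3 <- c(3, 1, 1)
  run3 <- run_from_matrix(X3, shape3)
  expect_warning(cm3 <- connectedness_map(
    run3, network_mask(1:3, vol_geometry(shape3))), "constant")
  expect_true(is.nan(cm3$values[3]))
  expect_equal(cm3$values[1], atanh(cor(X3[, 1], X3[, 2])),
               tolerance = 1e-12)
})

test_that("connectedness is invariant to per-voxel affine rescaling", {
  set.seed(32)
  shape <- c(4, 3, 2)
  X <- matrix(rnorm(80 * 24), 80, 24)
  net <- network_mask(1:24, vol_geometry(shape))
  base <- connectedness_map(run_from_matrix(X, shape), net)
  Xs <- sweep(X, 2, runif(24, 0.5, 3), `*`)
  Xs <- sweep(Xs, 2, rnorm(24, 10), `+`)
  resc <- connectedness_map(run_from_matrix(Xs, shape), net)
  expect_equal(resc$values, base$values, tolerance = 1e-10)
})

test_that("z-first averaging conserves the off-diagonal mean", {
  set.seed(33)
  shape <- c(4, 4, 1)
  X <- matrix(rnorm(60 * 16), 60, 16)
  net <- network_mask(1:16, vol_geometry(shape))
  run <- run_from_matrix(X, shape)
  cmz <- connectedness_map(run, net, z_first = TRUE)
  R <- cor(X)
  zoff <- atanh(R[row(R) != col(R)])
  expect_equal(mean(cmz$values[net$voxels]), mean(zoff),
               tolerance = 1e-10)
  ## include_self reproduces the diagonal-kept mean on the r scale
  cms <- connectedness_map(run, net, include_self = TRUE)
  expect_equal(cms$values[net$voxels], atanh(rowMeans(R)),
               tolerance = 1e-10)
})

test_that("identical conditions yield no hotspots", {
  set.seed(34)
  shape <- c(6, 6, 4)
  nvox <- prod(shape)
  runs <- lapply(1:5, function(i)
    run_from_matrix(matrix(rnorm(70 * nvox), 70), shape))
  net <- network_mask(block_region(2:5, 2:5, 2:3, shape),
                      vol_geometry(shape), "net")
  hs <- find_hotspots(runs, runs, net, n_perm = 30, seed = 1)
  expect_equal(nrow(hs), 0)
})

test_that("swapping the conditions flips every hotspot sign", {
  shape <- c(10, 10, 6)
  eff <- block_region(3:6, 3:6, 3:4, shape)
  cfg <- sim_config(n_subjects = 8, n_frames = 150, grid_shape = shape,
                    conditions = c("sham", "cTBS"),
                    network_specs = list(
                      network_spec("N", block_region(2:9, 2:9, 2:5, shape))),
                    effects = list(effect_spec(eff, "cTBS", -0.44, "N")))
  st <- generate_study(cfg, seed = 41)
  ab <- find_hotspots(st$runs$cTBS, st$runs$sham, st$masks$N,
                      n_perm = 60, seed = 5)
  ba <- find_hotspots(st$runs$sham, st$runs$cTBS, st$masks$N,
                      n_perm = 60, seed = 5)
  expect_gt(nrow(ab), 0)
  expect_equal(nrow(ab), nrow(ba))
  o <- order(vapply(ab$voxels, `[`, 0L, 1))
  o2 <- order(vapply(ba$voxels, `[`, 0L, 1))
  expect_identical(lapply(ab$voxels[o], sort),
                   lapply(ba$voxels[o2], sort))
  expect_true(all(ab$sign[o] != ba$sign[o2]))
  expect_equal(ab$peak_z[o], -ba$peak_z[o2], tolerance = 1e-10)
})

test_that("hotspot contrasts refuse mismatched run conditions", {
  shape <- c(6, 6, 2)
  runs_a <- lapply(1:3, function(i)
    run_from_matrix(matrix(rnorm(50 * prod(shape)), 50), shape,
                    condition = "cTBS"))
  runs_b <- lapply(1:3, function(i)
    run_from_matrix(matrix(rnorm(50 * prod(shape)), 50), shape,
                    condition = "sham"))
  net <- network_mask(1:20, vol_geometry(shape))
  expect_error(find_hotspots(runs_a, runs_b, net, n_perm = 10,
                             contrast = c("iTBS", "sham"), seed = 1),
               "contrast")
})
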