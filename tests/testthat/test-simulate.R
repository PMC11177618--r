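small_cfg <- function(...) {
  shape <- c(10, 10, 6)
  sim_config(n_subjects = 4, n_frames = 80, grid_shape = shape,
             conditions = c("sham", "cTBS"),
             network_specs = list(
               network_spec("HCN", block_region(2:7, 2:7, 2:5, shape))),
             censor_fraction = 0.05, ...)
}

test_that("generation is deterministic and validates effects", {
  cfg <- small_cfg()
  s1 <- generate_study(cfg, seed = 7)
  s2 <- generate_study(cfg, seed = 7)
  expect_identical(s1$runs$cTBS[[2]]$data, s2$runs$cTBS[[2]]$data)
  expect_identical(s1$runs$sham[[4]]$censored_frames,
                   s2$runs$sham[[4]]$censored_frames)
  s3 <- generate_study(cfg, seed = 8)
  expect_false(identical(s1$runs$cTBS[[2]]$data, s3$runs$cTBS[[2]]$data))
  ## every subject x condition present, shared geometry
  expect_named(s1$runs, c("sham", "cTBS"))
  expect_length(s1$runs$sham, 4)
  expect_true(all(vapply(s1$runs$cTBS, function(r)
    geometry_compatible(r$geometry, s1$geometry), TRUE)))
  ## effect outside the network is rejected
  shape <- c(10, 10, 6)
  expect_error(sim_config(
    grid_shape = shape, conditions = "sham",
    network_specs = list(network_spec("HCN",
                                      block_region(2:7, 2:7, 2:5, shape))),
    effects = list(effect_spec(block_region(8:9, 8:9, 1:2, shape),
                               "sham", -0.1, "HCN"))),
    "outside network")
})

test_that("censored frames are flagged zeros at the configured rate", {
  cfg <- small_cfg()
  st <- generate_study(cfg, seed = 3)
  run <- st$runs$sham[[1]]
  expect_length(run$censored_frames, floor(0.05 * 80))
  expect_true(all(run$data[, , , run$censored_frames] == 0))
})

test_that("in-network variance matches loading^2 + noise_sd^2", {
  shape <- c(10, 10, 6)
  cfg <- sim_config(n_subjects = 2, n_frames = 600, grid_shape = shape,
                    conditions = "sham",
                    network_specs = list(
                      network_spec("HCN", block_region(3:8, 3:8, 2:5, shape),
                                   base_loading = 0.7)),
                    noise_sd = 1, censor_fraction = 0)
  st <- generate_study(cfg, seed = 9)
  ## interior network voxels (away from the zero-padded grid edge)
  vox <- block_region(4:7, 4:7, 3:4, shape)
  M <- matrix(st$runs$sham[[1]]$data, prod(shape), 600)
  vars <- apply(M[vox, ], 1, var)
  expect_equal(mean(vars), 0.7^2 + 1, tolerance = 0.1)
})

test_that("with no noise and one network all in-network pairs correlate", {
  shape <- c(8, 8, 4)
  cfg <- sim_config(n_subjects = 2, n_frames = 100, grid_shape = shape,
                    conditions = "sham",
                    network_specs = list(
                      network_spec("N", block_region(2:6, 2:6, 2:3, shape))),
                    noise_sd = 1e-8, smooth_fwhm_mm = 0,
                    censor_fraction = 0)
  st <- generate_study(cfg, seed = 4)
  vox <- st$masks$N$voxels
  M <- matrix(st$runs$sham[[1]]$data, prod(shape), 100)
  r <- cor(M[vox[1], ], M[vox[25], ])
  expect_equal(r, 1, tolerance = 1e-6)
})

test_that("null condition contrast is exchangeable by construction", {
  cfg <- small_cfg()
  st <- generate_study(cfg, seed = 5)
  A <- conmap:::connectedness_matrix(st$runs$cTBS, st$masks$HCN)
  B <- conmap:::connectedness_matrix(st$runs$sham, st$masks$HCN)
  d <- colMeans(A - B)
  se <- apply(A - B, 2, sd) / sqrt(nrow(A))
  ## voxelwise mean difference within 3 SE almost everywhere
  expect_gt(mean(abs(d) < 3 * se), 0.95)
})

test_that("dice overlap follows the formula", {
  expect_equal(truth_overlap(1:10, 1:10), 1)
  expect_equal(truth_overlap(1:10, 11:20), 0)
  expect_equal(truth_overlap(1:30, 21:40), 0.4)  # 2*10 / (30+20)
  expect_warning(d0 <- truth_overlap(integer(0), integer(0)), "empty")
  expect_equal(d0, 0)
  ef <- effect_spec(5:14, "sham", -0.1, "N")
  expect_equal(truth_overlap(10:19, ef), 0.5)
})

test_that("study round-trips through the on-disk layout", {
  cfg <- small_cfg()
  st <- generate_study(cfg, seed = 6)
  dir <- file.path(tempdir(), "study_out")
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "sub01_sham.nii.gz")))
  expect_true(file.exists(file.path(dir, "mask_HCN.nii.gz")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$tr_s, 0.555)
  back <- read_volume(file.path(dir, "sub02_cTBS.nii.gz"), expect = "4d",
                      censored_frames = st$runs$cTBS[[2]]$censored_frames)
  expect_identical(back$data, st$runs$cTBS[[2]]$data)
  unlink(dir, recursive = TRUE)
})
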