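test_that("crop extraction follows the centring convention and copies data", {
  sc <- make_spot_scene(scene_params(n_loci = 1, shape = c(128, 128, 21),
                                     separation_model = 300, margin_vox = c(12, 12, 7),
                                     seed = 2, stack_id = "s"))
  seed <- list(stack_id = "s", locus_id = "l", channel_index = 1L,
               x = 50L, y = 60L, z = 10L)
  sub <- extract_subvolume(sc$stack, seed)
  expect_equal(sub$origin, c(40L, 50L, 7L))
  expect_equal(dim(sub$data), c(20L, 20L, 7L))
  # slice-sum oracle: crop content equals the parent window
  parent <- sc$stack$channels[[1]][51:70, 41:60, 8:14]
  expect_identical(sum(sub$data), sum(parent))
  expect_identical(sub$data, parent)
  # mutation isolation
  before <- sc$stack$channels[[1]][51, 41, 8]
  sub$data[1, 1, 1] <- 9999
  expect_identical(sc$stack$channels[[1]][51, 41, 8], before)
})

test_that("crops crossing the stack boundary are rejected by name", {
  sc <- make_spot_scene(scene_params(n_loci = 1, shape = c(128, 128, 21),
                                     separation_model = 300, margin_vox = c(12, 12, 7),
                                     seed = 2, stack_id = "s"))
  expect_error(
    extract_subvolume(sc$stack, list(stack_id = "s", locus_id = "edge",
                                     channel_index = 1L, x = 3L, y = 3L, z = 1L)),
    class = "fociquant_boundary_error", regexp = "edge")
})

test_that("the enumerable clip-and-threshold example segments exactly", {
  # 20 x 20 x 7 = 2800 voxels: 2599 zeros, 50 at 60, 150 at 100, 1 at 250,
  # non-zero voxels laid out contiguously.
  crop <- array(0, c(20, 20, 7))
  vals <- c(rep(60, 50), rep(100, 150), 250)
  crop[5:14, 5:14, 3:5] <- 0      # carve region; fill explicit block below
  block <- array(0, c(7, 6, 5))   # 210 voxel block holds the 201 non-zeros
  block[seq_along(vals)] <- vals
  crop[8:14, 8:13, 2:6] <- block
  s <- image_stack(crop, voxel_size(), "enum")
  sub <- extract_subvolume(s, list(channel_index = 1L, x = 10L, y = 10L, z = 3L),
                           size = c(20, 20, 7))
  seg <- segment_focus(sub, segmentation_params())
  # nearest-rank 96.5th percentile of 2800 values = rank 2702 = 100
  expect_identical(seg$clip_value, 100)
  expect_identical(seg$threshold, 90)
  expect_identical(seg$n_voxels, 151L)
  expect_identical(seg$volume_um3, 151 * 6.240375e-4)
  expect_equal(seg$volume_um3, 0.09423, tolerance = 1e-4)
  expect_false(seg$degenerate)
})

test_that("segmentation equals the sort-based brute-force oracle on random crops", {
  withr::with_seed(7, {
    for (rep in 1:12) {
      dims <- c(sample(6:14, 1), sample(6:14, 1), sample(3:7, 1))
      crop <- array(rpois(prod(dims), 3), dims)
      # plant a blob at the crop-centring seed so there is a focus to find
      c0 <- dims %/% 2                # 0-based (y, x, z) seed
      crop[c0[1] + (0:2), c0[2] + (0:2), c0[3] + 1] <- 40 + rpois(9, 5)
      crop[c0[1] + 1, c0[2] + 1, c0[3] + 1] <- 60
      s <- image_stack(crop, voxel_size(), "r")
      sub <- extract_subvolume(
        s, list(channel_index = 1L, x = c0[2], y = c0[1], z = c0[3]),
        size = c(dims[2], dims[1], dims[3]))
      seg <- segment_focus(sub, segmentation_params(border_policy = "none"))
      orc <- oracle_segment(crop)
      expect_identical(seg$clip_value, orc$clip)
      expect_identical(seg$threshold, orc$threshold)
      expect_identical(seg$n_voxels, orc$n_voxels)
      expect_identical(sort(which(seg$mask)), orc$mask_idx)
      # centroid: oracle is crop-relative, package reports parent frame
      cent_vox <- (seg$centroid_nm / c(64.5, 64.5, 150)) - sub$origin
      expect_equal(unname(cent_vox), unname(orc$centroid_crop), tolerance = 1e-9)
      expect_identical(seg$volume_um3, orc$n_voxels * 6.240375e-4)
      # every masked voxel satisfies the threshold inequality
      clipped <- pmin(crop, orc$clip)
      expect_true(all(clipped[seg$mask] >= seg$threshold))
      expect_identical(seg$threshold, 0.9 * max(clipped))
    }
  })
})

test_that("a symmetric noise-free spot centroids at its true centre", {
  # analytic Gaussian spot exactly on voxel (10, 10, 3) of a 20x20x7 crop
  vox <- voxel_size()
  xi <- 0:29; zi <- 0:9
  gx <- exp(-((xi - 10) * 64.5)^2 / (2 * 130^2))
  gz <- exp(-((zi - 3) * 150)^2 / (2 * 300^2))
  arr <- array(0, c(30, 30, 10))
  for (k in seq_along(zi)) arr[, , k] <- 200 * outer(gx, gx) * gz[k]
  s <- image_stack(arr, vox, "sym")
  sub <- extract_subvolume(s, list(channel_index = 1L, x = 10L, y = 10L, z = 3L))
  seg <- segment_focus(sub)
  expect_lt(abs(seg$centroid_vox[["x"]] - 10), 0.05)
  expect_lt(abs(seg$centroid_vox[["y"]] - 10), 0.05)
  expect_lt(abs(seg$centroid_vox[["z"]] - 3), 0.05)
  expect_false(seg$degenerate)
})

test_that("degenerate crops are flagged, empty crops error", {
  vox <- voxel_size()
  const <- image_stack(array(10, c(10, 10, 7)), vox, "const")
  sub <- extract_subvolume(const, list(channel_index = 1L, x = 5L, y = 5L, z = 3L),
                           size = c(10, 10, 7))
  seg <- segment_focus(sub)
  expect_true(seg$degenerate)
  expect_identical(seg$n_voxels, 700L)   # mask covers everything
  zero <- image_stack(array(0, c(10, 10, 7)), vox, "zero")
  subz <- extract_subvolume(zero, list(channel_index = 1L, x = 5L, y = 5L, z = 3L),
                            size = c(10, 10, 7))
  expect_error(segment_focus(subz), class = "fociquant_value_error")
})

test_that("border policy controls which contacts degrade a focus", {
  crop <- array(1, c(10, 10, 5))
  crop[1:3, 4:6, 2:4] <- 100          # blob touching the y = 0 crop face
  s <- image_stack(crop, voxel_size(), "b")
  sub <- extract_subvolume(s, list(channel_index = 1L, x = 5L, y = 5L, z = 2L),
                           size = c(10, 10, 5))
  expect_true(segment_focus(sub, segmentation_params(border_policy = "xy"))$degenerate)
  expect_false(segment_focus(sub, segmentation_params(border_policy = "none"))$degenerate)
  crop2 <- array(1, c(10, 10, 5))
  crop2[4:6, 4:6, 1:3] <- 100         # blob touching the z = 0 face only
  s2 <- image_stack(crop2, voxel_size(), "b2")
  sub2 <- extract_subvolume(s2, list(channel_index = 1L, x = 5L, y = 5L, z = 2L),
                            size = c(10, 10, 5))
  expect_false(segment_focus(sub2, segmentation_params(border_policy = "xy"))$degenerate)
  expect_true(segment_focus(sub2, segmentation_params(border_policy = "all"))$degenerate)
})

test_that("fraction-of-max clipping is available and behaves as documented", {
  crop <- array(0, c(8, 8, 4))
  crop[3:6, 3:6, 2:3] <- 100
  crop[4, 4, 2] <- 200
  s <- image_stack(crop, voxel_size(), "f")
  sub <- extract_subvolume(s, list(channel_index = 1L, x = 4L, y = 4L, z = 2L),
                           size = c(8, 8, 4))
  seg <- segment_focus(sub, segmentation_params(clip_mode = "fraction_of_max",
                                                border_policy = "none"))
  expect_equal(seg$clip_value, 0.965 * 200)
  expect_equal(seg$threshold, 0.9 * 0.965 * 200)
  # only the single hot voxel survives that threshold; min_voxels flags it
  expect_identical(seg$n_voxels, 1L)
  expect_true(seg$degenerate)
})

test_that("multi-component masks keep one component per policy", {
  crop <- array(0, c(12, 12, 5))
  crop[2:3, 2:3, 2] <- 100            # small far blob (8 voxels)
  crop[6:9, 6:9, 2:4] <- 100          # large central blob (48 voxels)
  crop[12, 12, 5] <- 1                # background speck
  s <- image_stack(crop, voxel_size(), "m")
  sub <- extract_subvolume(s, list(channel_index = 1L, x = 6L, y = 6L, z = 2L),
                           size = c(12, 12, 5))
  seg <- segment_focus(sub, segmentation_params(border_policy = "none"))
  expect_identical(seg$n_voxels, 48L)
  seg2 <- segment_focus(sub, segmentation_params(border_policy = "none",
                                                 component_policy = "nearest_center"))
  expect_identical(seg2$n_voxels, 48L)  # central blob is also nearest
})
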