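test_that("a fixed seed reproduces scenes bit-for-bit", {
  p <- scene_params(n_loci = 3, seed = 99)
  a <- make_spot_scene(p)
  b <- make_spot_scene(p)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$seeds, b$seeds)
  c2 <- make_spot_scene(scene_params(n_loci = 3, seed = 100))
  expect_false(identical(a$stack$channels, c2$stack$channels))
})

test_that("truth tables are self-consistent", {
  sc <- make_spot_scene(scene_params(n_loci = 8, seed = 21))
  per <- split(sc$truth, sc$truth$locus_id)
  for (tr in per) {
    d <- sqrt(sum((tr[1, c("x_nm", "y_nm", "z_nm")] -
                     tr[2, c("x_nm", "y_nm", "z_nm")])^2))
    expect_equal(d, tr$separation_nm[1], tolerance = 1e-6)
  }
  # triples: stored angle matches the law of cosines on stored centroids
  tg <- make_spot_scene(scene_params(n_loci = 6, geometry = "triple",
                                     separation_model = c(300, 700), seed = 22))
  for (tr in split(tg$truth, tg$truth$locus_id)) {
    v <- unlist(tr[tr$role == "vertex", c("x_nm", "y_nm", "z_nm")])
    p1 <- unlist(tr[tr$role == "arm1", c("x_nm", "y_nm", "z_nm")])
    p2 <- unlist(tr[tr$role == "arm2", c("x_nm", "y_nm", "z_nm")])
    expect_equal(oracle_dot_angle(v, p1, p2), tr$angle_deg[1], tolerance = 1e-6)
    expect_equal(sqrt(sum((p1 - v)^2)), tr$separation_nm[tr$role == "arm1"],
                 tolerance = 1e-6)
  }
})

test_that("noise-free rendered spots sit on their truth centroids", {
  sc <- make_spot_scene(scene_params(n_loci = 4, shot_noise = FALSE,
                                     background_mean = 0, background_sd = 0,
                                     seed = 31))
  vx <- sc$stack$voxel
  for (i in seq_len(nrow(sc$truth))) {
    tr <- sc$truth[i, ]
    ch <- sc$stack$channels[[tr$channel_index]]
    pos <- c(tr$x_nm / vx$dx_nm, tr$y_nm / vx$dy_nm, tr$z_nm / vx$dz_nm)
    xi <- round(pos[1]) + (-8:8); yi <- round(pos[2]) + (-8:8)
    zi <- round(pos[3]) + (-6:6)
    box <- ch[yi + 1, xi + 1, zi + 1]
    g <- expand.grid(y = yi, x = xi, z = zi)
    wc <- c(sum(g$x * box) / sum(box), sum(g$y * box) / sum(box),
            sum(g$z * box) / sum(box))
    expect_lt(max(abs(wc - pos)), 0.05)
  }
})

test_that("total rendered signal scales linearly with peak intensity", {
  base <- scene_params(n_loci = 3, shot_noise = FALSE, background_mean = 0,
                       background_sd = 0, peak_intensity = 100, seed = 8)
  hi <- scene_params(n_loci = 3, shot_noise = FALSE, background_mean = 0,
                     background_sd = 0, peak_intensity = 300, seed = 8)
  s1 <- sum(make_spot_scene(base)$stack$channels[[1]])
  s3 <- sum(make_spot_scene(hi)$stack$channels[[1]])
  expect_equal(s3 / s1, 3, tolerance = 0.01)
})

test_that("zero-separation pairs are measured as coincident", {
  sc <- make_spot_scene(scene_params(n_loci = 5, separation_model = 0, seed = 12))
  m <- measure_pairs(sc$stack, sc$seeds)
  expect_true(all(m$distance_nm < 50))  # within localization error
  expect_true(all(m$pearson_r > 0.8, na.rm = TRUE))
})

test_that("separations drawn uniform on [300, 1000] nm average near 650", {
  sc <- make_spot_scene(scene_params(n_loci = 100, seed = 17))
  seps <- unique(sc$truth[, c("locus_id", "separation_nm")])$separation_nm
  expect_length(seps, 100)
  se <- sd(seps) / sqrt(length(seps))
  expect_lt(abs(mean(seps) - 650), 3 * se)
})

test_that("rendered foci cover at least 98 voxels above threshold at defaults", {
  sc <- make_spot_scene(scene_params(n_loci = 4, seed = 41))
  m <- measure_pairs(sc$stack, sc$seeds)
  nvox_a <- m$volume_a_um3 / voxel_volume_um3(sc$stack$voxel)
  nvox_b <- m$volume_b_um3 / voxel_volume_um3(sc$stack$voxel)
  expect_true(all(c(nvox_a, nvox_b) >= 98))
})

test_that("infeasible geometry is rejected", {
  expect_error(make_spot_scene(scene_params(n_loci = 50, shape = c(40, 40, 10))),
               class = "fociquant_value_error", regexp = "infeasible")
})

test_that("z-resampling interpolates over the same physical depth", {
  sc <- make_spot_scene(scene_params(n_loci = 1, shape = c(64, 64, 21),
                                     separation_model = 300, margin_vox = c(12, 12, 7),
                                     seed = 5))
  expect_equal(unname(stack_dims(sc$stack))[3], 21)
  r100 <- resample_zstep(sc$stack, 100)
  # 21 planes at 150 nm span 3000 nm -> floor(3000/100) + 1 = 31 planes
  expect_equal(unname(stack_dims(r100))[3], 31)
  expect_equal(r100$voxel$dz_nm, 100)
  # identity resample leaves planes unchanged
  r150 <- resample_zstep(sc$stack, 150)
  expect_equal(r150$channels[[1]], sc$stack$channels[[1]])
  # constant stacks stay constant under any spacing
  const <- image_stack(array(7, c(8, 8, 11)), voxel_size(), "c")
  rc <- resample_zstep(const, 120)
  expect_true(all(rc$channels[[1]] == 7))
  expect_error(resample_zstep(const, 1e6), class = "fociquant_value_error")
})

test_that("bead fields honour their applied offset and spacing", {
  bf0 <- make_bead_field(bead_field_params(n_beads = 5, seed = 3),
                         shape = c(96, 96, 25))
  expect_true(all(bf0$truth$offset_dx_nm == 0))
  # at zero offset and zero noise the two channels are identical
  nf <- make_bead_field(bead_field_params(n_beads = 5, shot_noise = FALSE,
                                          background_sd = 0, seed = 3),
                        shape = c(96, 96, 25))
  expect_identical(nf$stack$channels[[1]], nf$stack$channels[[2]])
  # with noise the channels still co-localise strongly at signal voxels
  sig <- nf$stack$channels[[1]] > 20
  expect_gt(cor(bf0$stack$channels[[1]][sig], bf0$stack$channels[[2]][sig]), 0.9)
  # pairwise spacing respects the 4-diameter floor
  pos <- as.matrix(bf0$truth[, c("x_nm", "y_nm", "z_nm")])
  dm <- as.matrix(dist(pos))
  expect_gt(min(dm[upper.tri(dm)]), 4 * 100)
  # infeasible packing reports the achievable count
  expect_error(make_bead_field(bead_field_params(n_beads = 400, seed = 1),
                               shape = c(64, 64, 25)),
               class = "fociquant_value_error", regexp = "achievable")
})

test_that("500 nm bead volumes are stable across independent fields", {
  vols <- lapply(c(51, 52), function(s) {
    # margins sized for the larger 25 x 25 x 17 volume-validation crop
    bf <- make_bead_field(bead_field_params(n_beads = 8, bead_diameter_nm = 500,
                                            margin_vox = c(14, 14, 9), seed = s),
                          shape = c(160, 160, 29))
    df <- detect_foci(bf$stack, 1, size = c(25, 25, 17))
    df$volume_um3
  })
  expect_equal(length(vols[[1]]), 8)
  # same generative model, different seeds: indistinguishable distributions
  expect_gt(wilcox.test(vols[[1]], vols[[2]], exact = FALSE)$p.value, 0.05)
})
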