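#' Parameters for synthetic FISH scenes
#'
#' The generator emulates deconvolved widefield stacks of compact, bright
#' hybridisation foci on a low background: anisotropic Gaussian spots
#' (defaults sigma_xy 130 nm, sigma_z 300 nm — wide enough that a focus
#' covers well over 98 voxels of a 20x20x7 crop above threshold, the regime
#' the 96.5 % clipping rule presumes), Poisson shot noise on signal, and
#' Gaussian readout background (mean 5, sd 2 counts; deconvolved images
#' carry near-zero background). Channel 2 can be translated by a chromatic
#' offset. Loci are laid out on an interior grid with at least
#' `margin_vox` voxels of clearance, so every seeded crop is extractable.
#'
#' @param shape Optional (nx, ny, nz) voxel counts; `NULL` sizes the stack
#'   automatically from `n_loci`, the separation model and the margin.
#' @param voxel A [voxel_size()].
#' @param spot_sigma_xy_nm,spot_sigma_z_nm Gaussian spot widths (nm).
#' @param peak_intensity Expected peak signal, in counts.
#' @param background_mean,background_sd Additive Gaussian readout background
#'   (counts).
#' @param shot_noise Apply Poisson shot noise to the signal?
#' @param chromatic_offset_nm Length-3 (dx, dy, dz) translation applied to
#'   channel 2 when rendering, emulating chromatic aberration.
#' @param n_loci Number of probe pairs / triples per scene.
#' @param separation_model True 3D separation distribution, in nm: a single
#'   number (fixed) or a `(lo, hi)` pair (uniform). For triples this is the
#'   arm-length distribution.
#' @param geometry `"pair"` (one spot per channel), `"triple"` (vertex spot
#'   in channel 2, two arm spots in channel 1, arm lengths and vertex angle
#'   drawn independently) or `"triple_random"` (three i.i.d. uniform points
#'   in the locus cell — the random-arrangement baseline).
#' @param angle_range_deg For `geometry = "triple"`: uniform range of the
#'   drawn vertex angle, degrees.
#' @param seed_jitter_vox Seed points are truth positions perturbed by a
#'   uniform integer jitter in `[-seed_jitter_vox, seed_jitter_vox]` per
#'   axis, emulating manual clicking.
#' @param margin_vox Interior clearance, voxels; one value or one per axis
#'   (x, y, z). The default (14, 14, 8) keeps every jittered seed's
#'   20x20x7 crop inside the stack.
#' @param stack_id Label for the generated stack.
#' @param seed Integer random seed; a fixed seed reproduces the scene
#'   bit-for-bit.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(shape = NULL,
                         voxel = voxel_size(),
                         spot_sigma_xy_nm = 130,
                         spot_sigma_z_nm = 300,
                         peak_intensity = 200,
                         background_mean = 5,
                         background_sd = 2,
                         shot_noise = TRUE,
                         chromatic_offset_nm = c(0, 0, 0),
                         n_loci = 10,
                         separation_model = c(300, 1000),
                         geometry = c("pair", "triple", "triple_random"),
                         angle_range_deg = c(0, 180),
                         seed_jitter_vox = 2,
                         margin_vox = c(14, 14, 8),
                         stack_id = "scene",
                         seed = 1L) {
  geometry <- match.arg(geometry)
  if (spot_sigma_xy_nm <= 0 || spot_sigma_z_nm <= 0 || peak_intensity <= 0 ||
      background_sd < 0 || n_loci < 0 || any(margin_vox < 0)) {
    abort("invalid scene parameters: sigmas and peak must be > 0, background_sd and margins >= 0",
          class = "fociquant_value_error")
  }
  if (!length(separation_model) %in% 1:2 || any(separation_model < 0) ||
      (length(separation_model) == 2 && separation_model[1] > separation_model[2])) {
    abort("`separation_model` must be a fixed value or an increasing (lo, hi) pair, in nm",
          class = "fociquant_value_error")
  }
  structure(list(shape = shape, voxel = as_voxel_size(voxel),
                 spot_sigma_xy_nm = spot_sigma_xy_nm,
                 spot_sigma_z_nm = spot_sigma_z_nm,
                 peak_intensity = peak_intensity,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 shot_noise = isTRUE(shot_noise),
                 chromatic_offset_nm = as.numeric(chromatic_offset_nm),
                 n_loci = as.integer(n_loci),
                 separation_model = as.numeric(separation_model),
                 geometry = geometry,
                 angle_range_deg = as.numeric(angle_range_deg),
                 seed_jitter_vox = as.integer(seed_jitter_vox),
                 margin_vox = as.integer(rep_len(margin_vox, 3L)),
                 stack_id = as.character(stack_id),
                 seed = as.integer(seed)),
            class = "scene_params")
}

draw_separation <- function(model, n) {
  if (length(model) == 1L) rep(model, n) else runif(n, model[1], model[2])
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

# add an anisotropic Gaussian spot into `arr` (y, x, z array), position in
# fractional 0-based voxel coordinates
add_gaussian_spot <- function(arr, pos_vox, voxel, sigma_xy_nm, sigma_z_nm, peak) {
  d <- dim(arr)
  rx <- ceiling(4 * sigma_xy_nm / voxel$dx_nm)
  ry <- ceiling(4 * sigma_xy_nm / voxel$dy_nm)
  rz <- ceiling(4 * sigma_z_nm / voxel$dz_nm)
  xi <- max(0L, floor(pos_vox[1] - rx)):min(d[2] - 1L, ceiling(pos_vox[1] + rx))
  yi <- max(0L, floor(pos_vox[2] - ry)):min(d[1] - 1L, ceiling(pos_vox[2] + ry))
  zi <- max(0L, floor(pos_vox[3] - rz)):min(d[3] - 1L, ceiling(pos_vox[3] + rz))
  gx <- exp(-((xi - pos_vox[1]) * voxel$dx_nm)^2 / (2 * sigma_xy_nm^2))
  gy <- exp(-((yi - pos_vox[2]) * voxel$dy_nm)^2 / (2 * sigma_xy_nm^2))
  gz <- exp(-((zi - pos_vox[3]) * voxel$dz_nm)^2 / (2 * sigma_z_nm^2))
  plane <- peak * outer(gy, gx)
  for (k in seq_along(zi)) {
    arr[yi + 1L, xi + 1L, zi[k] + 1L] <- arr[yi + 1L, xi + 1L, zi[k] + 1L] +
      plane * gz[k]
  }
  arr
}

apply_scene_noise <- function(signal, background_mean, background_sd, shot_noise) {
  n <- length(signal)
  if (shot_noise) signal[] <- rpois(n, lambda = signal)
  bg <- if (background_sd > 0) rnorm(n, background_mean, background_sd) else background_mean
  out <- round(signal + bg)
  out[out < 0] <- 0
  out
}

#' Generate a synthetic multi-locus FISH scene with ground truth
#'
#' Renders `n_loci` probe pairs or triples into a two-channel stack, applies
#' the configured chromatic offset to channel 2 and the configured noise
#' model, and returns the stack together with a ground-truth table (true
#' centroids in nm, true separations and — for triples — vertex angles, the
#' applied offset) and a seed-point table with click-like jitter.
#'
#' True positions recorded in the truth table are aberration-free; channel-2
#' spots are *rendered* at `truth + chromatic_offset_nm`, so measurements on
#' the uncorrected stack recover truth only after chromatic correction.
#'
#' @param params A [scene_params()].
#' @return A list of class `fish_scene`: `stack` ([image_stack()]), `truth`
#'   (tibble), `seeds` (tibble), `params`.
#' @examples
#' sc <- make_spot_scene(scene_params(n_loci = 2, seed = 7))
#' sc$truth
#' @export
make_spot_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  vx <- p$voxel
  scale <- c(vx$dx_nm, vx$dy_nm, vx$dz_nm)

  reach_nm <- switch(p$geometry,
    pair = max(p$separation_model) / 2,
    triple = max(p$separation_model),
    triple_random = max(p$separation_model))
  half_vox <- ceiling(reach_nm / scale) + p$margin_vox
  cell <- 2L * as.integer(half_vox)   # (x, y, z) voxels per locus cell

  ncx <- ceiling(sqrt(p$n_loci)); ncy <- ceiling(p$n_loci / max(ncx, 1L))
  if (p$n_loci == 0L) { ncx <- 1L; ncy <- 1L }
  need <- c(ncx * cell[1], ncy * cell[2], cell[3])
  shape <- p$shape %||% need
  if (any(shape < need)) {
    abort(sprintf("geometry infeasible: %d loci with these separations need at least a (%s)-voxel stack, got (%s)",
                  p$n_loci, paste(need, collapse = ", "), paste(shape, collapse = ", ")),
          class = "fociquant_value_error")
  }

  withr::with_seed(p$seed, {
    sig <- list(array(0, c(shape[2], shape[1], shape[3])),
                array(0, c(shape[2], shape[1], shape[3])))
    truth <- list(); seeds <- list()
    off <- p$chromatic_offset_nm

    for (i in seq_len(p$n_loci)) {
      cxi <- (i - 1L) %% ncx; cyi <- (i - 1L) %/% ncx
      centre_vox <- c(cxi * cell[1] + cell[1] / 2,
                      cyi * cell[2] + cell[2] / 2,
                      cell[3] / 2) - 0.5 + runif(3, -1, 1)
      centre_nm <- centre_vox * scale
      lid <- sprintf("locus%03d", i)

      if (p$geometry == "pair") {
        u <- random_unit_vectors(1L)[1, ]
        d <- draw_separation(p$separation_model, 1L)
        pos <- rbind(centre_nm - d / 2 * u, centre_nm + d / 2 * u)
        chans <- c(1L, 2L); roles <- c(NA_character_, NA_character_)
        sep <- c(d, d); ang <- c(NA_real_, NA_real_)
      } else if (p$geometry == "triple") {
        u <- random_unit_vectors(1L)[1, ]
        w <- random_unit_vectors(1L)[1, ]
        w <- w - sum(w * u) * u
        w <- w / sqrt(sum(w^2))
        ab <- draw_separation(p$separation_model, 2L)
        theta <- runif(1, p$angle_range_deg[1], p$angle_range_deg[2]) * pi / 180
        arm1 <- centre_nm + ab[1] * u
        arm2 <- centre_nm + ab[2] * (cos(theta) * u + sin(theta) * w)
        pos <- rbind(centre_nm, arm1, arm2)
        chans <- c(2L, 1L, 1L); roles <- c("vertex", "arm1", "arm2")
        sep <- c(NA_real_, ab[1], ab[2])
        ang <- rep(theta * 180 / pi, 3)
      } else { # triple_random: three i.i.d. uniform points in the cell interior
        half_nm <- (cell / 2 - p$margin_vox) * scale
        pts <- sweep(matrix(runif(9, -1, 1), ncol = 3), 2L, half_nm, `*`)
        pts <- sweep(pts, 2L, centre_nm, `+`)
        pos <- pts[c(2L, 1L, 3L), , drop = FALSE]  # vertex is the middle point
        chans <- c(2L, 1L, 1L); roles <- c("vertex", "arm1", "arm2")
        a <- sqrt(sum((pos[2, ] - pos[1, ])^2))
        b <- sqrt(sum((pos[3, ] - pos[1, ])^2))
        cc <- sqrt(sum((pos[3, ] - pos[2, ])^2))
        th <- acos(pmin(1, pmax(-1, (a^2 + b^2 - cc^2) / (2 * a * b)))) * 180 / pi
        sep <- c(NA_real_, a, b); ang <- rep(th, 3)
      }

      for (j in seq_len(nrow(pos))) {
        render_nm <- pos[j, ] + if (chans[j] == 2L) off else c(0, 0, 0)
        sig[[chans[j]]] <- add_gaussian_spot(sig[[chans[j]]], render_nm / scale,
                                             vx, p$spot_sigma_xy_nm,
                                             p$spot_sigma_z_nm, p$peak_intensity)
        jit <- sample.int(2L * p$seed_jitter_vox + 1L, 3L, replace = TRUE) -
          p$seed_jitter_vox - 1L
        svox <- round(render_nm / scale) + jit
        truth[[length(truth) + 1L]] <- tibble(
          stack_id = p$stack_id, locus_id = lid, channel_index = chans[j],
          role = roles[j],
          x_nm = pos[j, 1], y_nm = pos[j, 2], z_nm = pos[j, 3],
          separation_nm = sep[j], angle_deg = ang[j],
          offset_dx_nm = off[1], offset_dy_nm = off[2], offset_dz_nm = off[3])
        seeds[[length(seeds) + 1L]] <- seed_points(
          p$stack_id, lid, chans[j], svox[1], svox[2], svox[3], roles[j])
      }
    }

    channels <- lapply(sig, apply_scene_noise,
                       background_mean = p$background_mean,
                       background_sd = p$background_sd,
                       shot_noise = p$shot_noise)
    truth <- if (length(truth)) dplyr::bind_rows(truth) else empty_truth()
    seeds <- if (length(seeds)) dplyr::bind_rows(seeds) else
      seed_points(character(), character(), integer(), integer(), integer(), integer())
    structure(list(stack = image_stack(channels, vx, p$stack_id),
                   truth = truth, seeds = seeds, params = unclass(p)),
              class = "fish_scene")
  })
}

empty_truth <- function() {
  tibble(stack_id = character(), locus_id = character(),
         channel_index = integer(), role = character(),
         x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
         separation_nm = numeric(), angle_deg = numeric(),
         offset_dx_nm = numeric(), offset_dy_nm = numeric(),
         offset_dz_nm = numeric())
}

#' Parameters for synthetic fiducial bead fields
#'
#' Bead fields emulate multi-colour fiducial ("TetraSpeck"-style) slides:
#' identical beads imaged in two channels, with channel 2 translated by a
#' known offset. 100 nm beads (default) are the chromatic-calibration
#' standard; 500 nm beads serve volume-measurement validation. Beads are
#' rendered as Gaussian-blurred solid spheres and placed randomly with a
#' minimum pairwise spacing of at least four bead diameters (and never below
#' 1.5 um, so neighbouring point-spread functions stay separable).
#'
#' @param n_beads Number of beads.
#' @param bead_diameter_nm Physical bead diameter, nm.
#' @param applied_offset_nm Length-3 (dx, dy, dz) translation of channel 2
#'   — the quantity a calibration must recover.
#' @param peak_intensity,background_mean,background_sd,shot_noise Noise
#'   model, as in [scene_params()].
#' @param psf_sigma_xy_nm,psf_sigma_z_nm Gaussian blur applied to the bead
#'   sphere, emulating the point-spread function.
#' @param min_spacing_nm Minimum pairwise 3D spacing; default
#'   `max(4 * bead_diameter_nm, 1500)`.
#' @param extra_beads_channel2 Beads rendered in channel 2 only (spurious,
#'   unmatched objects for robustness checks).
#' @param margin_vox Interior clearance, voxels; a single value or one per
#'   axis (x, y, z). The default keeps every bead extractable with the
#'   21 x 21 x 13 calibration crop.
#' @param seed Integer random seed.
#' @return An object of class `bead_field_params`.
#' @export
bead_field_params <- function(n_beads = 12,
                              bead_diameter_nm = 100,
                              applied_offset_nm = c(0, 0, 0),
                              peak_intensity = 200,
                              background_mean = 5,
                              background_sd = 2,
                              shot_noise = TRUE,
                              psf_sigma_xy_nm = 130,
                              psf_sigma_z_nm = 300,
                              min_spacing_nm = NULL,
                              extra_beads_channel2 = 0,
                              margin_vox = c(12, 12, 7),
                              seed = 1L) {
  if (bead_diameter_nm <= 0 || n_beads < 1) {
    abort("`bead_diameter_nm` must be > 0 and `n_beads` >= 1",
          class = "fociquant_value_error")
  }
  structure(list(n_beads = as.integer(n_beads),
                 bead_diameter_nm = bead_diameter_nm,
                 applied_offset_nm = as.numeric(applied_offset_nm),
                 peak_intensity = peak_intensity,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 shot_noise = isTRUE(shot_noise),
                 psf_sigma_xy_nm = psf_sigma_xy_nm,
                 psf_sigma_z_nm = psf_sigma_z_nm,
                 min_spacing_nm = min_spacing_nm %||% max(4 * bead_diameter_nm, 1500),
                 extra_beads_channel2 = as.integer(extra_beads_channel2),
                 margin_vox = as.integer(rep_len(margin_vox, 3L)),
                 seed = as.integer(seed)),
            class = "bead_field_params")
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# radial intensity profile of a solid sphere of radius R blurred by an
# isotropic Gaussian of width sigma (closed form), normalised to 1 at r = 0
ball_blur_profile <- function(r, R, sigma) {
  r <- pmax(r, 1e-3)
  s2 <- sqrt(2) * sigma
  f <- 0.5 * (erf((R - r) / s2) + erf((R + r) / s2)) -
    (sigma / (r * sqrt(2 * pi))) *
      (exp(-(r - R)^2 / (2 * sigma^2)) - exp(-(r + R)^2 / (2 * sigma^2)))
  f0 <- erf(R / s2) - (R * sqrt(2 / pi) / sigma) * exp(-R^2 / (2 * sigma^2))
  pmax(f / f0, 0)   # guard against far-tail floating cancellation
}

add_bead <- function(arr, pos_vox, voxel, R_nm, sigma_xy_nm, sigma_z_nm, peak) {
  d <- dim(arr)
  ext_xy <- R_nm + 4 * sigma_xy_nm
  ext_z <- (R_nm + 4 * sigma_xy_nm) * sigma_z_nm / sigma_xy_nm
  xi <- max(0L, floor(pos_vox[1] - ext_xy / voxel$dx_nm)):min(d[2] - 1L, ceiling(pos_vox[1] + ext_xy / voxel$dx_nm))
  yi <- max(0L, floor(pos_vox[2] - ext_xy / voxel$dy_nm)):min(d[1] - 1L, ceiling(pos_vox[2] + ext_xy / voxel$dy_nm))
  zi <- max(0L, floor(pos_vox[3] - ext_z / voxel$dz_nm)):min(d[3] - 1L, ceiling(pos_vox[3] + ext_z / voxel$dz_nm))
  dx <- (xi - pos_vox[1]) * voxel$dx_nm
  dy <- (yi - pos_vox[2]) * voxel$dy_nm
  # z distances are shrunk into the lateral frame so the blurred ball is
  # elongated by sigma_z / sigma_xy axially, mimicking PSF anisotropy
  dz <- (zi - pos_vox[3]) * voxel$dz_nm * sigma_xy_nm / sigma_z_nm
  for (k in seq_along(zi)) {
    rr <- sqrt(outer(dy^2, dx^2, `+`) + dz[k]^2)
    arr[yi + 1L, xi + 1L, zi[k] + 1L] <- arr[yi + 1L, xi + 1L, zi[k] + 1L] +
      peak * ball_blur_profile(rr, R_nm, sigma_xy_nm)
  }
  arr
}

#' Generate a two-channel fiducial bead field with known chromatic offset
#'
#' Channel 1 renders the beads at their true positions; channel 2 renders
#' the same beads translated by `applied_offset_nm`; both receive the
#' configured noise. The truth table records bead positions (channel-1
#' frame) and the applied offset — the oracle for [estimate_offset()].
#'
#' @param params A [bead_field_params()].
#' @param voxel A [voxel_size()].
#' @param shape (nx, ny, nz) voxel counts of the field.
#' @param stack_id Label for the stack.
#' @return A list of class `bead_field`: `stack`, `truth`, `params`.
#' @examples
#' bf <- make_bead_field(bead_field_params(n_beads = 4, seed = 3),
#'                       shape = c(96, 96, 25))
#' bf$truth
#' @export
make_bead_field <- function(params = bead_field_params(),
                            voxel = voxel_size(),
                            shape = c(128, 128, 25),
                            stack_id = "beads") {
  stopifnot(inherits(params, "bead_field_params"))
  p <- params
  vx <- as_voxel_size(voxel)
  scale <- c(vx$dx_nm, vx$dy_nm, vx$dz_nm)
  lo <- p$margin_vox
  hi <- shape - 1 - p$margin_vox
  if (any(hi <= lo)) {
    abort("bead field shape too small for the requested margin",
          class = "fociquant_value_error")
  }
  n_total <- p$n_beads + p$extra_beads_channel2

  withr::with_seed(p$seed, {
    pos <- matrix(NA_real_, 0L, 3L)
    tries <- 0L
    while (nrow(pos) < n_total && tries < 5000L) {
      tries <- tries + 1L
      cand <- lo + runif(3) * (hi - lo)
      cand_nm <- cand * scale
      if (nrow(pos) == 0L ||
          min(sqrt(rowSums(sweep(sweep(pos, 2L, scale, `*`), 2L, cand_nm, `-`)^2))) >=
            p$min_spacing_nm) {
        pos <- rbind(pos, cand)
      }
    }
    if (nrow(pos) < n_total) {
      abort(sprintf("could not place %d beads at %.0f nm spacing in this field; %d achievable",
                    n_total, p$min_spacing_nm, nrow(pos)),
            class = "fociquant_value_error")
    }
    R <- p$bead_diameter_nm / 2
    off_vox <- p$applied_offset_nm / scale
    ch1 <- array(0, c(shape[2], shape[1], shape[3]))
    ch2 <- array(0, c(shape[2], shape[1], shape[3]))
    for (i in seq_len(n_total)) {
      if (i <= p$n_beads) {
        ch1 <- add_bead(ch1, pos[i, ], vx, R, p$psf_sigma_xy_nm, p$psf_sigma_z_nm,
                        p$peak_intensity)
      }
      ch2 <- add_bead(ch2, pos[i, ] + off_vox, vx, R, p$psf_sigma_xy_nm,
                      p$psf_sigma_z_nm, p$peak_intensity)
    }
    channels <- lapply(list(ch1, ch2), apply_scene_noise,
                       background_mean = p$background_mean,
                       background_sd = p$background_sd,
                       shot_noise = p$shot_noise)
    truth <- tibble(stack_id = stack_id,
                    bead_id = sprintf("bead%03d", seq_len(n_total)),
                    spurious = seq_len(n_total) > p$n_beads,
                    x_nm = pos[, 1] * scale[1], y_nm = pos[, 2] * scale[2],
                    z_nm = pos[, 3] * scale[3],
                    offset_dx_nm = p$applied_offset_nm[1],
                    offset_dy_nm = p$applied_offset_nm[2],
                    offset_dz_nm = p$applied_offset_nm[3])
    structure(list(stack = image_stack(channels, vx, stack_id),
                   truth = truth, params = unclass(p)),
              class = "bead_field")
  })
}

#' Resample a stack to a new z-step by linear interpolation
#'
#' Planes are linearly interpolated at the new axial spacing over the same
#' physical depth (first and last plane positions preserved), and the voxel
#' geometry is updated. Used to compare measurements across 100, 150 and
#' 200 nm z-steps.
#'
#' @param stack An [image_stack()] with at least 2 planes.
#' @param new_dz_nm New z spacing, nm; must be positive and no larger than
#'   the stack's physical depth.
#' @return A resampled [image_stack()]; plane count
#'   `floor(depth / new_dz) + 1`.
#' @export
resample_zstep <- function(stack, new_dz_nm) {
  nz <- stack_dims(stack)[["nz"]]
  if (nz < 2L) {
    abort("resampling needs at least 2 planes", class = "fociquant_value_error")
  }
  dz <- stack$voxel$dz_nm
  depth <- (nz - 1) * dz
  if (new_dz_nm <= 0 || new_dz_nm > depth) {
    abort(sprintf("new z-step %.1f nm must be in (0, %.1f] nm (the stack depth)",
                  new_dz_nm, depth),
          class = "fociquant_value_error")
  }
  n_new <- floor(depth / new_dz_nm + 1e-9) + 1
  zq <- (seq_len(n_new) - 1) * new_dz_nm / dz   # positions in old plane units
  i0 <- pmin(floor(zq), nz - 2)
  f <- zq - i0
  channels <- lapply(stack$channels, function(ch) {
    out <- array(0, c(dim(ch)[1], dim(ch)[2], n_new))
    for (k in seq_len(n_new)) {
      out[, , k] <- (1 - f[k]) * ch[, , i0[k] + 1] + f[k] * ch[, , i0[k] + 2]
    }
    out
  })
  image_stack(channels,
              voxel_size(stack$voxel$dx_nm, stack$voxel$dy_nm, new_dz_nm),
              stack$stack_id)
}
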