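#' Inter-centroid 3D distance
#'
#' Euclidean distance, in nm, between the physical-frame centroids of two
#' segmented foci. Degeneracy flags are not policed here — table-level
#' drivers ([measure_pairs()]) carry them so flagged loci can be excluded
#' from summaries rather than erroring.
#'
#' @param seg1,seg2 [segment_focus()] results (or named x/y/z nm vectors).
#' @return Distance in nm.
#' @examples
#' pair_distance(c(x = 0, y = 0, z = 0), c(x = 645, y = 0, z = 0))
#' @export
pair_distance <- function(seg1, seg2) {
  c1 <- if (inherits(seg1, "focus_segmentation")) seg1$centroid_nm else seg1
  c2 <- if (inherits(seg2, "focus_segmentation")) seg2$centroid_nm else seg2
  sqrt(sum((as.numeric(c1) - as.numeric(c2))^2))
}

#' Pearson colocalization of two sub-volumes
#'
#' The standard Pearson correlation over all voxel pairs of the two *raw*
#' crops — aligned (chromatically corrected) but neither clipped nor
#' thresholded. The crops must be congruent: identical size and identical
#' origin in the parent stack, one per channel. If either crop has zero
#' variance the coefficient is undefined and `NA` is returned (the
#' flagged-result path; such loci are excluded from summaries).
#'
#' @param sub1,sub2 Congruent [extract_subvolume()] crops.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_pair <- function(sub1, sub2) {
  if (!identical(dim(sub1$data), dim(sub2$data)) ||
      !identical(sub1$origin, sub2$origin)) {
    abort("pearson_pair needs congruent crops: same size and same origin",
          class = "fociquant_value_error")
  }
  a <- as.vector(sub1$data); b <- as.vector(sub2$data)
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  cor(a, b)
}

# vectorised vertex angle by the law of cosines: c^2 = a^2 + b^2 - 2ab cos(theta)
# v, p1, p2: n x 3 matrices of positions
vertex_angle_deg <- function(v, p1, p2) {
  v <- rbind(v); p1 <- rbind(p1); p2 <- rbind(p2)
  a <- sqrt(rowSums((p1 - v)^2))
  b <- sqrt(rowSums((p2 - v)^2))
  cc <- sqrt(rowSums((p2 - p1)^2))
  costh <- (a^2 + b^2 - cc^2) / (2 * a * b)
  acos(pmin(1, pmax(-1, costh))) * 180 / pi
}

#' Vertex angle between three probe signals
#'
#' Given the centroids of a vertex probe and its two flanking probes,
#' computes the arm lengths a, b, the base c, and the vertex angle theta
#' from the law of cosines, `c^2 = a^2 + b^2 - 2ab cos(theta)` (cosine
#' clamped to `[-1, 1]` against floating error).
#'
#' @param vertex,arm1,arm2 [segment_focus()] results or (x, y, z) nm
#'   vectors. A vertex coincident with an arm is an error — the angle is
#'   undefined.
#' @return An object of class `triple_angle`: `vertex_nm`, `arm1_nm`,
#'   `arm2_nm`, `a_nm`, `b_nm`, `c_nm`, `theta_deg` (in `[0, 180]`).
#' @examples
#' triple_angle(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0))$theta_deg  # 90
#' @export
triple_angle <- function(vertex, arm1, arm2) {
  g <- function(s) if (inherits(s, "focus_segmentation")) as.numeric(s$centroid_nm) else as.numeric(s)
  v <- g(vertex); p1 <- g(arm1); p2 <- g(arm2)
  a <- sqrt(sum((p1 - v)^2)); b <- sqrt(sum((p2 - v)^2))
  if (a == 0 || b == 0) {
    abort("vertex coincides with an arm centroid: angle undefined",
          class = "fociquant_value_error")
  }
  structure(list(vertex_nm = v, arm1_nm = p1, arm2_nm = p2,
                 a_nm = a, b_nm = b, c_nm = sqrt(sum((p2 - p1)^2)),
                 theta_deg = vertex_angle_deg(v, p1, p2)),
            class = "triple_angle")
}

#' @export
print.triple_angle <- function(x, ...) {
  cat(sprintf("<triple_angle> a = %.1f nm, b = %.1f nm, c = %.1f nm, theta = %.2f deg\n",
              x$a_nm, x$b_nm, x$c_nm, x$theta_deg))
  invisible(x)
}

#' Vertex-angle baseline for randomly arranged probe triples
#'
#' Samples `n` triples of points i.i.d. uniform in a unit cube and computes
#' the vertex angle at the designated middle point. Because the three
#' angles of any triangle sum to 180 degrees and the labels are
#' exchangeable, the expected vertex angle for a random arrangement is 60
#' degrees — the reference against which measured probe-triple angles are
#' judged non-random.
#'
#' @param n Number of triples (`>= 1`).
#' @param seed Integer seed; fixed seed reproduces the draw exactly.
#' @return A list of class `angle_baseline`: `n`, `mean_deg`, `median_deg`,
#'   `angles` (the n draws, degrees).
#' @examples
#' random_angle_baseline(1000, seed = 1)$mean_deg
#' @export
random_angle_baseline <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    pts <- array(runif(9 * n), c(n, 3, 3))
    ang <- vertex_angle_deg(pts[, , 2], pts[, , 1], pts[, , 3])
    structure(list(n = as.integer(n), mean_deg = mean(ang),
                   median_deg = median(ang), angles = ang),
              class = "angle_baseline")
  })
}

#' @export
print.angle_baseline <- function(x, ...) {
  cat(sprintf("<angle_baseline> n = %d uniform triples: mean %.2f deg, median %.2f deg\n",
              x$n, x$mean_deg, x$median_deg))
  invisible(x)
}

# segment one seed row; returns NULL on boundary/empty-crop failure.
# With recenter = TRUE the crop is re-extracted once, centred on the
# first-pass centroid, which undoes mask truncation caused by click jitter.
segment_seed <- function(stack, seedrow, size, params, recenter = TRUE) {
  sub <- tryCatch(extract_subvolume(stack, seedrow, size = size),
                  fociquant_boundary_error = function(e) NULL)
  if (is.null(sub)) return(NULL)
  seg <- tryCatch(segment_focus(sub, params),
                  fociquant_value_error = function(e) NULL)
  if (is.null(seg)) return(NULL)
  if (recenter) {
    seed2 <- as.list(seedrow)
    cv <- round(seg$centroid_vox)
    if (any(cv != c(seedrow$x, seedrow$y, seedrow$z))) {
      seed2$x <- cv[["x"]]; seed2$y <- cv[["y"]]; seed2$z <- cv[["z"]]
      sub2 <- tryCatch(extract_subvolume(stack, seed2, size = size),
                       fociquant_boundary_error = function(e) NULL)
      if (!is.null(sub2)) {
        seg2 <- tryCatch(segment_focus(sub2, params),
                         fociquant_value_error = function(e) NULL)
        if (!is.null(seg2)) return(seg2)
      }
    }
  }
  seg
}

pair_row_skeleton <- function(stack_id, locus_id) {
  tibble(stack_id = stack_id, locus_id = locus_id,
         channel_a = NA_integer_, channel_b = NA_integer_,
         distance_nm = NA_real_, pearson_r = NA_real_,
         volume_a_um3 = NA_real_, volume_b_um3 = NA_real_,
         x_a_nm = NA_real_, y_a_nm = NA_real_, z_a_nm = NA_real_,
         x_b_nm = NA_real_, y_b_nm = NA_real_, z_b_nm = NA_real_,
         threshold_a = NA_real_, threshold_b = NA_real_,
         degenerate_a = NA, degenerate_b = NA,
         valid = FALSE, flag = "missing")
}

#' Measure all probe pairs referenced by a seed table
#'
#' The table-level measurement driver: for every (stack, locus) with two
#' seed points it extracts the 20x20x7 crops, segments both foci, and
#' reports the inter-centroid 3D distance, per-channel integrated volumes
#' and the Pearson colocalization of congruent raw crops taken at the
#' rounded midpoint of the two centroids. Loci whose crops cross a stack
#' boundary, or whose segmentations are flagged degenerate, are returned
#' with `valid = FALSE` and a `flag` reason — never an exception — so
#' partial failures do not abort a run and summaries can exclude them.
#'
#' @param stacks A single [image_stack()] or a list of stacks (matched to
#'   seed rows by `stack_id`).
#' @param seeds A seed-point tibble ([seed_points()]); pair loci are those
#'   whose `role` is `NA`.
#' @param size Crop size (nx, ny, nz).
#' @param params A [segmentation_params()].
#' @param recenter Re-extract each crop once centred on the first-pass
#'   centroid (recommended: undoes click-jitter truncation).
#' @param pearson Compute Pearson colocalization?
#' @param calibration Optional `chromatic_offset` applied to each stack
#'   before measurement.
#' @return A tibble with one row per locus: centroids, `distance_nm`,
#'   `pearson_r`, volumes, thresholds, degeneracy flags, `valid`, `flag`.
#' @export
measure_pairs <- function(stacks, seeds, size = c(20, 20, 7),
                          params = segmentation_params(), recenter = TRUE,
                          pearson = TRUE, calibration = NULL) {
  seeds <- dplyr::filter(seeds, is.na(.data$role) | .data$role == "")
  if (!nrow(seeds)) return(pair_row_skeleton(character(), character())[0, ])
  if (!is.null(calibration)) {
    if (is_image_stack(stacks)) stacks <- apply_offset(stacks, calibration)
    else stacks <- lapply(stacks, apply_offset, offset = calibration)
  }
  loci <- dplyr::distinct(seeds, .data$stack_id, .data$locus_id)
  purrr::pmap_dfr(loci, function(stack_id, locus_id) {
    rows <- dplyr::filter(seeds, .data$stack_id == !!stack_id,
                          .data$locus_id == !!locus_id)
    out <- pair_row_skeleton(stack_id, locus_id)
    if (nrow(rows) != 2L) {
      out$flag <- sprintf("expected 2 seeds, got %d", nrow(rows))
      return(out)
    }
    stack <- resolve_stack(stacks, stack_id)
    sa <- segment_seed(stack, rows[1, ], size, params, recenter)
    sb <- segment_seed(stack, rows[2, ], size, params, recenter)
    if (is.null(sa) || is.null(sb)) {
      out$flag <- "crop_failed"
      return(out)
    }
    out$channel_a <- rows$channel_index[1]; out$channel_b <- rows$channel_index[2]
    out$distance_nm <- pair_distance(sa, sb)
    out$volume_a_um3 <- sa$volume_um3; out$volume_b_um3 <- sb$volume_um3
    out$x_a_nm <- sa$centroid_nm[["x"]]; out$y_a_nm <- sa$centroid_nm[["y"]]
    out$z_a_nm <- sa$centroid_nm[["z"]]
    out$x_b_nm <- sb$centroid_nm[["x"]]; out$y_b_nm <- sb$centroid_nm[["y"]]
    out$z_b_nm <- sb$centroid_nm[["z"]]
    out$threshold_a <- sa$threshold; out$threshold_b <- sb$threshold
    out$degenerate_a <- sa$degenerate; out$degenerate_b <- sb$degenerate
    out$valid <- !sa$degenerate && !sb$degenerate
    out$flag <- if (out$valid) "" else
      paste(stats::na.omit(c(if (sa$degenerate) paste0("a:", sa$degenerate_reason),
                             if (sb$degenerate) paste0("b:", sb$degenerate_reason))),
            collapse = ";")
    if (pearson) {
      mid <- round((sa$centroid_vox + sb$centroid_vox) / 2)
      mk <- function(ci) tryCatch(
        extract_subvolume(stack, list(channel_index = ci, x = mid[["x"]],
                                      y = mid[["y"]], z = mid[["z"]],
                                      stack_id = stack_id, locus_id = locus_id),
                          size = size),
        fociquant_boundary_error = function(e) NULL)
      ca <- mk(rows$channel_index[1]); cb <- mk(rows$channel_index[2])
      if (!is.null(ca) && !is.null(cb)) out$pearson_r <- pearson_pair(ca, cb)
    }
    out
  })
}

#' Measure all probe triples referenced by a seed table
#'
#' Like [measure_pairs()] but for loci seeded with `role`s `"vertex"`,
#' `"arm1"`, `"arm2"`: the three foci are segmented and the vertex angle is
#' computed via [triple_angle()].
#'
#' @inheritParams measure_pairs
#' @return A tibble with one row per locus: `a_nm`, `b_nm`, `c_nm`,
#'   `theta_deg`, degeneracy flags, `valid`, `flag`.
#' @export
measure_triples <- function(stacks, seeds, size = c(20, 20, 7),
                            params = segmentation_params(), recenter = TRUE,
                            calibration = NULL) {
  seeds <- dplyr::filter(seeds, .data$role %in% c("vertex", "arm1", "arm2"))
  skel <- tibble(stack_id = character(), locus_id = character(),
                 a_nm = numeric(), b_nm = numeric(), c_nm = numeric(),
                 theta_deg = numeric(), degenerate_any = logical(),
                 valid = logical(), flag = character())
  if (!nrow(seeds)) return(skel)
  if (!is.null(calibration)) {
    if (is_image_stack(stacks)) stacks <- apply_offset(stacks, calibration)
    else stacks <- lapply(stacks, apply_offset, offset = calibration)
  }
  loci <- dplyr::distinct(seeds, .data$stack_id, .data$locus_id)
  purrr::pmap_dfr(loci, function(stack_id, locus_id) {
    rows <- dplyr::filter(seeds, .data$stack_id == !!stack_id,
                          .data$locus_id == !!locus_id)
    out <- tibble(stack_id = stack_id, locus_id = locus_id,
                  a_nm = NA_real_, b_nm = NA_real_, c_nm = NA_real_,
                  theta_deg = NA_real_, degenerate_any = NA,
                  valid = FALSE, flag = "")
    segs <- lapply(c("vertex", "arm1", "arm2"), function(r) {
      rr <- dplyr::filter(rows, .data$role == r)
      if (nrow(rr) != 1L) return(NULL)
      stack <- resolve_stack(stacks, stack_id)
      segment_seed(stack, rr, size, params, recenter)
    })
    if (any(vapply(segs, is.null, logical(1)))) {
      out$flag <- "crop_failed_or_missing_role"
      return(out)
    }
    ta <- tryCatch(triple_angle(segs[[1]], segs[[2]], segs[[3]]),
                   fociquant_value_error = function(e) NULL)
    if (is.null(ta)) {
      out$flag <- "coincident_centroids"
      return(out)
    }
    out$a_nm <- ta$a_nm; out$b_nm <- ta$b_nm; out$c_nm <- ta$c_nm
    out$theta_deg <- ta$theta_deg
    out$degenerate_any <- any(vapply(segs, function(s) s$degenerate, logical(1)))
    out$valid <- !out$degenerate_any
    out$flag <- if (out$valid) "" else "degenerate_focus"
    out
  })
}
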