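# Independent reference implementations used as oracles. These deliberately
# share no code with the package: explicit sorts, triple loops and pairwise
# union-find instead of the package's vectorised paths.

# brute-force clip-and-threshold segmentation on a (ny, nx, nz) crop array
oracle_segment <- function(crop, clip_percentile = 96.5, threshold_fraction = 0.9) {
  v <- sort(as.vector(crop))                 # explicit full sort
  n <- length(v)
  k <- ceiling(clip_percentile / 100 * n)    # nearest-rank percentile
  clip <- v[k]
  cl <- crop
  cl[cl > clip] <- clip
  thr <- threshold_fraction * max(cl)
  mask_idx <- which(cl >= thr)
  d <- dim(crop)
  pos <- arrayInd(mask_idx, d)               # (y, x, z)

  # union-find over all voxel pairs, 26-connectivity
  parent <- seq_along(mask_idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(mask_idx) > 1) {
    for (i in seq_len(length(mask_idx) - 1)) {
      for (j in (i + 1):length(mask_idx)) {
        if (all(abs(pos[i, ] - pos[j, ]) <= 1)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_along(mask_idx), find, integer(1))
  comp_sizes <- table(roots)
  best <- as.integer(names(comp_sizes)[comp_sizes == max(comp_sizes)])
  if (length(best) > 1) {                    # tie: component closest to centre
    centre <- (d - 1) / 2 + 1
    dist_min <- vapply(best, function(b) {
      p <- pos[roots == b, , drop = FALSE]
      min(sqrt(rowSums(sweep(p, 2, centre)^2)))
    }, numeric(1))
    best <- best[which.min(dist_min)]
  }
  keep <- roots == best
  kept_idx <- mask_idx[keep]
  kept_pos <- pos[keep, , drop = FALSE]
  w <- cl[kept_idx]
  centroid_crop <- c(
    x = sum(kept_pos[, 2] * w) / sum(w) - 1,  # 0-based within crop
    y = sum(kept_pos[, 1] * w) / sum(w) - 1,
    z = sum(kept_pos[, 3] * w) / sum(w) - 1)
  list(clip = clip, threshold = thr, n_voxels = sum(keep),
       mask_idx = sort(kept_idx), centroid_crop = centroid_crop)
}

# hand rank-based Kruskal-Wallis H with tie correction
oracle_kw_H <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (lev in levels(groups)) {
    sel <- groups == lev
    H <- H + sum(sel) * (mean(r[sel]) - (N + 1) / 2)^2
  }
  H <- 12 / (N * (N + 1)) * H
  tie_counts <- as.vector(table(values))
  H / (1 - sum(tie_counts^3 - tie_counts) / (N^3 - N))
}

# textbook sum-formula Pearson correlation
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# dot-product vertex angle in degrees
oracle_dot_angle <- function(v, p1, p2) {
  u1 <- p1 - v; u2 <- p2 - v
  ct <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# a small deterministic two-channel stack with one bright blob per channel
make_tiny_stack <- function(stack_id = "tiny") {
  a <- array(1, c(32, 32, 9))
  b <- array(1, c(32, 32, 9))
  a[14:18, 14:18, 4:6] <- 80
  b[15:19, 16:20, 4:6] <- 90
  image_stack(list(a, b), voxel_size(), stack_id)
}

# all ordered selections of k distinct items from 1..n (small n only)
gtools_like_perms <- function(n, k) {
  out <- list(integer(0))
  for (depth in seq_len(k)) {
    out <- unlist(lapply(out, function(pfx) {
      lapply(setdiff(seq_len(n), pfx), function(j) c(pfx, j))
    }), recursive = FALSE)
  }
  out
}
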