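#' Significance stars
#'
#' Standard coding: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns")
}

# tie-corrected Kruskal-Wallis H for a value vector and group factor
kw_H <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  H / C
}

# enumerate all distinct assignments of N items into groups of fixed sizes,
# calling fun(group_factor) for each; feasible for small N only
enumerate_partitions <- function(n_sizes, fun) {
  N <- sum(n_sizes)
  res <- numeric(0)
  recurse <- function(remaining, sizes, assign) {
    if (length(sizes) == 1L) {
      assign[remaining] <- length(n_sizes)
      res[[length(res) + 1L]] <<- fun(assign)
      return(invisible())
    }
    g <- length(n_sizes) - length(sizes) + 1L
    for (pick in utils::combn(remaining, sizes[1], simplify = FALSE)) {
      a2 <- assign; a2[pick] <- g
      recurse(setdiff(remaining, pick), sizes[-1], a2)
    }
  }
  recurse(seq_len(N), n_sizes, integer(N))
  res
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' The group-comparison engine for distance, volume and colocalization
#' tables: per-group medians with interquartile ranges, the tie-corrected
#' Kruskal-Wallis H with its two-tailed p value, and Dunn's pairwise z
#' tests on mean ranks with multiplicity-adjusted p values (Bonferroni by
#' default, Holm optionally) and significance stars.
#'
#' The global p value is asymptotic (chi-square) by default;
#' `p_method = "permutation"` replaces it with an exact enumeration over
#' all distinct group assignments when that count is at most
#' `max_enumeration`, otherwise a Monte-Carlo permutation estimate —
#' preferable for very small groups where the chi-square approximation is
#' rough.
#'
#' If all observations are identical the result is flagged degenerate with
#' `H = 0` and `p_global = 1`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurements and the
#'   group labels.
#' @param p_adjust `"bonferroni"` (default) or `"holm"`.
#' @param p_method `"asymptotic"` or `"permutation"` for the global p.
#' @param n_perm Monte-Carlo draws when enumeration is infeasible.
#' @param max_enumeration Enumeration budget (number of distinct
#'   assignments).
#' @param seed Seed for the Monte-Carlo path.
#' @return An object of class `kruskal_dunn`; see [tidy()] / [glance()]
#'   methods.
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' kruskal_dunn(df, v, g)
#' @export
kruskal_dunn <- function(data, value, group,
                         p_adjust = c("bonferroni", "holm"),
                         p_method = c("asymptotic", "permutation"),
                         n_perm = 10000, max_enumeration = 50000,
                         seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  p_method <- match.arg(p_method)
  values <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2L || any(tabulate(g) < 1L)) {
    abort("kruskal_dunn needs >= 2 groups with >= 1 observation each",
          class = "fociquant_value_error")
  }
  groups <- tibble(group = levels(g),
                   n = as.integer(tabulate(g)),
                   median = as.numeric(tapply(values, g, median)),
                   q25 = as.numeric(tapply(values, g, quantile, probs = 0.25)),
                   q75 = as.numeric(tapply(values, g, quantile, probs = 0.75)))

  degenerate <- length(unique(values)) < 2L
  if (degenerate) {
    H <- 0; p_global <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    H <- unname(kt$statistic); p_global <- kt$p.value
    if (p_method == "permutation") {
      sizes <- tabulate(g)
      n_assign <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
      Hobs <- H - 1e-9
      if (n_assign <= max_enumeration) {
        Hs <- enumerate_partitions(sizes, function(a) kw_H(values, a))
        p_global <- mean(Hs >= Hobs)
      } else {
        p_global <- withr::with_seed(seed, {
          Hs <- replicate(n_perm, kw_H(values, sample(as.integer(g))))
          (sum(Hs >= Hobs) + 1) / (n_perm + 1)
        })
      }
    }
  }

  # Dunn's z on mean ranks, tie-corrected
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(values)
  tiesum <- sum(ties^3 - ties)
  pairs <- utils::combn(seq_len(k), 2)
  m <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tiesum / (12 * (N - 1))) * (1 / n[i1] + 1 / n[i2]))
    z <- if (se > 0) (Rbar[[i1]] - Rbar[[i2]]) / se else 0
    tibble(group1 = levels(g)[i1], group2 = levels(g)[i2],
           z = z, p = 2 * pnorm(-abs(z)))
  })
  pw$p_adj <- if (degenerate) rep(1, m) else
    switch(p_adjust,
           bonferroni = pmin(1, pw$p * m),
           holm = stats::p.adjust(pw$p, method = "holm"))
  pw$stars <- p_stars(pw$p_adj)

  structure(list(groups = groups, H = H, df = k - 1L, p_global = p_global,
                 pairwise = pw, p_adjust = p_adjust, p_method = p_method,
                 degenerate = degenerate, n = N),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g%s\n",
              x$H, x$df, x$p_global,
              if (x$degenerate) " [degenerate: all values identical]" else ""))
  print(x$groups)
  cat(sprintf("Dunn's pairwise comparisons (%s-adjusted):\n", x$p_adjust))
  print(x$pairwise)
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
#' @method tidy kruskal_dunn
#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @rdname kruskal_dunn
#' @method glance kruskal_dunn
#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble(H = x$H, df = x$df, p_global = x$p_global, n = x$n,
         n_groups = nrow(x$groups), p_adjust = x$p_adjust,
         p_method = x$p_method, degenerate = x$degenerate)
}

#' Cumulative volume distribution in voxel-sized bins
#'
#' Bins are spaced by exactly one voxel volume starting at 0, and
#' right-inclusive; the curve is the fraction of observations at or below
#' each edge — the standard display for FISH signal-volume comparisons.
#'
#' @param volumes Non-negative volumes, um^3.
#' @param voxel A [voxel_size()] fixing the bin width.
#' @return A tibble of class `volume_cdf` with columns `bin_edge_um3`,
#'   `n_le`, `cum_freq` (non-decreasing, final value 1).
#' @export
volume_cdf <- function(volumes, voxel = voxel_size()) {
  if (!length(volumes)) {
    abort("volume_cdf needs at least one observation", class = "fociquant_value_error")
  }
  if (any(volumes < 0)) {
    abort("volumes must be non-negative", class = "fociquant_value_error")
  }
  w <- voxel_volume_um3(voxel)
  kmax <- ceiling(max(volumes) / w - 1e-9)
  edges <- (0:max(kmax, 1)) * w
  n_le <- vapply(edges, function(e) sum(volumes <= e + 1e-12 * w), integer(1))
  out <- tibble(bin_edge_um3 = edges, n_le = n_le,
                cum_freq = n_le / length(volumes))
  class(out) <- c("volume_cdf", class(out))
  attr(out, "voxel_volume_um3") <- w
  attr(out, "n") <- length(volumes)
  out
}

#' Group-level medians and IQRs for pair measurements
#'
#' Summarises a [measure_pairs()] table per group: observation counts,
#' flagged-row counts (degenerate or failed loci are excluded from the
#' statistics but counted), and median plus interquartile range (linear
#' interpolation, type-7 quantiles) of the distances, volumes and Pearson
#' coefficients. A group losing all rows to flags is reported with
#' `n_used = 0` and `NA` statistics.
#'
#' @param measurements A [measure_pairs()] tibble, optionally with extra
#'   grouping columns joined on.
#' @param ... Grouping columns (tidy-eval), e.g. a condition column; default
#'   groups by `stack_id`.
#' @return A tibble, one row per group.
#' @export
summarize_pairs <- function(measurements, ...) {
  gvars <- rlang::enquos(...)
  if (!length(gvars)) gvars <- rlang::quos(.data$stack_id)
  med3 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(tibble(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    tibble(median = median(x), q25 = quantile(x, 0.25, names = FALSE),
           q75 = quantile(x, 0.75, names = FALSE))
  }
  measurements |>
    dplyr::group_by(!!!gvars) |>
    dplyr::group_modify(function(df, key) {
      used <- dplyr::filter(df, .data$valid)
      d <- med3(used$distance_nm); p <- med3(used$pearson_r)
      va <- med3(used$volume_a_um3); vb <- med3(used$volume_b_um3)
      tibble(n_total = nrow(df), n_used = nrow(used),
             n_flagged = nrow(df) - nrow(used),
             distance_median_nm = d$median, distance_q25_nm = d$q25,
             distance_q75_nm = d$q75,
             pearson_median = p$median, pearson_q25 = p$q25, pearson_q75 = p$q75,
             volume_a_median_um3 = va$median, volume_a_q25_um3 = va$q25,
             volume_a_q75_um3 = va$q75,
             volume_b_median_um3 = vb$median, volume_b_q25_um3 = vb$q25,
             volume_b_q75_um3 = vb$q75)
    }) |>
    dplyr::ungroup()
}

#' Estimator-quality report against synthetic ground truth
#'
#' Joins a [measure_pairs()] table to a scene truth table on
#' (stack_id, locus_id), takes per-locus error = measured - true
#' separation, and reports the mean signed error (bias), the RMSE and the
#' median absolute error over the QC-passing loci. If re-measurements at
#' other z-steps are supplied, the per-locus spread (max - min across
#' variants) is summarised by its median — the pipeline's axial-sampling
#' tolerance.
#'
#' @param measurements A [measure_pairs()] tibble.
#' @param truth A scene truth table (from [make_spot_scene()]); rows are
#'   collapsed to one true separation per locus.
#' @param zstep_variants Optional named list of [measure_pairs()] tibbles
#'   re-measured on z-resampled stacks (see [resample_zstep()]).
#' @return An object of class `recovery_report`: `per_locus` tibble,
#'   `n`, `n_flagged`, `bias_nm`, `rmse_nm`, `median_abs_error_nm`,
#'   `zstep_tolerance_nm` (NA without variants). See [glance()].
#' @export
evaluate_recovery <- function(measurements, truth, zstep_variants = NULL) {
  tr <- truth |>
    dplyr::filter(!is.na(.data$separation_nm)) |>
    dplyr::distinct(.data$stack_id, .data$locus_id, .data$separation_nm)
  unmatched <- dplyr::anti_join(measurements, tr, by = c("stack_id", "locus_id"))
  if (nrow(unmatched)) {
    abort(sprintf("measurements and truth do not join; unmatched loci: %s",
                  paste(head(paste(unmatched$stack_id, unmatched$locus_id, sep = "/"),
                             10), collapse = ", ")),
          class = "fociquant_value_error")
  }
  per <- measurements |>
    dplyr::inner_join(tr, by = c("stack_id", "locus_id")) |>
    dplyr::mutate(error_nm = .data$distance_nm - .data$separation_nm)
  used <- dplyr::filter(per, .data$valid)

  tol <- NA_real_
  if (!is.null(zstep_variants)) {
    all_v <- c(list(base = measurements), zstep_variants)
    wide <- purrr::imap_dfr(all_v, function(tb, nm) {
      tb |> dplyr::filter(.data$valid) |>
        dplyr::transmute(.data$stack_id, .data$locus_id, variant = nm,
                         .data$distance_nm)
    }) |>
      dplyr::group_by(.data$stack_id, .data$locus_id) |>
      dplyr::filter(dplyr::n() == length(all_v)) |>
      dplyr::summarise(spread_nm = max(.data$distance_nm) - min(.data$distance_nm),
                       .groups = "drop")
    tol <- if (nrow(wide)) median(wide$spread_nm) else NA_real_
  }

  structure(list(per_locus = per,
                 n = nrow(used), n_flagged = nrow(per) - nrow(used),
                 bias_nm = mean(used$error_nm),
                 rmse_nm = sqrt(mean(used$error_nm^2)),
                 median_abs_error_nm = median(abs(used$error_nm)),
                 zstep_tolerance_nm = tol),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %d loci used (%d flagged): bias %.2f nm, RMSE %.2f nm, median |error| %.2f nm%s\n",
    x$n, x$n_flagged, x$bias_nm, x$rmse_nm, x$median_abs_error_nm,
    if (is.na(x$zstep_tolerance_nm)) "" else
      sprintf(", z-step tolerance %.2f nm", x$zstep_tolerance_nm)))
  invisible(x)
}

#' @rdname evaluate_recovery
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(n = x$n, n_flagged = x$n_flagged, bias_nm = x$bias_nm,
         rmse_nm = x$rmse_nm, median_abs_error_nm = x$median_abs_error_nm,
         zstep_tolerance_nm = x$zstep_tolerance_nm)
}

#' @rdname evaluate_recovery
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$per_locus
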