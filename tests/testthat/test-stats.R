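test_that("the Kruskal-Wallis H matches hand rank arithmetic", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  kd <- kruskal_dunn(df, v, g)
  expect_equal(kd$H, 27 / 7, tolerance = 1e-9)           # 3.857
  expect_equal(kd$H, 3.857, tolerance = 1e-3)
  expect_equal(kd$H, oracle_kw_H(df$v, df$g), tolerance = 1e-9)
})

test_that("H equals the rank-based oracle on 100 random small datasets", {
  withr::with_seed(19, {
    for (i in 1:100) {
      k <- sample(2:4, 1)
      n <- sample(3:6, k, replace = TRUE)
      df <- data.frame(
        v = round(rnorm(sum(n), 0, 2), 1),   # rounding induces ties
        g = rep(letters[1:k], times = n))
      kd <- kruskal_dunn(df, v, g)
      expect_equal(kd$H, oracle_kw_H(df$v, df$g), tolerance = 1e-9)
      expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p - 1e-12))
    }
  })
})

test_that("identical groups are a degenerate null result", {
  df <- data.frame(v = rep(5, 8), g = rep(c("a", "b"), each = 4))
  kd <- kruskal_dunn(df, v, g)
  expect_true(kd$degenerate)
  expect_equal(kd$H, 0)
  expect_equal(kd$p_global, 1)
  expect_false(any(kd$pairwise$p_adj < 0.05))
})

test_that("Dunn pairwise statistics follow the mean-rank formula", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  kd <- kruskal_dunn(df, v, g)
  # mean ranks 2 and 5, se = sqrt(3.5 * 2/3)
  z_hand <- (2 - 5) / sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(kd$pairwise$z, z_hand, tolerance = 1e-9)
  expect_equal(kd$pairwise$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  expect_equal(kd$pairwise$p_adj, kd$pairwise$p)   # one pair: Bonferroni x1
  expect_equal(kd$pairwise$stars, "*")
  expect_equal(p_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("the permutation p value equals exhaustive enumeration", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  kd <- kruskal_dunn(df, v, g, p_method = "permutation")
  # oracle: enumerate all choose(6,3) = 20 splits explicitly
  Hs <- apply(combn(6, 3), 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    oracle_kw_H(df$v, gg)
  })
  expect_equal(kd$p_global, mean(Hs >= kd$H - 1e-9), tolerance = 1e-12)
  # three tiny groups: asymptotic p is close to the exact permutation p
  withr::with_seed(4, {
    df3 <- data.frame(v = rnorm(12), g = rep(c("a", "b", "c"), each = 4))
  })
  exact <- kruskal_dunn(df3, v, g, p_method = "permutation")$p_global
  asym <- kruskal_dunn(df3, v, g)$p_global
  expect_lt(abs(exact - asym), 0.1)
  # Monte-Carlo path approximates the exact enumeration
  mc <- kruskal_dunn(df3, v, g, p_method = "permutation",
                     max_enumeration = 10, n_perm = 4000, seed = 2)$p_global
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)
})

test_that("volume CDFs use exact voxel-sized right-inclusive bins", {
  w <- voxel_volume_um3(voxel_size())
  one <- volume_cdf(10 * w)
  expect_equal(one$bin_edge_um3[11], 10 * w)
  expect_equal(one$cum_freq[11], 1.0)
  expect_lt(max(one$cum_freq[1:10]), 1.0)
  three <- volume_cdf(c(1, 2, 3) * w)
  expect_equal(three$cum_freq[2:4], c(1 / 3, 2 / 3, 1))
  expect_equal(three$bin_edge_um3[2:4], c(w, 2 * w, 3 * w))
})

test_that("volume CDFs are monotone, order-invariant and duplication-idempotent", {
  withr::with_seed(6, {
    vols <- runif(40, 0, 30) * voxel_volume_um3(voxel_size())
    cdf <- volume_cdf(vols)
    expect_true(all(diff(cdf$cum_freq) >= 0))
    expect_equal(cdf$cum_freq[nrow(cdf)], 1.0)
    # sort-based oracle
    expect_equal(cdf$cum_freq,
                 vapply(cdf$bin_edge_um3,
                        function(e) mean(sort(vols) <= e + 1e-15), numeric(1)))
    expect_equal(volume_cdf(rev(vols))$cum_freq, cdf$cum_freq)
    expect_equal(volume_cdf(rep(vols, 2))$cum_freq, cdf$cum_freq)
  })
  expect_error(volume_cdf(numeric(0)), class = "fociquant_value_error")
  expect_error(volume_cdf(c(1, -1)), class = "fociquant_value_error")
})

test_that("pair summaries report medians with type-7 IQRs and honour flags", {
  m <- tibble::tibble(
    stack_id = "s", locus_id = sprintf("l%d", 1:4),
    distance_nm = c(100, 200, 300, 9999), pearson_r = c(0.2, 0.4, 0.6, NA),
    volume_a_um3 = c(0.01, 0.02, 0.03, 1), volume_b_um3 = c(0.01, 0.02, 0.03, 1),
    valid = c(TRUE, TRUE, TRUE, FALSE), flag = c("", "", "", "bad"))
  sm <- summarize_pairs(m)
  expect_equal(sm$n_total, 4L)
  expect_equal(sm$n_used, 3L)
  expect_equal(sm$distance_median_nm, 200)
  expect_equal(sm$distance_q25_nm, 150)   # linear-interpolation quartiles
  expect_equal(sm$distance_q75_nm, 250)
  # singleton group
  one <- summarize_pairs(m[1, ])
  expect_equal(one$distance_q25_nm, one$distance_q75_nm)
  # group losing all rows to flags
  none <- summarize_pairs(m[4, ])
  expect_equal(none$n_used, 0L)
  expect_true(is.na(none$distance_median_nm))
})

test_that("recovery reports satisfy forced arithmetic and error bounds", {
  truth <- tibble::tibble(stack_id = "s", locus_id = c("a", "b", "c"),
                          separation_nm = c(400, 500, 600))
  m <- tibble::tibble(stack_id = "s", locus_id = c("a", "b", "c"),
                      distance_nm = c(400, 500, 600), valid = TRUE)
  perfect <- evaluate_recovery(m, truth)
  expect_equal(perfect$bias_nm, 0)
  expect_equal(perfect$rmse_nm, 0)
  expect_equal(perfect$median_abs_error_nm, 0)
  shifted <- m; shifted$distance_nm <- shifted$distance_nm + 100
  r <- evaluate_recovery(shifted, truth)
  expect_equal(r$bias_nm, 100)
  expect_equal(r$rmse_nm, 100)
  expect_gte(r$rmse_nm, abs(r$bias_nm))
  bad <- m; bad$locus_id[1] <- "zz"
  expect_error(evaluate_recovery(bad, truth), class = "fociquant_value_error",
               regexp = "zz")
  # Jensen: RMSE >= |bias| on random error patterns
  withr::with_seed(13, {
    for (i in 1:10) {
      mm <- m; mm$distance_nm <- mm$distance_nm + rnorm(3, 0, 50)
      rr <- evaluate_recovery(mm, truth)
      expect_gte(rr$rmse_nm + 1e-12, abs(rr$bias_nm))
    }
  })
})

test_that("tidy and glance expose the fitted objects as tibbles", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6, 7, 9), g = rep(c("a", "b"), each = 4))
  kd <- kruskal_dunn(df, v, g)
  expect_s3_class(tidy(kd), "tbl_df")
  expect_named(glance(kd),
               c("H", "df", "p_global", "n", "n_groups", "p_adjust",
                 "p_method", "degenerate"))
  p <- autoplot(kd)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(volume_cdf(c(1, 2) * voxel_volume_um3(voxel_size()))),
                  "ggplot")
})

test_that("the pipeline separates 350 nm from 700 nm cohorts decisively", {
  # two simulated cohorts per replicate, n = 50 loci each
  hits <- sapply(1:20, function(s) {
    g1 <- make_spot_scene(scene_params(n_loci = 50, separation_model = 350,
                                       stack_id = "d350", seed = 5000 + s))
    g2 <- make_spot_scene(scene_params(n_loci = 50, separation_model = 700,
                                       stack_id = "d700", seed = 6000 + s))
    m <- rbind(measure_pairs(g1$stack, g1$seeds, pearson = FALSE),
               measure_pairs(g2$stack, g2$seeds, pearson = FALSE))
    kd <- kruskal_dunn(dplyr::filter(m, valid), distance_nm, stack_id)
    kd$pairwise$p_adj[1] < 0.0001
  })
  expect_gte(mean(hits), 0.95)
})
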