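#' Plot a cumulative volume distribution
#'
#' Step plot of the voxel-binned cumulative frequency curve from
#' [volume_cdf()].
#'
#' @param object A `volume_cdf`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot volume_cdf
#' @export
autoplot.volume_cdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_edge_um3, y = .data$cum_freq)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(x = expression("signal volume (" * mu * m^3 * ")"),
                  y = "cumulative frequency") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_classic()
}

#' Plot group medians with interquartile ranges
#'
#' The standard median-with-IQR dot plot for a [kruskal_dunn()] result.
#'
#' @param object A `kruskal_dunn`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kruskal_dunn
#' @export
autoplot.kruskal_dunn <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75)) +
    ggplot2::labs(x = NULL, y = "median (IQR)",
                  subtitle = sprintf("Kruskal-Wallis H = %.3g, p = %.3g",
                                     object$H, object$p_global)) +
    ggplot2::theme_classic()
}

#' Plot measured against true separations
#'
#' Scatter of per-locus measured inter-centroid distance versus true
#' separation from a [evaluate_recovery()] report, with the identity line;
#' flagged loci are shown hollow.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$per_locus,
                  ggplot2::aes(x = .data$separation_nm, y = .data$distance_nm,
                               shape = .data$valid)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "QC pass") +
    ggplot2::labs(x = "true separation (nm)", y = "measured distance (nm)") +
    ggplot2::theme_classic()
}

#' QC montage for one measured locus
#'
#' Mid-plane view of the two channel crops with the segmentation mask
#' outline and the centroid marked — the per-locus visual-inspection image
#' the measurement scripts emit.
#'
#' @param subs List of [extract_subvolume()] crops (one per channel).
#' @param segs Matching list of [segment_focus()] results.
#' @return A ggplot (facetted by channel).
#' @export
plot_locus_qc <- function(subs, segs) {
  stopifnot(length(subs) == length(segs))
  df <- purrr::map2_dfr(subs, segs, function(sub, seg) {
    k <- round((dim(sub$data)[3] + 1) / 2)
    plane <- sub$data[, , k]
    mask <- seg$mask[, , k]
    g <- expand.grid(y = seq_len(nrow(plane)), x = seq_len(ncol(plane)))
    tibble(channel = sprintf("channel %d", sub$channel_index),
           x = g$x + sub$origin[1] - 1, y = g$y + sub$origin[2] - 1,
           intensity = as.vector(plane), in_mask = as.vector(mask))
  })
  cents <- purrr::map2_dfr(subs, segs, function(sub, seg) {
    tibble(channel = sprintf("channel %d", sub$channel_index),
           x = seg$centroid_vox[["x"]], y = seg$centroid_vox[["y"]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$in_mask),
                       fill = NA, colour = "red", linewidth = 0.2) +
    ggplot2::geom_point(data = cents, colour = "cyan", shape = 3, size = 2) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)",
                  title = sprintf("%s / %s", subs[[1]]$stack_id, subs[[1]]$locus_id)) +
    ggplot2::theme_minimal()
}
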