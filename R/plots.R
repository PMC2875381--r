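#' Skyline recurrence plot of cohort copy-number calls
#'
#' For every probe, the fraction of samples gained (upward) and lost
#' (downward) at the calling thresholds, faceted by cohort -- the classic
#' aCGH recurrence skyline.
#'
#' @param seg Centered segment tibble.
#' @param samples Sample sheet.
#' @param map Genome map.
#' @param thresholds A [cna_thresholds()].
#' @return A ggplot object.
#' @export
plot_recurrence <- function(seg, samples, map, thresholds = cna_thresholds()) {
  v <- seg_to_probe_matrix(seg, samples, map)
  dat <- purrr::map_dfr(levels(samples$group), function(g) {
    vg <- v[, samples$sample_id[samples$group == g], drop = FALSE]
    tibble(group = g, index = seq_len(nrow(map)), chrom = map$chrom,
           gain = rowMeans(vg >= thresholds$gain),
           loss = -rowMeans(vg <= thresholds$loss))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$gain), fill = "darkred") +
    ggplot2::geom_area(ggplot2::aes(y = .data$loss), fill = "darkgreen") +
    ggplot2::geom_vline(xintercept = cumsum(rle(dat$chrom[dat$group == dat$group[1]])$lengths),
                        linewidth = 0.1, colour = "grey70") +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::labs(x = "probe (genome order, chr 1-22)",
                  y = "fraction of samples altered") +
    ggplot2::theme_minimal()
}

#' Genome-wide q-value profile of the cohort comparison
#'
#' -log10(q) per tested R-segment along the genome, the package's analogue of
#' a whole-genome differential-alteration profile; the dashed line marks the
#' ROI threshold.
#'
#' @param result An `igc_result` from [igc_compare()].
#' @return A ggplot object.
#' @export
plot_qvalue_profile <- function(result) {
  rec <- result$records
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$rseg_id, y = -log10(pmax(.data$q, 1e-6)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(result$q_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(gain = "darkred", loss = "darkgreen")) +
    ggplot2::labs(x = "R-segment (genome order)", y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' @rdname plot_qvalue_profile
#' @param object An `igc_result`.
#' @param ... Unused.
#' @export
autoplot.igc_result <- function(object, ...) plot_qvalue_profile(object)

#' Consensus matrix heatmap
#'
#' Samples ordered by the consensus dendrogram; a stable rank shows crisp
#' diagonal blocks.
#'
#' @param object A `gnmf_consensus` from [consensus_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gnmf_consensus <- function(object, ...) {
  ord <- object$hclust$order
  m <- object$consensus[ord, ord]
  dat <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  dat$value <- as.vector(t(m))
  ggplot2::ggplot(dat, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "red", limits = c(0, 1),
                                 name = "co-cluster\nfrequency") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus, K = %d (rho = %.3f)", object$k, object$rho)) +
    ggplot2::theme_minimal()
}
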