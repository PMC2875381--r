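#' Collapse a segmented cohort to reduced segments (R-segments)
#'
#' Per chromosome, the breakpoint positions of all samples are pooled; the
#' intervals between consecutive union breakpoints are the R-segments, within
#' which every sample's segmented value is constant. The number of R-segments
#' always equals the number of distinct interior breakpoints plus the number
#' of chromosomes.
#'
#' @param seg Segment tibble for the pooled cohorts.
#' @param samples Sample sheet.
#' @param map Genome map shared by every profile.
#' @return Wide tibble: `rseg_id` (genome-ordered), `chrom`, `start`, `end`,
#'   `n_probes`, then one segment-value column per sample.
#' @export
build_rsegments <- function(seg, samples, map) {
  samples <- as_sample_sheet(samples)
  v <- seg_to_probe_matrix(seg, samples, map)
  out <- purrr::map_dfr(unique(map$chrom), function(chr) {
    sel <- which(map$chrom == chr)
    # union of breakpoints: bp starts of all samples' segments on this
    # chromosome, expressed as probe indices
    starts <- sort(unique(seg$start[seg$chrom == chr]))
    idx <- sort(unique(match(starts, map$pos[sel])))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0 || idx[1] != 1L) idx <- c(1L, idx)
    from <- sel[idx]
    to <- c(from[-1] - 1L, max(sel))
    tibble(chrom = chr, start = map$pos[from],
           end = c(map$pos[from[-1]], map$pos[max(sel)] + 1),
           n_probes = to - from + 1L) %>%
      dplyr::bind_cols(as_tibble(v[from, , drop = FALSE]))
  })
  # every sample must be constant within every R-segment
  for (i in seq_len(nrow(out))) {
    sel <- which(map$chrom == out$chrom[i] & map$pos >= out$start[i] & map$pos < out$end[i])
    if (length(sel) > 1 &&
        any(matrixStats_colRange(v[sel, , drop = FALSE]) > 0)) {
      abort("profiles do not share a consistent genome map (non-constant R-segment)")
    }
  }
  mutate(out, rseg_id = row_number(), .before = 1)
}

# per-column max - min without extra deps
matrixStats_colRange <- function(m) {
  apply(m, 2, function(col) diff(range(col)))
}

#' Fisher exact comparison of cohorts per R-segment
#'
#' For each R-segment every sample is classified gained / lost / neutral at
#' the +/-0.15 thresholds; a direction is tested only if at least one sample
#' (either cohort) carries that alteration. The gain test tabulates gained
#' vs. normal by cohort (lost samples excluded), and symmetrically for loss.
#' The two-sided p-value is the minimum-likelihood Fisher exact p
#' ([stats::fisher.test]).
#'
#' @param rseg R-segment tibble from [build_rsegments()].
#' @param samples Sample sheet.
#' @param thresholds A [cna_thresholds()].
#' @return Tibble: one row per tested (R-segment, direction) with the 2x2
#'   counts (`alt_primary`, `norm_primary`, `alt_metastatic`,
#'   `norm_metastatic`) and `p`.
#' @export
fisher_compare <- function(rseg, samples, thresholds = cna_thresholds()) {
  samples <- as_sample_sheet(samples)
  if (!all(levels(samples$group) %in% samples$group)) {
    abort("both cohorts must be non-empty")
  }
  vals <- as.matrix(rseg[samples$sample_id])
  dir <- matrix(state_direction(call_state(as.vector(vals), thresholds)),
                nrow(vals), ncol(vals))
  is_primary <- samples$group == "primary"
  purrr::map_dfr(c("gain", "loss"), function(d) {
    other <- if (d == "gain") "loss" else "gain"
    purrr::map_dfr(seq_len(nrow(rseg)), function(i) {
      alt <- dir[i, ] == d
      keep <- dir[i, ] != other
      if (!any(alt)) return(NULL)
      a <- sum(alt & is_primary); b <- sum(keep & !alt & is_primary)
      c_ <- sum(alt & !is_primary); d_ <- sum(keep & !alt & !is_primary)
      p <- min(1, fisher.test(matrix(c(a, b, c_, d_), 2, byrow = TRUE))$p.value)
      tibble(rseg_id = rseg$rseg_id[i], chrom = rseg$chrom[i],
             start = rseg$start[i], end = rseg$end[i], direction = d,
             alt_primary = a, norm_primary = b,
             alt_metastatic = c_, norm_metastatic = d_, p = p)
    })
  }) %>%
    arrange(.data$direction, .data$rseg_id)
}

#' Storey q-values for a family of p-values
#'
#' The proportion of true nulls pi0 is estimated on the lambda grid 0, 0.05,
#' ..., 0.90 and extrapolated to lambda = 1 with a cubic smoothing spline
#' (Storey's estimator); with fewer than 100 p-values pi0 is fixed at 1, which
#' reduces the estimate to Benjamini-Hochberg. q-values are monotone
#' non-decreasing in p-value rank.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as `p`, with the pi0
#'   estimate attached as attribute `"pi0"`.
#' @export
estimate_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  m <- length(p)
  pi0 <- if (m < 100) 1 else {
    lambda <- seq(0, 0.90, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    min(1, max(predict(fit, x = 1)$y, 1e-8))
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  ranks <- rank(p, ties.method = "max")
  for (i in ord) {
    running <- min(running, pi0 * m * p[i] / ranks[i])
    q[i] <- running
  }
  attr(q, "pi0") <- pi0
  q
}

#' Merge significant R-segments into regions of interest
#'
#' Significant (q at or below the threshold) same-direction R-segments that
#' are genomically adjacent -- consecutive in the R-segment partition of a
#' chromosome, with no intervening R-segment -- merge into one ROI; merging
#' never crosses a chromosome boundary.
#'
#' @param records Fisher records carrying a `q` column (see
#'   [fisher_compare()] + [estimate_qvalues()]).
#' @param q_threshold Significance cutoff (default 0.1, i.e. FDR 10%).
#' @return Tibble (`chrom`, `start`, `end`, `direction`, `n_rsegments`,
#'   `min_q`).
#' @export
call_rois <- function(records, q_threshold = 0.1) {
  sig <- records %>% filter(.data$q <= q_threshold)
  if (nrow(sig) == 0) {
    return(tibble(chrom = integer(), start = numeric(), end = numeric(),
                  direction = character(), n_rsegments = integer(),
                  min_q = numeric()))
  }
  sig %>%
    arrange(.data$direction, .data$rseg_id) %>%
    group_by(.data$direction) %>%
    mutate(roi = cumsum(.data$rseg_id != lag(.data$rseg_id, default = -9L) + 1L |
                          .data$chrom != lag(.data$chrom, default = -1L))) %>%
    group_by(.data$direction, .data$roi) %>%
    summarise(chrom = first(.data$chrom), start = first(.data$start),
              end = last(.data$end), n_rsegments = n(),
              min_q = min(.data$q), .groups = "drop") %>%
    select("chrom", "start", "end", "direction", "n_rsegments", "min_q") %>%
    arrange(.data$chrom, .data$start, .data$direction)
}

#' Run the full cohort comparison stage
#'
#' Convenience wrapper: build R-segments, Fisher-test both directions,
#' estimate q-values over the combined family (or per direction), and merge
#' significant segments into ROIs.
#'
#' @param seg Segment tibble (both cohorts, centered).
#' @param samples Sample sheet.
#' @param map Genome map.
#' @param thresholds A [cna_thresholds()].
#' @param q_threshold FDR threshold for ROI membership.
#' @param family `"together"` corrects gains and losses as one family
#'   (default), `"per-direction"` separately.
#' @return List of class `igc_result`: `rsegments`, `records` (with `q`),
#'   `rois`, `q_threshold`.
#' @export
igc_compare <- function(seg, samples, map, thresholds = cna_thresholds(),
                        q_threshold = 0.1, family = c("together", "per-direction")) {
  family <- match.arg(family)
  rseg <- build_rsegments(seg, samples, map)
  records <- fisher_compare(rseg, samples, thresholds)
  if (nrow(records)) {
    if (family == "together") {
      records$q <- estimate_qvalues(records$p)
    } else {
      records <- records %>% group_by(.data$direction) %>%
        mutate(q = estimate_qvalues(.data$p)) %>% ungroup()
    }
  } else {
    records$q <- numeric(0)
  }
  rois <- call_rois(records, q_threshold)
  structure(list(rsegments = rseg, records = records, rois = rois,
                 q_threshold = q_threshold),
            class = "igc_result")
}
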