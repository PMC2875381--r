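#' Filter expression probes to those expressed inside ROIs
#'
#' Keeps probes whose value exceeds `floor` in at least `min_fraction` of
#' samples and whose genomic coordinates fall inside a supplied ROI
#' (any-overlap, half-open intervals).
#'
#' @param expression Wide expression tibble: `probe_id`, `chrom`, `start`,
#'   `end` (and optionally `symbol`), one column per sample. Values are log2
#'   unless `scale = "linear"`.
#' @param samples Sample sheet.
#' @param rois ROI tibble (`chrom`, `start`, `end`), e.g. from [call_rois()].
#' @param floor Expression floor on the log2 scale (default `log2(100)`, a
#'   MAS5-like "deemed expressed" cutoff).
#' @param min_fraction Minimum fraction of samples above the floor.
#' @param scale `"log2"` (default) or `"linear"` for the stored values.
#' @return The retained rows of `expression`.
#' @export
filter_expressed <- function(expression, samples, rois, floor = log2(100),
                             min_fraction = 0.25, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!all(c("chrom", "start", "end") %in% names(expression))) {
    abort("expression probes need chrom/start/end coordinates")
  }
  vals <- as.matrix(expression[samples$sample_id])
  if (scale == "linear") vals <- log2(pmax(vals, .Machine$double.eps))
  frac <- rowMeans(vals > floor)
  in_roi <- vapply(seq_len(nrow(expression)), function(i) {
    any(rois$chrom == expression$chrom[i] &
          rois$start < expression$end[i] &
          rois$end > expression$start[i])
  }, logical(1))
  expression[frac >= min_fraction & in_roi, , drop = FALSE]
}

#' SAM two-class analysis of expression
#'
#' Significance analysis of microarrays: per probe,
#' `d = (mean_met - mean_prim) / (s + s0)` with `s` the pooled-scatter
#' standard error and `s0` a fudge factor chosen by Tusher's percentile
#' search (minimizing the coefficient of variation of windowed MAD(d) across
#' the range of `s`), or fixed at `median(s)`. q-values come from group-label
#' permutations: the fraction of permuted |d| values at or above each
#' observed |d|, scaled by the permutation-estimated null proportion, and
#' monotonized. Relative expression is the ratio of unlogged
#' metastatic/primary group means.
#'
#' @param expression Wide expression tibble (log2 values), as in
#'   [filter_expressed()].
#' @param samples Sample sheet (both groups >= 2 samples).
#' @param s0_mode `"tusher"` (default) or `"median"`.
#' @param n_perm Group-label permutations (>= 10).
#' @param seed Integer seed.
#' @param s0 Explicit fudge factor, overriding `s0_mode` (e.g. 0 for the raw
#'   fold-over-scatter statistic).
#' @return List of class `sam_fit` with `records`: tibble (`probe_id`,
#'   `symbol` if present, `d`, `s`, `rel_exp`, `q`), plus `s0`, `n_perm`.
#' @export
sam_two_class <- function(expression, samples, s0_mode = c("tusher", "median"),
                          n_perm = 200, seed = NULL, s0 = NULL) {
  s0_mode <- match.arg(s0_mode)
  if (n_perm < 10) abort("n_perm must be at least 10")
  samples <- as_sample_sheet(samples)
  if (any(table(samples$group) < 2)) abort("both groups need at least 2 samples")
  x <- as.matrix(expression[samples$sample_id])
  grp2 <- samples$group == "metastatic"
  stat <- sam_stat_parts(x, grp2)
  if (is.null(s0)) {
    s0 <- if (s0_mode == "median") median(stat$s) else sam_s0_tusher(stat$diff, stat$s)
  }
  d <- stat$diff / (stat$s + s0)
  rel_exp <- rowMeans(2^x[, grp2, drop = FALSE]) / rowMeans(2^x[, !grp2, drop = FALSE])
  q <- with_seed(seed, sam_perm_q(x, grp2, s0, d, n_perm))
  records <- tibble(probe_id = expression$probe_id)
  if ("symbol" %in% names(expression)) records$symbol <- expression$symbol
  records$d <- unname(d)
  records$s <- unname(stat$s)
  records$rel_exp <- unname(rel_exp)
  records$q <- q
  structure(list(records = records, s0 = s0, n_perm = n_perm), class = "sam_fit")
}

# mean difference (group2 - group1) and pooled-scatter standard error
sam_stat_parts <- function(x, grp2) {
  n2 <- sum(grp2); n1 <- sum(!grp2)
  m2 <- rowMeans(x[, grp2, drop = FALSE]); m1 <- rowMeans(x[, !grp2, drop = FALSE])
  ss <- rowSums((x[, grp2, drop = FALSE] - m2)^2) +
    rowSums((x[, !grp2, drop = FALSE] - m1)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(diff = m2 - m1, s = s)
}

# Tusher's fudge-factor search: candidate s0 = percentiles of s; pick the one
# minimizing the CV of MAD(d) computed within 100 s-quantile windows
sam_s0_tusher <- function(diff, s, n_windows = 100) {
  if (length(s) < 2 * n_windows) return(median(s))
  cand <- quantile(s, seq(0, 1, by = 0.05), names = FALSE)
  breaks <- quantile(s, seq(0, 1, length.out = n_windows + 1), names = FALSE)
  win <- cut(s, unique(breaks), include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    v <- tapply(diff / (s + s0), win, stats::mad)
    v <- v[is.finite(v)]
    sd(v) / abs(mean(v))
  }, numeric(1))
  cand[which.min(cv)]
}

# permutation q-values on |d|: monotonized pi0-scaled exceedance ratio
sam_perm_q <- function(x, grp2, s0, d, n_perm) {
  n <- ncol(x)
  abs_obs <- abs(d)
  null_d <- numeric(0)
  for (b in seq_len(n_perm)) {
    idx <- sample(n)
    st <- sam_stat_parts(x[, idx, drop = FALSE], grp2)
    null_d <- c(null_d, abs(st$diff / (st$s + s0)))
  }
  # pi0 from the central half of the permuted |d| distribution
  q25 <- quantile(null_d, 0.25); q75 <- quantile(null_d, 0.75)
  pi0 <- min(1, mean(abs_obs >= q25 & abs_obs <= q75) / 0.5)
  m <- length(d)
  exp_false <- vapply(abs_obs, function(th) sum(null_d >= th) / n_perm, numeric(1))
  called <- vapply(abs_obs, function(th) sum(abs_obs >= th), numeric(1))
  q <- pmin(1, pi0 * exp_false / called)
  # enforce monotonicity: larger |d| never has larger q
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  q
}

#' Select candidate genes from SAM records within ROIs
#'
#' Keeps overexpressed records (`d > 0`) with `q` at or below `q_threshold`
#' and relative expression at or above `fold_threshold`, deduplicates by gene
#' symbol keeping the max-fold probe, and sorts by fold descending.
#'
#' @param records SAM record tibble (needs `symbol`, `rel_exp`, `q`; `d`
#'   optional).
#' @param fold_threshold Minimum linear fold change (default 2).
#' @param q_threshold Maximum SAM q (default 0.05).
#' @return Candidate tibble, one row per gene.
#' @export
select_candidates <- function(records, fold_threshold = 2, q_threshold = 0.05) {
  rec <- as_tibble(records)
  if (!"symbol" %in% names(rec)) abort("records must carry gene symbols")
  if ("d" %in% names(rec)) rec <- filter(rec, .data$d > 0)
  rec %>%
    filter(.data$q <= q_threshold, .data$rel_exp >= fold_threshold) %>%
    group_by(.data$symbol) %>%
    slice(which.max(.data$rel_exp)) %>%
    ungroup() %>%
    arrange(dplyr::desc(.data$rel_exp))
}
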