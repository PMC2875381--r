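#' Copy-number state thresholds
#'
#' The study's calling scheme: gain/loss at +/-0.15 log2 (about six standard
#' deviations of the middle 75% of centered data on this platform),
#' amplification/deletion at +/-0.4, extreme events at +/-1.0, and MCRs capped
#' below 2 Mb.
#'
#' @param gain,loss,amp,del,extreme Log2-ratio cutoffs (boundaries inclusive).
#' @param max_mcr_width Maximum MCR width in bp.
#' @return Named list of class `cna_thresholds`.
#' @export
cna_thresholds <- function(gain = 0.15, loss = -0.15, amp = 0.4, del = -0.4,
                           extreme = 1.0, max_mcr_width = 2e6) {
  if (!(loss < 0 && 0 < gain)) abort("need loss < 0 < gain")
  if (!(del < loss && amp > gain && extreme > amp)) {
    abort("need del < loss, amp > gain, extreme > amp")
  }
  structure(list(gain = gain, loss = loss, amp = amp, del = del,
                 extreme = extreme, max_mcr_width = max_mcr_width),
            class = "cna_thresholds")
}

#' Center segmented profiles on their tallest mode
#'
#' Shifts each sample so the tallest mode of its per-probe distribution of
#' segment values (each segment weighted by its probe count) sits at log2 = 0
#' -- the modal state is assumed diploid. The mode is located on a fixed
#' histogram with 0.01-log2 bins centered on multiples of 0.01, ties broken
#' toward the bin nearest 0; since every shift is a grid multiple the
#' operation is exactly idempotent.
#'
#' @param seg Segment tibble from [cbs_segment()].
#' @param per_sample Center each sample separately (default) or apply one
#'   global shift from the pooled distribution.
#' @param bin Histogram bin width in log2 units.
#' @return Segment tibble with shifted `seg_mean`.
#' @export
mode_center <- function(seg, per_sample = TRUE, bin = 0.01) {
  shift_of <- function(values, weights) {
    if (length(values) == 0 || all(is.na(values))) {
      abort("cannot mode-center an all-missing profile")
    }
    centers <- round(values / bin) * bin
    tab <- tapply(weights, centers, sum)
    loc <- as.numeric(names(tab))
    best <- which(tab == max(tab))
    # ties: prefer the mode nearest 0 (then the lower value)
    best <- best[order(abs(loc[best]), loc[best])][1]
    loc[best]
  }
  if (per_sample) {
    seg %>%
      group_by(.data$sample_id) %>%
      mutate(seg_mean = .data$seg_mean - shift_of(.data$seg_mean, .data$n_probes)) %>%
      ungroup()
  } else {
    mutate(seg, seg_mean = .data$seg_mean - shift_of(seg$seg_mean, seg$n_probes))
  }
}

#' Derive gain/loss thresholds from centered data
#'
#' Gain/loss cutoffs are set to +/- six standard deviations of the middle 75%
#' of the centered per-probe values (those between the 12.5th and 87.5th
#' percentiles). Amplification/deletion stay at the fixed +/-0.4, and a
#' degenerate (zero-variance) input falls back to the fixed defaults with a
#' warning.
#'
#' @param values Centered per-probe log2 values (>= 1000 unless `fixed`).
#' @param fixed If `TRUE`, skip derivation and return [cna_thresholds()]
#'   defaults (+/-0.15, +/-0.4).
#' @param n_sd Multiplier on the trimmed SD.
#' @return A `cna_thresholds` object.
#' @export
derive_thresholds <- function(values, fixed = FALSE, n_sd = 6) {
  if (fixed) return(cna_thresholds())
  values <- values[!is.na(values)]
  if (length(values) < 1000) abort("need at least 1000 values to derive thresholds")
  qs <- quantile(values, c(0.125, 0.875), names = FALSE, type = 7)
  mid <- values[values >= qs[1] & values <= qs[2]]
  s <- sd(mid)
  if (!is.finite(s) || s == 0) {
    warn("zero-variance input: falling back to fixed thresholds")
    return(cna_thresholds())
  }
  cna_thresholds(gain = n_sd * s, loss = -n_sd * s)
}

#' Call the copy-number state of segment values
#'
#' Boundaries are inclusive, and the extreme states imply the milder ones:
#' an amplification is also a gain, a deletion also a loss (see
#' [state_direction()]).
#'
#' @param value Numeric vector of (centered) segment log2 values.
#' @param thresholds A [cna_thresholds()].
#' @return Character vector in
#'   `{"deletion", "loss", "neutral", "gain", "amplification"}`.
#' @export
call_state <- function(value, thresholds = cna_thresholds()) {
  case_when(
    value >= thresholds$amp ~ "amplification",
    value >= thresholds$gain ~ "gain",
    value <= thresholds$del ~ "deletion",
    value <= thresholds$loss ~ "loss",
    TRUE ~ "neutral"
  )
}

#' Collapse copy-number states to gain/loss/neutral direction
#'
#' @param state Output of [call_state()].
#' @return Character vector in `{"gain", "loss", "neutral"}`.
#' @export
state_direction <- function(state) {
  case_when(
    state %in% c("gain", "amplification") ~ "gain",
    state %in% c("loss", "deletion") ~ "loss",
    TRUE ~ "neutral"
  )
}

#' Compare genome instability between cohorts by breakpoint counts
#'
#' A sample's instability score is its number of copy-number transitions whose
#' flanking segments include at least one altered segment (|log2| at or above
#' the gain threshold). Scores are compared between the two cohorts with a
#' Welch two-sample t test.
#'
#' @param seg Segment tibble.
#' @param samples Sample sheet (both groups need >= 2 samples).
#' @param thresholds A [cna_thresholds()].
#' @return List of class `instability_result`: `counts` tibble (per-sample
#'   breakpoint count), `t`, `p`, `degenerate` flag (zero variance in both
#'   groups, `p` reported as 1).
#' @export
instability_test <- function(seg, samples, thresholds = cna_thresholds()) {
  samples <- as_sample_sheet(samples)
  sizes <- table(samples$group)
  if (any(sizes < 2)) abort("both cohorts need at least 2 samples for the t test")
  counts <- seg %>%
    arrange(.data$sample_id, .data$chrom, .data$start) %>%
    group_by(.data$sample_id, .data$chrom) %>%
    summarise(breaks = sum(pmax(abs(.data$seg_mean[-1]),
                                abs(.data$seg_mean[-n()])) >= thresholds$gain),
              .groups = "drop") %>%
    group_by(.data$sample_id) %>%
    summarise(n_breakpoints = sum(.data$breaks), .groups = "drop") %>%
    right_join(samples, by = "sample_id") %>%
    mutate(n_breakpoints = dplyr::coalesce(.data$n_breakpoints, 0L))
  x <- counts$n_breakpoints[counts$group == "metastatic"]
  y <- counts$n_breakpoints[counts$group == "primary"]
  if (sd(x) == 0 && sd(y) == 0) {
    res <- list(counts = counts, t = if (mean(x) == mean(y)) 0 else NA_real_,
                p = 1, degenerate = TRUE)
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
    res <- list(counts = counts, t = unname(tt$statistic), p = tt$p.value,
                degenerate = FALSE)
  }
  structure(res, class = "instability_result")
}
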