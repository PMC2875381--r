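#' Segment raw log2-ratio profiles by circular binary segmentation
#'
#' Classic change-point detection for aCGH: each chromosome is treated as a
#' circle and recursively split at the arc whose two-sample t statistic
#' against its complement is maximal, a split being accepted when its
#' permutation p-value is at most `alpha`. Each final segment is assigned the
#' median of the log2 ratios of its spanned probes. Missing probe values are
#' imputed from flanking probes first.
#'
#' @param profiles Wide profile tibble (`probe_id`, `chrom`, `pos`, one column
#'   per sample).
#' @param samples Sample sheet (`sample_id`, `group`).
#' @param alpha Significance level for accepting a split.
#' @param n_perm Permutations per split test (>= 100); early-stopped once a
#'   split can no longer be accepted.
#' @param min_width Minimum probes per segment.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Segment tibble (`sample_id`, `chrom`, `start`, `end`, `n_probes`,
#'   `seg_mean`); segments partition each sample's probes, with half-open bp
#'   bounds running from a segment's first probe to the next segment's first
#'   probe (last probe position + 1 at a chromosome end).
#' @export
cbs_segment <- function(profiles, samples, alpha = 0.01, n_perm = 1000,
                        min_width = 2, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_perm < 100) abort("n_perm must be at least 100")
  samples <- as_sample_sheet(samples)
  profiles <- impute_missing(profiles, samples)
  max_exceed <- floor(alpha * (n_perm + 1)) - 1
  with_seed(seed, {
    res <- purrr::map_dfr(samples$sample_id, function(sid) {
      purrr::map_dfr(unique(profiles$chrom), function(chr) {
        sel <- profiles$chrom == chr
        x <- profiles[[sid]][sel]
        pos <- profiles$pos[sel]
        cuts <- cbs_find_cuts(x, min_width, n_perm, max_exceed)
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, length(x))
        tibble(
          sample_id = sid, chrom = chr,
          start = pos[starts],
          end = c(pos[starts[-1]], pos[length(x)] + 1),
          n_probes = ends - starts + 1L,
          seg_mean = purrr::map2_dbl(starts, ends, ~ median(x[.x:.y]))
        )
      })
    })
    arrange(res, .data$sample_id, .data$chrom, .data$start)
  })
}

# recursive CBS on one chromosome; returns sorted interior cut indices
# (a cut after probe k separates probes 1..k from k+1..)
cbs_find_cuts <- function(x, min_width, n_perm, max_exceed) {
  n <- length(x)
  cuts <- integer(0)
  if (n < 2) return(cuts)
  rec <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return(invisible(NULL))
    xs <- x[lo:hi]
    best <- cpp_max_arc_t(xs, as.integer(min_width))
    if (best[3] <= 0) return(invisible(NULL))
    exceed <- cpp_perm_exceed(xs, as.integer(min_width), best[3],
                              as.integer(n_perm), as.integer(max_exceed))
    if (exceed > max_exceed) return(invisible(NULL))
    new_cuts <- setdiff(unique(c(best[1], best[2])), c(0, m)) + lo - 1L
    cuts <<- c(cuts, as.integer(new_cuts))
    bounds <- c(lo - 1L, sort(as.integer(new_cuts)), hi)
    for (b in seq_len(length(bounds) - 1L)) rec(bounds[b] + 1L, bounds[b + 1L])
    invisible(NULL)
  }
  rec(1L, n)
  sort(cuts)
}

#' Expand segments back to a probe-level value matrix
#'
#' @param seg Segment tibble.
#' @param samples Sample sheet.
#' @param map Genome map shared by all samples.
#' @return Numeric matrix probes x samples of segment values.
#' @export
seg_to_probe_matrix <- function(seg, samples, map) {
  out <- matrix(NA_real_, nrow(map), nrow(samples),
                dimnames = list(map$probe_id, samples$sample_id))
  for (sid in samples$sample_id) {
    s <- seg[seg$sample_id == sid, ]
    for (r in seq_len(nrow(s))) {
      idx <- which(map$chrom == s$chrom[r] & map$pos >= s$start[r] & map$pos < s$end[r])
      out[idx, sid] <- s$seg_mean[r]
    }
  }
  if (anyNA(out)) abort("segments do not cover every probe of the map")
  out
}
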