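#' Extract per-sample copy-number aberration intervals
#'
#' Maximal runs of consecutive same-direction altered segments (gain at or
#' above the gain threshold, loss at or below the loss threshold; a neutral
#' segment breaks a run) are merged into one interval per run, keeping the
#' most extreme segment value as the interval's peak.
#'
#' @param seg Centered segment tibble.
#' @param thresholds A [cna_thresholds()].
#' @return Tibble (`sample_id`, `chrom`, `start`, `end`, `direction`, `peak`).
#' @export
extract_cnas <- function(seg, thresholds = cna_thresholds()) {
  altered <- seg %>%
    arrange(.data$sample_id, .data$chrom, .data$start) %>%
    mutate(direction = state_direction(call_state(.data$seg_mean, thresholds))) %>%
    filter(.data$direction != "neutral")
  if (nrow(altered) == 0) {
    return(tibble(sample_id = character(), chrom = integer(), direction = character(),
                  start = numeric(), end = numeric(), peak = numeric()))
  }
  altered %>%
    group_by(.data$sample_id, .data$chrom) %>%
    # a new run starts where the previous altered segment is not adjacent
    # (bp gap) or has the other direction
    mutate(run = cumsum(.data$direction != lag(.data$direction, default = "") |
                          .data$start != lag(.data$end, default = -1))) %>%
    group_by(.data$sample_id, .data$chrom, .data$direction, .data$run) %>%
    summarise(start = first(.data$start), end = last(.data$end),
              peak = .data$seg_mean[which.max(abs(.data$seg_mean))],
              .groups = "drop") %>%
    select(-"run") %>%
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Call minimal common regions of amplification and deletion
#'
#' Per direction, per-probe recurrence (number of samples whose CNA intervals
#' cover the probe) is computed; candidate regions are maximal probe runs with
#' recurrence at or above `min_recurrence`, and the MCR is the
#' maximal-recurrence plateau within a candidate (every contiguous plateau of
#' probes attaining the candidate's recurrence maximum becomes its own MCR).
#' Bounds are half-open, running from the first plateau probe to the next
#' probe beyond it. High-confidence filtering keeps MCRs that contain an
#' extreme event (some sample's probe at |log2| >= `extreme`, in direction)
#' and are narrower than `max_width`.
#'
#' @param cnas CNA intervals from [extract_cnas()].
#' @param seg Centered segment tibble (for per-probe sample values).
#' @param samples Sample sheet.
#' @param map Genome map.
#' @param thresholds A [cna_thresholds()].
#' @param min_recurrence Minimum number of samples sharing the region.
#' @param mode `"plateau"` (minimal regions, default) or `"envelope"` (the
#'   whole recurrence >= `min_recurrence` run).
#' @return Tibble (`chrom`, `start`, `end`, `width`, `direction`, `peak`,
#'   `n_tumors`), sorted by direction then genome order.
#' @export
call_mcrs <- function(cnas, seg, samples, map,
                      thresholds = cna_thresholds(), min_recurrence = 2,
                      mode = c("plateau", "envelope")) {
  mode <- match.arg(mode)
  if (nrow(cnas) == 0) {
    return(tibble(chrom = integer(), start = numeric(), end = numeric(),
                  width = numeric(), direction = character(), peak = numeric(),
                  n_tumors = integer()))
  }
  empty <- tibble(chrom = integer(), start = numeric(), end = numeric(),
                  width = numeric(), direction = character(), peak = numeric(),
                  n_tumors = integer())
  values <- seg_to_probe_matrix(seg, samples, map)
  raw <- purrr::map_dfr(c("gain", "loss"), function(dir) {
    iv <- cnas[cnas$direction == dir, ]
    if (nrow(iv) == 0) return(NULL)
    rec <- integer(nrow(map))
    for (r in seq_len(nrow(iv))) {
      idx <- which(map$chrom == iv$chrom[r] & map$pos >= iv$start[r] & map$pos < iv$end[r])
      rec[idx] <- rec[idx] + 1L
    }
    purrr::map_dfr(unique(map$chrom), function(chr) {
      sel <- which(map$chrom == chr)
      r <- rec[sel]
      cand <- probe_runs(r >= min_recurrence)
      purrr::map_dfr(seq_len(nrow(cand)), function(ci) {
        lo <- cand$from[ci]; hi <- cand$to[ci]
        peak_rec <- max(r[lo:hi])
        plateaus <- if (mode == "plateau") {
          pr <- probe_runs(seq_along(r) >= lo & seq_along(r) <= hi & r == peak_rec)
          pr
        } else {
          tibble(from = lo, to = hi)
        }
        purrr::map_dfr(seq_len(nrow(plateaus)), function(pi) {
          a <- sel[plateaus$from[pi]]; b <- sel[plateaus$to[pi]]
          nxt <- if (b < max(sel)) map$pos[b + 1L] else map$pos[b] + 1
          vals <- values[a:b, , drop = FALSE]
          peak <- if (dir == "gain") max(vals) else min(vals)
          tibble(chrom = chr, start = map$pos[a], end = nxt,
                 width = nxt - map$pos[a], direction = dir,
                 peak = peak, n_tumors = peak_rec)
        })
      })
    })
  })
  if (nrow(raw) == 0) return(empty)
  raw %>%
    filter((.data$direction == "gain" & .data$peak >= thresholds$extreme) |
             (.data$direction == "loss" & .data$peak <= -thresholds$extreme),
           .data$width < thresholds$max_mcr_width) %>%
    arrange(.data$direction, .data$chrom, .data$start)
}

# maximal runs of TRUE in a logical vector, as (from, to) index pairs
probe_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(from = starts[r$values], to = ends[r$values])
}

#' Annotate intervals with resident gene symbols
#'
#' A gene belongs to an interval when it overlaps it by at least one bp
#' (half-open intervals on both sides).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (e.g. MCRs or ROIs).
#' @param genes Gene annotation from [gene_annotation()].
#' @return `intervals` with list-column `gene_symbols` (deduplicated, sorted)
#'   and integer `n_genes`.
#' @export
annotate_genes <- function(intervals, genes) {
  hits <- purrr::map(seq_len(nrow(intervals)), function(i) {
    g <- genes[genes$chrom == intervals$chrom[i] &
                 genes$start < intervals$end[i] &
                 genes$end > intervals$start[i], ]
    sort(unique(g$symbol))
  })
  intervals$gene_symbols <- hits
  intervals$n_genes <- lengths(hits)
  intervals
}
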