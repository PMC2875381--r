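#' Read a SEG file of per-sample copy-number segments
#'
#' SEG is the community tab-delimited format for segmented aCGH/log2-ratio
#' profiles: one row per segment with columns `Sample`, `Chromosome`, `Start`,
#' `End`, `Num_Probes`, `Seg_Mean`. Intervals are half-open `[start, end)`.
#'
#' @param path Path to a SEG file (or a connection / literal text).
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `seg_mean`, grouped-sorted by sample then genome order.
#' @export
read_seg <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("sample", "chromosome", "start", "end", "num_probes", "seg_mean")
  if (!all(need %in% names(raw))) {
    abort(paste("SEG header must contain:", paste(need, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(sample_id = character(), chrom = integer(), start = numeric(),
                  end = numeric(), n_probes = integer(), seg_mean = numeric()))
  }
  mean_num <- suppressWarnings(as.numeric(raw$seg_mean))
  if (anyNA(mean_num)) {
    abort(sprintf("non-numeric seg_mean at line %d", which(is.na(mean_num))[1] + 1L))
  }
  seg <- tibble(
    sample_id = raw$sample,
    chrom = as.integer(raw$chromosome),
    start = as.numeric(raw$start),
    end = as.numeric(raw$end),
    n_probes = as.integer(raw$num_probes),
    seg_mean = mean_num
  )
  bad <- which(seg$start >= seg$end)
  if (length(bad)) abort(sprintf("segment with start >= end at line %d", bad[1] + 1L))
  seg <- arrange(seg, .data$sample_id, .data$chrom, .data$start)
  ovl <- seg %>%
    group_by(.data$sample_id, .data$chrom) %>%
    summarise(bad = any(.data$start < lag(.data$end, default = -Inf)), .groups = "drop")
  if (any(ovl$bad)) {
    o <- ovl[ovl$bad, ][1, ]
    abort(sprintf("overlapping segments for sample %s chromosome %d", o$sample_id, o$chrom))
  }
  seg
}

#' Write segments to a SEG file
#'
#' Round-trips losslessly through [read_seg()] for means printed at four
#' decimal places (the writer prints full precision).
#'
#' @param seg Segment tibble as returned by [read_seg()] or [cbs_segment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  out <- tibble(
    Sample = seg$sample_id, Chromosome = seg$chrom,
    Start = format(seg$start, scientific = FALSE, trim = TRUE),
    End = format(seg$end, scientific = FALSE, trim = TRUE),
    Num_Probes = seg$n_probes,
    Seg_Mean = format(seg$seg_mean, scientific = FALSE, trim = TRUE, digits = 15)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Emits 0-based half-open BED4+score lines (`chrom`, `start`, `end`, `name`,
#' `score`), sorted by `(chrom, start)`; interval width is `end - start`.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @param path Output path.
#' @param track Track comment line written first.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, track = "igcomp intervals") {
  if (nrow(intervals) > 0 && any(intervals$start < 0 | intervals$end < 0)) {
    abort("BED coordinates must be non-negative")
  }
  lines <- sprintf("# track name=\"%s\"", track)
  if (nrow(intervals) > 0) {
    iv <- arrange(as_tibble(intervals), .data$chrom, .data$start)
    nm <- if ("name" %in% names(iv)) iv$name else sprintf("iv_%d", seq_len(nrow(iv)))
    sc <- if ("score" %in% names(iv)) iv$score else 0
    lines <- c(lines, sprintf("chr%s\t%s\t%s\t%s\t%s", iv$chrom,
                              format(iv$start, scientific = FALSE, trim = TRUE),
                              format(iv$end, scientific = FALSE, trim = TRUE), nm,
                              format(sc, trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column sample sheet
#'
#' @param path TSV with columns `sample_id` and `group`; group must be
#'   `primary` or `metastatic`.
#' @return Tibble with `sample_id` (character) and `group` (factor).
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  as_sample_sheet(s)
}

as_sample_sheet <- function(samples) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(samples))) abort("sample sheet needs sample_id and group")
  s <- as_tibble(samples)[need]
  if (!all(s$group %in% c("primary", "metastatic"))) {
    abort("group must be 'primary' or 'metastatic'")
  }
  if (anyDuplicated(s$sample_id)) abort("sample_ids must be unique")
  s$group <- factor(s$group, levels = c("primary", "metastatic"))
  s
}

#' Read a YAML analysis configuration
#'
#' Unknown keys are rejected so typos fail loudly; missing keys take the
#' package defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    alpha = 0.01, n_perm = 1000, min_width = 2,
    derive_thresholds = FALSE, q_threshold = 0.1,
    fold_threshold = 2, sam_q_threshold = 0.05,
    min_recurrence = 2, extreme = 1.0, max_mcr_width = 2e6,
    seed = 1L
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, user)
}

#' Start a line-oriented run log
#'
#' Writes a header recording the time, package version and seed so any
#' randomized run is reproducible from its log.
#'
#' @param path Log file path.
#' @param seed Integer seed recorded in the header.
#' @return A function `log(msg)` appending timestamped lines.
#' @export
open_run_log <- function(path, seed = NA_integer_) {
  writeLines(c(
    sprintf("# igcomp %s", as.character(utils::packageVersion("igcomp"))),
    sprintf("# started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("# seed %s", seed)
  ), path)
  function(msg) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
                    file = path, append = TRUE)
}
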