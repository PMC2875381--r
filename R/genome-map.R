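#' Construct and validate a probe genome map
#'
#' A genome map is the ordered probe scaffold every profile in a cohort shares:
#' one row per array probe with its autosomal chromosome (1-22) and basepair
#' position. All coordinates in the package are half-open `[start, end)` and
#' widths are always `end - start`.
#'
#' @param probes A data frame with columns `probe_id`, `chrom`, `pos`.
#'   Rows on sex chromosomes (X/Y/23/24) are dropped with a warning; everything
#'   else must be an autosome 1-22.
#' @return A tibble with columns `probe_id` (character), `chrom` (integer),
#'   `pos` (double), sorted by `(chrom, pos)`.
#' @export
as_genome_map <- function(probes) {
  stopifnot(is.data.frame(probes))
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(probes))) {
    abort(paste("genome map needs columns:", paste(need, collapse = ", ")))
  }
  map <- as_tibble(probes)[need]
  sex <- map$chrom %in% c("X", "Y", "x", "y", "23", "24", 23, 24)
  if (any(sex)) {
    warn(sprintf("dropping %d probe(s) on sex chromosomes; only autosomes 1-22 are analysed", sum(sex)))
    map <- map[!sex, , drop = FALSE]
  }
  map$probe_id <- as.character(map$probe_id)
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (any(is.na(map$chrom)) || any(map$chrom < 1L | map$chrom > 22L)) {
    abort("chromosomes must be autosomes 1-22")
  }
  if (anyDuplicated(map$probe_id)) abort("probe_ids must be unique")
  map <- arrange(map, .data$chrom, .data$pos)
  dup <- unlist(tapply(map$pos, map$chrom, function(p) c(FALSE, diff(p) <= 0)), use.names = FALSE)
  if (any(dup)) abort("probe positions must be strictly increasing within a chromosome")
  map
}

#' Construct and validate a gene annotation table
#'
#' @param genes A data frame with columns `symbol`, `chrom`, `start`, `end`
#'   (half-open intervals, `start < end`).
#' @return A tibble sorted by `(chrom, start)`.
#' @export
gene_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("symbol", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    abort(paste("gene annotation needs columns:", paste(need, collapse = ", ")))
  }
  g <- as_tibble(genes)[need]
  g$symbol <- as.character(g$symbol)
  g$chrom <- as.integer(g$chrom)
  if (any(g$start >= g$end)) abort("gene intervals must satisfy start < end")
  arrange(g, .data$chrom, .data$start)
}

# probe-level value matrix (probes x samples) from a wide profile tibble
profile_matrix <- function(profiles, samples) {
  miss <- setdiff(samples$sample_id, names(profiles))
  if (length(miss)) abort(paste("profiles missing sample columns:", paste(miss, collapse = ", ")))
  m <- as.matrix(profiles[samples$sample_id])
  rownames(m) <- profiles$probe_id
  storage.mode(m) <- "double"
  m
}

#' Impute missing probe values from flanking probes
#'
#' Missing log2 ratios are filled with the midpoint of the two nearest
#' non-missing probes on the same chromosome (one-sided at chromosome ends).
#' A chromosome that is entirely missing for a sample is an error.
#'
#' @param profiles Wide profile tibble (`probe_id`, `chrom`, `pos`, one column
#'   per sample).
#' @param samples Sample sheet tibble (`sample_id`, `group`).
#' @return `profiles` with missing values imputed.
#' @export
impute_missing <- function(profiles, samples) {
  for (sid in samples$sample_id) {
    x <- profiles[[sid]]
    if (!anyNA(x)) next
    for (chr in unique(profiles$chrom[is.na(x)])) {
      idx <- which(profiles$chrom == chr)
      v <- x[idx]
      if (all(is.na(v))) abort(sprintf("sample %s: chromosome %s entirely missing", sid, chr))
      ok <- which(!is.na(v))
      for (i in which(is.na(v))) {
        lo <- ok[ok < i]; hi <- ok[ok > i]
        flank <- c(if (length(lo)) v[max(lo)], if (length(hi)) v[min(hi)])
        v[i] <- median(flank)
      }
      x[idx] <- v
    }
    profiles[[sid]] <- x
  }
  profiles
}
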