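#' Define a planted copy-number event
#'
#' Truth-model building block for the synthetic cohorts: a genomic interval
#' carried independently (Bernoulli) by each sample at its cohort's frequency,
#' adding `amplitude` log2 units to every probe it covers. Overlapping events
#' sum in log2 space, so the noiseless signal is always exactly reconstructible
#' from the truth table.
#'
#' @param chrom Chromosome (1-22).
#' @param start,end Half-open interval in bp.
#' @param amplitude Log2-ratio shift; sign must match `direction`.
#' @param direction `"gain"` or `"loss"`.
#' @param frequency_primary,frequency_metastatic Carriage probability per
#'   sample in each cohort, in `[0, 1]`.
#' @return One-row tibble describing the event.
#' @export
planted_event <- function(chrom, start, end, amplitude,
                          direction = if (amplitude >= 0) "gain" else "loss",
                          frequency_primary = 0, frequency_metastatic = 0) {
  stopifnot(start < end, direction %in% c("gain", "loss"))
  if ((direction == "gain") != (amplitude >= 0)) {
    abort("amplitude sign inconsistent with direction")
  }
  if (frequency_primary < 0 || frequency_primary > 1 ||
      frequency_metastatic < 0 || frequency_metastatic > 1) {
    abort("frequencies must be in [0, 1]")
  }
  tibble(chrom = as.integer(chrom), start = as.numeric(start), end = as.numeric(end),
         amplitude = amplitude, direction = direction,
         frequency_primary = frequency_primary,
         frequency_metastatic = frequency_metastatic)
}

#' Configuration for the synthetic two-cohort simulator
#'
#' Defaults mirror the melanoma study design the package targets: 25 primary
#' and 61 metastatic samples profiled on ~16,097 probes over autosomes 1-22
#' with a median inter-probe spacing of 54.8 kb, probe noise of 0.12 log2
#' units, and cis-dosage-driven expression for resident genes.
#'
#' @param n_primary,n_metastatic Cohort sizes.
#' @param n_probes Total probes over chromosomes 1-22 (>= 22).
#' @param probe_spacing_bp Median inter-probe gap in bp (exponential gaps).
#' @param noise_sd Gaussian probe noise, log2 units.
#' @param planted_events Tibble of [planted_event()] rows (may be empty).
#' @param n_genes Genes tiled over the simulated map.
#' @param dosage_slope Expression-log2 added per copy-number log2 unit.
#' @param expression_baseline Baseline log2 expression of every gene.
#' @param expression_noise_sd Gaussian expression noise, log2 units.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_primary = 25, n_metastatic = 61,
                       n_probes = 16097, probe_spacing_bp = 54800,
                       noise_sd = 0.12, planted_events = NULL,
                       n_genes = 400, dosage_slope = 1,
                       expression_baseline = 8, expression_noise_sd = 0.25,
                       seed = 1L) {
  if (n_primary < 1 || n_metastatic < 1) abort("cohort sizes must be positive")
  if (n_probes < 22) abort("need at least one probe per chromosome (n_probes >= 22)")
  if (probe_spacing_bp <= 0) abort("probe spacing must be positive")
  if (noise_sd < 0 || expression_noise_sd < 0) abort("noise_sd must be >= 0")
  if (is.null(planted_events)) {
    planted_events <- planted_event(1, 1, 2, 0)[0, ]
  }
  structure(list(
    n_primary = n_primary, n_metastatic = n_metastatic, n_probes = n_probes,
    probe_spacing_bp = probe_spacing_bp, noise_sd = noise_sd,
    planted_events = as_tibble(planted_events), n_genes = n_genes,
    dosage_slope = dosage_slope, expression_baseline = expression_baseline,
    expression_noise_sd = expression_noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a probe genome map and gene annotation
#'
#' Probes are spread over 22 autosomes (near-equal counts; exactly one per
#' chromosome when `n_probes = 22`) with inter-probe gaps drawn from an
#' exponential distribution whose median is `probe_spacing_bp`. Genes are
#' tiled at evenly spaced anchor probes, 20 kb wide, never straddling a
#' chromosome boundary.
#'
#' @param config A [sim_config()].
#' @return List with `map` (genome map tibble) and `genes`
#'   (gene annotation tibble).
#' @export
simulate_genome_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n_chr <- 22L
    base <- config$n_probes %/% n_chr
    extra <- config$n_probes %% n_chr
    counts <- rep(base, n_chr) + c(rep(1L, extra), rep(0L, n_chr - extra))
    rate <- log(2) / config$probe_spacing_bp
    map <- purrr::map_dfr(seq_len(n_chr), function(chr) {
      gaps <- pmax(1, round(rexp(counts[chr], rate)))
      tibble(chrom = chr, pos = cumsum(gaps))
    })
    map$probe_id <- sprintf("P%05d", seq_len(nrow(map)))
    map <- as_genome_map(map)

    per_chr <- pmax(0L, round(config$n_genes * counts / sum(counts)))
    genes <- purrr::map_dfr(seq_len(n_chr), function(chr) {
      ng <- per_chr[chr]
      if (ng == 0) return(NULL)
      pos <- map$pos[map$chrom == chr]
      anchors <- pos[unique(pmax(1L, round(seq(1, length(pos), length.out = ng))))]
      tibble(chrom = chr, start = pmax(1, anchors - 10000), end = anchors + 10000)
    })
    genes$symbol <- sprintf("GENE%04d", seq_len(nrow(genes)))
    list(map = map, genes = gene_annotation(genes))
  })
}

#' Simulate two-cohort aCGH profiles with a truth table
#'
#' Each sample's probe value is the sum of the amplitudes of the planted
#' events it carries (Bernoulli carriage at its cohort's frequency) plus
#' Gaussian noise. The returned truth table records every realized
#' sample-event carriage so noiseless profiles are exactly reconstructible.
#'
#' @param config A [sim_config()].
#' @return List of class `igc_sim`: `map`, `genes`, `profiles` (wide tibble:
#'   `probe_id`, `chrom`, `pos`, one column per sample), `samples` (sample
#'   sheet), `truth` (per sample x event carriage), `events`, `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geo <- simulate_genome_map(config)
  map <- geo$map
  ev <- config$planted_events
  if (nrow(ev)) {
    span <- map %>% group_by(.data$chrom) %>%
      summarise(lo = min(.data$pos), hi = max(.data$pos), .groups = "drop")
    chk <- left_join(ev, span, by = "chrom")
    if (any(is.na(chk$lo)) || any(chk$end <= chk$lo) || any(chk$start > chk$hi)) {
      abort("planted event lies outside the simulated genome map")
    }
  }
  samples <- tibble(
    sample_id = c(sprintf("P%02d", seq_len(config$n_primary)),
                  sprintf("M%02d", seq_len(config$n_metastatic))),
    group = c(rep("primary", config$n_primary), rep("metastatic", config$n_metastatic))
  ) %>% as_sample_sheet()

  with_seed(derive_seed(config$seed, 2L), {
    n_s <- nrow(samples)
    carried <- if (nrow(ev)) {
      freq <- if_else(samples$group[rep(seq_len(n_s), each = nrow(ev))] == "primary",
                      rep(ev$frequency_primary, n_s), rep(ev$frequency_metastatic, n_s))
      matrix(rbinom(nrow(ev) * n_s, 1, freq) == 1, nrow = nrow(ev))
    } else {
      matrix(logical(0), nrow = 0, ncol = n_s)
    }
    signal <- matrix(0, nrow(map), n_s)
    if (nrow(ev)) {
      for (e in seq_len(nrow(ev))) {
        idx <- which(map$chrom == ev$chrom[e] & map$pos >= ev$start[e] & map$pos < ev$end[e])
        if (length(idx)) {
          signal[idx, carried[e, ]] <- signal[idx, carried[e, ], drop = FALSE] + ev$amplitude[e]
        }
      }
    }
    noise <- if (config$noise_sd > 0) {
      matrix(rnorm(length(signal), 0, config$noise_sd), nrow(map), n_s)
    } else 0
    values <- signal + noise
    profiles <- map
    profiles[samples$sample_id] <- as.data.frame(values)
    truth <- if (nrow(ev)) {
      # event index varies fastest, matching the column-major carriage matrix
      tidyr::expand_grid(sample_id = samples$sample_id, event_id = seq_len(nrow(ev))) %>%
        mutate(carried = as.vector(carried)) %>%
        left_join(mutate(ev, event_id = seq_len(nrow(ev))), by = "event_id") %>%
        filter(.data$carried) %>%
        select("sample_id", "event_id", "chrom", "start", "end", "amplitude", "direction")
    } else {
      tibble(sample_id = character(), event_id = integer(), chrom = integer(),
             start = numeric(), end = numeric(), amplitude = numeric(),
             direction = character())
    }
    structure(list(map = map, genes = geo$genes, profiles = profiles,
                   samples = samples, truth = truth, events = ev, config = config),
              class = "igc_sim")
  })
}

#' Simulate a dosage-driven expression matrix
#'
#' Gene expression (log2) is `baseline + dosage_slope * copy` where `copy` is
#' the sample's planted copy-number log2 at the gene midpoint, plus Gaussian
#' noise. The truth list flags genes whose realized (noise-free)
#' metastatic/primary linear fold reaches 2.
#'
#' @param sim An `igc_sim` from [simulate_cohorts()].
#' @param config Defaults to `sim$config`.
#' @return List with `expression` (wide tibble: `probe_id`, `symbol`, `chrom`,
#'   `start`, `end`, one log2 column per sample) and `truth_genes` (per gene
#'   realized linear fold and `dosage_driven` flag for fold >= 2).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "igc_sim"))
  genes <- sim$genes
  if (nrow(genes) == 0) abort("no annotated gene coordinates to simulate expression for")
  samples <- sim$samples
  with_seed(derive_seed(config$seed, 3L), {
    mid <- (genes$start + genes$end) / 2
    copy <- matrix(0, nrow(genes), nrow(samples),
                   dimnames = list(genes$symbol, samples$sample_id))
    if (nrow(sim$truth)) {
      for (r in seq_len(nrow(sim$truth))) {
        g <- which(genes$chrom == sim$truth$chrom[r] &
                     mid >= sim$truth$start[r] & mid < sim$truth$end[r])
        if (length(g)) {
          copy[g, sim$truth$sample_id[r]] <- copy[g, sim$truth$sample_id[r]] +
            sim$truth$amplitude[r]
        }
      }
    }
    clean <- config$expression_baseline + config$dosage_slope * copy
    noise <- if (config$expression_noise_sd > 0) {
      matrix(rnorm(length(clean), 0, config$expression_noise_sd), nrow(clean), ncol(clean))
    } else 0
    expr_mat <- clean + noise
    is_met <- samples$group == "metastatic"
    fold <- rowMeans(2^clean[, is_met, drop = FALSE]) /
      rowMeans(2^clean[, !is_met, drop = FALSE])
    expression <- tibble(probe_id = paste0("x_", genes$symbol), symbol = genes$symbol,
                         chrom = genes$chrom, start = genes$start, end = genes$end)
    expression[samples$sample_id] <- as.data.frame(expr_mat)
    truth_genes <- tibble(symbol = genes$symbol, realized_fold = unname(fold),
                          dosage_driven = unname(fold) >= 2)
    list(expression = expression, truth_genes = truth_genes)
  })
}

#' Reconstruct noiseless profiles from a truth table
#'
#' Sums planted amplitudes per probe per sample; with `noise_sd = 0` this
#' reproduces [simulate_cohorts()] output exactly.
#'
#' @param sim An `igc_sim`.
#' @return Matrix probes x samples of planted signal.
#' @export
truth_signal <- function(sim) {
  out <- matrix(0, nrow(sim$map), nrow(sim$samples),
                dimnames = list(sim$map$probe_id, sim$samples$sample_id))
  if (nrow(sim$truth)) {
    for (r in seq_len(nrow(sim$truth))) {
      idx <- which(sim$map$chrom == sim$truth$chrom[r] &
                     sim$map$pos >= sim$truth$start[r] & sim$map$pos < sim$truth$end[r])
      out[idx, sim$truth$sample_id[r]] <- out[idx, sim$truth$sample_id[r]] +
        sim$truth$amplitude[r]
    }
  }
  out
}
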