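#' Study-design configuration for the metastasis-enrichment experiment
#'
#' The canonical synthetic benchmark for the comparison stage: 25 primary vs
#' 61 metastatic samples on 2,000 probes, probe noise 0.12 log2, and three
#' planted metastasis-enriched gains (carriage 0.50 in metastases vs 0.04 in
#' primaries) on chromosomes 1, 7 and 17 -- the chromosomes where melanoma
#' progression gains concentrate.
#'
#' @param seed Integer seed.
#' @param noise_sd Probe noise (log2).
#' @return A [sim_config()] whose `planted_events` are the three truth gains.
#' @export
enrichment_design <- function(seed, noise_sd = 0.12) {
  ev <- bind_rows(
    planted_event(1, 3.0e6, 4.5e6, 0.8, frequency_primary = 0.04, frequency_metastatic = 0.5),
    planted_event(7, 2.0e6, 3.5e6, 1.1, frequency_primary = 0.04, frequency_metastatic = 0.5),
    planted_event(17, 1.0e6, 2.2e6, 0.6, frequency_primary = 0.04, frequency_metastatic = 0.5)
  )
  sim_config(n_primary = 25, n_metastatic = 61, n_probes = 2000,
             noise_sd = noise_sd, planted_events = ev, seed = seed)
}

#' Seeded recovery benchmark for the cohort-comparison stage
#'
#' Runs the full compare pipeline (simulate, CBS, mode-center, R-segments,
#' Fisher, q-values, ROIs) on [enrichment_design()] cohorts over independent
#' seeds and scores, per run, how many of the three planted regions intersect
#' a called gain ROI and the empirical false discovery rate among significant
#' R-segments (significant segments not overlapping any planted region).
#'
#' @param n_runs Number of independent seeded runs.
#' @param seed Master seed; run `i` uses a seed derived from it.
#' @param q_threshold ROI significance threshold.
#' @param alpha,n_perm CBS split test parameters.
#' @return Tibble: `run`, `n_recovered` (0-3), `n_significant`, `n_false`,
#'   `fdr`.
#' @export
run_enrichment_recovery <- function(n_runs = 20, seed = 1, q_threshold = 0.1,
                                    alpha = 0.01, n_perm = 100) {
  purrr::map_dfr(seq_len(n_runs), function(i) {
    cfg <- enrichment_design(seed = derive_seed(seed, 10L + i))
    sim <- simulate_cohorts(cfg)
    seg <- cbs_segment(sim$profiles, sim$samples, alpha = alpha, n_perm = n_perm,
                       seed = derive_seed(seed, 50L + i))
    res <- igc_compare(mode_center(seg), sim$samples, sim$map,
                       q_threshold = q_threshold)
    ev <- cfg$planted_events
    recovered <- vapply(seq_len(nrow(ev)), function(e) {
      any(res$rois$direction == "gain" & res$rois$chrom == ev$chrom[e] &
            res$rois$start < ev$end[e] & res$rois$end > ev$start[e])
    }, logical(1))
    sig <- res$records[res$records$q <= q_threshold, ]
    is_true <- vapply(seq_len(nrow(sig)), function(r) {
      any(ev$chrom == sig$chrom[r] & ev$start < sig$end[r] & ev$end > sig$start[r] &
            ev$direction == sig$direction[r])
    }, logical(1))
    tibble(run = i, n_recovered = sum(recovered), n_significant = nrow(sig),
           n_false = sum(!is_true),
           fdr = if (nrow(sig)) sum(!is_true) / nrow(sig) else 0)
  })
}

#' Planted three-subclass metastatic cohort
#'
#' Segment-shaped profiles mimicking the three genomic subclasses of
#' metastatic melanoma: one class with broad gains (chr 1, 6, 7, 8, 13, 20,
#' 22), one mixing gains (1, 7, 8) with losses (6, 9, 11), and one
#' hypoploidy-like class of scattered losses. Each class-defining chromosome
#' event is carried with probability `carriage` and chromosomes are broken
#' into blocks with segment-level Gaussian jitter so NMF restarts are
#' non-trivial.
#'
#' @param n_per_class Samples per subclass.
#' @param probes_per_chrom Probes per chromosome (22 autosomes).
#' @param noise_sd Segment-level jitter (log2).
#' @param carriage Per-sample probability of carrying each class event.
#' @param seed Integer seed.
#' @return List: `map`, `samples`, `seg`, `classes` (true labels).
#' @export
subclass_cohort <- function(n_per_class = 10, probes_per_chrom = 10,
                            noise_sd = 0.1, carriage = 0.9, seed = 1) {
  class_events <- list(
    list(gain = c(1, 6, 7, 8, 13, 20, 22), loss = integer(0)),
    list(gain = c(1, 7, 8), loss = c(6, 9, 11)),
    list(gain = integer(0), loss = c(4, 5, 9, 10, 14, 16))
  )
  map <- as_genome_map(purrr::map_dfr(1:22, function(chr) {
    tibble(probe_id = sprintf("c%02d_p%03d", chr, seq_len(probes_per_chrom)),
           chrom = chr, pos = 54800 * seq_len(probes_per_chrom))
  }))
  n <- 3 * n_per_class
  samples <- tibble(sample_id = sprintf("M%02d", seq_len(n)), group = "metastatic") %>%
    as_sample_sheet()
  classes <- rep(1:3, each = n_per_class)
  blocks_per_chrom <- max(2L, probes_per_chrom %/% 5L)
  with_seed(seed, {
    v <- matrix(0, nrow(map), n, dimnames = list(NULL, samples$sample_id))
    for (i in seq_len(n)) {
      evs <- class_events[[classes[i]]]
      for (chr in evs$gain) if (runif(1) < carriage) v[map$chrom == chr, i] <- 0.6
      for (chr in evs$loss) if (runif(1) < carriage) v[map$chrom == chr, i] <- -0.6
      for (chr in 1:22) {
        sel <- which(map$chrom == chr)
        blk <- cut(seq_along(sel), blocks_per_chrom, labels = FALSE)
        v[sel, i] <- v[sel, i] + rnorm(blocks_per_chrom, 0, noise_sd)[blk]
      }
    }
    seg <- purrr::map_dfr(samples$sample_id, function(sid) {
      purrr::map_dfr(1:22, function(chr) {
        sel <- which(map$chrom == chr)
        r <- rle(v[sel, sid])
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        tibble(sample_id = sid, chrom = chr,
               start = map$pos[sel[starts]],
               end = c(map$pos[sel[starts[-1]]], map$pos[max(sel)] + 1),
               n_probes = r$lengths, seg_mean = r$values)
      })
    })
    list(map = map, samples = samples, seg = seg, classes = classes)
  })
}

#' Consensus-NMF rank benchmark on the planted three-subclass cohort
#'
#' Reduces and non-negativizes the cohort, consensus-clusters it at ranks 3
#' and 4, and scores the rank-3 assignment accuracy against the planted
#' labels (best cluster-to-class mapping).
#'
#' @param seed Integer seed.
#' @param n_runs NMF restarts per rank.
#' @param ... Passed to [subclass_cohort()].
#' @return List: `rho_k3`, `rho_k4`, `accuracy`, `consensus_k3`
#'   (the `gnmf_consensus` object), `n_samples`.
#' @export
run_subclass_benchmark <- function(seed = 1, n_runs = 50, ...) {
  ch <- subclass_cohort(seed = derive_seed(seed, 7L), ...)
  V <- nonneg_transform(reduce_matrix(ch$seg, ch$samples, ch$map))
  rownames(V) <- ch$samples$sample_id
  res3 <- consensus_cluster(V, 3, n_runs = n_runs, seed = derive_seed(seed, 8L))
  res4 <- consensus_cluster(V, 4, n_runs = n_runs, seed = derive_seed(seed, 9L))
  tab <- table(res3$assignments$cluster, ch$classes)
  acc <- sum(apply(tab, 2, max)) / length(ch$classes)
  list(rho_k3 = res3$rho, rho_k4 = res4$rho, accuracy = acc,
       consensus_k3 = res3, n_samples = length(ch$classes))
}
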